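#' Parameters for the signed-hybrid co-expression network
#'
#' @param soft_power Soft-thresholding power beta (default 4).
#' @param min_module_size Smallest cluster kept as a module (default 30);
#'   smaller clusters go to module 0 (unassigned, the grey module).
#' @param cut_height_fraction Static tree-cut height as a fraction of the
#'   maximum merge height (default 0.75; with ten samples, correlation
#'   noise pushes unrelated genes' merges close to the maximum height, so
#'   a cut near 1 would swallow them into real modules).
#' @param min_kme Module members whose correlation with their own module
#'   eigengene falls below this are returned to module 0 (default 0.6).
#' @param filter_threshold Genes with mean log2(TPM+1) below this across
#'   the pure-species individuals are excluded upstream (default 1).
#' @return list of class `network_params`.
#' @export
network_params <- function(soft_power = 4, min_module_size = 30,
                           cut_height_fraction = 0.75,
                           min_kme = 0.6,
                           filter_threshold = 1) {
  if (soft_power < 1) stop("soft_power must be >= 1")
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  structure(list(soft_power = soft_power,
                 min_module_size = min_module_size,
                 cut_height_fraction = cut_height_fraction,
                 min_kme = min_kme,
                 filter_threshold = filter_threshold),
            class = "network_params")
}

#' Signed-hybrid adjacency
#'
#' a_ij = cor(i, j)^beta when the Pearson correlation is positive, 0
#' otherwise (negative correlations carry no edge weight in a
#' signed-hybrid network); the diagonal is 1.
#'
#' @param expr Numeric gene x sample matrix.
#' @param params [network_params()].
#' @return Symmetric gene x gene weight matrix.
#' @export
adjacency <- function(expr, params = network_params()) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need at least 3 samples")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene: ", rownames(expr)[sds == 0][1])
  r <- stats::cor(t(expr))
  a <- ifelse(r > 0, r^params$soft_power, 0)
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' connectivities k = row sums excluding the diagonal and the shared-
#' neighbor sum taken over u != i, j; TOM_ii = 1. Values lie in [0, 1];
#' 1 - TOM is the clustering dissimilarity.
#'
#' @param a Symmetric adjacency matrix from [adjacency()].
#' @return Symmetric similarity matrix.
#' @export
topological_overlap <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  num <- a0 %*% a0 + a0                        # shared neighbors + direct edge
  den <- outer(k, k, pmin) + 1 - a0
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect modules by average-linkage clustering of 1 - TOM
#'
#' The dendrogram is cut at `cut_height_fraction` of its maximum merge
#' height; clusters smaller than `min_module_size` are collected into
#' module 0 (unassigned), and surviving modules are renumbered by
#' decreasing size.
#'
#' @param tom Similarity matrix from [topological_overlap()].
#' @param params [network_params()].
#' @return Named integer vector gene -> module id (0 = unassigned).
#' @export
detect_modules <- function(tom, params = network_params()) {
  n <- nrow(tom)
  labels <- rownames(tom)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < params$min_module_size)
    return(stats::setNames(rep(0L, n), labels))
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  h <- params$cut_height_fraction * max(hc$height)
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= params$min_module_size]
  out <- rep(0L, n)
  if (length(keep)) {
    ord <- keep[order(-sizes[keep])]
    for (i in seq_along(ord)) out[cl == ord[i]] <- i
  }
  stats::setNames(out, labels)
}

#' Module eigengene
#'
#' The leading principal direction across samples of the gene-standardized
#' (zero mean, unit variance per gene) module submatrix, scaled to unit
#' norm and oriented so that its correlation with the mean standardized
#' module profile is non-negative.
#'
#' @param expr Numeric gene x sample matrix restricted to one module
#'   (>= 2 genes).
#' @return Named numeric sample vector with attribute `var_explained`.
#' @export
eigengene <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2) stop("module must contain >= 2 genes")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene in module: ", rownames(expr)[sds == 0][1])
  z <- t(scale(t(expr)))
  sv <- svd(z)
  v <- sv$v[, 1]
  if (stats::cor(v, colMeans(z)) < 0) v <- -v
  ve <- sv$d[1]^2 / sum(sv$d^2)
  structure(stats::setNames(v, colnames(expr)), var_explained = ve)
}

#' Correlate a module eigengene (or gene profile) with a trait
#'
#' Pearson correlation with a per-sample trait (e.g. species coded CF = 0,
#' PF = 1), with the two-sided p-value from the Student t-distribution:
#' t = r sqrt(n-2) / sqrt(1-r^2) on n-2 degrees of freedom. The same
#' contract serves module membership (gene vs own eigengene) and gene
#' significance (gene vs trait).
#'
#' @param eig Numeric per-sample vector.
#' @param trait Numeric per-sample vector; must not be constant.
#' @return list: `r`, `t`, `p`, `n`.
#' @export
module_trait <- function(eig, trait) {
  n <- length(eig)
  if (n < 3) stop("need n >= 3 samples")
  if (length(trait) != n) stop("trait length mismatch")
  if (stats::sd(trait) == 0) stop("trait is constant")
  r <- stats::cor(eig, trait)
  if (abs(r) >= 1) return(list(r = r, t = Inf * sign(r), p = 0, n = n))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, t = t, p = 2 * stats::pt(-abs(t), n - 2), n = n)
}

#' Prune weak module members by eigengene correlation
#'
#' With few samples, spurious correlations attach unrelated genes to a
#' module's dendrogram branch. Members whose correlation with their own
#' module eigengene (kME, the module-membership statistic) falls below
#' `min_kme` are returned to module 0, and modules dropping under the
#' minimum size are dissolved.
#'
#' @param expr Gene x sample matrix (same genes as `modules`).
#' @param modules Named gene -> module vector from [detect_modules()].
#' @param params [network_params()].
#' @return Pruned module assignment.
#' @export
prune_module_membership <- function(expr, modules, params = network_params()) {
  expr <- as.matrix(expr)
  for (m in sort(unique(modules[modules > 0]))) {
    ix <- which(modules == m)
    eg <- eigengene(expr[ix, , drop = FALSE])
    kme <- apply(expr[ix, , drop = FALSE], 1, stats::cor, y = eg)
    modules[ix[kme < params$min_kme]] <- 0L
  }
  for (m in sort(unique(modules[modules > 0])))
    if (sum(modules == m) < params$min_module_size) modules[modules == m] <- 0L
  # renumber by decreasing size
  ids <- sort(unique(modules[modules > 0]))
  if (length(ids)) {
    sz <- vapply(ids, function(m) sum(modules == m), 0L)
    out <- modules
    for (i in seq_along(ids)) out[modules == ids[order(-sz)][i]] <- i
    modules <- out
  }
  modules
}

#' Full co-expression analysis of one expression matrix
#'
#' Filters genes by mean expression, builds the signed-hybrid network,
#' detects modules, and computes per-module eigengenes, module-trait
#' correlations, per-gene module membership (correlation with the own
#' module's eigengene) and gene significance (correlation with the trait).
#'
#' @param expr Gene x sample matrix of log2(TPM+1) values (pure-species
#'   individuals).
#' @param trait Per-sample numeric trait (species 0/1).
#' @param params [network_params()].
#' @return list: `modules` (gene -> id), `eigengenes` (sample x module),
#'   `module_trait` data.frame, `membership` data.frame (gene, module, MM,
#'   GS), `n_filtered`.
#' @export
coexpression_analysis <- function(expr, trait, params = network_params()) {
  expr <- as.matrix(expr)
  keep <- rowMeans(expr) >= params$filter_threshold
  expr <- expr[keep, , drop = FALSE]
  a <- adjacency(expr, params)
  tom <- topological_overlap(a)
  mods <- detect_modules(tom, params)
  mods <- prune_module_membership(expr, mods, params)
  ids <- sort(unique(mods[mods > 0]))
  eigs <- sapply(ids, function(m) eigengene(expr[mods == m, , drop = FALSE]))
  if (length(ids)) colnames(eigs) <- paste0("ME", ids)
  mt <- if (length(ids)) do.call(rbind, lapply(seq_along(ids), function(i) {
    ct <- module_trait(eigs[, i], trait)
    data.frame(module = ids[i], size = sum(mods == ids[i]),
               r = ct$r, p = ct$p)
  })) else data.frame(module = integer(), size = integer(),
                      r = numeric(), p = numeric())
  mm <- gs <- rep(NA_real_, nrow(expr))
  for (i in seq_len(nrow(expr))) {
    gs[i] <- stats::cor(expr[i, ], trait)
    m <- mods[i]
    if (m > 0) mm[i] <- stats::cor(expr[i, ], eigs[, paste0("ME", m)])
  }
  list(modules = mods,
       eigengenes = if (length(ids)) eigs else NULL,
       module_trait = mt,
       membership = data.frame(gene_id = rownames(expr), module = unname(mods),
                               module_membership = mm, gene_significance = gs,
                               stringsAsFactors = FALSE),
       n_filtered = sum(!keep))
}
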