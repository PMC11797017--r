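#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for genes with all-positive counts,
#' the ratio of each sample's count to the gene's geometric mean is taken,
#' and the sample's factor is the median of those ratios, rescaled so the
#' factors have geometric mean 1.
#'
#' @param counts Numeric gene x sample count matrix.
#' @return Named positive numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop("no gene with positive counts in every sample; filter low genes first")
  logg <- rowMeans(log(counts[ok, , drop = FALSE]))
  sf <- apply(counts[ok, , drop = FALSE], 2,
              function(cc) exp(stats::median(log(cc) - logg)))
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald test for two groups
#'
#' Counts are normalized by median-of-ratios size factors; a moment
#' estimate of the dispersion alpha is taken from the pooled within-group
#' variance (Var = mu + alpha mu^2); by default a single common alpha (a
#' trimmed mean of the per-gene moment estimates) is shared across genes —
#' at five samples per group the per-gene estimate is far too noisy to plug
#' into a Wald statistic, and sharing it restores both calibration and
#' power. The log2 fold change uses a pseudo-count of 0.5; the Wald
#' statistic divides it by its delta-method standard error and is referred
#' to the standard normal.
#'
#' @param counts Gene x sample count matrix (one tissue).
#' @param groups Factor/character of length ncol(counts) with exactly two
#'   levels; the first level is the "first" group of the fold change
#'   (positive log2fc = first group higher).
#' @param contrast Label stored in the result (e.g. "CFvsPF").
#' @param sf Optional precomputed size factors.
#' @param dispersion `"common"` (default) shares one moment-estimated
#'   alpha across genes; `"per_gene"` plugs in each gene's own floored
#'   estimate (anti-conservative at small n; kept for comparison).
#' @return data.frame: `gene_id`, `contrast`, `base_mean`, `log2fc`, `se`,
#'   `p`, `p_adj` (BH), `direction`.
#' @export
nb_wald_test <- function(counts, groups, contrast = "CFvsPF", sf = NULL,
                         dispersion = c("common", "per_gene")) {
  dispersion <- match.arg(dispersion)
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  n1 <- sum(groups == lev[1]); n2 <- sum(groups == lev[2])
  if (min(n1, n2) < 2) stop("each group needs n >= 2")
  for (l in lev) if (all(counts[, groups == l] == 0))
    stop("group with all-zero counts: ", l)
  if (is.null(sf)) sf <- size_factors(counts)
  q <- sweep(counts, 2, sf, "/")
  q1 <- q[, groups == lev[1], drop = FALSE]
  q2 <- q[, groups == lev[2], drop = FALSE]
  mu1 <- rowMeans(q1); mu2 <- rowMeans(q2)
  v1 <- apply(q1, 1, stats::var); v2 <- apply(q2, 1, stats::var)
  vpool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mubar <- (n1 * mu1 + n2 * mu2) / (n1 + n2)
  araw <- (vpool - mubar) / mubar^2
  alpha <- if (dispersion == "common") {
    informative <- is.finite(araw) & mubar > 5
    if (!any(informative)) rep(0, length(araw))
    else rep(max(0, mean(araw[informative], trim = 0.05)), length(araw))
  } else {
    a <- pmax(0, araw)
    a[!is.finite(a)] <- 0
    a
  }
  c0 <- 0.5
  log2fc <- log2((mu1 + c0) / (mu2 + c0))
  se2 <- (1 / (n1 * log(2)^2)) * (1 / (mu1 + c0) + alpha) +
         (1 / (n2 * log(2)^2)) * (1 / (mu2 + c0) + alpha)
  se <- sqrt(se2)
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))
  d1 <- substr(lev[1], 1, 1); d2 <- substr(lev[2], 1, 1)
  data.frame(gene_id = rownames(counts), contrast = contrast,
             base_mean = (mu1 + mu2) / 2, log2fc = log2fc, se = se, p = p,
             p_adj = bh_adjust(p),
             direction = ifelse(log2fc >= 0, paste0(d1, ">", d2),
                                paste0(d2, ">", d1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Validates the inputs and applies the standard step-up procedure
#' (delegating to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Focal-tissue-specific differential expression rule
#'
#' A gene shows focal-tissue (brain) specific differential expression when
#' it is DE between species in the focal tissue and, in every other tissue
#' where it is DE, the change runs in the opposite direction (e.g. CF > PF
#' in the brain but PF > CF in the other tissue). DE means adjusted p below
#' `fdr` for the species contrast.
#'
#' @param de_by_tissue Named list of [nb_wald_test()] results, one per
#'   tissue; names are tissue names and must include `focal`.
#' @param focal Focal tissue name (default "brain").
#' @param fdr Adjusted-p cutoff (default 0.05).
#' @return data.frame: `gene_id`, `de_focal`, `focal_direction`,
#'   `n_other_de`, `n_other_same_direction`, `brain_specific`.
#' @export
brain_specific_rule <- function(de_by_tissue, focal = "brain", fdr = 0.05) {
  if (!focal %in% names(de_by_tissue))
    stop("missing focal tissue results: ", focal)
  others <- setdiff(names(de_by_tissue), focal)
  deb <- de_by_tissue[[focal]]
  genes <- deb$gene_id
  for (t in others) {
    if (!setequal(de_by_tissue[[t]]$gene_id, genes))
      stop("tissue ", t, " tested a different gene set")
  }
  de_focal <- deb$p_adj < fdr
  dir_focal <- deb$direction
  n_other_de <- n_same <- integer(length(genes))
  for (t in others) {
    dt <- de_by_tissue[[t]][match(genes, de_by_tissue[[t]]$gene_id), ]
    is_de <- dt$p_adj < fdr
    n_other_de <- n_other_de + is_de
    n_same <- n_same + (is_de & dt$direction == dir_focal)
  }
  data.frame(gene_id = genes, de_focal = de_focal,
             focal_direction = ifelse(de_focal, dir_focal, NA),
             n_other_de = n_other_de, n_other_same_direction = n_same,
             brain_specific = de_focal & n_same == 0,
             stringsAsFactors = FALSE)
}

#' Classify the hybrid inheritance pattern from three group means
#'
#' Orders the collared (C), pied (P) and hybrid (H) mean expression values
#' into a pattern string such as "P > H > C" and classifies the mode:
#' `intermediate` when the hybrid mean lies strictly between the parental
#' means, `transgressive_high`/`transgressive_low` when it falls outside
#' the parental range, and `tied` on exact equality with a parental bound.
#'
#' @param m_C,m_P,m_H Numeric vectors of group mean expression (TPM).
#' @param gene_id Optional gene ids.
#' @return data.frame: `gene_id`, `m_C`, `m_P`, `m_H`, `pattern`, `mode`.
#' @export
hybrid_pattern <- function(m_C, m_P, m_H, gene_id = NULL) {
  n <- length(m_C)
  stopifnot(length(m_P) == n, length(m_H) == n)
  if (any(c(m_C, m_P, m_H) < 0)) stop("means must be >= 0")
  if (is.null(gene_id)) gene_id <- as.character(seq_len(n))
  pattern <- character(n); mode <- character(n)
  for (i in seq_len(n)) {
    v <- c(C = m_C[i], P = m_P[i], H = m_H[i])
    ord <- names(sort(v, decreasing = TRUE))
    sep <- ifelse(diff(sort(v, decreasing = TRUE)) == 0, " = ", " > ")
    pattern[i] <- paste0(ord[1], sep[1], ord[2], sep[2], ord[3])
    lo <- min(m_C[i], m_P[i]); hi <- max(m_C[i], m_P[i])
    mode[i] <- if (m_H[i] == lo || m_H[i] == hi) "tied"
      else if (m_H[i] > hi) "transgressive_high"
      else if (m_H[i] < lo) "transgressive_low"
      else "intermediate"
  }
  data.frame(gene_id = gene_id, m_C = m_C, m_P = m_P, m_H = m_H,
             pattern = pattern, mode = mode, stringsAsFactors = FALSE)
}

#' Between-species variance fraction from group summary statistics
#'
#' One-way ANOVA decomposition for two groups given each group's mean,
#' standard deviation and size: the between-group sum of squares over the
#' total, SSspecies/SStotal. Computed from summaries it is identical to the
#' decomposition on the raw values.
#'
#' @param m1,sd1,n1 First group mean, sd, size.
#' @param m2,sd2,n2 Second group mean, sd, size.
#' @return list: `ss_between`, `ss_within`, `fraction`.
#' @export
variance_partition <- function(m1, sd1, n1, m2, sd2, n2) {
  if (min(n1, n2) < 2) stop("each group needs n >= 2")
  if (min(sd1, sd2) < 0) stop("sd must be >= 0")
  g <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - g)^2 + n2 * (m2 - g)^2
  ssw <- (n1 - 1) * sd1^2 + (n2 - 1) * sd2^2
  list(ss_between = ssb, ss_within = ssw,
       fraction = if (ssb + ssw == 0) 0 else ssb / (ssb + ssw))
}
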