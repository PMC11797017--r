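#' Hypergeometric over-representation test for gene sets
#'
#' For each set, the one-sided upper-tail hypergeometric probability of
#' observing at least the seen overlap between the query and the set,
#' given the universe (Fisher's exact test, greater alternative), followed
#' by Benjamini-Hochberg adjustment across sets.
#'
#' @param query Character vector of query gene ids (must lie in the
#'   universe).
#' @param sets Named list of character vectors (set members; members
#'   outside the universe are dropped).
#' @param universe Character vector of all testable gene ids.
#' @return data.frame: `set_id`, `set_size`, `overlap`, `p`, `p_adj`.
#' @export
overrep_test <- function(query, sets, universe) {
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) stop("query genes must be in the universe")
  N <- length(universe); n <- length(query)
  res <- lapply(names(sets), function(s) {
    members <- intersect(unique(sets[[s]]), universe)
    K <- length(members)
    ov <- length(intersect(query, members))
    # P(X >= ov), X ~ Hypergeom(N, K, n)
    p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = s, set_size = K, overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Directional gene-set test by resampling
#'
#' Each gene gets a signed score z = sign(direction) * qnorm(1 - p/2)
#' (p floored at 1e-15); a set's statistic is the mean score over its
#' members. The null is built by drawing `n_perm` random gene sets of the
#' same size from the universe without replacement; the upper-tail p uses
#' the add-one correction p = (1 + #{null >= observed}) / (n_perm + 1),
#' and `p_down` mirrors it for the lower tail.
#'
#' @param gene_stats data.frame with `gene_id`, `p` (typically the
#'   FDR-adjusted DE p-value) and `direction` (+1/-1 or a string whose sign
#'   is taken from `log2fc`-style sign; numeric expected).
#' @param sets Named list of member gene id vectors; every member must have
#'   a gene statistic.
#' @param n_perm Number of resamples (>= 100).
#' @param seed Integer seed for the resampling.
#' @return data.frame: `set_id`, `set_size`, `score`, `p_up`, `p_down`.
#' @export
directional_set_test <- function(gene_stats, sets, n_perm = 10000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  need <- c("gene_id", "p", "direction")
  if (!all(need %in% colnames(gene_stats)))
    stop("gene_stats needs columns gene_id, p, direction")
  dirn <- gene_stats$direction
  if (!is.numeric(dirn)) stop("direction must be numeric (+1 / -1)")
  p <- pmax(gene_stats$p, 1e-15)
  z <- stats::setNames(sign(dirn) * stats::qnorm(1 - p / 2),
                       gene_stats$gene_id)
  set.seed(seed)
  out <- lapply(names(sets), function(s) {
    members <- unique(sets[[s]])
    if (!all(members %in% names(z)))
      stop("set ", s, " has members without gene statistics")
    k <- length(members)
    obs <- mean(z[members])
    null <- vapply(seq_len(n_perm),
                   function(i) mean(z[sample.int(length(z), k)]), 0)
    data.frame(set_id = s, set_size = k, score = obs,
               p_up = (1 + sum(null >= obs)) / (n_perm + 1),
               p_down = (1 + sum(null <= obs)) / (n_perm + 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
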