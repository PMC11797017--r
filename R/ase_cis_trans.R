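#' Allele-specific expression test per gene
#'
#' For each hybrid, maternal and paternal reads are summed over the gene's
#' phased SNPs and tested against a balanced 1:1 ratio with a two-sided
#' exact binomial test; per-hybrid p-values are combined across hybrids by
#' Fisher's method (chi-square with 2k df). Genes with fewer than
#' `min_snps` SNPs or fewer than `min_reads` total informative reads are
#' flagged underpowered. An optional beta-binomial variant (fixed
#' intra-class correlation `rho`) absorbs overdispersion across reads.
#'
#' @param table An `AlleleCountTable` (see [read_allele_counts()]).
#' @param min_snps Minimum phased SNPs per gene (default 1).
#' @param min_reads Minimum summed informative reads per gene (default 20).
#' @param rho Beta-binomial intra-class correlation; 0 (default) uses the
#'   exact binomial.
#' @return data.frame per gene: `gene_id`, `n_snps`, `n_hybrids`,
#'   `total_reads`, `maternal_fraction`, `p_combined`, `sufficient`.
#' @export
ase_test <- function(table, min_snps = 1, min_reads = 20, rho = 0) {
  need <- c("hybrid_id", "gene_id", "maternal_reads", "paternal_reads")
  if (!all(need %in% colnames(table)))
    stop("allele count table must be phased: needs ", paste(need, collapse = ", "))
  out <- lapply(split(seq_len(nrow(table)), table$gene_id), function(ix) {
    sub <- table[ix, ]
    n_snps <- length(unique(sub$snp_id))
    per_h <- split(seq_len(nrow(sub)), sub$hybrid_id)
    ps <- vapply(per_h, function(hx) {
      mat <- sum(sub$maternal_reads[hx]); pat <- sum(sub$paternal_reads[hx])
      n <- mat + pat
      if (n == 0) return(NA_real_)
      if (rho > 0) betabinom_test(mat, n, rho) else binom_two_sided(mat, n)
    }, 0)
    ps <- ps[!is.na(ps)]
    tot <- sum(sub$maternal_reads) + sum(sub$paternal_reads)
    pc <- if (length(ps)) fisher_combine(ps) else NA_real_
    data.frame(gene_id = sub$gene_id[1], n_snps = n_snps,
               n_hybrids = length(ps), total_reads = tot,
               maternal_fraction = sum(sub$maternal_reads) / max(tot, 1),
               p_combined = pc,
               sufficient = n_snps >= min_snps && tot >= min_reads,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# two-sided exact binomial p at p0 = 1/2: by symmetry, the two-sided p is
# twice the smaller tail (capped at 1), which equals the minlike rule here
binom_two_sided <- function(x, n) {
  min(1, 2 * min(stats::pbinom(x, n, 0.5),
                 stats::pbinom(n - x, n, 0.5)))
}

# beta-binomial two-sided tail at mean 1/2 with intra-class correlation rho
betabinom_test <- function(x, n, rho) {
  ab <- (1 - rho) / (2 * rho)      # symmetric Beta(a, a) with icc rho
  dens <- vapply(0:n, function(k)
    exp(lchoose(n, k) + lbeta(k + ab, n - k + ab) - lbeta(ab, ab)), 0)
  lo <- sum(dens[seq_len(x + 1)])
  hi <- sum(dens[seq(x + 1, n + 1)])
  min(1, 2 * min(lo, hi))
}

fisher_combine <- function(p) {
  p <- pmax(p, 1e-300)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Classify species expression divergence as cis-containing or
#' trans-consistent
#'
#' Defined only for genes differentially expressed between the species in
#' the focal tissue. A gene is called `cis` when the combined ASE p-value
#' (BH-adjusted across tested genes) falls below `fdr` and the direction
#' of allelic imbalance is concordant with the species difference given
#' the cross orientation; `trans_consistent` when ASE is non-significant
#' with at least `min_reads` informative reads (absence of ASE, with
#' power, is the trans signature); otherwise `undetermined`.
#'
#' @param ase Result of [ase_test()].
#' @param de [nb_wald_test()] result for the species contrast (CF vs PF,
#'   positive log2fc = CF higher) in the focal tissue.
#' @param cross Cross direction shared by the hybrids
#'   (default "CFfather_PFmother": paternal allele = CF).
#' @param fdr Significance cutoff on BH-adjusted combined p (default 0.05).
#' @param de_fdr Adjusted-p cutoff defining which genes are DE.
#' @return data.frame: `gene_id`, `maternal_fraction`, `p_combined`,
#'   `p_adj`, `concordant`, `call`.
#' @export
classify_cis_trans <- function(ase, de, cross = "CFfather_PFmother",
                               fdr = 0.05, de_fdr = 0.05) {
  de_genes <- de$gene_id[de$p_adj < de_fdr]
  not_de <- setdiff(ase$gene_id, de_genes)
  if (length(not_de))
    stop("classification is only defined for species-DE genes; not DE: ",
         paste(utils::head(not_de, 3), collapse = ", "))
  x <- ase
  x$p_adj <- bh_adjust(x$p_combined)
  lfc <- de$log2fc[match(x$gene_id, de$gene_id)]
  # CF-higher genes should show paternal excess under a CF-father cross
  cf_frac <- if (cross == "CFfather_PFmother") 1 - x$maternal_fraction
             else x$maternal_fraction
  x$concordant <- (lfc > 0) == (cf_frac > 0.5)
  x$call <- ifelse(!x$sufficient, "undetermined",
            ifelse(x$p_adj < fdr & x$concordant, "cis",
            ifelse(x$p_adj >= fdr, "trans_consistent", "undetermined")))
  x[, c("gene_id", "maternal_fraction", "p_combined", "p_adj",
        "concordant", "call")]
}
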