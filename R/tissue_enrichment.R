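#' Parameters for tissue-enrichment classification
#'
#' A gene is called expressed in a tissue when the mean log2(TPM + 1) over
#' that tissue's samples is at least `expr_threshold`. Fold enrichment is
#' the ratio of the focal tissue's mean raw TPM to the highest other
#' tissue's mean raw TPM, with inclusive 5x ("enriched") and 50x ("highly
#' enriched") cutoffs.
#'
#' @param expr_threshold Expression call threshold on mean log2(TPM+1).
#' @param enriched_fold,high_fold Inclusive fold cutoffs (5 and 50).
#' @param focal_tissue Tissue the enrichment is relative to.
#' @return list of class `enrichment_params`.
#' @export
enrichment_params <- function(expr_threshold = 1, enriched_fold = 5,
                              high_fold = 50, focal_tissue = "brain") {
  if (!(enriched_fold > 0 && enriched_fold < high_fold))
    stop("need 0 < enriched_fold < high_fold")
  structure(list(expr_threshold = expr_threshold,
                 enriched_fold = enriched_fold, high_fold = high_fold,
                 focal_tissue = focal_tissue), class = "enrichment_params")
}

tissue_means <- function(m, samples) {
  tiss <- unique(samples$tissue)
  out <- sapply(tiss, function(t) {
    cols <- samples$sample_id[samples$tissue == t]
    if (!length(cols)) stop("tissue with zero samples: ", t)
    rowMeans(m$values[, cols, drop = FALSE])
  })
  colnames(out) <- tiss
  out
}

#' Call in which tissues each gene is expressed
#'
#' @param m `ExpressionMatrix` with unit `log2tpm1`.
#' @param samples Sample table (all individuals pooled).
#' @param params [enrichment_params()].
#' @return Logical gene x tissue matrix (TRUE = expressed; inclusive
#'   threshold).
#' @export
call_expressed <- function(m, samples, params = enrichment_params()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "log2tpm1") stop("call_expressed expects unit = 'log2tpm1'")
  tissue_means(m, samples) >= params$expr_threshold
}

#' Fold-enrichment classification relative to the focal tissue
#'
#' For every gene expressed in the focal tissue, fold enrichment is the
#' mean focal-tissue TPM divided by the largest mean TPM among the other
#' tissues (raw TPM, not the log transform). If no other tissue has any
#' expression the fold is +Inf and the gene is focal-only. Classes (by
#' inclusive thresholds): `not_expressed`, `expressed`, `enriched` (>= 5x),
#' `highly_enriched` (>= 50x). Genes not expressed in the focal tissue get
#' their class from the expression calls and a missing fold.
#'
#' @param tpm `ExpressionMatrix` with unit `tpm`.
#' @param samples Sample table.
#' @param params [enrichment_params()].
#' @return data.frame with `gene_id`, `expressed_focal`, `n_tissues_expressed`,
#'   `fold_enrichment`, `focal_only`, `class`.
#' @export
fold_enrichment <- function(tpm, samples, params = enrichment_params()) {
  stopifnot(inherits(tpm, "ExpressionMatrix"))
  if (tpm$unit != "tpm") stop("fold_enrichment expects unit = 'tpm'")
  focal <- params$focal_tissue
  if (!focal %in% samples$tissue) stop("focal tissue absent: ", focal)
  logm <- log_transform(tpm)
  expr <- call_expressed(logm, samples, params)
  mt <- tissue_means(tpm, samples)
  other <- setdiff(colnames(mt), focal)
  best_other <- apply(mt[, other, drop = FALSE], 1, max)
  fold <- ifelse(expr[, focal], mt[, focal] / best_other, NA_real_)
  focal_only <- expr[, focal] & rowSums(expr[, other, drop = FALSE]) == 0
  cls <- ifelse(!expr[, focal],
                ifelse(rowSums(expr) > 0, "expressed", "not_expressed"),
         ifelse(fold >= params$high_fold, "highly_enriched",
         ifelse(fold >= params$enriched_fold, "enriched", "expressed")))
  data.frame(gene_id = rownames(tpm$values),
             expressed_focal = unname(expr[, focal]),
             n_tissues_expressed = unname(rowSums(expr)),
             fold_enrichment = unname(fold),
             focal_only = unname(focal_only),
             class = unname(cls), stringsAsFactors = FALSE)
}
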