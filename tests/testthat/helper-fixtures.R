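# shared generators for tests; all pure functions of their seed

# minimal count matrix with gene/sample names
toy_counts <- function(values, lengths = rep(1000L, nrow(values))) {
  rownames(values) <- paste0("g", seq_len(nrow(values)))
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  expression_matrix(values, "counts", gene_lengths = lengths)
}

# sample table for one tissue, n per species (+ hybrids)
toy_samples <- function(n_cf = 5, n_pf = 5, n_f1 = 0, tissue = "brain") {
  sp <- c(rep("CF", n_cf), rep("PF", n_pf), rep("F1", n_f1))
  validate_sample_table(data.frame(
    sample_id = paste0("s", seq_along(sp)),
    species = sp, tissue = tissue,
    cross = ifelse(sp == "F1", "CFfather_PFmother", "none"),
    stringsAsFactors = FALSE))
}

# gaussian latent-factor expression with two planted modules + noise,
# mirroring the study's ten pure-species brain samples
planted_module_profiles <- function(seed, sizes = c(50, 60), n_noise = 100,
                                    rho = 0.8, n_samp = 10, trait_shift = 2) {
  set.seed(seed)
  sp <- rep(0:1, each = n_samp / 2)
  blocks <- lapply(seq_along(sizes), function(i) {
    z <- stats::rnorm(n_samp) + if (i == 1) trait_shift * (sp - 0.5) else 0
    sqrt(rho) * matrix(z, sizes[i], n_samp, byrow = TRUE) +
      sqrt(1 - rho) * matrix(stats::rnorm(sizes[i] * n_samp), sizes[i])
  })
  expr <- rbind(do.call(rbind, blocks),
                matrix(stats::rnorm(n_noise * n_samp), n_noise, n_samp))
  rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  colnames(expr) <- paste0("s", seq_len(n_samp))
  list(expr = expr,
       truth = c(rep(seq_along(sizes), sizes), rep(0L, n_noise)),
       trait = sp)
}

# brain-tissue pure-species count submatrix + groups from a simulation
brain_submatrix <- function(sim) {
  cols <- sim$samples$sample_id[sim$samples$tissue == "brain" &
                                sim$samples$species %in% c("CF", "PF")]
  list(counts = sim$counts$values[, cols],
       groups = sim$samples$species[match(cols, sim$samples$sample_id)])
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
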