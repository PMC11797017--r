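#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()],
#' optionally overridden from a YAML file. Input paths may be omitted when
#' `simulate: true`, in which case fixtures are generated under
#' `outdir/fixtures` from the seed.
#'
#' @param path Optional YAML file whose entries override the defaults.
#' @param ... Named overrides applied after the file.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    outdir = "hybridexpr_out",
    simulate = TRUE,
    inputs = list(counts = NULL, samples = NULL, gene_sets = NULL,
                  allele_counts = NULL, vcf = NULL, genome = NULL,
                  gff = NULL, domains = NULL, tree = NULL, states = NULL),
    thresholds = list(fdr = 0.05, expr_threshold = 1, enriched_fold = 5,
                      high_fold = 50, soft_power = 4, min_module_size = 30,
                      cut_height_fraction = 0.995, ase_min_snps = 1,
                      ase_min_reads = 20, flank_bp = 5000, ml_rate = 0.1),
    sim = list(n_genes = 600, frac_tissue_enriched = 0.1,
               frac_species_de = 0.05,
               module_spec = list(list(size = 40, cor = 0.8, trait_assoc = TRUE),
                                  list(size = 50, cor = 0.8))),
    stages = list(enrichment = TRUE, de = TRUE, patterns = TRUE,
                  sets = TRUE, modules = TRUE, ase = TRUE,
                  variants = TRUE, ancestral = TRUE))
  if (!is.null(path)) cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  cfg <- utils::modifyList(cfg, list(...))
  cfg
}

stage_log <- function(stage, t0) {
  message(sprintf("[hybridexpr] %-12s %.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full pipeline
#'
#' Stages run in dependency order: TPM normalization, tissue-enrichment
#' classification, per-tissue species differential expression with the
#' focal-tissue specificity rule, hybrid-pattern classification and
#' variance partitioning, gene-set tests, co-expression modules,
#' ASE-based cis/trans classification, the fixed-difference scan, and
#' ancestral reconstruction. Every stage writes a TSV under
#' `config$outdir`; the same config and seed give byte-identical outputs.
#'
#' @param config List from [pipeline_config()] (or a YAML path).
#' @return Invisible report list with per-stage summaries.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  report <- list(defaults = c(
    "fdr cutoff 0.05 (DE calls; threshold not printed by comparable studies)",
    "TPM uses summed-exon transcript length",
    "log base 2 throughout"))
  t0 <- as.numeric(Sys.time())

  sim <- NULL
  if (isTRUE(config$simulate)) {
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    simc <- simulate_counts(scfg)
    counts <- simc$counts; samples <- simc$samples
    ase_tab <- simulate_allele_counts(scfg, simc$truth)
    gsim <- simulate_genotypes_and_sequence(scfg)
    tsim <- simulate_tree_with_site(40, seed = config$seed + 3L)
    fx <- file.path(config$outdir, "fixtures")
    dir.create(fx, showWarnings = FALSE)
    write_expression_tsv(counts, file.path(fx, "counts.tsv"))
    write_results_tsv(samples, file.path(fx, "samples.tsv"))
    write_vcf(gsim, file.path(fx, "population.vcf"))
    write_genome_fasta(gsim, file.path(fx, "genome.fa"))
    write_gene_models_gff3(gsim$gene_models, file.path(fx, "genes.gff3"))
    write_results_tsv(simc$truth, file.path(fx, "truth_genes.tsv"))
    write_results_tsv(gsim$site_truth, file.path(fx, "truth_sites.tsv"))
    sim <- list(counts = simc, ase = ase_tab, geno = gsim, tree = tsim)
    stage_log("simulate", t0)
  } else {
    counts <- read_counts(config$inputs$counts)
    samples <- read_sample_table(config$inputs$samples)
    ase_tab <- if (!is.null(config$inputs$allele_counts))
      read_allele_counts(config$inputs$allele_counts) else NULL
  }
  focal <- samples$tissue[1]
  tissues <- unique(samples$tissue)

  tpm <- compute_tpm(counts)
  logm <- log_transform(tpm)
  write_expression_tsv(tpm, file.path(config$outdir, "tpm.tsv"))
  stage_log("tpm", t0)

  enr <- NULL
  if (isTRUE(config$stages$enrichment)) {
    ep <- enrichment_params(th$expr_threshold, th$enriched_fold,
                            th$high_fold, focal)
    enr <- fold_enrichment(tpm, samples, ep)
    write_results_tsv(enr, file.path(config$outdir, "enrichment.tsv"))
    report$enrichment <- table(enr$class)
    stage_log("enrichment", t0)
  }

  de_by_tissue <- NULL; spec_rule <- NULL
  if (isTRUE(config$stages$de)) {
    de_by_tissue <- lapply(tissues, function(t) {
      cols <- samples$sample_id[samples$tissue == t &
                                samples$species %in% c("CF", "PF")]
      grp <- samples$species[match(cols, samples$sample_id)]
      nb_wald_test(counts$values[, cols], grp, contrast = "CFvsPF")
    })
    names(de_by_tissue) <- tissues
    for (t in tissues)
      write_results_tsv(de_by_tissue[[t]],
                        file.path(config$outdir, paste0("de_", t, ".tsv")),
                        header_comments = "DE call threshold: adjusted p < 0.05 (default, configurable)")
    spec_rule <- brain_specific_rule(de_by_tissue, focal, th$fdr)
    write_results_tsv(spec_rule, file.path(config$outdir, "brain_specific.tsv"))
    report$de <- c(n_de_focal = sum(spec_rule$de_focal),
                   n_brain_specific = sum(spec_rule$brain_specific))
    stage_log("de", t0)
  }

  if (isTRUE(config$stages$patterns) && !is.null(de_by_tissue)) {
    bcols <- function(sp) samples$sample_id[samples$tissue == focal &
                                            samples$species == sp]
    tb <- tpm$values
    mC <- rowMeans(tb[, bcols("CF"), drop = FALSE])
    mP <- rowMeans(tb[, bcols("PF"), drop = FALSE])
    mH <- rowMeans(tb[, bcols("F1"), drop = FALSE])
    sdC <- apply(tb[, bcols("CF"), drop = FALSE], 1, stats::sd)
    sdP <- apply(tb[, bcols("PF"), drop = FALSE], 1, stats::sd)
    de_g <- de_by_tissue[[focal]]$gene_id[de_by_tissue[[focal]]$p_adj < th$fdr]
    idx <- match(de_g, rownames(tb))
    pat <- hybrid_pattern(mC[idx], mP[idx], mH[idx], gene_id = de_g)
    nC <- sum(samples$tissue == focal & samples$species == "CF")
    nP <- sum(samples$tissue == focal & samples$species == "PF")
    pat$var_fraction <- vapply(seq_along(idx), function(i)
      variance_partition(mC[idx[i]], sdC[idx[i]], nC,
                         mP[idx[i]], sdP[idx[i]], nP)$fraction, 0)
    write_results_tsv(pat, file.path(config$outdir, "hybrid_patterns.tsv"))
    report$patterns <- table(pat$mode)
    stage_log("patterns", t0)
  }

  if (isTRUE(config$stages$sets) && !is.null(enr)) {
    sets <- if (!is.null(config$inputs$gene_sets))
      read_gene_sets(config$inputs$gene_sets)
    else { # demo sets over the simulated universe
      set.seed(config$seed + 10L)
      u <- enr$gene_id[enr$class != "not_expressed"]
      stats::setNames(lapply(1:10, function(i) sample(u, 25)),
                      paste0("set", 1:10))
    }
    universe <- enr$gene_id[enr$class != "not_expressed"]
    query <- enr$gene_id[enr$class %in% c("enriched", "highly_enriched")]
    sets <- lapply(sets, intersect, universe)
    sets <- sets[vapply(sets, length, 0L) > 0]
    if (length(sets) && length(query)) {
      ov <- overrep_test(query, sets, universe)
      write_results_tsv(ov, file.path(config$outdir, "gene_sets_overrep.tsv"))
      if (!is.null(de_by_tissue)) {
        deb <- de_by_tissue[[focal]]
        gs <- data.frame(gene_id = deb$gene_id, p = deb$p_adj,
                         direction = sign(deb$log2fc))
        gs <- gs[gs$gene_id %in% universe, ]
        sets2 <- lapply(sets, intersect, gs$gene_id)
        sets2 <- sets2[vapply(sets2, length, 0L) > 0]
        dr <- directional_set_test(gs, sets2, n_perm = 1000,
                                   seed = config$seed + 11L)
        write_results_tsv(dr, file.path(config$outdir, "gene_sets_directional.tsv"))
      }
      report$sets <- nrow(ov)
    }
    stage_log("sets", t0)
  }

  if (isTRUE(config$stages$modules)) {
    np <- network_params(soft_power = th$soft_power,
                         min_module_size = th$min_module_size,
                         cut_height_fraction = th$cut_height_fraction,
                         filter_threshold = th$expr_threshold)
    pure <- samples$sample_id[samples$tissue == focal &
                              samples$species %in% c("CF", "PF")]
    trait <- samples$species_code[match(pure, samples$sample_id)]
    cx <- coexpression_analysis(logm$values[, pure], trait, np)
    write_results_tsv(cx$membership, file.path(config$outdir, "modules.tsv"))
    write_results_tsv(cx$module_trait, file.path(config$outdir, "module_trait.tsv"))
    report$modules <- nrow(cx$module_trait)
    stage_log("modules", t0)
  }

  if (isTRUE(config$stages$ase) && !is.null(ase_tab) && nrow(ase_tab) &&
      !is.null(de_by_tissue)) {
    ast <- ase_test(ase_tab, th$ase_min_snps, th$ase_min_reads)
    deb <- de_by_tissue[[focal]]
    de_g <- deb$gene_id[deb$p_adj < th$fdr]
    ast <- ast[ast$gene_id %in% de_g, ]
    if (nrow(ast)) {
      ct <- classify_cis_trans(ast, deb, fdr = th$fdr, de_fdr = th$fdr)
      write_results_tsv(ct, file.path(config$outdir, "cis_trans.tsv"))
      report$ase <- table(ct$call)
    }
    stage_log("ase", t0)
  }

  if (isTRUE(config$stages$variants)) {
    if (!is.null(sim)) {
      vcf <- sim$geno$vcf; spmap <- sim$geno$species_map
      gmods <- sim$geno$gene_models; genome <- sim$geno$genome
      doms <- sim$geno$domains
    } else if (!is.null(config$inputs$vcf)) {
      vcf <- read_vcf_genotypes(config$inputs$vcf)
      spmap_df <- utils::read.delim(config$inputs$species_map)
      spmap <- stats::setNames(spmap_df[[2]], spmap_df[[1]])
      gmods <- read_gene_models(config$inputs$gff, th$flank_bp)
      gseq <- Biostrings::readDNAStringSet(config$inputs$genome)
      genome <- stats::setNames(as.character(gseq), names(gseq))
      doms <- if (!is.null(config$inputs$domains))
        read_domains(config$inputs$domains) else NULL
    } else vcf <- NULL
    if (!is.null(vcf)) {
      fdann <- scan_fixed_differences(vcf, spmap, gmods, genome, doms)
      write_results_tsv(fdann, file.path(config$outdir, "fixed_differences.tsv"))
      report$variants <- nrow(fdann)
      stage_log("variants", t0)
    }
  }

  if (isTRUE(config$stages$ancestral)) {
    if (!is.null(sim)) {
      tree <- sim$tree$tree; tips <- sim$tree$tip_states
    } else if (!is.null(config$inputs$tree)) {
      tw <- read_newick_with_characters(config$inputs$tree,
                                        config$inputs$states)
      tree <- tw$tree; tips <- tw$tip_states
    } else tree <- NULL
    if (!is.null(tree)) {
      fi <- fitch_ancestral(tree, tips)
      post <- ml_ancestral(tree, tips, th$ml_rate)
      anc <- data.frame(state = names(post), ml_posterior = unname(post),
                        in_fitch_root_set = names(post) %in% fi$root_states,
                        tip_count = as.integer(tip_state_tally(tips)[names(post)]))
      anc$tip_count[is.na(anc$tip_count)] <- 0L
      write_results_tsv(anc, file.path(config$outdir, "ancestral.tsv"),
                        header_comments = sprintf("fitch parsimony score: %d", fi$score))
      report$ancestral <- fi$score
      stage_log("ancestral", t0)
    }
  }
  invisible(report)
}
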