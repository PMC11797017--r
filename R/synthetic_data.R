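#' Configuration for the synthetic study generator
#'
#' Defaults emulate the study design the pipeline was built for: 5 collared
#' (CF) and 5 pied (PF) flycatcher males plus 3 F1 hybrids (all with CF
#' fathers and PF mothers), each sampled in five tissues, with planted
#' brain-enriched genes, species-DE genes split into cis and trans
#' regulatory architectures, planted co-expression modules, and hybrid
#' inheritance modes.
#'
#' @param n_genes Number of genes.
#' @param n_per_species Pure-species males per species (default 5).
#' @param n_hybrids F1 males (default 3).
#' @param tissues Tissue names; the first is the focal (brain) tissue.
#' @param nb_dispersion Negative-binomial dispersion alpha, Var = mu +
#'   alpha*mu^2 (default 0.05, typical of bulk RNA-seq; 0 gives Poisson).
#' @param frac_tissue_enriched Fraction of genes planted brain-enriched;
#'   half at 10x the best other tissue (twice the 5x class boundary), half
#'   at 100x (twice the 50x boundary).
#' @param frac_species_de Fraction of genes planted species-DE in brain.
#' @param effect_size_log2fc Planted |log2 fold change| for DE genes.
#' @param frac_cis Fraction of DE genes with cis architecture (rest trans).
#' @param module_spec List of planted co-expression modules, each
#'   `list(size =, cor =, trait_assoc =)`; gene pairs within a module share
#'   a latent factor giving expected profile correlation `cor`; a
#'   trait-associated module's latent factor is shifted between species.
#' @param hybrid_mode_probs Named probabilities over inheritance modes
#'   `additive`, `dominant_CF`, `dominant_PF`, `transgressive` used to label
#'   DE genes. Additive is mid-parent on the log2 scale; transgressive falls
#'   outside the parental range by the planted effect size.
#' @param ase_mean_reads Mean phased reads per gene per hybrid for the
#'   allele-specific counts.
#' @param n_resequenced_per_species Individuals per species in the
#'   population VCF (default 19).
#' @param flank_bp Flank window size for the variant scan (default 5000).
#' @param library_size_sdlog Log-normal sd of per-sample library size
#'   factors (default 0.2).
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_per_species = 5,
                       n_hybrids = 3,
                       tissues = c("brain", "heart", "liver", "kidney", "testis"),
                       nb_dispersion = 0.05,
                       frac_tissue_enriched = 0.10,
                       frac_species_de = 0.05,
                       effect_size_log2fc = 1,
                       frac_cis = 0.5,
                       module_spec = NULL,
                       hybrid_mode_probs = c(additive = 0.7, dominant_CF = 0.1,
                                             dominant_PF = 0.1, transgressive = 0.1),
                       ase_mean_reads = 500,
                       n_resequenced_per_species = 19,
                       flank_bp = 5000,
                       library_size_sdlog = 0.2,
                       seed = 1L) {
  fr <- c(frac_tissue_enriched, frac_species_de, frac_cis)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (frac_tissue_enriched + frac_species_de > 1)
    stop("planted fractions sum to more than 1")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (abs(sum(hybrid_mode_probs) - 1) > 1e-8)
    stop("hybrid_mode_probs must sum to 1")
  if (!is.null(module_spec)) {
    sz <- vapply(module_spec, `[[`, 0, "size")
    if (any(sz < 2)) stop("module sizes must be >= 2")
  }
  structure(as.list(environment()), class = "sim_config")
}

mode_levels <- c("additive", "dominant_CF", "dominant_PF", "transgressive")

#' Simulate the count study with planted ground truth
#'
#' Draws per-gene baseline expression levels, applies tissue, species,
#' hybrid-mode and module effects on the log2 scale, and samples
#' negative-binomial counts with log-normal library-size factors. Ground
#' truth class labels are derived by applying the pipeline's own
#' classification rules to the noise-free expected TPM, so every label is
#' recoverable in expectation.
#'
#' @param cfg A [sim_config()].
#' @return list with `counts` (ExpressionMatrix of counts), `samples`
#'   (sample table), and `truth` (per-gene data.frame plus attributes
#'   `expr_levels`, the noise-free expression array).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  tissues <- cfg$tissues
  focal <- tissues[1]
  genes <- sprintf("g%04d", seq_len(ng))

  ## individuals (shared across tissues, as in the study design)
  ind <- c(paste0("CF", seq_len(cfg$n_per_species)),
           paste0("PF", seq_len(cfg$n_per_species)),
           paste0("F1", seq_len(cfg$n_hybrids)))
  grp <- c(rep("CF", cfg$n_per_species), rep("PF", cfg$n_per_species),
           rep("F1", cfg$n_hybrids))
  samples <- expand.grid(individual = ind, tissue = tissues,
                         stringsAsFactors = FALSE)
  samples$species <- grp[match(samples$individual, ind)]
  samples$sample_id <- paste(samples$individual, samples$tissue, sep = "_")
  samples$cross <- ifelse(samples$species == "F1", "CFfather_PFmother", "none")
  samples <- validate_sample_table(
    samples[, c("sample_id", "species", "tissue", "cross")])
  samples$individual <- sub("_[^_]+$", "", samples$sample_id)

  ## gene index blocks: enriched | DE | modules | null
  n_te <- round(cfg$frac_tissue_enriched * ng)
  n_de <- round(cfg$frac_species_de * ng)
  mod_sizes <- if (is.null(cfg$module_spec)) integer(0) else
    vapply(cfg$module_spec, `[[`, 0, "size")
  if (n_te + n_de + sum(mod_sizes) > ng)
    stop("planted genes exceed n_genes")
  idx_te <- seq_len(n_te)
  idx_de <- seq_len(n_de) + n_te
  idx_mod <- if (sum(mod_sizes)) split(seq_len(sum(mod_sizes)) + n_te + n_de,
                                       rep(seq_along(mod_sizes), mod_sizes))
             else list()

  ## baseline levels (TPM-like units) and tissue profiles
  base <- exp(stats::rnorm(ng, log(50), 1.2))
  tf <- matrix(exp(stats::rnorm(ng * length(tissues), 0, 0.5)),
               ng, length(tissues), dimnames = list(genes, tissues))
  e <- base * tf  # gene x tissue expected level, pre species effects

  ## planted tissue enrichment: other tissues at brain/fold, so the fold
  ## survives per-tissue TPM renormalization (raising brain instead would
  ## inflate the brain normalizer and shrink every realized fold)
  planted_fold <- rep(NA_real_, ng)
  if (n_te) {
    planted_fold[idx_te] <- rep(c(10, 100), length.out = n_te)
    e[idx_te, 1] <- pmax(e[idx_te, 1], 20)
    e[idx_te, -1] <- e[idx_te, 1] / planted_fold[idx_te]
  }

  ## species / hybrid levels in the focal tissue
  de <- rep(FALSE, ng); lfc <- rep(0, ng)
  arch <- rep(NA_character_, ng); hmode <- rep(NA_character_, ng)
  if (n_de) {
    de[idx_de] <- TRUE
    e[idx_de, 1] <- pmax(e[idx_de, 1], 20)  # DE planted in expressed genes
    lfc[idx_de] <- cfg$effect_size_log2fc * sample(c(-1, 1), n_de, TRUE)
    n_cis <- round(cfg$frac_cis * n_de)
    arch[idx_de] <- sample(c(rep("cis", n_cis), rep("trans", n_de - n_cis)))
    hmode[idx_de] <- sample(mode_levels, n_de, TRUE, cfg$hybrid_mode_probs)
  }
  eCF <- ePF <- eH <- e
  eCF[, 1] <- e[, 1] * 2^(lfc / 2)
  ePF[, 1] <- e[, 1] * 2^(-lfc / 2)
  hi <- pmax(eCF[, 1], ePF[, 1]); lo <- pmin(eCF[, 1], ePF[, 1])
  eH[, 1] <- ifelse(is.na(hmode), e[, 1],
    ifelse(hmode == "additive", sqrt(eCF[, 1] * ePF[, 1]),
    ifelse(hmode == "dominant_CF", eCF[, 1],
    ifelse(hmode == "dominant_PF", ePF[, 1], NA))))
  trans_i <- which(!is.na(hmode) & hmode == "transgressive")
  if (length(trans_i)) {
    up <- sample(c(TRUE, FALSE), length(trans_i), TRUE)
    eH[trans_i, 1] <- ifelse(up,
      hi[trans_i] * 2^cfg$effect_size_log2fc,
      lo[trans_i] * 2^(-cfg$effect_size_log2fc))
  }

  ## module structure: shared latent factor on the log2 scale (brain only)
  module <- rep(0L, ng)
  nb <- sum(samples$tissue == focal)
  modfx <- matrix(0, ng, nrow(samples))  # per-sample log2 offsets
  brain_cols <- which(samples$tissue == focal)
  if (length(idx_mod)) {
    for (m in seq_along(idx_mod)) {
      gm <- idx_mod[[m]]
      module[gm] <- m
      spec <- cfg$module_spec[[m]]
      rho <- spec$cor
      trait <- isTRUE(spec$trait_assoc)
      z <- stats::rnorm(nb)
      if (trait) {
        sp <- samples$species[brain_cols]
        z <- z + ifelse(sp == "CF", -1, ifelse(sp == "PF", 1, 0))
      }
      eps <- matrix(stats::rnorm(length(gm) * nb), length(gm), nb)
      w <- sqrt(rho) * matrix(z, length(gm), nb, byrow = TRUE) +
        sqrt(1 - rho) * eps
      modfx[gm, brain_cols] <- w  # sigma = 1 log2 unit
      e[gm, ] <- pmax(e[gm, ], 20)  # modules must pass the expression filter
      eCF[gm, ] <- ePF[gm, ] <- eH[gm, ] <- e[gm, ]
    }
  }

  ## expected level per gene x sample, then NB counts
  lengths <- sample(500:5000, ng, TRUE)
  libf <- exp(stats::rnorm(nrow(samples), 0, cfg$library_size_sdlog))
  ti <- match(samples$tissue, tissues)
  emat <- matrix(0, ng, nrow(samples), dimnames = list(genes, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    lev <- switch(samples$species[s], CF = eCF, PF = ePF, F1 = eH)[, ti[s]]
    emat[, s] <- lev * 2^modfx[, s]
  }
  mu <- emat * (lengths / 1000) * rep(libf, each = ng)
  counts <- if (cfg$nb_dispersion == 0)
    matrix(stats::rpois(length(mu), mu), ng, ncol(mu))
  else
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
           ng, ncol(mu))
  dimnames(counts) <- dimnames(emat)

  ## truth classes from noise-free expected TPM, via the pipeline's own rules
  w_grp <- c(CF = cfg$n_per_species, PF = cfg$n_per_species, F1 = cfg$n_hybrids)
  pool <- (w_grp["CF"] * eCF + w_grp["PF"] * ePF + w_grp["F1"] * eH) / sum(w_grp)
  tpm_true <- sweep(pool, 2, colSums(pool), "/") * 1e6
  expressed <- log2(tpm_true + 1) >= 1
  fold_true <- ifelse(expressed[, 1],
                      tpm_true[, 1] / apply(tpm_true[, -1, drop = FALSE], 1, max),
                      NA_real_)
  class_truth <- ifelse(!expressed[, 1], "not_expressed",
    ifelse(fold_true >= 50, "highly_enriched",
    ifelse(fold_true >= 5, "enriched", "expressed")))

  truth <- data.frame(gene_id = genes, planted_fold = planted_fold,
                      class = class_truth, de = de, lfc = lfc,
                      direction = ifelse(!de, NA,
                                         ifelse(lfc > 0, "C>P", "P>C")),
                      architecture = arch, hybrid_mode = hmode,
                      module = module, gene_length = lengths,
                      stringsAsFactors = FALSE)
  attr(truth, "expr_levels") <- list(CF = eCF, PF = ePF, H = eH)
  list(counts = expression_matrix(counts, "counts", gene_lengths = lengths),
       samples = samples, truth = truth)
}

#' Simulate phased allele-specific read counts for the hybrids
#'
#' For cis genes the maternal:paternal read-ratio parameter equals the
#' planted species fold change; for trans genes it is 0.5. All hybrids
#' follow the study's cross direction (CF father, PF mother), so the
#' paternal allele is the CF allele. Reads are split multinomially over
#' 1-12 phased SNPs per gene.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth table from [simulate_counts()].
#' @return An `AlleleCountTable` data.frame.
#' @export
simulate_allele_counts <- function(cfg, truth) {
  set.seed(cfg$seed + 1L)
  de_genes <- truth$gene_id[truth$de]
  if (!length(de_genes)) return(structure(
    data.frame(hybrid_id = character(), gene_id = character(),
               snp_id = character(), maternal_reads = integer(),
               paternal_reads = integer()),
    class = c("AlleleCountTable", "data.frame")))
  hybrids <- paste0("F1", seq_len(cfg$n_hybrids))
  rows <- list()
  for (g in de_genes) {
    i <- match(g, truth$gene_id)
    if (is.na(truth$architecture[i]))
      stop("gene without regulatory architecture requested as ASE: ", g)
    n_snp <- sample(1:12, 1)
    R <- 2^truth$lfc[i]                 # CF / PF expression ratio
    # paternal allele is CF; cis -> allelic ratio mirrors the species ratio
    p_pat <- if (truth$architecture[i] == "cis") R / (1 + R) else 0.5
    for (h in hybrids) {
      tot <- stats::rpois(1, cfg$ase_mean_reads)
      per_snp <- stats::rmultinom(1, tot, rep(1 / n_snp, n_snp))[, 1]
      pat <- stats::rbinom(n_snp, per_snp, p_pat)
      rows[[length(rows) + 1]] <- data.frame(
        hybrid_id = h, gene_id = g, snp_id = paste0(g, "_s", seq_len(n_snp)),
        maternal_reads = per_snp - pat, paternal_reads = pat,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("AlleleCountTable", class(out))
  out
}

## -- synthetic genome, gene models, domains, genotypes ---------------------

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

`substr_assign` <- function(x, at, value) {
  substr(x, at, at + nchar(value) - 1L) <- value
  x
}

#' Simulate a population VCF, genome and gene models with planted variants
#'
#' Builds a small synthetic chromosome with three protein-coding genes (one
#' on the minus strand), a protein-domain table, and genotypes for
#' `n_resequenced_per_species` individuals per species. Planted site
#' classes: true fixed differences (in flanks, UTR/intron gene body, and
#' CDS, both synonymous and nonsynonymous — including one Ser->Thr change
#' within 10 amino acids of a domain start), shared polymorphisms,
#' species-private polymorphisms, and one site failing the coverage filter
#' (an individual with zero reads).
#'
#' @param cfg A [sim_config()].
#' @return list with `genome` (named character, chromosome sequence),
#'   `gene_models`, `domains`, `vcf` (list: chrom/pos/ref/alt/gt/dp; pos
#'   1-based as in VCF), `species_map` (individual -> species), and
#'   `site_truth` data.frame.
#' @export
simulate_genotypes_and_sequence <- function(cfg) {
  set.seed(cfg$seed + 2L)
  chrom <- "chr1"
  glen <- 42000L
  seq <- random_dna(glen)

  ## three genes, 0-based half-open coordinates
  mk_gene <- function(id, start, strand) {
    # layout (plus-strand sense): utr5 300bp | CDS1 600 | intron 400 | CDS2 600 | utr3 300
    utr5 <- c(start, start + 300L)
    cds1 <- c(start + 300L, start + 900L)
    cds2 <- c(start + 1300L, start + 1900L)
    utr3 <- c(start + 1900L, start + 2200L)
    if (strand == "-") {  # mirror labels; genomic layout identical
      tmp <- utr5; utr5 <- utr3; utr3 <- tmp
      cds <- data.frame(start = c(cds2[1], cds1[1]), end = c(cds2[2], cds1[2]),
                        phase = c(0L, 0L))
    } else {
      cds <- data.frame(start = c(cds1[1], cds2[1]), end = c(cds1[2], cds2[2]),
                        phase = c(0L, 0L))
    }
    gene_model(gene_id = id, chrom = chrom, start = start, end = start + 2200L,
               strand = strand, cds = cds,
               utr5 = data.frame(start = utr5[1], end = utr5[2]),
               utr3 = data.frame(start = utr3[1], end = utr3[2]),
               flank_bp = cfg$flank_bp)
  }
  models <- list(mk_gene("geneA", 8000L, "+"),
                 mk_gene("geneB", 20000L, "-"),
                 mk_gene("geneC", 32000L, "+"))
  names(models) <- vapply(models, `[[`, "", "gene_id")

  ## scrub premature stops from each CDS so planted proteins are clean
  for (gm in models) {
    n_aa <- sum(gm$cds$end - gm$cds$start) / 3
    for (aa in seq_len(n_aa)) {
      pos <- cds_genomic_positions(gm)[(3 * aa - 2):(3 * aa)]
      codon <- codon_from_genome(seq, gm, aa)
      if (codon %in% c("TAA", "TAG", "TGA") && aa < n_aa) {
        repl <- "CTG"  # Leu, strand-adjusted below
        if (gm$strand == "-") repl <- revcomp(repl)
        for (k in 1:3) {
          p <- if (gm$strand == "+") pos[k] else pos[4 - k]
          seq <- substr_assign(seq, p + 1L, substr(repl, k, k))
        }
      }
    }
  }

  domains <- data.frame(
    protein_id = c("geneA", "geneB", "geneC"),
    domain_id = c("coiled_coil", "C2", "PDZ"),
    start_aa = c(120L, 50L, 150L), end_aa = c(160L, 90L, 190L),
    stringsAsFactors = FALSE)

  ## helper to plant a codon and derive the SNP
  plant_codon <- function(seq, gm, aa_pos, ref_codon, alt_codon) {
    gpos <- cds_genomic_positions(gm)[(3 * aa_pos - 2):(3 * aa_pos)]
    cp <- which(strsplit(ref_codon, "")[[1]] != strsplit(alt_codon, "")[[1]])
    stopifnot(length(cp) == 1)
    wr <- if (gm$strand == "+") ref_codon else revcomp(ref_codon)
    ord <- if (gm$strand == "+") gpos else rev(gpos)
    for (k in 1:3) seq <- substr_assign(seq, ord[k] + 1L, substr(wr, k, k))
    site_pos <- gpos[cp]  # tx order -> genomic pos of the changed base
    ref_base <- substr(if (gm$strand == "+") ref_codon else ref_codon, cp, cp)
    alt_base <- substr(alt_codon, cp, cp)
    if (gm$strand == "-") { ref_base <- revcomp(ref_base); alt_base <- revcomp(alt_base) }
    list(seq = seq, pos = site_pos, ref = ref_base, alt = alt_base)
  }

  sites <- list()
  add_site <- function(pos, ref, alt, category, region, gene = NA,
                       consequence = "noncoding", aa_pos = NA, aa_change = NA,
                       covered = TRUE) {
    sites[[length(sites) + 1]] <<- data.frame(
      chrom = chrom, pos0 = as.integer(pos), ref = ref, alt = alt,
      category = category, region = region, gene_id = gene,
      consequence = consequence, aa_pos = aa_pos, aa_change = aa_change,
      covered = covered, stringsAsFactors = FALSE)
  }

  ## planted coding fixed differences
  # geneA: Ser->Thr (TCA->ACA) at 5 aa before the coiled-coil domain start
  aa_st <- domains$start_aa[1] - 5L
  p <- plant_codon(seq, models$geneA, aa_st, "TCA", "ACA"); seq <- p$seq
  add_site(p$pos, p$ref, p$alt, "fixed_diff", "gene_body", "geneA",
           "nonsynonymous", aa_st, "S->T")
  # geneA: synonymous CTT->CTC (Leu) at aa 30
  p <- plant_codon(seq, models$geneA, 30L, "CTT", "CTC"); seq <- p$seq
  add_site(p$pos, p$ref, p$alt, "fixed_diff", "gene_body", "geneA",
           "synonymous", 30L, "L->L")
  # geneB (minus strand): nonsynonymous GAT->GTT (Asp->Val) at aa 60 (in C2 domain)
  p <- plant_codon(seq, models$geneB, 60L, "GAT", "GTT"); seq <- p$seq
  add_site(p$pos, p$ref, p$alt, "fixed_diff", "gene_body", "geneB",
           "nonsynonymous", 60L, "D->V")
  # geneC: synonymous GGA->GGG at aa 100
  p <- plant_codon(seq, models$geneC, 100L, "GGA", "GGG"); seq <- p$seq
  add_site(p$pos, p$ref, p$alt, "fixed_diff", "gene_body", "geneC",
           "synonymous", 100L, "G->G")

  snp_at <- function(pos0) {
    ref <- substr(seq, pos0 + 1L, pos0 + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    c(ref, alt)
  }
  ## noncoding planted sites
  ra <- snp_at(8000L - 1000L)  # 1 kb upstream of geneA (+): flank_up
  add_site(8000L - 1000L, ra[1], ra[2], "fixed_diff", "flank_up", "geneA")
  ra <- snp_at(20000L + 2200L + 3000L)  # 3 kb past geneB end; minus strand: flank_up
  add_site(20000L + 2200L + 3000L, ra[1], ra[2], "fixed_diff", "flank_up", "geneB")
  ra <- snp_at(8000L + 1000L)  # geneA intron
  add_site(8000L + 1000L, ra[1], ra[2], "fixed_diff", "gene_body", "geneA")
  ra <- snp_at(32000L + 100L)  # geneC 5' UTR
  add_site(32000L + 100L, ra[1], ra[2], "fixed_diff", "utr5", "geneC")
  ra <- snp_at(2000L)          # far from any gene
  add_site(2000L, ra[1], ra[2], "fixed_diff", "intergenic")
  ## shared and private polymorphisms inside gene bodies
  ra <- snp_at(8000L + 1100L)
  add_site(8000L + 1100L, ra[1], ra[2], "shared_poly", "gene_body", "geneA")
  ra <- snp_at(20000L + 1000L)
  add_site(20000L + 1000L, ra[1], ra[2], "private_poly_CF", "gene_body", "geneB")
  ra <- snp_at(32000L + 1000L)
  add_site(32000L + 1000L, ra[1], ra[2], "private_poly_PF", "gene_body", "geneC")
  ## a would-be fixed difference failing the coverage filter
  ra <- snp_at(8000L + 1200L)
  add_site(8000L + 1200L, ra[1], ra[2], "fixed_diff_lowcov", "gene_body", "geneA",
           covered = FALSE)

  site_truth <- do.call(rbind, sites)
  site_truth <- site_truth[order(site_truth$pos0), ]
  rownames(site_truth) <- NULL

  ## genotypes and depths
  nI <- cfg$n_resequenced_per_species
  inds <- c(paste0("CF_ind", seq_len(nI)), paste0("PF_ind", seq_len(nI)))
  species_map <- stats::setNames(rep(c("CF", "PF"), each = nI), inds)
  ns <- nrow(site_truth)
  gt <- matrix("0/0", ns, 2 * nI, dimnames = list(NULL, inds))
  for (i in seq_len(ns)) {
    cat_i <- site_truth$category[i]
    if (cat_i %in% c("fixed_diff", "fixed_diff_lowcov")) {
      gt[i, (nI + 1):(2 * nI)] <- "1/1"  # PF carries the alternative allele
    } else if (cat_i == "shared_poly") {
      gt[i, ] <- sample(c("0/0", "0/1", "1/1"), 2 * nI, TRUE, c(.49, .42, .09))
      gt[i, 1] <- "0/1"; gt[i, nI + 1] <- "0/1"  # guarantee both segregate
    } else if (cat_i == "private_poly_CF") {
      gt[i, 1:nI] <- sample(c("0/0", "0/1"), nI, TRUE); gt[i, 1] <- "0/1"
    } else if (cat_i == "private_poly_PF") {
      gt[i, (nI + 1):(2 * nI)] <- sample(c("0/0", "0/1"), nI, TRUE)
      gt[i, nI + 1] <- "0/1"
    }
  }
  dp <- matrix(stats::rpois(ns * 2 * nI, 10) + 1L, ns, 2 * nI,
               dimnames = list(NULL, inds))
  dp[site_truth$category == "fixed_diff_lowcov", 3] <- 0L

  list(genome = stats::setNames(seq, chrom), gene_models = models,
       domains = domains,
       vcf = list(chrom = rep(chrom, ns), pos = site_truth$pos0 + 1L,
                  ref = site_truth$ref, alt = site_truth$alt, gt = gt, dp = dp),
       species_map = species_map, site_truth = site_truth)
}

#' Write the simulated genotypes as a VCF v4.2 text file
#' @param sim Output of [simulate_genotypes_and_sequence()].
#' @param path Output path.
#' @export
write_vcf <- function(sim, path) {
  v <- sim$vcf
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(v$gt)), collapse = "\t")), con)
  body <- vapply(seq_along(v$pos), function(i) {
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS", ".",
            "GT:DP", paste0(v$gt[i, ], ":", v$dp[i, ])), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Write the simulated genome as FASTA
#' @param sim Output of [simulate_genotypes_and_sequence()].
#' @param path Output path.
#' @export
write_genome_fasta <- function(sim, path) {
  ss <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write gene models as GFF3
#' @param models List of gene models.
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  rows <- list()
  for (gm in models) {
    add <- function(type, s, e, attrs, phase = ".")
      rows[[length(rows) + 1]] <<- sprintf("%s\t.\t%s\t%d\t%d\t.\t%s\t%s\t%s",
        gm$chrom, type, s + 1L, e, gm$strand, phase, attrs)
    add("gene", gm$start, gm$end, sprintf("ID=%s", gm$gene_id))
    mrna <- paste0(gm$gene_id, ".t1")
    add("mRNA", gm$start, gm$end, sprintf("ID=%s;Parent=%s", mrna, gm$gene_id))
    if (!is.null(gm$cds)) for (i in seq_len(nrow(gm$cds)))
      add("CDS", gm$cds$start[i], gm$cds$end[i],
          sprintf("ID=%s.cds;Parent=%s", gm$gene_id, mrna), gm$cds$phase[i])
    if (!is.null(gm$utr5) && nrow(gm$utr5)) for (i in seq_len(nrow(gm$utr5)))
      add("five_prime_UTR", gm$utr5$start[i], gm$utr5$end[i],
          sprintf("ID=%s.u5;Parent=%s", gm$gene_id, mrna))
    if (!is.null(gm$utr3) && nrow(gm$utr3)) for (i in seq_len(nrow(gm$utr3)))
      add("three_prime_UTR", gm$utr3$start[i], gm$utr3$end[i],
          sprintf("ID=%s.u3;Parent=%s", gm$gene_id, mrna))
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Simulate a rooted tree with one evolving amino-acid character
#'
#' A Yule (pure-birth) tree is drawn with ape, and a single categorical
#' character is evolved from a known root state under the symmetric k-state
#' Markov model used by [ml_ancestral()]. The true root state and the
#' realized number of state changes are recorded.
#'
#' @param n_tips Number of tips.
#' @param states Character alphabet (default c("T", "S"), mirroring a
#'   threonine/serine site).
#' @param rate Substitution rate per unit branch length.
#' @param seed Integer seed.
#' @return list with `tree` (phylo, rooted), `tip_states` (named), `k`,
#'   `root_state`, `n_changes`.
#' @export
simulate_tree_with_site <- function(n_tips, states = c("T", "S"), rate = 0.1,
                                    seed = 1L) {
  set.seed(seed)
  k <- length(states)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  root_state <- sample(states, 1)
  ntot <- n_tips + tree$Nnode
  node_state <- rep(NA_character_, ntot)
  root <- n_tips + 1L
  node_state[root] <- root_state
  n_changes <- 0L
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1]; child <- ord$edge[i, 2]
    t <- ord$edge.length[i]
    p_stay <- 1 / k + (1 - 1 / k) * exp(-k * rate * t / (k - 1))
    cur <- node_state[par]
    if (stats::runif(1) < p_stay) new <- cur
    else new <- sample(setdiff(states, cur), 1)
    if (new != cur) n_changes <- n_changes + 1L
    node_state[child] <- new
  }
  tips <- stats::setNames(node_state[seq_len(n_tips)], tree$tip.label)
  list(tree = tree, tip_states = tips, k = k, root_state = root_state,
       n_changes = n_changes)
}
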