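# one-gene toy genome on the chosen strand, CDS split over two exons
toy_gene_genome <- function(strand, seed = 1) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  cds <- if (strand == "+")
    data.frame(start = c(100L, 200L), end = c(160L, 260L), phase = 0L)
  else
    data.frame(start = c(200L, 100L), end = c(260L, 160L), phase = 0L)
  gm <- gene_model("toy", "chrT", 80L, 300L, strand, cds = cds,
                   utr5 = data.frame(start = 80L, end = 100L),
                   utr3 = data.frame(start = 260L, end = 300L))
  list(seq = seq, gm = gm)
}

test_that("coverage filter distinguishes per-individual and total modes", {
  dp <- rbind(rep(3L, 6), c(0L, rep(5L, 5)), rep(0L, 6))
  vcf <- list(chrom = rep("c", 3), pos = 1:3, dp = dp)
  expect_equal(coverage_filter(vcf), c(TRUE, FALSE, FALSE))
  expect_equal(coverage_filter(vcf, mode = "total"), c(TRUE, TRUE, FALSE))
  vcf$dp[1, 1] <- NA
  expect_error(coverage_filter(vcf), "missing depth at site c:1")
  empty <- list(chrom = character(), pos = integer(),
                dp = matrix(0L, 0, 6))
  expect_length(coverage_filter(empty), 0)
})

test_that("fixedness requires reciprocal homozygosity of covered individuals", {
  mk <- function(gtA, gtB) {
    gt <- matrix(c(gtA, gtB), 1)
    colnames(gt) <- paste0("i", 1:6)
    list(chrom = "c", pos = 10L, ref = "A", alt = "G", gt = gt)
  }
  spmap <- stats::setNames(rep(c("sp1", "sp2"), each = 3), paste0("i", 1:6))
  fixed <- mk(rep("0/0", 3), rep("1/1", 3))
  out <- fixed_differences(fixed, spmap)
  expect_equal(nrow(out), 1)
  expect_equal(out$allele_A, "A")
  expect_equal(out$allele_B, "G")

  expect_equal(nrow(fixed_differences(mk(c("0/0", "0/1", "0/0"),
                                         rep("1/1", 3)), spmap)), 0)
  expect_equal(nrow(fixed_differences(mk(rep("0/0", 3), rep("0/0", 3)),
                                      spmap)), 0)
  # missing genotypes are excluded, remaining individuals decide
  out2 <- fixed_differences(mk(c("./.", "0/0", "0/0"), rep("1/1", 3)), spmap)
  expect_equal(nrow(out2), 1)
  # multiallelic skipped with a count
  multi <- mk(rep("0/0", 3), rep("1/1", 3)); multi$alt <- "G,T"
  res <- fixed_differences(multi, spmap)
  expect_equal(nrow(res), 0)
  expect_equal(attr(res, "n_multiallelic_skipped"), 1L)
})

test_that("region assignment is strand-aware with half-open flank windows", {
  gm_plus <- gene_model("gp", "c1", 10000L, 12000L, "+")
  gm_minus <- gene_model("gm", "c2", 10000L, 12000L, "-")
  models <- list(gp = gm_plus, gm = gm_minus)

  expect_equal(assign_region(11000L, models, "c1")$region, "gene_body")
  # 4999 bp upstream of a +-strand start is in the 5' flank ...
  expect_equal(assign_region(10000L - 4999L, models, "c1")$region, "flank_up")
  expect_equal(assign_region(10000L - 5000L, models, "c1")$region, "flank_up")
  # ... and 5001 bp upstream is out
  expect_equal(assign_region(10000L - 5001L, models, "c1")$region, "intergenic")
  # minus strand: the left flank is downstream (3') of the gene
  expect_equal(assign_region(9000L, models, "c2")$region, "flank_down")
  expect_equal(assign_region(13000L, models, "c2")$region, "flank_up")

  # UTR sublabels inside the gene body
  g <- toy_gene_genome("+")
  expect_equal(assign_region(90L, list(g$gm), "chrT")$region, "utr5")
  expect_equal(assign_region(270L, list(g$gm), "chrT")$region, "utr3")
  expect_equal(assign_region(180L, list(g$gm), "chrT")$region, "gene_body")
})

test_that("consequence annotation translates planted codons on both strands", {
  for (strand in c("+", "-")) {
    g <- toy_gene_genome(strand)
    # plant TCA (Ser) at amino acid 5 and test the T->A first-position change
    gpos <- hybridexpr:::cds_genomic_positions(g$gm)[13:15]
    codon <- if (strand == "+") "TCA" else "TGA"  # genomic plus-strand bases
    seq <- g$seq
    ord <- if (strand == "+") gpos else rev(gpos)
    wr <- if (strand == "+") "TCA" else
      paste(rev(strsplit(chartr("ACGT", "TGCA", "TCA"), "")[[1]]), collapse = "")
    for (k in 1:3) substr(seq, ord[k] + 1, ord[k] + 1) <- substr(wr, k, k)
    site <- gpos[1]
    ref <- substr(seq, site + 1, site + 1)
    alt <- if (strand == "+") "A" else chartr("ACGT", "TGCA", "A")
    ann <- annotate_consequence(site, ref, alt, g$gm, seq)
    expect_equal(ann$ref_codon, "TCA")
    expect_equal(ann$alt_codon, "ACA")
    expect_equal(ann$ref_aa, "S")
    expect_equal(ann$alt_aa, "T")
    expect_equal(ann$consequence, "nonsynonymous")
    expect_equal(ann$aa_pos, 5)
  }
  g <- toy_gene_genome("+")
  expect_error(annotate_consequence(5L, "A", "C", g$gm, g$seq), "not inside")
})

test_that("synonymous changes are recognized from the genetic code", {
  g <- toy_gene_genome("+")
  gpos <- hybridexpr:::cds_genomic_positions(g$gm)[1:3]
  seq <- g$seq
  for (k in 1:3) substr(seq, gpos[k] + 1, gpos[k] + 1) <- substr("CTT", k, k)
  ann <- annotate_consequence(gpos[3], "T", "C", g$gm, seq)
  expect_equal(ann$consequence, "synonymous")
  expect_equal(ann$ref_aa, "L")
  expect_equal(ann$alt_aa, "L")
})

test_that("every CDS substitution agrees with the full-protein oracle", {
  # brute force: rebuild the mutant genome, retranslate the whole protein
  for (strand in c("+", "-")) {
    g <- toy_gene_genome(strand, seed = 3)
    gpos <- hybridexpr:::cds_genomic_positions(g$gm)
    ref_prot <- translate_gene(g$seq, g$gm)
    set.seed(1)
    sites <- sample(seq_along(gpos), 30)
    for (ci in sites) {
      site <- gpos[ci]
      ref <- substr(g$seq, site + 1, site + 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      ann <- annotate_consequence(site, ref, alt, g$gm, g$seq)
      mutant <- g$seq
      substr(mutant, site + 1, site + 1) <- alt
      mut_prot <- translate_gene(mutant, g$gm)
      diff_pos <- which(strsplit(ref_prot, "")[[1]] != strsplit(mut_prot, "")[[1]])
      if (ann$consequence == "synonymous") {
        expect_length(diff_pos, 0)
      } else {
        expect_equal(diff_pos, ann$aa_pos)
        expect_equal(substr(mut_prot, ann$aa_pos, ann$aa_pos), ann$alt_aa)
      }
      expect_equal(substr(ref_prot, ann$aa_pos, ann$aa_pos), ann$ref_aa)
    }
  }
})

test_that("domain relations follow the 10-residue proximity rule", {
  doms <- data.frame(protein_id = "p", domain_id = "d",
                     start_aa = 50L, end_aa = 80L)
  expect_equal(domain_overlap(55, doms)$relation, "inside")
  hit <- domain_overlap(45, doms)
  expect_equal(hit$relation, "within_10_of_start")
  expect_equal(hit$distance_to_start, 5)
  out <- domain_overlap(20, doms)
  expect_equal(out$relation, "outside")
  expect_equal(out$distance_to_start, 30)
  # boundary: exactly 10 away counts as proximal
  expect_equal(domain_overlap(40, doms)$relation, "within_10_of_start")
  expect_equal(domain_overlap(39, doms)$relation, "outside")
})

test_that("the full scan recovers exactly the planted fixed differences", {
  cfg <- sim_config(seed = 23)
  g <- simulate_genotypes_and_sequence(cfg)
  res <- scan_fixed_differences(g$vcf, g$species_map, g$gene_models,
                                g$genome, g$domains)
  truth <- g$site_truth
  want <- truth[truth$category == "fixed_diff" & truth$covered, ]
  expect_setequal(res$pos0, want$pos0)
  m <- match(res$pos0, want$pos0)
  expect_equal(res$region, want$region[m])
  expect_equal(res$consequence, want$consequence[m])
  coding <- !is.na(want$aa_pos[m])
  expect_equal(res$aa_pos[coding], want$aa_pos[m][coding])
  # the Ser->Thr change sits within 10 residues of its domain start
  st <- res[res$aa_change %in% "S->T", ]
  expect_equal(st$domain_relation, "within_10_of_start")
})
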