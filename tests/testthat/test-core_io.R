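test_that("expression_matrix enforces non-negativity and unique gene ids", {
  m <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  em <- expression_matrix(m, "counts", gene_lengths = c(100L, 200L))
  expect_s3_class(em, "ExpressionMatrix")
  expect_equal(em$unit, "counts")

  m[2, 1] <- -1
  expect_error(expression_matrix(m, "counts", gene_lengths = c(100L, 200L)),
               "negative value at gene 'g2', sample 's1'")
  rownames(m) <- c("g1", "g1")
  expect_error(expression_matrix(abs(m), "tpm"), "duplicate gene id")
  expect_error(expression_matrix(matrix(1, 1, 1,
                                        dimnames = list("g", "s")), "counts"),
               "gene_lengths")
})

test_that("count TSV round-trips through write and read", {
  vals <- matrix(c(0, 5, 17, 3, 8, 120), 3, 2,
                 dimnames = list(paste0("g", 1:3), c("sampA", "sampB")))
  em <- expression_matrix(vals, "counts", gene_lengths = c(500L, 1500L, 900L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(em, path)
  back <- read_counts(path)
  expect_equal(back$values, em$values)
  expect_equal(unname(back$gene_lengths), unname(em$gene_lengths))
  expect_equal(back$unit, "counts")
})

test_that("TPM columns sum to one million and follow length weighting", {
  # counts {10,10}, lengths {1000,2000}: rates 0.01/0.005 -> 2/3 and 1/3
  em <- toy_counts(matrix(c(10, 10), 2, 1), lengths = c(1000L, 2000L))
  tpm <- compute_tpm(em)
  expect_equal(unname(tpm$values[, 1]), c(2, 1) / 3 * 1e6, tolerance = 1e-9)

  # single gene: forced to 1e6 whatever the count
  one <- toy_counts(matrix(7, 1, 1), lengths = 1234L)
  expect_equal(unname(compute_tpm(one)$values[1, 1]), 1e6)

  # scale invariance within a sample
  em2 <- toy_counts(matrix(c(10, 10, 20, 20), 2, 2), lengths = c(1000L, 2000L))
  t2 <- compute_tpm(em2)
  expect_equal(t2$values[, 1], t2$values[, 2])

  # random matrix: every column sums to 1e6 within 1e-6 relative
  set.seed(1)
  r <- toy_counts(matrix(rpois(50, 40), 10, 5),
                  lengths = sample(200:3000, 10))
  expect_equal(unname(colSums(compute_tpm(r)$values)), rep(1e6, 5),
               tolerance = 1e-6)

  z <- toy_counts(matrix(c(1, 0, 1, 0), 2, 2))
  z$values[, 2] <- 0
  expect_error(compute_tpm(z), "all-zero sample")
})

test_that("log transform is log2(x + 1) with unit bookkeeping", {
  em <- toy_counts(matrix(c(4, 4), 2, 1))
  tpm <- compute_tpm(em)
  tpm$values[] <- c(0, 1, 3)[c(1, 2)]
  lt <- log_transform(tpm)
  expect_equal(unname(lt$values[, 1]), c(0, 1))
  tpm$values[] <- 3
  expect_equal(unname(log_transform(tpm)$values[1, 1]), 2)
  expect_error(log_transform(lt), "unit")
})

test_that("sample table validation enforces species codes and hybrid crosses", {
  st <- toy_samples(2, 2, 1)
  expect_equal(st$species_code, c(0, 0, 1, 1, NA))
  bad <- data.frame(sample_id = "x", species = "F1", tissue = "brain",
                    cross = "none")
  expect_error(validate_sample_table(bad), "cross direction")
  expect_error(validate_sample_table(data.frame(sample_id = "x")),
               "missing column")
})

test_that("gene models read back from GFF3 match what was written", {
  cfg <- sim_config(seed = 4)
  g <- simulate_genotypes_and_sequence(cfg)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff3(g$gene_models, path)
  back <- read_gene_models(path)
  expect_setequal(names(back), names(g$gene_models))
  for (id in names(back)) {
    a <- g$gene_models[[id]]; b <- back[[id]]
    expect_equal(b$start, a$start)
    expect_equal(b$end, a$end)
    expect_equal(b$strand, a$strand)
    expect_equal(b$cds$start, a$cds$start)
    expect_equal(b$cds$end, a$cds$end)
  }
})

test_that("VCF written by the simulator reads back identically", {
  cfg <- sim_config(seed = 4)
  g <- simulate_genotypes_and_sequence(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, path)
  v <- read_vcf_genotypes(path)
  expect_identical(v$pos, g$vcf$pos)
  expect_identical(v$ref, g$vcf$ref)
  expect_identical(unname(v$gt), unname(g$vcf$gt))
  expect_identical(unname(v$dp), unname(g$vcf$dp) + 0)
})

test_that("tree plus tip-state readers accept TSV and FASTA states", {
  ts <- simulate_tree_with_site(8, seed = 2)
  tp <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(ts$tree, tp)
  sp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tip\tstate",
               paste(names(ts$tip_states), ts$tip_states, sep = "\t")), sp)
  got <- read_newick_with_characters(tp, sp)
  # newick serialization may reorder tips; states stay keyed by tip name
  expect_equal(got$tip_states[names(ts$tip_states)], ts$tip_states)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(ts$tip_states), "\n", ts$tip_states), fa)
  got2 <- read_newick_with_characters(tp, fa)
  expect_equal(got2$tip_states[names(ts$tip_states)], ts$tip_states)
})
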