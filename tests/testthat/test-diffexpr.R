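test_that("size factors recover construction and ignore gene order", {
  set.seed(3)
  base <- matrix(rpois(60, 50) + 1, 20, 3)
  m <- cbind(base[, 1], base[, 1] * 2, base[, 1])  # sample 2 doubled gene-wise
  sf <- size_factors(m)
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-12)
  expect_equal(sf[3], sf[1], tolerance = 1e-12)

  ident <- cbind(base[, 2], base[, 2], base[, 2])
  expect_equal(unname(size_factors(ident)), rep(1, 3))

  perm <- sample(nrow(base))
  expect_equal(size_factors(base), size_factors(base[perm, ]))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)), "filter")
})

test_that("wald test is null-centered for identical group means", {
  m <- matrix(rep(c(30, 60, 90, 120), 6), 4, 6)
  rownames(m) <- paste0("g", 1:4)
  de <- nb_wald_test(m, rep(c("CF", "PF"), each = 3))
  expect_equal(de$log2fc, rep(0, 4))
  expect_equal(de$p, rep(1, 4))
  expect_error(nb_wald_test(m[, 1:3], c("CF", "PF", "PF")), "n >= 2")
  z <- m; z[, 1:3] <- 0
  expect_error(nb_wald_test(z, rep(c("CF", "PF"), each = 3)), "all-zero")
})

test_that("wald p ranking agrees with the exhaustive permutation oracle", {
  set.seed(42)
  mu <- exp(rnorm(200, log(100), 1))
  fc <- ifelse(runif(200) < 0.3, 2^(sample(c(-1, 1), 200, TRUE)), 1)
  cm <- cbind(matrix(rnbinom(200 * 5, mu = mu * fc, size = 20), 200),
              matrix(rnbinom(200 * 5, mu = mu, size = 20), 200))
  dimnames(cm) <- list(paste0("g", 1:200), paste0("s", 1:10))
  de <- nb_wald_test(cm, rep(c("A", "B"), each = 5))
  # oracle: all 252 group relabelings of the mean difference statistic
  lq <- log2(sweep(cm, 2, size_factors(cm), "/") + 0.5)
  splits <- utils::combn(10, 5)
  pperm <- vapply(seq_len(nrow(lq)), function(g) {
    st <- apply(splits, 2, function(ix) abs(mean(lq[g, ix]) - mean(lq[g, -ix])))
    mean(st >= abs(mean(lq[g, 1:5]) - mean(lq[g, 6:10])) - 1e-12)
  }, 0)
  expect_gt(cor(de$p, pperm, method = "spearman"), 0.9)
})

test_that("wald power rises with effect size", {
  power_at <- function(lfc, seed = 8) {
    set.seed(seed)
    mu <- rep(100, 300)
    cm <- cbind(matrix(rnbinom(300 * 5, mu = mu * 2^lfc, size = 20), 300),
                matrix(rnbinom(300 * 5, mu = mu, size = 20), 300))
    dimnames(cm) <- list(paste0("g", 1:300), paste0("s", 1:10))
    mean(nb_wald_test(cm, rep(c("A", "B"), each = 5))$p < 0.05)
  }
  p <- vapply(c(0.25, 0.5, 1), power_at, 0)
  expect_true(all(diff(p) > 0))
})

test_that("BH adjustment reproduces the hand-worked step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("focal-tissue specificity rule applies the opposite-direction clause", {
  mk <- function(p_adj, direction) {
    data.frame(gene_id = paste0("g", seq_along(p_adj)), contrast = "CFvsPF",
               p = p_adj, p_adj = p_adj, log2fc = 0, direction = direction)
  }
  de <- list(
    brain = mk(c(0.01, 0.01, 0.01, 0.50), c("C>P", "C>P", "C>P", "C>P")),
    heart = mk(c(0.90, 0.90, 0.01, 0.01), c("C>P", "P>C", "C>P", "C>P")),
    liver = mk(c(0.90, 0.01, 0.90, 0.90), c("C>P", "P>C", "P>C", "P>C")),
    kidney = mk(rep(0.9, 4), rep("C>P", 4)),
    testis = mk(rep(0.9, 4), rep("C>P", 4)))
  out <- brain_specific_rule(de, focal = "brain", fdr = 0.05)
  expect_equal(out$brain_specific,
               c(TRUE,    # DE in brain only
                 TRUE,    # DE elsewhere but opposite direction everywhere
                 FALSE,   # same direction in heart
                 FALSE))  # not DE in brain at all
  expect_error(brain_specific_rule(de[-1], focal = "brain"), "focal")
})

test_that("hybrid patterns match the printed flycatcher examples", {
  # group means as printed for SAMD7 and CA12 (collared; pied; hybrid)
  out <- hybrid_pattern(m_C = c(0.31, 3.43), m_P = c(1.34, 1.02),
                        m_H = c(0.08, 2.52), gene_id = c("SAMD7", "CA12"))
  expect_equal(out$pattern, c("P > C > H", "C > H > P"))
  expect_equal(out$mode, c("transgressive_low", "intermediate"))

  mid <- hybrid_pattern(2, 6, 4)
  expect_equal(mid$mode, "intermediate")
  expect_equal(hybrid_pattern(2, 6, 6)$mode, "tied")
  expect_equal(hybrid_pattern(2, 6, 9)$mode, "transgressive_high")
  expect_equal(hybrid_pattern(5, 5, 2)$mode, "transgressive_low")
  expect_error(hybrid_pattern(-1, 1, 1), ">= 0")
})

test_that("variance partitioning reproduces the ANOVA decomposition", {
  # summary-statistic form equals aov on raw values
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(5, 10, 3); y <- rnorm(7, 12, 2)
    vp <- variance_partition(mean(x), sd(x), 5, mean(y), sd(y), 7)
    fit <- stats::aov(v ~ g, data = data.frame(v = c(x, y),
                                               g = rep(c("a", "b"), c(5, 7))))
    ss <- summary(fit)[[1]][["Sum Sq"]]
    expect_equal(vp$fraction, ss[1] / sum(ss), tolerance = 1e-10)
  }
  expect_equal(variance_partition(5, 1, 4, 5, 2, 4)$fraction, 0)
  expect_error(variance_partition(1, 1, 1, 2, 1, 5), "n >= 2")
})
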