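# two profiles with an exact target Pearson correlation
profiles_with_cor <- function(r, n = 8) {
  x <- scale(stats::rnorm(n))[, 1]
  e <- stats::residuals(stats::lm(stats::rnorm(n) ~ x))
  y <- r * x + sqrt(1 - r^2) * scale(e)[, 1]
  rbind(a = x, b = y)
}

test_that("signed-hybrid adjacency powers positive correlations and zeroes negatives", {
  set.seed(1)
  m <- profiles_with_cor(0.5)
  a <- adjacency(m, network_params(soft_power = 4))
  expect_equal(a["a", "b"], 0.5^4, tolerance = 1e-10)

  mneg <- profiles_with_cor(-0.3)
  an <- adjacency(mneg)
  expect_equal(an["a", "b"], 0)

  dup <- rbind(x = m[1, ], y = m[1, ])
  expect_equal(adjacency(dup)["x", "y"], 1)
  expect_equal(diag(a), c(a = 1, b = 1))

  flat <- rbind(m, c = rep(2, ncol(m)))
  expect_error(adjacency(flat), "zero-variance gene: c")
})

test_that("topological overlap matches hand-evaluated cases and stays in [0,1]", {
  # 3-node path: a12 = a23 = 0.5, a13 = 0
  a <- matrix(c(1, .5, 0, .5, 1, .5, 0, .5, 1), 3, 3)
  tom <- topological_overlap(a)
  expect_equal(tom[1, 3], 0.25 / 1.5, tolerance = 1e-12)
  expect_equal(diag(tom), rep(1, 3))

  # isolated identical pair
  a2 <- diag(2); a2[1, 2] <- a2[2, 1] <- 1
  expect_equal(topological_overlap(a2)[1, 2], 1)

  # empty network
  expect_equal(topological_overlap(diag(3))[1, 2], 0)

  set.seed(4)
  m <- matrix(rnorm(30 * 8), 30, 8)
  rownames(m) <- paste0("g", 1:30)
  tr <- topological_overlap(adjacency(m))
  expect_true(all(tr >= 0 & tr <= 1 + 1e-12))

  bad <- a; bad[1, 2] <- 0.9
  expect_error(topological_overlap(bad), "symmetric")
})

test_that("module detection recovers planted blocks and rejects noise", {
  d <- planted_module_profiles(seed = 2)
  np <- network_params()
  mods <- detect_modules(topological_overlap(adjacency(d$expr, np)), np)
  mods <- prune_module_membership(d$expr, mods, np)
  expect_gt(adjusted_rand(d$truth, mods), 0.8)

  # pure noise: nearly everything unassigned
  set.seed(9)
  noise <- matrix(rnorm(210 * 10), 210, 10,
                  dimnames = list(paste0("n", 1:210), NULL))
  m0 <- detect_modules(topological_overlap(adjacency(noise, np)), np)
  expect_gte(mean(m0 == 0), 0.9)

  # a lone block below the minimum size goes to module 0
  d10 <- planted_module_profiles(seed = 3, sizes = 10, n_noise = 40,
                                 trait_shift = 0)
  ms <- detect_modules(topological_overlap(adjacency(d10$expr, np)), np)
  expect_true(all(ms[d10$truth == 1] == 0))
})

test_that("eigengene is the oriented leading principal direction", {
  set.seed(5)
  base <- rnorm(12)
  m <- rbind(g1 = base * 2 + 3, g2 = base * 0.5 - 1, g3 = base + 0.2)
  colnames(m) <- paste0("s", 1:12)
  eg <- eigengene(m)
  expect_equal(abs(cor(eg, base)), 1, tolerance = 1e-10)
  expect_equal(attr(eg, "var_explained"), 1, tolerance = 1e-10)
  expect_equal(sum(eg^2), 1, tolerance = 1e-10)
  expect_gte(cor(eg, colMeans(t(scale(t(m))))), 0)

  # orientation contract: the eigengene tracks its genes' consensus, so
  # flipping every profile flips it with them (correlation with the
  # module's mean profile stays non-negative either way)
  eg2 <- eigengene(-m)
  expect_equal(unname(eg2), -unname(eg), tolerance = 1e-10)
  expect_gte(cor(eg2, colMeans(t(scale(t(-m))))), 0)

  # optimality: explains at least as much variance as any single gene
  mm <- rbind(m, g4 = rnorm(12), g5 = rnorm(12))
  egm <- eigengene(mm)
  z <- t(scale(t(mm)))
  ve_gene <- apply(z, 1, function(g) {
    gn <- g / sqrt(sum(g^2))
    sum((z %*% gn)^2) / sum(z^2)
  })
  expect_gte(attr(egm, "var_explained") + 1e-12, max(ve_gene))

  expect_error(eigengene(m[1, , drop = FALSE]), ">= 2")
})

test_that("module-trait correlation uses the Student t reference", {
  # r = 0.632, n = 10 -> t = 2.3066, p ~ 0.0500
  set.seed(6)
  tr <- rep(0:1, each = 5)
  x <- profiles_with_cor(0.632, n = 10)  # build vector with exact r vs another
  # construct eig with exact correlation 0.632 against the trait
  e <- stats::residuals(stats::lm(stats::rnorm(10) ~ tr))
  eig <- 0.632 * scale(tr)[, 1] + sqrt(1 - 0.632^2) * scale(e)[, 1]
  ct <- module_trait(eig, tr)
  expect_equal(ct$r, 0.632, tolerance = 1e-10)
  expect_equal(ct$t, 2.3066, tolerance = 1e-4)
  expect_equal(ct$p, 0.04995, tolerance = 1e-4)

  orth <- scale(e)[, 1]
  expect_equal(module_trait(orth, tr)$p, 1, tolerance = 1e-10)
  expect_equal(module_trait(tr, tr)$p, 0)
  expect_error(module_trait(eig, rep(1, 10)), "constant")
})

test_that("full analysis ranks the species-shifted module first on |r|", {
  hits <- 0
  for (seed in 1:5) {
    d <- planted_module_profiles(seed = seed)
    cx <- coexpression_analysis(d$expr, d$trait,
                                network_params(filter_threshold = -Inf))
    mt <- cx$module_trait
    if (!nrow(mt)) next
    best <- mt$module[which.max(abs(mt$r))]
    overlap <- vapply(mt$module, function(m)
      mean(d$truth[cx$modules == m] == 1), 0)
    if (overlap[mt$module == best] > 0.5) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
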