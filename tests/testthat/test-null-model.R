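test_that("every replicate conserves the per-biome richness exactly", {
  marg <- c(I = 5, II = 9, III = 3, VII = 6)
  ens <- simulate_null(marg, n_species = 12, n_reps = 40, seed = 2,
                       keep_draws = TRUE)
  for (r in seq_len(40)) {
    cs <- colSums(ens$draws[r, , ])
    expect_equal(cs[biome_levels() %in% names(marg)], unname(marg),
                 ignore_attr = TRUE)
    expect_true(all(cs[!biome_levels() %in% names(marg)] == 0))
  }
})

test_that("degenerate systems behave as enumeration dictates", {
  # one biome holding every species: all specialists, always
  ens <- simulate_null(c(I = 4), n_species = 4, n_reps = 50, seed = 1)
  expect_true(all(ens$bsi_pct[, 1] == 100))
  expect_true(all(ens$specialist_pct[, "I"] == 100))
  an <- analytic_null_bsi(c(I = 4), n_species = 4)
  expect_equal(an$specialist$prob[an$specialist$biome == "I"], 1)
  expect_equal(an$bsi$prob[1], 1)

  # two biomes, one species each, two species: the four equally likely
  # assignments give 50% all-specialist and 50% one-generalist replicates
  ens2 <- simulate_null(c(I = 1, II = 1), n_species = 2, n_reps = 4000, seed = 8)
  expect_equal(mean(ens2$bsi_pct[, 1]), 50, tolerance = 0.05)
  expect_equal(mean(ens2$bsi_pct[, 2]), 50, tolerance = 0.05)
  # the per-species analytic law differs from the replicate-mean statistic
  # in tiny systems: P(BSI = 1 | >= 1) = 2/3 here
  an2 <- analytic_null_bsi(c(I = 1, II = 1), n_species = 2)
  expect_equal(an2$bsi$prob[1], 2 / 3)
})

test_that("the simulated ensemble matches exhaustive enumeration on toys", {
  marg <- c(I = 2, II = 1, III = 2)
  n <- 4
  oracle <- enum_null_exact(marg, n)
  ens <- simulate_null(marg, n_species = n, n_reps = 6000, seed = 13)
  se <- apply(ens$bsi_pct, 2, sd) / sqrt(ens$n_reps)
  for (k in 1:3) {
    expect_lt(abs(mean(ens$bsi_pct[, k]) - oracle$mean_bsi_pct[k]),
              4 * se[k] + 1e-9)
  }
  spec_cols <- names(marg)
  se_s <- apply(ens$specialist_pct[, spec_cols], 2, sd) / sqrt(ens$n_reps)
  for (b in spec_cols) {
    expect_lt(abs(mean(ens$specialist_pct[, b]) - oracle$mean_specialist_pct[b]),
              4 * se_s[b] + 1e-9)
  }
  # per-biome specialist expectations are linear statistics, so the
  # analytic product formula is exact even at this size
  an <- analytic_null_bsi(marg, n)
  expect_equal(100 * an$specialist$prob[match(spec_cols, an$specialist$biome)],
               unname(oracle$mean_specialist_pct), tolerance = 1e-10)
})

test_that("the Poisson-binomial convolution matches brute-force enumeration", {
  set.seed(4)
  for (rep in 1:3) {
    p <- runif(6, 0, 0.8)
    marg <- setNames(round(p * 50), biome_levels()[1:6])
    an <- analytic_null_bsi(marg, 50)
    f <- pb_bruteforce(as.numeric(marg / 50))
    expect_equal(an$p_zero, f[1], tolerance = 1e-12)
    expect_equal(an$bsi$prob[1:6], f[2:7] / (1 - f[1]), tolerance = 1e-12)
  }
  expect_error(analytic_null_bsi(c(I = 0, II = 0), 5), "zero")
})

test_that("empirical p-values use inclusive counts on both tails", {
  pv <- empirical_pvalue(4, c(1, 2, 3, 4, 5), "upper")
  expect_equal(pv$p, 2 / 5)
  pv2 <- empirical_pvalue(3, rep(3, 10))
  expect_equal(pv2$p_upper, 1)
  expect_equal(pv2$p_lower, 1)
  # observed beyond every replicate: p collapses to the display threshold
  pv3 <- empirical_pvalue(99, runif(10000), "upper")
  expect_equal(pv3$p, 0)
  expect_equal(pv3$p_display, "<0.001")
  # auto picks the tail on the side of the null mean
  expect_equal(empirical_pvalue(10, c(1, 2, 3))$direction, "upper")
  expect_equal(empirical_pvalue(-10, c(1, 2, 3))$direction, "lower")
  expect_error(empirical_pvalue(1, numeric(0)), "Empty")
})

test_that("upper-tail p-values are super-uniform under the null", {
  marg <- c(I = 6, II = 10, IV = 4)
  n <- 15
  ens <- simulate_null(marg, n_species = n, n_reps = 400, seed = 21)
  obs <- simulate_null(marg, n_species = n, n_reps = 200, seed = 22)
  p <- vapply(seq_len(200), function(i) {
    empirical_pvalue(obs$bsi_pct[i, 1], ens$bsi_pct[, 1], "upper")$p
  }, numeric(1))
  for (alpha in c(0.05, 0.2, 0.5)) {
    se <- sqrt(alpha * (1 - alpha) / 200)
    expect_lte(mean(p <= alpha), alpha + 3 * se)
  }
})

test_that("seeded runs are bit-identical and clade filters recompute marginals", {
  pm <- generate_presence_matrix(60, c(I = 20, II = 30, III = 15, VI = 12),
                                 seed = 31)
  a <- run_null_analysis(pm, n_reps = 300, seed = 7)
  b <- run_null_analysis(pm, n_reps = 300, seed = 7)
  expect_identical(a$bsi, b$bsi)
  expect_identical(a$ensemble$bsi_pct, b$ensemble$bsi_pct)

  pm$clade <- rep("All", nrow(pm))
  cl <- run_null_analysis(pm, clade = "All", n_reps = 300, seed = 7)
  expect_equal(cl$bsi, a$bsi)
  expect_error(run_null_analysis(pm, clade = "Missing"), "Missing")

  # empty biomes are reported as undefined, not as zero
  expect_true(is.na(a$biome$null_mean[a$biome$biome == "IX"]))
  expect_true(all(!is.na(a$biome$null_mean[a$biome$sp > 0])))
})

test_that("the summary table reports observed, null moments and both tails", {
  pm <- generate_presence_matrix(50, c(I = 18, II = 25, VIII = 14),
                                 specialist_excess = 0.4, seed = 41)
  res <- run_null_analysis(pm, n_reps = 500, seed = 3)
  expect_named(res$bsi,
               c("bsi", "observed_pct", "null_mean", "null_sd", "null_min",
                 "null_max", "p", "direction", "p_upper", "p_lower", "p_display"))
  expect_true(all(res$bsi$null_mean >= res$bsi$null_min - 1e-12))
  expect_true(all(res$bsi$null_mean <= res$bsi$null_max + 1e-12))
  expect_true(all(res$bsi$p >= 0 & res$bsi$p <= 1))
  expect_equal(sum(res$bsi$observed_pct), 100, tolerance = 1e-9)
  # inclusive two-tail bookkeeping: p_upper + p_lower >= 1 always
  expect_true(all(res$bsi$p_upper + res$bsi$p_lower >= 1 - 1e-12))
})
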