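test_that("speciation-rate shapes evaluate correctly and count parameters", {
  con <- speciation_model("constant", lambda0 = 0.2, mu = 0.01, sigma2 = 0.1)
  expect_equal(lambda_at(con, c(-5, 0, 12)), rep(0.2, 3))
  expect_equal(con$n_par, 3L)

  lin <- speciation_model("linear", lambda0 = 0.2, slope = -0.05,
                          mu = 0.01, sigma2 = 0.1)
  expect_equal(lambda_at(lin, c(0, 2, 10)), c(0.2, 0.1, 0))  # clamped at 0
  expect_equal(lin$n_par, 4L)

  sig <- speciation_model("sigmoid", lambda0 = 0.17, lambda1 = 0.018,
                          xmid = 4.61, r = 40, mu = 0.01, sigma2 = 0.1)
  expect_equal(sig$n_par, 6L)
  expect_equal(lambda_at(sig, 4.61), (0.17 + 0.018) / 2)  # midpoint
  # steep sigmoid: near the asymptotes at BSI 1 and 8
  expect_equal(lambda_at(sig, 1), 0.17, tolerance = 1e-6)
  expect_equal(lambda_at(sig, 8), 0.018, tolerance = 1e-6)

  flat <- speciation_model("sigmoid", lambda0 = 0.1, lambda1 = 0.1,
                           xmid = 3, r = 1, mu = 0, sigma2 = 0.1)
  expect_equal(lambda_at(flat, seq(0, 10)), rep(0.1, 11))  # shape degeneracy

  mod <- speciation_model("modal", lambda0 = 0.3, lambda1 = 0.05, xmid = 4,
                          width = 1.5, mu = 0, sigma2 = 0.1, phi = 0.01)
  expect_equal(lambda_at(mod, 4), 0.3)
  expect_lt(lambda_at(mod, 9), 0.06)
  expect_equal(mod$n_par, 7L)  # drift adds one
})

test_that("the simulator honours degenerate traits, stops and seeds", {
  frozen <- speciation_model("constant", lambda0 = 0.4, mu = 0, sigma2 = 0)
  sim <- simulate_tree(frozen, x0 = 3, max_tips = 12, seed = 5)
  expect_equal(length(sim$tree$tip.label), 12L)
  expect_true(all(sim$traits$x == 3))
  expect_true(ape::is.binary(sim$tree))

  again <- simulate_tree(frozen, x0 = 3, max_tips = 12, seed = 5)
  expect_identical(ape::write.tree(sim$tree), ape::write.tree(again$tree))

  m <- speciation_model("constant", lambda0 = 0.3, mu = 0.1, sigma2 = 0.02)
  timed <- simulate_tree(m, x0 = 2, max_time = 20, seed = 11)
  if (!timed$extinct) {
    depths <- ape::node.depth.edgelength(timed$tree)
    tips <- seq_along(timed$tree$tip.label)
    expect_true(all(abs(depths[tips] - max(depths[tips])) < 1e-9))
  }
})

test_that("pure-birth tip counts match the Yule expectation", {
  lam <- 0.3; tt <- 8
  m <- speciation_model("constant", lambda0 = lam, mu = 0, sigma2 = 0.01)
  set.seed(99)
  counts <- vapply(1:60, function(i) {
    s <- simulate_tree(m, x0 = 2, max_time = tt)
    if (s$extinct) 1 else length(s$tree$tip.label)  # mu = 0: "extinct" = 1 tip
  }, numeric(1))
  expected <- exp(lam * tt)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.5)
})

test_that("speciation enriches low-trait lineages under a decreasing sigmoid", {
  sig <- speciation_model("sigmoid", lambda0 = 0.5, lambda1 = 0.02, xmid = 2,
                          r = 2, mu = 0, sigma2 = 0.4)
  neutral <- speciation_model("constant", lambda0 = 0.25, mu = 0, sigma2 = 0.4)
  set.seed(17)
  mean_tip <- function(model) {
    mean(vapply(1:12, function(i) {
      mean(generate_phylo_dataset(model, x0 = 2, max_tips = 40)$traits$x)
    }, numeric(1)))
  }
  expect_lt(mean_tip(sig), mean_tip(neutral))
})

test_that("trait-independent rates factorize into birth-death and Brownian parts", {
  ds <- quick_dataset(n_tips = 25, lambda = 0.3, mu = 0.05, sigma2 = 0.05, seed = 3)
  mod <- speciation_model("constant", lambda0 = 0.3, mu = 0.05, sigma2 = 0.05)
  tsd <- 0.25
  got <- quasse_loglik(ds, mod, quasse_grid(n_x = 128, dt = 0.5, tip_sd = tsd),
                       root = "flat")
  want <- bd_desolve_loglik(ds$tree, 0.3, 0.05) +
    bm_flat_loglik(ds$tree, ds$traits$x, 0.05, tsd)
  expect_equal(got, want, tolerance = 1e-3)

  # a second parameter set, pure birth
  mod2 <- speciation_model("constant", lambda0 = 0.3, mu = 0, sigma2 = 0.12)
  got2 <- quasse_loglik(ds, mod2, quasse_grid(n_x = 128, dt = 0.5, tip_sd = tsd),
                        root = "flat")
  want2 <- bd_desolve_loglik(ds$tree, 0.3, 0) +
    bm_flat_loglik(ds$tree, ds$traits$x, 0.12, tsd)
  expect_equal(got2, want2, tolerance = 1e-3)
})

test_that("the likelihood converges under grid refinement", {
  ds <- quick_dataset(n_tips = 25, seed = 3)
  sig <- speciation_model("sigmoid", lambda0 = 0.4, lambda1 = 0.05, xmid = 2.5,
                          r = 1.5, mu = 0.03, sigma2 = 0.08)
  base <- quasse_loglik(ds, sig, quasse_grid(n_x = 128, dt = 0.5))
  fine <- quasse_loglik(ds, sig, quasse_grid(n_x = 256, dt = 0.25))
  expect_lt(abs(base - fine), 1e-2)
})

test_that("a three-tip toy matches a fine-resolution reference integration", {
  tree <- ape::read.tree(text = "((a:1.2,b:1.2):0.8,c:2);")
  ds <- phylo_dataset(tree, c(a = 1, b = 2, c = 4))
  sig <- speciation_model("sigmoid", lambda0 = 0.3, lambda1 = 0.05, xmid = 2.5,
                          r = 2, mu = 0.05, sigma2 = 0.1)
  coarse <- quasse_loglik(ds, sig, quasse_grid(n_x = 128, dt = 0.25))
  reference <- quasse_loglik(ds, sig, quasse_grid(n_x = 1024, dt = 0.01))
  expect_equal(coarse, reference, tolerance = 1e-4)
})

test_that("sigmoid with equal asymptotes reproduces the constant likelihood", {
  ds <- quick_dataset(n_tips = 20, seed = 8)
  g <- quasse_grid(n_x = 128, dt = 0.5, lo = -8, hi = 12)
  con <- speciation_model("constant", lambda0 = 0.25, mu = 0.02, sigma2 = 0.06)
  deg <- speciation_model("sigmoid", lambda0 = 0.25, lambda1 = 0.25, xmid = 3,
                          r = 1, mu = 0.02, sigma2 = 0.06)
  expect_equal(quasse_loglik(ds, con, g), quasse_loglik(ds, deg, g),
               tolerance = 1e-9)
})

test_that("extinction probabilities stay inside [0, 1] along a branch", {
  gr <- biomespec:::resolve_grid(quasse_grid(n_x = 128, dt = 0.5), c(1, 5),
                                 spread = 4.5 * sqrt(0.3 * 25))
  lam <- lambda_at(speciation_model("sigmoid", lambda0 = 0.5, lambda1 = 0.01,
                                    xmid = 3, r = 2, mu = 0.2, sigma2 = 0.3),
                   gr$x)
  st <- biomespec:::propagate_branch(
    E = numeric(gr$n), D = dnorm(gr$x, 3, 0.25), len = 25,
    lam = lam, mu = 0.2, sigma2 = 0.3, phi = 0,
    gr = gr, kernel_cache = new.env()
  )
  expect_true(all(st$E >= 0 & st$E <= 1))
  expect_true(all(st$D >= 0))
})

test_that("narrow grids are rejected rather than silently truncated", {
  ds <- quick_dataset(n_tips = 15, seed = 12)
  mod <- speciation_model("constant", lambda0 = 0.3, mu = 0, sigma2 = 2)
  expect_error(
    quasse_loglik(ds, mod, quasse_grid(lo = min(ds$traits$x) - 1.2,
                                       hi = max(ds$traits$x) + 1.2, n_x = 64)),
    "bounds"
  )
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_error(
    quasse_loglik(phylo_dataset(star, c(a = 1, b = 2, c = 3)), mod),
    "binary"
  )
})

test_that("a richer nested model never fits worse than its special case", {
  ds <- quick_dataset(n_tips = 40, seed = 21)
  ctl <- list(maxit = 150)
  fc <- fit_speciation_model(ds, "constant", n_starts = 1, control = ctl)
  fs <- fit_speciation_model(
    ds, "sigmoid", n_starts = 1, control = ctl,
    init = list(lambda0 = fc$model$pars$lambda0,
                lambda1 = fc$model$pars$lambda0,
                mu = fc$model$pars$mu, sigma2 = fc$model$pars$sigma2)
  )
  expect_gte(fs$lnL, fc$lnL - 1e-4)
  # refits are deterministic
  fc2 <- fit_speciation_model(ds, "constant", n_starts = 1, control = ctl)
  expect_identical(fc$estimates, fc2$estimates)
  expect_identical(fc$lnL, fc2$lnL)
  expect_equal(fc$AIC, 2 * 3 - 2 * fc$lnL)
})

test_that("AIC comparison flags ties and summarizes across trees", {
  mk_fit <- function(lnL, n_par, shape, tree) {
    structure(list(shape = shape, drift = FALSE, lnL = lnL,
                   AIC = 2 * n_par - 2 * lnL, n_par = n_par, converged = TRUE),
              class = "speciation_fit")
  }
  fits <- list(mk_fit(-100, 6, "sigmoid"), mk_fit(-100, 7, "modal"),
               mk_fit(-120, 3, "constant"))
  cmp <- compare_speciation_models(fits, tree = c(1, 1, 1))
  per <- cmp$per_fit
  expect_equal(per$dAIC[per$model == "modal"], 2)   # equal lnL, one extra par
  expect_true(per$tie[per$model == "modal"])
  expect_false(per$tie[per$model == "constant"])
  expect_equal(per$model[per$best], "sigmoid")

  # a non-converged fit is excluded, and single-fit trees are dropped
  bad <- mk_fit(-90, 6, "sigmoid")
  bad$converged <- FALSE
  expect_warning(
    expect_warning(
      cmp2 <- compare_speciation_models(c(fits, list(bad, mk_fit(-80, 3, "constant"))),
                                        tree = c(1, 1, 1, 2, 2)),
      "non-converged"
    ),
    "fewer than two"
  )
  expect_equal(sort(unique(cmp2$per_fit$tree)), 1)
})

test_that("polytomy resolution yields binary trees with conserved depths", {
  binary <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  out <- resolve_polytomies(binary, n_resolutions = 3, seed = 1)
  expect_length(out, 3)
  for (tr in out) expect_identical(ape::write.tree(tr), ape::write.tree(binary))

  star <- ape::read.tree(text = "(a:3,b:3,c:3,d:3,e:3);")
  res <- resolve_polytomies(star, n_resolutions = 5, seed = 2)
  for (tr in res) {
    expect_true(ape::is.binary(tr))
    expect_equal(tr$Nnode, 4L)  # k - 1 internal nodes for k = 5 tips
    d <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
    expect_equal(d, rep(3, 5), tolerance = 1e-9)
  }

  mixed <- ape::read.tree(text = "((a:1,b:1,c:1):2,(d:2,e:2,f:2,g:2):1);")
  res2 <- resolve_polytomies(mixed, n_resolutions = 10, seed = 3)
  ref <- ape::node.depth.edgelength(mixed)[seq_along(mixed$tip.label)]
  for (tr in res2) {
    expect_true(ape::is.binary(tr))
    ord <- match(mixed$tip.label, tr$tip.label)
    d <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)][ord]
    expect_equal(d, ref, tolerance = 1e-9)
  }
  # distinct resolutions do appear
  expect_gt(length(unique(vapply(res2, ape::write.tree, character(1)))), 1)
})
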