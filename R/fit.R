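# Maximum-likelihood fitting of trait-dependent speciation models and AIC
# comparison across a distribution of trees. Rates are optimized on the log
# scale (which enforces positivity), location/slope/drift parameters on
# their natural scale, by Nelder-Mead simplex search from a documented set
# of starting points.

# mean squared phylogenetic independent contrast, robust to zero-length
# branches (which yield non-finite contrasts)
est_sigma2 <- function(dataset) {
  p2 <- ape::pic(setNames(dataset$traits$x, dataset$tree$tip.label),
                 dataset$tree)^2
  p2 <- p2[is.finite(p2)]
  if (length(p2) == 0) return(1e-3)
  max(mean(p2), 1e-3)
}

par_spec <- function(shape, drift) {
  base <- switch(shape,
    constant = c(lambda0 = "log"),
    linear = c(lambda0 = "log", slope = "id"),
    sigmoid = c(lambda0 = "log", lambda1 = "log", xmid = "id", r = "log"),
    modal = c(lambda0 = "log", lambda1 = "log", xmid = "id", width = "log")
  )
  out <- c(base, mu = "log", sigma2 = "log")
  if (drift) out <- c(out, phi = "id")
  out
}

pack_par <- function(pars, spec) {
  vapply(names(spec), function(nm) {
    v <- pars[[nm]]
    if (spec[nm] == "log") log(max(v, 1e-8)) else v
  }, numeric(1))
}

unpack_par <- function(theta, spec) {
  out <- as.list(theta)
  names(out) <- names(spec)
  for (nm in names(spec)) if (spec[nm] == "log") out[[nm]] <- exp(out[[nm]])
  out
}

model_from_pars <- function(shape, drift, p) {
  speciation_model(shape,
    lambda0 = p$lambda0, lambda1 = p$lambda1, xmid = p$xmid, r = p$r,
    width = p$width, slope = p$slope, mu = p$mu, sigma2 = p$sigma2,
    phi = if (drift) p$phi else NULL)
}

# Documented multistart table. lam_hat is a Yule-type rate guess
# (ntip - 2) / total branch length; sig_hat the mean squared phylogenetic
# independent contrast; trait quantiles anchor the location parameters.
default_starts <- function(dataset, shape, drift) {
  phy <- dataset$tree
  xs <- dataset$traits$x
  tl <- sum(phy$edge.length)
  lam_hat <- max((length(phy$tip.label) - 2) / tl, 0.01)
  sig_hat <- est_sigma2(dataset)
  wd <- max(sd(xs), 0.5)
  base <- list(mu = lam_hat / 10, sigma2 = sig_hat)
  starts <- switch(shape,
    constant = list(
      c(list(lambda0 = lam_hat), base),
      c(list(lambda0 = 2 * lam_hat), list(mu = lam_hat / 2, sigma2 = 3 * sig_hat)),
      c(list(lambda0 = lam_hat / 2), list(mu = lam_hat / 50, sigma2 = sig_hat / 3))
    ),
    linear = list(
      c(list(lambda0 = lam_hat, slope = 0), base),
      c(list(lambda0 = 2 * lam_hat, slope = -lam_hat / (2 * wd)), base),
      c(list(lambda0 = lam_hat / 2, slope = lam_hat / (2 * wd)), base)
    ),
    sigmoid = list(
      c(list(lambda0 = 2 * lam_hat, lambda1 = lam_hat / 2,
             xmid = median(xs), r = 1), base),
      c(list(lambda0 = lam_hat, lambda1 = lam_hat,
             xmid = mean(xs), r = 1), base),
      c(list(lambda0 = 4 * lam_hat, lambda1 = lam_hat / 4,
             xmid = unname(quantile(xs, 0.3)), r = 2), base)
    ),
    modal = list(
      c(list(lambda0 = 2 * lam_hat, lambda1 = lam_hat / 2,
             xmid = median(xs), width = wd), base),
      c(list(lambda0 = lam_hat, lambda1 = lam_hat,
             xmid = mean(xs), width = wd), base),
      c(list(lambda0 = 4 * lam_hat, lambda1 = lam_hat / 4,
             xmid = unname(quantile(xs, 0.7)), width = wd / 2), base)
    )
  )
  if (drift) starts <- purrr::map2(starts, c(0, 0.02, -0.02),
                                   function(s, ph) c(s, list(phi = ph)))
  starts
}

#' Fit a trait-dependent speciation model by maximum likelihood
#'
#' Maximizes [quasse_loglik()] over the model's free parameters
#' (Nelder-Mead on log-transformed rates, multistarted from a documented set
#' of initial values). Grid bounds are resolved once from the data and held
#' fixed across the optimization so likelihoods are comparable.
#'
#' @inheritParams quasse_loglik
#' @param shape Speciation-rate shape (see [speciation_model()]).
#' @param drift If `TRUE`, include the directional drift parameter `phi`.
#' @param n_starts Number of starting points from the documented multistart
#'   table (1 to 3).
#' @param init Optional named list of starting parameter values, used as an
#'   additional starting point (e.g. the estimates of a simpler nested fit).
#' @param control Passed to [stats::optim()] (defaults: `maxit = 500`,
#'   `reltol = 1e-8`).
#' @return An object of class `speciation_fit`: the fitted
#'   [speciation_model()], `lnL`, `AIC = 2 n_par - 2 lnL`, convergence
#'   diagnostics, and the resolved grid.
#' @export
fit_speciation_model <- function(dataset, shape = "constant", drift = FALSE,
                                 grid = quasse_grid(), root = "weighted",
                                 n_starts = 3, init = NULL, control = list()) {
  stopifnot(inherits(dataset, "phylo_dataset"))
  spec <- par_spec(shape, drift)
  # freeze bounds once so every evaluation integrates over the same domain;
  # the padding leaves room for diffusion up to several times the
  # contrast-based sigma2 estimate over the full tree depth
  depth <- max(ape::node.depth.edgelength(dataset$tree))
  sig_hat <- est_sigma2(dataset)
  # independent of shape and drift so fits on one dataset share the domain
  gr0 <- resolve_grid(grid, dataset$traits$x,
                      spread = 5 * sqrt(sig_hat * depth) + 3 * grid$tip_sd)
  grid_fixed <- quasse_grid(lo = gr0$lo, hi = gr0$hi, n_x = grid$n_x,
                            dt = grid$dt, tip_sd = grid$tip_sd)
  control <- modifyList(list(maxit = 500, reltol = 1e-8), control)

  negloglik <- function(theta) {
    p <- unpack_par(theta, spec)
    ll <- tryCatch(
      quasse_loglik(dataset, model_from_pars(shape, drift, p), grid_fixed, root),
      error = function(e) -Inf
    )
    if (!is.finite(ll)) 1e10 else -ll
  }

  starts <- default_starts(dataset, shape, drift)[seq_len(min(n_starts, 3))]
  if (!is.null(init)) {
    base <- starts[[1]]
    starts <- c(list(modifyList(base, init[names(init) %in% names(spec)])), starts)
  }
  best <- NULL; best_start <- NA_integer_
  for (i in seq_along(starts)) {
    fit <- optim(pack_par(starts[[i]], spec), negloglik,
                 method = "Nelder-Mead", control = control)
    if (is.null(best) || fit$value < best$value) {
      best <- fit; best_start <- i
    }
  }
  pars <- unpack_par(best$par, spec)
  lnL <- -best$value
  model <- model_from_pars(shape, drift, pars)
  n_par <- model$n_par
  structure(
    list(shape = shape, drift = drift, model = model,
         estimates = tibble::tibble(term = names(spec), estimate = unlist(pars)),
         lnL = lnL, AIC = 2 * n_par - 2 * lnL, n_par = n_par,
         converged = best$convergence == 0 && lnL > -1e9,
         counts = best$counts, start_used = best_start,
         grid = grid_fixed, root = root),
    class = "speciation_fit"
  )
}

#' @export
print.speciation_fit <- function(x, ...) {
  cat("Trait-dependent speciation fit: ", x$shape,
      if (x$drift) " + drift", "\n", sep = "")
  cat("  lnL =", signif(x$lnL, 6), " AIC =", signif(x$AIC, 6),
      " (", x$n_par, "parameters,",
      if (x$converged) "converged" else "NOT converged", ")\n")
  print(as.data.frame(x$estimates), row.names = FALSE)
  invisible(x)
}

model_label <- function(shape, drift) paste0(shape, ifelse(drift, "+drift", ""))

#' Compare speciation-model fits by AIC, within and across trees
#'
#' Computes `AIC = 2 n - 2 lnL` per fit, per-tree `dAIC` relative to the
#' best model on that tree, and across-tree summaries (mean, sd, range of
#' lnL/AIC/dAIC and the frequency with which each model is best). A dAIC of
#' two units or less is flagged as an indistinguishable tie. Non-converged
#' fits are excluded with a warning; trees left with fewer than two fits are
#' dropped.
#'
#' @param fits A list of `speciation_fit` objects.
#' @param tree Optional vector of tree identifiers parallel to `fits`
#'   (default: all fits belong to one tree).
#' @return An object of class `model_comparison`: list with `per_fit` and
#'   `summary` tibbles.
#' @export
compare_speciation_models <- function(fits, tree = NULL) {
  stopifnot(length(fits) >= 2, all(vapply(fits, inherits, logical(1), "speciation_fit")))
  if (is.null(tree)) tree <- rep(1L, length(fits))
  stopifnot(length(tree) == length(fits))
  tab <- purrr::map2_dfr(fits, tree, function(f, tr) {
    tibble::tibble(tree = tr, model = model_label(f$shape, f$drift),
                   n_par = f$n_par, lnL = f$lnL, AIC = f$AIC,
                   converged = f$converged)
  })
  if (any(!tab$converged)) {
    warn(paste0(sum(!tab$converged), " non-converged fit(s) excluded from comparison."))
    tab <- tab[tab$converged, ]
  }
  ok_trees <- names(which(table(tab$tree) >= 2))
  dropped <- setdiff(unique(as.character(tab$tree)), ok_trees)
  if (length(dropped) > 0) {
    warn(paste0("Tree(s) with fewer than two successful fits dropped: ",
                paste(dropped, collapse = ", ")))
    tab <- tab[as.character(tab$tree) %in% ok_trees, ]
  }
  if (nrow(tab) == 0) abort("No tree has two or more successful fits.")
  per_fit <- tab |>
    dplyr::group_by(.data$tree) |>
    dplyr::mutate(
      dAIC = .data$AIC - min(.data$AIC),
      best = .data$AIC == min(.data$AIC),
      tie = .data$dAIC <= 2
    ) |>
    dplyr::ungroup()
  summary <- per_fit |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n_par = .data$n_par[1],
      n_trees = dplyr::n(),
      mean_lnL = mean(.data$lnL), sd_lnL = sd(.data$lnL),
      min_lnL = min(.data$lnL), max_lnL = max(.data$lnL),
      mean_AIC = mean(.data$AIC), sd_AIC = sd(.data$AIC),
      min_AIC = min(.data$AIC), max_AIC = max(.data$AIC),
      mean_dAIC = mean(.data$dAIC),
      freq_best = mean(.data$best),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean_dAIC)
  structure(list(per_fit = per_fit, summary = summary), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison across", length(unique(x$per_fit$tree)), "tree(s):\n")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}
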