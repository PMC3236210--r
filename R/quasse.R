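# Likelihood of a tree + tip traits under trait-dependent speciation
# (QuaSSE-style). Along every branch the pair (E, D) -- extinction
# probability and lineage likelihood density over trait space -- is
# propagated root-ward on a regular trait grid by operator splitting:
# the birth-death reaction is solved pointwise in closed form (lambda(x)
# frozen at each grid point over a step), and Brownian diffusion with drift
# is applied spectrally (exact Gaussian multiplier in Fourier space), in a
# Strang (reaction half-step / diffusion / reaction half-step) sequence.
# At internal nodes D_left * D_right * lambda(x); at the root the log of a
# weighted average of D over the grid.

#' Numerical configuration for the trait-grid likelihood
#'
#' @param lo,hi Trait-grid bounds. When `NULL` they are resolved from the
#'   data at likelihood time as the tip-trait range padded by
#'   `max(5 * tip_sd, 3 * sd(x), 2)`, wide enough that probability mass does
#'   not reach the (periodic) boundary.
#' @param n_x Number of grid points (>= 64; powers of two make the FFT
#'   cheapest).
#' @param dt Maximum time step for branch propagation (Myr).
#' @param tip_sd Standard deviation of the Gaussian kernel used as tip
#'   initial condition (trait units). BSI is integer-valued but modeled as
#'   continuous; a narrow kernel (default 0.25) stands in for a delta.
#' @return An object of class `quasse_grid`.
#' @export
quasse_grid <- function(lo = NULL, hi = NULL, n_x = 128, dt = 0.5, tip_sd = 0.25) {
  stopifnot(n_x >= 64, dt > 0, tip_sd > 0)
  if (!is.null(lo) && !is.null(hi) && hi <= lo) abort("`hi` must exceed `lo`.")
  structure(list(lo = lo, hi = hi, n_x = as.integer(n_x), dt = dt, tip_sd = tip_sd),
            class = "quasse_grid")
}

resolve_grid <- function(grid, x_tips, spread = 0) {
  lo <- grid$lo; hi <- grid$hi
  if (is.null(lo) || is.null(hi)) {
    # bound the domain by the tip range plus room for the diffusive spread
    # accumulated over the tree depth (`spread`, supplied by the caller)
    pad <- max(5 * grid$tip_sd, sd(x_tips), 2, spread)
    if (is.null(lo)) lo <- min(x_tips) - pad
    if (is.null(hi)) hi <- max(x_tips) + pad
  }
  n <- grid$n_x
  dx <- (hi - lo) / n
  x <- lo + (seq_len(n) - 1) * dx
  # angular frequencies of the periodic domain, fft ordering
  kk <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  w <- 2 * pi * kk / (n * dx)
  list(lo = lo, hi = hi, n = n, dx = dx, x = x, w = w,
       dt = grid$dt, tip_sd = grid$tip_sd)
}

# Closed-form solution of the birth-death reaction over a step of length t,
# pointwise in x (lam is a vector over the grid):
#   dE/dt = mu - (lam + mu) E + lam E^2,   dD/dt = -(lam + mu) D + 2 lam E D
reaction_step <- function(E0, D0, lam, mu, t) {
  if (t == 0) return(list(E = E0, D = D0))
  r <- lam - mu
  E1 <- numeric(length(E0)); fac <- numeric(length(E0))
  crit <- abs(r) * t < 1e-10          # lambda ~= mu (double root at E = 1)
  dead <- lam < 1e-14                 # pure death
  gen <- !crit & !dead
  if (any(gen)) {
    b <- mu / lam[gen]
    ert <- exp(r[gen] * t)
    a1 <- E0[gen] - b
    a2 <- E0[gen] - 1
    den <- a1 - a2 * ert
    E1[gen] <- (a1 - b * a2 * ert) / den
    fac[gen] <- ert * (1 - b)^2 / den^2
  }
  if (any(crit)) {
    g <- lam[crit] * t * (1 - E0[crit])
    E1[crit] <- 1 - (1 - E0[crit]) / (1 + g)
    fac[crit] <- 1 / (1 + g)^2
  }
  if (any(dead)) {
    emt <- exp(-mu * t)
    E1[dead] <- 1 + (E0[dead] - 1) * emt
    fac[dead] <- emt
  }
  list(E = E1, D = D0 * fac)
}

# Propagate (E, D) along one branch of length `len`. Returns the updated
# pair plus the log normalization factor taken out of D.
propagate_branch <- function(E, D, len, lam, mu, sigma2, phi, gr, kernel_cache) {
  if (len <= 0) return(list(E = E, D = D, logcomp = 0))
  nst <- max(1L, ceiling(len / gr$dt))
  h <- len / nst
  key <- as.character(signif(h, 12))
  M <- kernel_cache[[key]]
  if (is.null(M)) {
    # spectral multiplier of E[f(x + phi h + sqrt(sigma2 h) Z)]
    M <- exp(-sigma2 * h * gr$w^2 / 2 + 1i * phi * h * gr$w)
    kernel_cache[[key]] <- M
  }
  st <- reaction_step(E, D, lam, mu, h / 2)
  n <- gr$n
  for (s in seq_len(nst)) {
    z <- fft(st$E + 1i * st$D)
    z <- fft(z * M, inverse = TRUE) / n
    E1 <- pmin(pmax(Re(z), 0), 1)
    D1 <- pmax(Im(z), 0)
    st <- reaction_step(E1, D1, lam, mu, if (s < nst) h else h / 2)
  }
  q <- sum(st$D) * gr$dx
  if (!is.finite(q) || q <= 0) abort("Likelihood underflow during branch propagation.")
  edge_mass <- (sum(st$D[1:3]) + sum(st$D[(n - 2):n])) * gr$dx / q
  if (edge_mass > 1e-4) {
    abort("Probability mass is leaking past the trait-grid bounds; widen `lo`/`hi`.")
  }
  list(E = st$E, D = st$D / q, logcomp = log(q))
}

#' Trait-grid log-likelihood of a tree under a speciation model
#'
#' @param dataset A [phylo_dataset()] with a strictly binary tree.
#' @param model A [speciation_model()].
#' @param grid A [quasse_grid()] numerical configuration.
#' @param root Root treatment: `"weighted"` (default) averages D over the
#'   grid with weights proportional to D itself; `"flat"` integrates D
#'   against a flat prior on the grid.
#' @return The log-likelihood (a single numeric value).
#' @export
quasse_loglik <- function(dataset, model, grid = quasse_grid(),
                          root = c("weighted", "flat")) {
  root <- match.arg(root)
  stopifnot(inherits(dataset, "phylo_dataset"), inherits(model, "speciation_model"),
            inherits(grid, "quasse_grid"))
  phy <- dataset$tree
  if (!ape::is.binary(phy)) abort("Tree must be strictly binary; resolve polytomies first.")
  xobs <- setNames(dataset$traits$x, dataset$traits$species)
  depth <- max(ape::node.depth.edgelength(phy))
  spread <- 4.5 * sqrt(model$pars$sigma2 * depth) + 3 * grid$tip_sd +
    abs(drift_of(model)) * depth
  gr <- resolve_grid(grid, xobs, spread = spread)
  # never let the tip kernel fall below one grid cell, or the discretized
  # delta degenerates into sampling noise
  gr$tip_sd <- max(gr$tip_sd, gr$dx)
  if (min(xobs) - 3 * gr$tip_sd < gr$lo || max(xobs) + 3 * gr$tip_sd > gr$hi) {
    abort("Tip traits fall too close to the trait-grid bounds; widen `lo`/`hi`.")
  }
  lam <- lambda_at(model, gr$x)
  mu <- model$pars$mu
  sigma2 <- model$pars$sigma2
  phi <- drift_of(model)
  kernel_cache <- new.env(parent = emptyenv())

  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  pending <- vector("list", ntip + phy$Nnode)
  logcomp <- 0

  node_state <- function(node) {
    if (node <= ntip) {
      list(E = numeric(gr$n), D = dnorm(gr$x, xobs[phy$tip.label[node]], gr$tip_sd))
    } else {
      kids <- pending[[node]]
      if (length(kids) != 2) abort("Tree must be strictly binary.")
      list(E = kids[[1]]$E, D = kids[[1]]$D * kids[[2]]$D * lam)
    }
  }

  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]; child <- phy$edge[e, 2]
    st <- node_state(child)
    res <- propagate_branch(st$E, st$D, phy$edge.length[e], lam, mu,
                            sigma2, phi, gr, kernel_cache)
    logcomp <- logcomp + res$logcomp
    pending[[par]] <- c(pending[[par]], list(list(E = res$E, D = res$D)))
  }
  root_node <- ntip + 1L
  st <- node_state(root_node)
  D <- st$D
  tot <- sum(D) * gr$dx
  if (!is.finite(tot) || tot <= 0) abort("Likelihood underflow at the root.")
  lik <- switch(root,
    flat = tot,
    weighted = sum(D^2) / sum(D)
  )
  logcomp + log(lik)
}
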