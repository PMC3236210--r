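# Independent oracles, deliberately kept on different computational routes
# than the implementation they check.

# Exhaustive enumeration of the richness-constrained null on tiny systems:
# every combination of sp_b-subsets across biomes, all equally likely.
# Returns the expected per-replicate conditional BSI percentages and the
# expected per-biome specialist fractions.
enum_null_exact <- function(marginals, n_species) {
  marginals <- marginals[marginals > 0]
  subsets <- lapply(marginals, function(k) {
    utils::combn(n_species, k, simplify = FALSE)
  })
  idx <- expand.grid(lapply(subsets, seq_along))
  bsi_pct <- matrix(0, nrow(idx), n_species)
  spec <- matrix(NA_real_, nrow(idx), length(marginals))
  for (a in seq_len(nrow(idx))) {
    counts <- integer(n_species)
    members <- vector("list", length(marginals))
    for (b in seq_along(marginals)) {
      s <- subsets[[b]][[idx[a, b]]]
      counts[s] <- counts[s] + 1L
      members[[b]] <- s
    }
    occ <- sum(counts > 0)
    bsi_pct[a, ] <- 100 * tabulate(counts, n_species) / occ
    for (b in seq_along(marginals)) {
      spec[a, b] <- 100 * mean(counts[members[[b]]] == 1L)
    }
  }
  list(mean_bsi_pct = colMeans(bsi_pct),
       mean_specialist_pct = setNames(colMeans(spec), names(marginals)),
       n_assignments = nrow(idx))
}

# Poisson-binomial mass by brute-force enumeration over all 2^B occupancy
# patterns (independent route from the implementation's convolution).
pb_bruteforce <- function(p) {
  B <- length(p)
  f <- numeric(B + 1)
  for (code in 0:(2^B - 1)) {
    bits <- as.integer(intToBits(code)[1:B])
    prob <- prod(ifelse(bits == 1, p, 1 - p))
    f[sum(bits) + 1] <- f[sum(bits) + 1] + prob
  }
  f
}

# Closed-form Brownian-motion likelihood with a flat prior on the root
# state and Gaussian tip measurement error (the tip kernel sd).
bm_flat_loglik <- function(tree, x, sigma2, tip_sd) {
  V <- sigma2 * ape::vcv(tree) + diag(tip_sd^2, length(x))
  n <- length(x)
  Vi <- solve(V)
  a <- sum(Vi)
  b <- sum(Vi %*% x)
  cc <- drop(t(x) %*% Vi %*% x)
  as.numeric(-n / 2 * log(2 * pi) - 0.5 * determinant(V)$modulus +
               0.5 * log(2 * pi / a) - 0.5 * (cc - b^2 / a))
}

# Constant-rate birth-death tree likelihood via scalar ODE integration
# (deSolve), same E/D recursion conventions as the grid code but an
# entirely different integrator.
bd_desolve_loglik <- function(tree, lambda, mu) {
  deriv <- function(t, y, parms) {
    E <- y[1]; D <- y[2]
    list(c(mu - (lambda + mu) * E + lambda * E^2,
           -(lambda + mu) * D + 2 * lambda * E * D))
  }
  phy <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(phy$tip.label)
  st <- vector("list", ntip + phy$Nnode)
  logc <- 0
  init <- function(n) {
    if (n <= ntip) c(0, 1)
    else { k <- st[[n]]; c(k[[1]][1], k[[1]][2] * k[[2]][2] * lambda) }
  }
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    y0 <- init(ch)
    sc <- y0[2]; y0[2] <- 1
    len <- phy$edge.length[e]
    if (len > 0) {
      out <- deSolve::lsoda(y0, c(0, len), deriv, NULL, rtol = 1e-10, atol = 1e-12)
      yf <- out[nrow(out), 2:3]
    } else yf <- y0
    logc <- logc + log(sc) + log(yf[2])
    st[[p]] <- c(st[[p]], list(c(yf[1], 1)))
  }
  root <- init(ntip + 1)
  unname(logc + log(root[2]))
}
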