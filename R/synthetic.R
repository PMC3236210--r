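# Synthetic-data generators. These emulate the statistical structure the
# analyses assume -- per-biome richness marginals, an excess of single-biome
# specialists, montane routing, and trees grown under the trait-dependent
# birth-death process -- without attempting to reconstruct any real
# species-by-biome dataset.

#' Generate a presence matrix with exact richness marginals
#'
#' Species are assigned to biomes by a mixture process: a configurable
#' share of species are biome specialists (exactly one biome, drawn without
#' replacement from an urn holding each biome's richness), and the rest draw
#' their biome sets from the independent-occupancy null law
#' (`P(biome b) = sp_b / N`) conditioned on a minimum of one (or, when the
#' specialist count is pinned exactly, two) biomes. Because occupying every
#' species while matching the marginals can require more (or fewer)
#' presences than that law naturally produces, the occupancy probabilities
#' are exponentially tilted so the expected non-specialist total equals the
#' required total; the block is then redrawn until the total matches
#' exactly, and residual column-sum mismatches are repaired by moving
#' single presences between biomes within a species, which leaves every
#' species' BSI unchanged. Column sums therefore match the target marginals
#' exactly. When the marginals make zero occupancy likely under the null
#' law, the tilt is what reconciles full occupancy with exact marginals --
#' the per-species BSI law is then mildly shifted relative to the
#' unconstrained null (see the methods vignette).
#'
#' @param n_species Number of species N.
#' @param marginals Target per-biome richness (named vector over
#'   [biome_levels()] or data frame `biome`, `sp`); must satisfy
#'   `sum(marginals) >= n_species` so every species can occupy a biome.
#' @param specialist_excess Probability that a species is generated as a
#'   pure specialist, beyond what the null law already produces. Use
#'   [calibrate_specialist_excess()] to hit a target observed specialist
#'   percentage.
#' @param n_specialists Exact number of specialists (overrides
#'   `specialist_excess`; remaining species get BSI >= 2).
#' @param specialist_counts Exact per-biome specialist counts (named
#'   vector; overrides both other specialist arguments).
#' @param montane_fraction Fraction of species flagged as montane dwellers
#'   (routed through montane dominions by [generate_overlap_table()]).
#' @param clade Optional character vector of clade labels, length
#'   `n_species`, stored as a `clade` column.
#' @param seed Optional integer seed.
#' @param max_redraws Redraw budget for matching the total presence count.
#' @return A presence tibble (`species`, ten 0/1 biome columns, `montane`,
#'   optionally `clade`).
#' @export
#' @examples
#' pm <- generate_presence_matrix(30, c(I = 12, II = 20, III = 10), seed = 1)
#' biome_richness(pm)[c("I", "II", "III")]
generate_presence_matrix <- function(n_species, marginals,
                                     specialist_excess = 0,
                                     n_specialists = NULL,
                                     specialist_counts = NULL,
                                     montane_fraction = 0,
                                     clade = NULL, seed = NULL,
                                     max_redraws = 5000) {
  marginals <- as_marginals(marginals)
  N <- as.integer(n_species)
  Tt <- sum(marginals)
  B <- length(marginals)
  if (any(marginals > N)) abort("A biome's richness cannot exceed `n_species`.")
  if (Tt < N) abort("Infeasible marginals: fewer presences than species.")
  if (!is.null(seed)) set.seed(seed)

  exact_spec <- !is.null(n_specialists) || !is.null(specialist_counts)
  if (!is.null(specialist_counts)) {
    sc <- as_marginals(specialist_counts)
    if (any(sc > marginals)) {
      abort("Per-biome specialist counts cannot exceed the richness marginals.")
    }
    spec_biome <- rep(names(sc), sc)
  } else {
    S <- if (!is.null(n_specialists)) as.integer(n_specialists)
         else sum(runif(N) < specialist_excess)
    urn <- rep(names(marginals), marginals)
    spec_biome <- if (S > 0) sample(urn, S) else character(0)
  }
  S <- length(spec_biome)
  kmin <- if (exact_spec) 2L else 1L
  M <- N - S
  target_rest <- Tt - S
  if (M > 0 && (target_rest < kmin * M || target_rest > B * M)) {
    abort("Infeasible combination of marginals and specialist settings.")
  }
  if (M == 0 && target_rest != 0) {
    abort("All species are specialists but the marginals require more presences.")
  }

  p <- marginals / N
  # tilt the occupancy probabilities so that the expected per-species count
  # (conditional on >= kmin) matches what the marginals require
  q <- p
  if (M > 0) {
    cond_mean <- function(theta) {
      qq <- p * exp(theta) / (1 - p + p * exp(theta))
      f <- 1
      for (qb in qq) f <- c(f * (1 - qb), 0) + c(0, f * qb)
      k <- seq_along(f) - 1
      keep <- k >= kmin
      sum(k[keep] * f[keep]) / sum(f[keep])
    }
    m_star <- target_rest / M
    if (abs(cond_mean(0) - m_star) > 1e-9) {
      theta <- tryCatch(
        stats::uniroot(function(t) cond_mean(t) - m_star, c(-12, 12))$root,
        error = function(e) abort("Marginals are too extreme to tilt toward.")
      )
      q <- p * exp(theta) / (1 - p + p * exp(theta))
    }
  }
  draw_species <- function() {
    repeat {
      v <- runif(B) < q
      if (sum(v) >= kmin) return(v)
    }
  }
  occ <- matrix(FALSE, N, B, dimnames = list(NULL, names(marginals)))
  if (S > 0) {
    for (i in seq_len(S)) occ[i, spec_biome[i]] <- TRUE
  }
  if (M > 0) {
    rows <- (S + 1):N
    done <- FALSE
    best <- NULL; best_gap <- Inf
    for (it in seq_len(max_redraws)) {
      block <- t(vapply(rows, function(i) draw_species(), logical(B)))
      gap <- abs(sum(block) - target_rest)
      if (gap < best_gap) { best <- block; best_gap <- gap }
      if (gap == 0) { done <- TRUE; break }
    }
    if (!done) {
      warn("Could not match the total presence count exactly by redrawing; adjusting.")
      block <- best
      diffn <- target_rest - sum(block)
      while (diffn != 0) {
        i <- sample.int(M, 1)
        if (diffn > 0) {
          cand <- which(!block[i, ])
          if (length(cand) > 0) {
            block[i, sample(cand, 1)] <- TRUE; diffn <- diffn - 1
          }
        } else {
          cand <- which(block[i, ])
          if (length(cand) > kmin) {
            block[i, sample(cand, 1)] <- FALSE; diffn <- diffn + 1
          }
        }
      }
    }
    occ[rows, ] <- block
  }

  # column-sum repair by BSI-preserving swaps within a species
  swappable <- rep(TRUE, N)
  if (!is.null(specialist_counts) && S > 0) swappable[seq_len(S)] <- FALSE
  guard <- 0L
  repeat {
    cur <- colSums(occ)
    if (all(cur == marginals)) break
    guard <- guard + 1L
    if (guard > 20L * Tt + 100L) abort("Column-sum repair failed to converge.")
    over <- which(cur > marginals)
    under <- which(cur < marginals)
    moved <- FALSE
    for (b1 in sample(over)) {
      for (b2 in sample(under)) {
        cand <- which(occ[, b1] & !occ[, b2] & swappable)
        if (length(cand) > 0) {
          i <- cand[sample.int(length(cand), 1)]
          occ[i, b1] <- FALSE; occ[i, b2] <- TRUE
          moved <- TRUE; break
        }
      }
      if (moved) break
    }
    if (!moved) {
      # last resort: move a presence between two species (changes their BSI)
      b1 <- over[1]; b2 <- under[1]
      donors <- which(occ[, b1] & rowSums(occ) > kmin)
      takers <- which(!occ[, b2] & swappable)
      if (length(donors) == 0 || length(takers) == 0) {
        abort("Column-sum repair failed: no valid move available.")
      }
      occ[donors[sample.int(length(donors), 1)], b1] <- FALSE
      occ[takers[sample.int(length(takers), 1)], b2] <- TRUE
    }
  }

  ord <- sample.int(N)  # shuffle so specialists are not the leading rows
  occ <- occ[ord, , drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(ifelse(occ, 1L, 0L)))
  names(out) <- names(marginals)
  out <- dplyr::bind_cols(
    tibble::tibble(species = sprintf("sp%03d", seq_len(N))), out
  )
  out$montane <- runif(N) < montane_fraction
  if (!is.null(clade)) {
    stopifnot(length(clade) == N)
    out$clade <- clade[ord]
  }
  validate_presence(out)
}

#' Calibrate the specialist-excess mixture weight
#'
#' Inverts the mixture expectation `w + (1 - w) * p1` where `p1` is the
#' analytic null probability of BSI = 1 conditional on occupancy, so that
#' the generated matrix has approximately the target observed specialist
#' percentage.
#'
#' @param target_pct Target observed percentage of specialists (e.g. 40.1).
#' @inheritParams simulate_null
#' @return The mixture weight, clamped to `[0, 1]`.
#' @export
calibrate_specialist_excess <- function(target_pct, marginals, n_species) {
  p1 <- analytic_null_bsi(marginals, n_species)$bsi$prob[1]
  min(max((target_pct / 100 - p1) / (1 - p1), 0), 1)
}

#' Generate an overlap table that codes back to a given presence matrix
#'
#' The inverse of the biome-coding step, for round-trip testing. For each
#' presence exactly one coding rule is triggered, chosen at random: either
#' the range rule (summed range fraction >= 0.15 with all dominion coverages
#' below 0.5) or the dominion rule (range fraction below 0.15 but one
#' dominion covered >= 0.5). Absences may receive sub-threshold decoy
#' records. For species flagged montane, one presence is routed through the
#' biome's montane-analog dominion, so coding flags them montane again.
#' Per-species range fractions always sum to less than 1.
#'
#' @param presence A presence tibble (with optional `montane` column).
#' @param catalog A [biome_catalog()]; needs a non-montane dominion for
#'   every biome used (and a montane dominion for biomes of montane-routed
#'   presences). Defaults to [synthetic_catalog()].
#' @param rule_mix Probability a presence is encoded through the range rule
#'   rather than the dominion rule.
#' @param decoy_prob Probability an absent biome receives a sub-threshold
#'   record.
#' @param seed Optional integer seed.
#' @return An overlap tibble (`species`, `dominion`, `range_fraction`,
#'   `dominion_fraction`, `montane`).
#' @export
generate_overlap_table <- function(presence, catalog = synthetic_catalog(),
                                   rule_mix = 0.5, decoy_prob = 0.25,
                                   seed = NULL) {
  presence <- validate_presence(presence)
  stopifnot(inherits(catalog, "biome_catalog"))
  if (!is.null(seed)) set.seed(seed)
  montane_flags <- if ("montane" %in% names(presence)) presence$montane
                   else rep(FALSE, nrow(presence))
  cols <- presence_cols(presence)
  regular_doms <- split(catalog$dominion[!catalog$montane], catalog$biome[!catalog$montane])
  montane_doms <- split(catalog$dominion[catalog$montane], catalog$biome[catalog$montane])

  rows <- vector("list", nrow(presence))
  for (i in seq_len(nrow(presence))) {
    sp <- presence$species[i]
    pres <- cols[as.logical(presence[i, cols] == 1L)]
    abs_biomes <- setdiff(cols, pres)
    k <- length(pres)
    use_range <- runif(k) < rule_mix
    # the range rule needs >= 0.15 of the range each; keep within budget
    if (sum(use_range) > 6) {
      use_range[sample(which(use_range), sum(use_range) - 6)] <- FALSE
    }
    u <- runif(sum(use_range), 0.15, 0.30)
    if (sum(u) > 0.90) u <- 0.15 + (u - 0.15) * (0.90 - 0.15 * length(u)) / (sum(u) - 0.15 * length(u))
    budget <- 1 - sum(u) - 1e-3
    mont_target <- if (montane_flags[i] && k > 0) sample(pres, 1) else NA_character_

    recs <- list(); ui <- 0L
    for (j in seq_len(k)) {
      b <- pres[j]
      via_montane <- identical(b, mont_target)
      dom_pool <- if (via_montane) montane_doms[[b]] else regular_doms[[b]]
      if (is.null(dom_pool) || length(dom_pool) == 0) {
        abort(paste0("Catalog lacks a ", if (via_montane) "montane " else "",
                     "dominion for biome ", b, "."))
      }
      dom <- dom_pool[sample.int(length(dom_pool), 1)]
      if (use_range[j]) {
        ui <- ui + 1L
        rf <- u[ui]; df <- runif(1, 0.05, 0.49)
      } else {
        rf <- runif(1, 0.005, max(min(0.149, 0.5 * budget), 0.006))
        df <- runif(1, 0.50, 0.95)
        budget <- budget - rf
      }
      recs[[length(recs) + 1L]] <- tibble::tibble(
        species = sp, dominion = dom, range_fraction = rf,
        dominion_fraction = df, montane = via_montane
      )
    }
    for (b in abs_biomes) {
      if (budget > 0.02 && runif(1) < decoy_prob) {
        rf <- runif(1, 0.001, min(0.05, 0.4 * budget))
        budget <- budget - rf
        recs[[length(recs) + 1L]] <- tibble::tibble(
          species = sp, dominion = regular_doms[[b]][1], range_fraction = rf,
          dominion_fraction = runif(1, 0, 0.49), montane = FALSE
        )
      }
    }
    rows[[i]] <- dplyr::bind_rows(recs)
  }
  validate_overlaps(dplyr::bind_rows(rows))
}

#' Generate a tree plus tip traits under a speciation model
#'
#' Wraps [simulate_tree()], retrying on complete extinction, with optional
#' clamping of tip traits to the BSI range `[1, 10]` and rounding to
#' integers for integer-BSI realism.
#'
#' @inheritParams simulate_tree
#' @param clamp If `TRUE`, clamp tip traits to `[1, 10]`.
#' @param round_traits If `TRUE`, round tip traits to integers (applied
#'   after clamping).
#' @param max_retries Retries allowed when the simulated clade dies out.
#' @return A `phylo_dataset`.
#' @export
generate_phylo_dataset <- function(model, x0, max_time = NULL, max_tips = NULL,
                                   clamp = FALSE, round_traits = FALSE,
                                   dt = 0.02, seed = NULL, max_retries = 50) {
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_retries)) {
    sim <- simulate_tree(model, x0, max_time = max_time, max_tips = max_tips,
                         dt = dt, seed = NULL)
    if (!sim$extinct) {
      x <- sim$traits$x
      if (clamp) x <- pmin(pmax(x, 1), 10)
      if (round_traits) x <- round(x)
      sim$traits$x <- x
      return(sim)
    }
  }
  abort(paste0("Clade went extinct in all ", max_retries, " attempts."))
}
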