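# Richness-constrained Monte Carlo null model. Each replicate places
# species in biomes at random while holding the observed per-biome species
# richness fixed: biome b receives sp_b distinct species drawn uniformly
# without replacement from the N species, independently across biomes.
# BSI frequencies are expressed as percentages of the species that occupy
# at least one biome in that replicate.

as_marginals <- function(marginals) {
  if (is.data.frame(marginals)) {
    stopifnot(all(c("biome", "sp") %in% names(marginals)))
    marginals <- setNames(marginals$sp, marginals$biome)
  }
  if (is.null(names(marginals))) {
    if (length(marginals) != length(.BIOME_LEVELS)) {
      abort("Unnamed marginals must have one entry per biome (10).")
    }
    names(marginals) <- .BIOME_LEVELS
  }
  bad <- setdiff(names(marginals), .BIOME_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("Unknown biome label(s) in marginals: ", paste(bad, collapse = ", ")))
  }
  out <- setNames(integer(length(.BIOME_LEVELS)), .BIOME_LEVELS)
  out[names(marginals)] <- as.integer(round(marginals))
  if (any(out < 0)) abort("Richness marginals must be non-negative.")
  out
}

#' Simulate the richness-constrained null ensemble
#'
#' @param marginals Per-biome species richness: a named vector over
#'   [biome_levels()] or a data frame with columns `biome`, `sp`.
#' @param n_species Total number of species N in the assemblage.
#' @param n_reps Number of Monte Carlo replicates (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @param keep_draws If `TRUE`, also store the replicate occupancy arrays
#'   (`n_reps` x `n_species` x 10 logical) for auditing; only sensible for
#'   small runs.
#' @return An object of class `null_ensemble`: a list with `bsi_pct`
#'   (`n_reps` x 10 matrix, percentage of occupied species with BSI = k),
#'   `specialist_pct` (`n_reps` x 10 matrix, percentage of each biome's
#'   occupants that are specialists; `NaN` for empty biomes), plus
#'   `marginals`, `n_species`, `n_reps`, `seed`.
#' @export
#' @examples
#' ens <- simulate_null(c(I = 2, II = 2), n_species = 3, n_reps = 100, seed = 1)
#' colMeans(ens$bsi_pct)[1:3]
simulate_null <- function(marginals, n_species, n_reps = 10000, seed = NULL,
                          keep_draws = FALSE) {
  marginals <- as_marginals(marginals)
  n_species <- as.integer(n_species)
  stopifnot(n_reps >= 1, n_species >= 1)
  if (any(marginals > n_species)) {
    abort("Each biome's richness must not exceed the total number of species.")
  }
  if (sum(marginals) == 0) abort("All richness marginals are zero.")
  if (!is.null(seed)) set.seed(seed)
  nb <- length(marginals)
  occupied <- which(marginals > 0)
  max_bsi <- nb
  bsi_pct <- matrix(0, n_reps, max_bsi,
                    dimnames = list(NULL, paste0("bsi", seq_len(max_bsi))))
  spec_pct <- matrix(NaN, n_reps, nb, dimnames = list(NULL, names(marginals)))
  draws <- if (keep_draws) array(FALSE, c(n_reps, n_species, nb)) else NULL
  counts <- integer(n_species)
  for (r in seq_len(n_reps)) {
    counts[] <- 0L
    members <- vector("list", nb)
    for (b in occupied) {
      idx <- sample.int(n_species, marginals[b])
      counts[idx] <- counts[idx] + 1L
      members[[b]] <- idx
      if (keep_draws) draws[r, idx, b] <- TRUE
    }
    n_occ <- sum(counts > 0L)
    tab <- tabulate(counts, nbins = max_bsi)
    bsi_pct[r, ] <- 100 * tab / n_occ
    for (b in occupied) {
      spec_pct[r, b] <- 100 * mean(counts[members[[b]]] == 1L)
    }
  }
  structure(
    list(bsi_pct = bsi_pct, specialist_pct = spec_pct,
         marginals = marginals, n_species = n_species,
         n_reps = as.integer(n_reps), seed = seed, draws = draws),
    class = "null_ensemble"
  )
}

#' Exact Poisson-binomial expectation for the null model
#'
#' Analytic counterpart of [simulate_null()]. Under the richness-constrained
#' randomization a given species occupies biome b with probability
#' `p_b = sp_b / N`, independently across biomes, so its BSI follows a
#' Poisson-binomial distribution. The BSI distribution is returned
#' conditioned on occupying at least one biome (the denominator the
#' Monte Carlo percentages use), and the per-biome specialist probability is
#' `P(BSI = 1 | present in b) = prod_{j != b} (1 - p_j)`.
#'
#' @inheritParams simulate_null
#' @return An object of class `null_analytic`: list with `bsi` (tibble
#'   `bsi`, `prob` for BSI 1..10, conditional on >= 1), `p_zero` (probability
#'   of occupying no biome), and `specialist` (tibble `biome`, `prob`;
#'   `NA` for empty biomes).
#' @export
analytic_null_bsi <- function(marginals, n_species) {
  marginals <- as_marginals(marginals)
  if (sum(marginals) == 0) abort("All richness marginals are zero; conditioning undefined.")
  p <- marginals / n_species
  if (any(p > 1)) abort("Each biome's richness must not exceed the total number of species.")
  # Poisson-binomial mass by direct convolution over biomes
  f <- 1
  for (pb in p) f <- c(f * (1 - pb), 0) + c(0, f * pb)
  p_zero <- f[1]
  cond <- f[-1] / (1 - p_zero)
  spec <- vapply(seq_along(p), function(b) {
    if (p[b] == 0) NA_real_ else prod(1 - p[-b])
  }, numeric(1))
  structure(
    list(
      bsi = tibble::tibble(bsi = seq_along(cond), prob = cond),
      p_zero = p_zero,
      specialist = tibble::tibble(biome = names(marginals), prob = spec)
    ),
    class = "null_analytic"
  )
}

#' Empirical tail p-value against a null ensemble
#'
#' Inclusive counting: the upper-tail p-value is the fraction of replicates
#' greater than or equal to the observed value; the lower tail uses less
#' than or equal. `direction = "auto"` picks the tail on the side of the
#' null mean the observation falls.
#'
#' @param observed Observed statistic (scalar).
#' @param null_values Numeric vector of replicate statistics.
#' @param direction `"auto"`, `"upper"` or `"lower"`.
#' @return A one-row tibble: `p` (the selected tail), `direction`,
#'   `p_upper`, `p_lower`, and a display string `p_display` that collapses
#'   very small values to `"<0.001"`.
#' @export
#' @examples
#' empirical_pvalue(4, c(1, 2, 3, 4, 5), "upper") # p = 2/5
empirical_pvalue <- function(observed, null_values,
                             direction = c("auto", "upper", "lower")) {
  direction <- match.arg(direction)
  null_values <- null_values[!is.na(null_values)]
  if (length(null_values) == 0) abort("Empty null ensemble.")
  n <- length(null_values)
  p_upper <- sum(null_values >= observed) / n
  p_lower <- sum(null_values <= observed) / n
  if (direction == "auto") {
    direction <- if (observed >= mean(null_values)) "upper" else "lower"
  }
  p <- if (direction == "upper") p_upper else p_lower
  tibble::tibble(
    p = p, direction = direction, p_upper = p_upper, p_lower = p_lower,
    p_display = ifelse(p < 0.001, "<0.001", formatC(p, digits = 3, format = "f"))
  )
}

#' Null summary of per-biome specialist fractions
#'
#' @param ensemble A `null_ensemble` from [simulate_null()].
#' @return A tibble with one row per biome: `biome`, `sp` (richness),
#'   `null_mean`, `null_sd`, `null_min`, `null_max` of the percentage of the
#'   biome's occupants that are specialists (BSI = 1). Biomes with no
#'   species are reported with `NA` summaries.
#' @export
biome_specialist_null <- function(ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  m <- ensemble$specialist_pct
  tibble::tibble(
    biome = colnames(m),
    sp = as.integer(ensemble$marginals),
    null_mean = ifelse(ensemble$marginals > 0, colMeans(m), NA_real_),
    null_sd = apply(m, 2, sd),
    null_min = suppressWarnings(apply(m, 2, min)),
    null_max = suppressWarnings(apply(m, 2, max))
  )
}

#' Full richness-constrained null analysis of a presence matrix
#'
#' Computes the observed BSI frequency distribution and per-biome specialist
#' proportions, simulates the richness-constrained null from the matrix's
#' own marginals, and reports null mean/sd/range with inclusive empirical
#' p-values for both tails.
#'
#' @param presence A presence tibble; an optional `clade` column enables
#'   `clade` filtering.
#' @param clade Optional clade label; marginals and N are recomputed on the
#'   filtered matrix.
#' @param n_reps Number of Monte Carlo replicates.
#' @param seed Optional integer seed.
#' @return An object of class `bsi_null_test`: list with `bsi` (per-BSI
#'   summary table), `biome` (per-biome specialist summary), `ensemble`,
#'   `n_species`, `n_reps`, `seed`, `clade`.
#' @export
run_null_analysis <- function(presence, clade = NULL, n_reps = 10000, seed = NULL) {
  presence <- validate_presence(presence)
  if (!is.null(clade)) {
    if (!"clade" %in% names(presence)) abort("`presence` has no `clade` column.")
    presence <- presence[presence$clade == clade, ]
    if (nrow(presence) == 0) abort(paste0("No species in clade ", clade, "."))
  }
  marginals <- biome_richness(presence)
  n <- nrow(presence)
  bsi <- compute_bsi(presence)
  obs_bsi_pct <- 100 * tabulate(bsi$bsi, nbins = length(.BIOME_LEVELS)) / n
  ens <- simulate_null(marginals, n_species = n, n_reps = n_reps, seed = seed)

  bsi_tab <- purrr::map_dfr(seq_along(.BIOME_LEVELS), function(k) {
    nulls <- ens$bsi_pct[, k]
    pv <- empirical_pvalue(obs_bsi_pct[k], nulls)
    tibble::tibble(
      bsi = k, observed_pct = obs_bsi_pct[k],
      null_mean = mean(nulls), null_sd = sd(nulls),
      null_min = min(nulls), null_max = max(nulls),
      p = pv$p, direction = pv$direction,
      p_upper = pv$p_upper, p_lower = pv$p_lower, p_display = pv$p_display
    )
  })

  specialists <- bsi$species[bsi$bsi == 1]
  pmat <- as.matrix(presence[presence_cols(presence)])
  obs_spec <- vapply(seq_along(.BIOME_LEVELS), function(b) {
    if (marginals[b] == 0) return(NA_real_)
    members <- presence$species[pmat[, b] == 1]
    100 * mean(members %in% specialists)
  }, numeric(1))
  n_spec_b <- vapply(seq_along(.BIOME_LEVELS), function(b) {
    sum(pmat[, b] == 1 & bsi$bsi == 1)
  }, numeric(1))

  biome_tab <- biome_specialist_null(ens)
  biome_tab$n_specialists <- as.integer(n_spec_b)
  biome_tab$observed_pct <- obs_spec
  pv <- purrr::map_dfr(seq_along(.BIOME_LEVELS), function(b) {
    if (marginals[b] == 0) {
      return(tibble::tibble(p = NA_real_, direction = NA_character_,
                            p_upper = NA_real_, p_lower = NA_real_,
                            p_display = NA_character_))
    }
    empirical_pvalue(obs_spec[b], ens$specialist_pct[, b])
  })
  biome_tab <- dplyr::bind_cols(
    biome_tab[, c("biome", "sp", "n_specialists", "observed_pct",
                  "null_mean", "null_sd", "null_min", "null_max")],
    pv
  )

  structure(
    list(bsi = bsi_tab, biome = biome_tab, ensemble = ens,
         n_species = n, n_reps = as.integer(n_reps), seed = seed,
         clade = clade),
    class = "bsi_null_test"
  )
}

#' @export
print.bsi_null_test <- function(x, ...) {
  cat("Richness-constrained null analysis",
      if (!is.null(x$clade)) paste0(" (clade: ", x$clade, ")"), "\n", sep = "")
  cat(x$n_species, "species,", x$n_reps, "replicates",
      if (!is.null(x$seed)) paste0("(seed ", x$seed, ")"), "\n\n")
  rnd <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) & names(df) != "bsi" &
      names(df) != "sp" & names(df) != "n_specialists"
    df[num] <- lapply(df[num], round, digits = 2)
    as.data.frame(df)
  }
  cat("BSI frequency distribution (%):\n")
  print(rnd(x$bsi[, c("bsi", "observed_pct", "null_mean", "null_sd",
                      "p_display", "direction")]), row.names = FALSE)
  cat("\nPer-biome specialist proportions (%):\n")
  print(rnd(x$biome[, c("biome", "sp", "n_specialists", "observed_pct",
                        "null_mean", "null_sd", "p_display")]),
        row.names = FALSE)
  invisible(x)
}
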