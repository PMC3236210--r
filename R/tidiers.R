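# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a richness-constrained null analysis
#'
#' @param x A `bsi_null_test` from [run_null_analysis()].
#' @param which `"bsi"` (per-BSI frequency summary) or `"biome"` (per-biome
#'   specialist summary).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bsi_null_test
#' @export
tidy.bsi_null_test <- function(x, which = c("bsi", "biome"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' @rdname tidy.bsi_null_test
#' @method glance bsi_null_test
#' @export
glance.bsi_null_test <- function(x, ...) {
  tibble::tibble(
    n_species = x$n_species, n_reps = x$n_reps,
    seed = x$seed %||% NA_integer_, clade = x$clade %||% NA_character_,
    observed_specialist_pct = x$bsi$observed_pct[1],
    null_specialist_pct = x$bsi$null_mean[1]
  )
}

#' Tidy a speciation-model fit
#'
#' @param x A `speciation_fit` from [fit_speciation_model()].
#' @param ... Unused.
#' @return `tidy()`: a tibble of parameter estimates; `glance()`: a one-row
#'   model summary.
#' @method tidy speciation_fit
#' @export
tidy.speciation_fit <- function(x, ...) x$estimates

#' @rdname tidy.speciation_fit
#' @method glance speciation_fit
#' @export
glance.speciation_fit <- function(x, ...) {
  tibble::tibble(
    model = model_label(x$shape, x$drift), n_par = x$n_par,
    lnL = x$lnL, AIC = x$AIC, converged = x$converged,
    evaluations = unname(x$counts["function"])
  )
}

#' Tidy an AIC model comparison
#'
#' @param x A `model_comparison` from [compare_speciation_models()].
#' @param ... Unused.
#' @return `tidy()`: the per-tree, per-model fit table; `glance()`: the
#'   across-tree summary, one row per model.
#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) x$per_fit

#' @rdname tidy.model_comparison
#' @method glance model_comparison
#' @export
glance.model_comparison <- function(x, ...) x$summary
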