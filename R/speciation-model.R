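# Trait-dependent speciation models: the per-lineage speciation rate is a
# function lambda(x) of a continuously evolving trait x (BSI treated as
# quantitative), extinction mu is trait-independent, and the trait follows
# Brownian motion with diffusion rate sigma2 and optional directional
# drift phi (positive phi pushes lineages toward higher BSI, i.e. toward
# generalism).

#' Construct a trait-dependent speciation model
#'
#' Four speciation-rate shapes are supported. With trait `x`:
#' * `constant`: `lambda(x) = lambda0`;
#' * `linear`: `lambda(x) = max(0, lambda0 + slope * x)` (clamped at zero);
#' * `sigmoid` (four-parameter logistic, decreasing when `lambda0 > lambda1`):
#'   `lambda(x) = lambda1 + (lambda0 - lambda1) / (1 + exp(r * (x - xmid)))`;
#' * `modal` (Gaussian bump):
#'   `lambda(x) = lambda1 + (lambda0 - lambda1) * exp(-(x - xmid)^2 / (2 w^2))`.
#'
#' Free-parameter counts (for AIC) are 3, 4, 6 and 6 respectively
#' (`lambda` parameters plus `mu` and `sigma2`), plus 1 when drift `phi` is
#' present.
#'
#' @param shape One of `"constant"`, `"linear"`, `"sigmoid"`, `"modal"`.
#' @param lambda0 Speciation rate at low trait values (lineages/Myr); for
#'   `linear`, the intercept at `x = 0`.
#' @param lambda1 Rate at high trait values (sigmoid asymptote / modal
#'   baseline).
#' @param xmid Inflection point (sigmoid) or mode location (modal), in trait
#'   units.
#' @param r Sigmoid steepness (1/trait units).
#' @param width Modal width `w` (trait units).
#' @param slope Linear slope (rate per trait unit).
#' @param mu Extinction rate (trait-independent, >= 0).
#' @param sigma2 Brownian diffusion rate of the trait (trait^2/Myr, > 0 for
#'   likelihood work).
#' @param phi Optional directional drift (trait/Myr); `NULL` means no drift
#'   term.
#' @return An object of class `speciation_model`.
#' @export
#' @examples
#' m <- speciation_model("sigmoid", lambda0 = 0.17, lambda1 = 0.018,
#'                       xmid = 4.61, r = 1.5, mu = 0.01, sigma2 = 0.15)
#' lambda_at(m, c(1, 4.61, 8))
speciation_model <- function(shape = c("constant", "linear", "sigmoid", "modal"),
                             lambda0, lambda1 = NULL, xmid = NULL, r = NULL,
                             width = NULL, slope = NULL, mu = 0, sigma2 = 0,
                             phi = NULL) {
  shape <- match.arg(shape)
  stopifnot(lambda0 >= 0, mu >= 0, sigma2 >= 0)
  pars <- list(lambda0 = lambda0, mu = mu, sigma2 = sigma2)
  if (shape == "linear") {
    if (is.null(slope)) abort("`linear` shape requires `slope`.")
    pars$slope <- slope
  } else if (shape == "sigmoid") {
    if (is.null(lambda1) || is.null(xmid) || is.null(r)) {
      abort("`sigmoid` shape requires `lambda1`, `xmid` and `r`.")
    }
    stopifnot(lambda1 >= 0, r >= 0)
    pars <- c(pars, list(lambda1 = lambda1, xmid = xmid, r = r))
  } else if (shape == "modal") {
    if (is.null(lambda1) || is.null(xmid) || is.null(width)) {
      abort("`modal` shape requires `lambda1`, `xmid` and `width`.")
    }
    stopifnot(lambda1 >= 0, width > 0)
    pars <- c(pars, list(lambda1 = lambda1, xmid = xmid, width = width))
  }
  drift <- !is.null(phi)
  if (drift) pars$phi <- phi
  n_par <- switch(shape, constant = 3L, linear = 4L, sigmoid = 6L, modal = 6L) +
    as.integer(drift)
  structure(list(shape = shape, pars = pars, drift = drift, n_par = n_par),
            class = "speciation_model")
}

#' Speciation rate at given trait values
#'
#' @param model A [speciation_model()].
#' @param x Numeric vector of trait values.
#' @return Numeric vector of rates, non-negative everywhere.
#' @export
lambda_at <- function(model, x) {
  stopifnot(inherits(model, "speciation_model"))
  p <- model$pars
  switch(model$shape,
    constant = rep(p$lambda0, length(x)),
    linear = pmax(0, p$lambda0 + p$slope * x),
    sigmoid = p$lambda1 + (p$lambda0 - p$lambda1) / (1 + exp(p$r * (x - p$xmid))),
    modal = p$lambda1 + (p$lambda0 - p$lambda1) * exp(-(x - p$xmid)^2 / (2 * p$width^2))
  )
}

drift_of <- function(model) if (model$drift) model$pars$phi else 0

#' @export
print.speciation_model <- function(x, ...) {
  cat("Trait-dependent speciation model: ", x$shape,
      if (x$drift) " + directional drift", "\n", sep = "")
  cat("  ", paste(names(x$pars), signif(unlist(x$pars), 4),
                  sep = " = ", collapse = ", "), "\n", sep = "")
  cat("  free parameters:", x$n_par, "\n")
  invisible(x)
}

#' Bundle a tree with tip trait values
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param traits Tip trait values: a named numeric vector or a data frame
#'   with columns `species`, `x` (or `bsi`). Must match the tip labels
#'   exactly.
#' @return An object of class `phylo_dataset`: list with `tree` and `traits`
#'   (tibble `species`, `x` ordered as the tip labels).
#' @export
phylo_dataset <- function(tree, traits) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("Tree must have branch lengths.")
  if (any(tree$edge.length < 0)) abort("Negative branch lengths are not allowed.")
  if (is.data.frame(traits)) {
    xcol <- if ("x" %in% names(traits)) "x" else if ("bsi" %in% names(traits)) "bsi"
      else abort("`traits` data frame needs an `x` or `bsi` column.")
    traits <- setNames(as.numeric(traits[[xcol]]), traits$species)
  }
  missing_tips <- setdiff(tree$tip.label, names(traits))
  if (length(missing_tips) > 0) {
    abort(paste0("No trait value for tip(s): ",
                 paste(head(missing_tips, 5), collapse = ", ")))
  }
  extra <- setdiff(names(traits), tree$tip.label)
  if (length(extra) > 0) {
    abort(paste0("Trait table has species not in the tree: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  structure(
    list(tree = tree,
         traits = tibble::tibble(species = tree$tip.label,
                                 x = as.numeric(traits[tree$tip.label]))),
    class = "phylo_dataset"
  )
}

#' @export
print.phylo_dataset <- function(x, ...) {
  cat("phylo_dataset:", length(x$tree$tip.label), "tips, trait range [",
      signif(min(x$traits$x), 3), ",", signif(max(x$traits$x), 3), "]\n")
  invisible(x)
}
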