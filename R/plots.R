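# ggplot2 displays: observed-versus-null BSI frequency distributions and
# fitted speciation-rate curves.

#' Plot an observed BSI distribution against its null
#'
#' Bars show the observed percentage of species at each BSI value; the line
#' and ribbon show the null mean and min-max range from the
#' richness-constrained randomization.
#'
#' @param object A `bsi_null_test` from [run_null_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bsi_null_test
#' @export
autoplot.bsi_null_test <- function(object, ...) {
  df <- object$bsi
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bsi)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed_pct), fill = "grey70") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$null_min, ymax = .data$null_max),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_mean)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$null_mean)) +
    ggplot2::scale_x_continuous(breaks = df$bsi) +
    ggplot2::labs(x = "biomic specialization index (BSI)",
                  y = "% of species",
                  title = "Observed vs. richness-constrained null",
                  subtitle = paste0(object$n_species, " species, ",
                                    object$n_reps, " replicates")) +
    ggplot2::theme_minimal()
}

#' Plot per-biome specialist proportions against their null
#'
#' @inheritParams autoplot.bsi_null_test
#' @return A ggplot object.
#' @export
plot_biome_specialists <- function(object, ...) {
  df <- object$biome
  df$biome <- factor(df$biome, levels = biome_levels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$biome)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed_pct), fill = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$null_mean,
                                          ymin = .data$null_min,
                                          ymax = .data$null_max)) +
    ggplot2::labs(x = "biome", y = "% of occupants with BSI = 1",
                  title = "Biome specialists: observed vs. null") +
    ggplot2::theme_minimal()
}

#' Plot a speciation-rate curve over trait values
#'
#' @param object A [speciation_model()] or `speciation_fit`.
#' @param xlim Trait range to draw (default 0 to 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot speciation_model
#' @export
autoplot.speciation_model <- function(object, xlim = c(0, 10), ...) {
  x <- seq(xlim[1], xlim[2], length.out = 256)
  df <- tibble::tibble(x = x, lambda = lambda_at(object, x))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$lambda)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trait (BSI)", y = expression(lambda(x)),
                  title = paste0("Speciation rate: ", object$shape,
                                 if (object$drift) " + drift")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.speciation_model
#' @method autoplot speciation_fit
#' @export
autoplot.speciation_fit <- function(object, xlim = c(0, 10), ...) {
  autoplot.speciation_model(object$model, xlim = xlim, ...) +
    ggplot2::labs(subtitle = paste0("lnL = ", signif(object$lnL, 6),
                                    ", AIC = ", signif(object$AIC, 6)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
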