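#' Plot an eQTL effect deconstructed by purity bins
#'
#' Per-bin effect sizes (points with 95% confidence whiskers) plotted
#' against the mean normal-cell fraction of each bin, with the whole-cohort
#' conventional estimate (green) and the extrapolated cancer-cell estimate
#' from the interaction model (red) as horizontal reference lines. A
#' normal-driven eQTL shows effects falling toward 0 as cancer content
#' rises, with the interaction estimate near 0.
#'
#' @param object An `eqtl_binned` tibble from [binned_effects()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @method autoplot eqtl_binned
autoplot.eqtl_binned <- function(object, ...) {
  conv <- attr(object, "conventional")
  intr <- attr(object, "interaction")
  df <- dplyr::mutate(tibble::as_tibble(object),
                      normal_mid = 1 - (.data$purity_low + .data$purity_high) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$normal_mid, y = .data$beta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = conv$beta1, colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = intr$beta1, colour = "red") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.02) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "proportion of tumor-associated normal cells (bin mean)",
                  y = "eQTL effect size",
                  title = "Purity-binned eQTL effect",
                  subtitle = "green: conventional (bulk); red: interaction (extrapolated to cancer cells)") +
    ggplot2::theme_minimal()
}

#' Plot a purity-measurement noise sweep
#'
#' Sensitivity, specificity and realized FDR of the interaction model as a
#' function of the Pearson correlation between the true and noise-added
#' purity (high correlation = accurate measurement, plotted left to right
#' as accuracy degrades). The dashed red line marks the nominal BH level.
#'
#' @param object An `eqtl_sweep` tibble from [noise_sweep()].
#' @param fdr_level Nominal FDR level to mark (default 0.05).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
#' @method autoplot eqtl_sweep
autoplot.eqtl_sweep <- function(object, fdr_level = 0.05, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("sensitivity", "specificity", "true_fdr"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pearson_r, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_hline(yintercept = fdr_level, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Pearson r (true vs measured purity)", y = NULL,
                  title = "Interaction-model performance vs purity measurement noise") +
    ggplot2::theme_minimal()
}
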