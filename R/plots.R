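#' @rdname bland_altman
#' @param object A `"femver_ba"` object.
#' @param ... Unused.
#' @method autoplot femver_ba
#' @export
autoplot.femver_ba <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", linewidth = 0.5) +
    ggplot2::labs(
      x = "Mean of paired measurements (degrees)",
      y = "Difference (degrees)",
      title = "Bland-Altman agreement",
      subtitle = sprintf("bias %.2f, 95%% limits of agreement (%.2f, %.2f)",
                         object$bias, object$loa_low, object$loa_high)
    ) +
    ggplot2::theme_minimal()
}

#' Histograms of cohort angle distributions
#'
#' Faceted histograms of every numeric angle column of a cohort table, for a
#' quick look at whether a simulated cohort matches the intended truncated
#' normal spread.
#'
#' @param cohort A cohort tibble (e.g. from [sample_orientations()]).
#' @param bins Number of histogram bins (default 40).
#' @return A ggplot object.
#' @export
plot_angle_distributions <- function(cohort, bins = 40) {
  num <- dplyr::select(cohort, dplyr::where(is.numeric))
  long <- tidyr::pivot_longer(num, dplyr::everything(),
                              names_to = "angle", values_to = "degrees")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$degrees)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~angle, scales = "free") +
    ggplot2::labs(x = "Angle (degrees)", y = "Hips") +
    ggplot2::theme_minimal()
}
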