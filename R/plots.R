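#' Plot class-averaged spectra
#'
#' Averages the selected channel over measurements of each diagnostic class
#' and draws one curve per class.
#'
#' @param spectra Spectra tibble (raw, normalized or standardized).
#' @param manifest Manifest with `measurement_id`, `class`.
#' @param channel Channel to plot.
#' @return A ggplot.
#' @export
plot_spectra <- function(spectra, manifest, channel = "BF1") {
  check_spectra_frame(spectra)
  df <- spectra %>%
    left_join(select(manifest, "measurement_id", "class"),
      by = "measurement_id"
    ) %>%
    group_by(.data$class, .data$wavelength_nm) %>%
    summarise(intensity = mean(.data[[channel]]), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(
    .data$wavelength_nm, .data$intensity, colour = .data$class
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Wavelength (nm)", y = paste(channel, "reflectance"),
      colour = "Class"
    ) +
    ggplot2::theme_minimal()
}

#' Plot phantom depth-response curves
#'
#' Depth-response curves per channel with the 90%-saturation depths marked.
#'
#' @param curves Tibble from [simulate_phantom_series()].
#' @param depths Optional [saturation_depths()] result to annotate.
#' @return A ggplot.
#' @export
plot_depth_response <- function(curves, depths = NULL) {
  long <- tidyr::pivot_longer(curves, -"thickness_um",
    names_to = "channel", values_to = "intensity"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(
    .data$thickness_um, .data$intensity, colour = .data$channel
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Phantom thickness (µm)", y = "Integrated intensity",
      colour = "Channel"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(depths)) {
    p <- p + ggplot2::geom_vline(
      data = depths,
      ggplot2::aes(xintercept = .data$depth90_um, colour = .data$channel),
      linetype = "dashed", show.legend = FALSE
    )
  }
  p
}

#' ROC curve of a task result
#'
#' @param object An `oprs_task_result`.
#' @param ... Unused.
#' @return A ggplot of the out-of-fold ROC curve.
#' @export
autoplot.oprs_task_result <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("%s (AUC = %.3f)", object$task_id, object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Permutation-test summary plot
#'
#' Histogram of shuffled AUCs with the real AUC marked.
#'
#' @param object An `oprs_permutation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oprs_permutation <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$auc)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$real_auc, colour = "red") +
    ggplot2::labs(
      x = "Shuffled AUC", y = "Count",
      title = sprintf(
        "%s: real AUC %.3f vs shuffled %.3f ± %.3f",
        object$task_id, object$real_auc, object$mean_shuffled,
        object$sd_shuffled
      )
    ) +
    ggplot2::theme_minimal()
}
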