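# ggplot2 figures for each result type.

#' Plot the photon time trace
#'
#' @param trace A `time_trace` (corrected column shown when present).
#' @param events Optional tibble of intervals to shade.
#' @param threshold Optional horizontal threshold line.
#' @param max_frames Downsample cap for very long traces (keeps plotting
#'   responsive; the per-frame maximum within each bin is shown).
#' @return A ggplot object.
#' @export
plot_time_trace <- function(trace, events = NULL, threshold = NULL,
                            max_frames = 20000) {
  y <- if ("corrected" %in% names(trace)) "corrected" else "photons"
  df <- tibble::tibble(frame = trace$frame, value = trace[[y]])
  if (nrow(df) > max_frames) {
    bin <- ceiling(nrow(df) / max_frames)
    df <- df |>
      dplyr::mutate(g = (.data$frame - 1L) %/% bin) |>
      dplyr::group_by(.data$g) |>
      dplyr::summarise(frame = dplyr::first(.data$frame),
                       value = max(.data$value), .groups = "drop")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "frame", y = paste(y, "photons/frame"),
                  title = "Photon time trace") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0)
    p <- p + ggplot2::geom_rect(
      data = events,
      ggplot2::aes(xmin = .data$start_frame, xmax = .data$end_frame),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "tomato",
      inherit.aes = FALSE)
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 colour = "steelblue")
  p
}

#' Plot averaged spectra per class
#'
#' @param spectra A spectrum table with labels.
#' @param axis Optional wavenumber axis for the kept channels (x axis in
#'   cm^-1; channel index otherwise).
#' @return A ggplot object.
#' @export
plot_cumulative_spectra <- function(spectra, axis = NULL) {
  cum <- cumulative_spectrum(spectra)
  if (!is.null(axis)) cum$x <- axis[cum$channel + 1] else cum$x <- cum$channel
  ggplot2::ggplot(cum, ggplot2::aes(x = .data$x, y = .data$mean_photons,
                                    colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (is.null(axis)) "channel" else "wavenumber (cm⁻¹)",
                  y = "mean photons/event",
                  title = "Averaged single-molecule SERS spectra") +
    ggplot2::theme_minimal()
}

#' Scatter plot of PCA scores by class
#'
#' @param scores Matrix or data frame with `PC1`, `PC2`.
#' @param labels Class label per row.
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(scores, labels) {
  df <- tibble::tibble(PC1 = as.data.frame(scores)$PC1,
                       PC2 = as.data.frame(scores)$PC2,
                       label = labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::stat_ellipse(level = 0.68) +
    ggplot2::labs(title = "PCA of single-event spectra") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot sers_eval
#' @export
autoplot.sers_eval <- function(object, ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(x = factor(.data$run), y = .data$accuracy)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy, linetype = 2) +
    ggplot2::labs(x = "run", y = "held-out accuracy",
                  title = sprintf("Repeated evaluation: mean accuracy %.3f",
                                  object$mean_accuracy)) +
    ggplot2::theme_minimal()
}

#' @method autoplot accuracy_curve
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$n_events, y = .data$mean_accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2,
                        colour = "tomato") +
    ggplot2::labs(x = "events averaged per spectrum", y = "mean accuracy",
                  title = "Discrimination accuracy vs events averaged") +
    ggplot2::theme_minimal()
}

#' @param reference Optional [hypergeometric_ratio_pmf()] tibble overlaid as
#'   a reference distribution (scaled to the histogram mass).
#' @rdname autoplot.sers_eval
#' @method autoplot ratio_histogram
#' @export
autoplot.ratio_histogram <- function(object, reference = NULL, ...) {
  p <- ggplot2::ggplot(object$bins) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                                    ymin = 0, ymax = .data$count),
                       fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mode, colour = "tomato",
                        linetype = 2) +
    ggplot2::labs(x = "VP:OT redistribution ratio", y = "runs",
                  title = sprintf("Ratio histogram (mode %.2f)", object$mode)) +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    ref <- reference[is.finite(reference$ratio), ]
    ref$scaled <- ref$prob * object$n_included
    p <- p + ggplot2::geom_point(data = ref,
                                 ggplot2::aes(x = .data$ratio, y = .data$scaled),
                                 colour = "black", size = 1)
  }
  p
}
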