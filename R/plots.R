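#' Plot a fluorescence trace, optionally with detected events
#'
#' @param object A `fluor_trace`.
#' @param events Optional tibble from [detect_events()]; onsets and peaks are
#'   marked.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fluor_trace
#' @export
autoplot.fluor_trace <- function(object, events = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("fluorescence (%s)", trace_unit(object)),
                  title = roi_id(object)) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    p <- p +
      ggplot2::geom_vline(xintercept = events$onset_s, colour = "#2c7fb8",
                          linetype = "dashed", linewidth = 0.3) +
      ggplot2::geom_point(data = events,
                          ggplot2::aes(x = .data$peak_s,
                                       y = .data$peak_value),
                          colour = "#d95f02", size = 1.5)
  }
  p
}

#' @rdname autoplot.fluor_trace
#' @method autoplot vm_trace
#' @export
autoplot.vm_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$vm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "Vm (mV)", title = roi_id(object)) +
    ggplot2::theme_minimal()
}

#' Plot an STO spectrum
#'
#' Welch power spectral density with the analysis band shaded and the peak
#' frequency marked.
#'
#' @param object An `sto_result` from [welch_psd()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sto_result
#' @export
autoplot.sto_result <- function(object, ...) {
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = .data$freq, y = .data$psd)) +
    ggplot2::annotate("rect", xmin = object$band[1], xmax = object$band[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "#2c7fb8") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peak_freq, colour = "#d95f02",
                        linetype = "dashed") +
    ggplot2::labs(x = "frequency (Hz)",
                  y = sprintf("PSD (%s^2/Hz)", object$unit)) +
    ggplot2::theme_minimal()
}

#' Plot spike clusters in principal-component space
#'
#' @param pca A `spike_pca` from [pca_waveforms()].
#' @param clusters A `spike_clusters` from [cluster_spikes()].
#' @return A ggplot of PC1/PC2 scores coloured by cluster.
#' @export
plot_spike_clusters <- function(pca, clusters) {
  d <- dplyr::mutate(pca$scores, cluster = factor(clusters$labels))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                  colour = .data$cluster)) +
    ggplot2::geom_point() +
    ggplot2::labs(title = sprintf("k = %d (elbow)", clusters$k)) +
    ggplot2::theme_minimal()
}

#' Plot a rise-time-to-width calibration
#'
#' @param model An `io_calibration`.
#' @param data Optional tibble with `rise_time_ms` and `width_ms` points.
#' @param rt_range Rise-time range (ms) over which to draw the line.
#' @return A ggplot.
#' @export
plot_calibration <- function(model, data = NULL, rt_range = c(150, 600)) {
  line <- tibble::tibble(rise_time_ms = seq(rt_range[1], rt_range[2],
                                            length.out = 100))
  line$width_ms <- rt_to_width(line$rise_time_ms, model)
  p <- ggplot2::ggplot(line, ggplot2::aes(x = .data$rise_time_ms,
                                          y = .data$width_ms)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "calcium event rise time (ms)",
                  y = "spike width (ms)") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = data, alpha = 0.6)
  }
  p
}
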