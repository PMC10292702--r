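# ggplot2 views of the package's result types.

#' Plot an SEMG signal trace
#'
#' @param object A [semg_signal()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot semg_signal
#' @export
autoplot.semg_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)")
}

#' Plot windowed fatigue-feature trajectories
#'
#' IEMG, RMS and MPF against window start time, one facet per feature.
#'
#' @param object A `semg_features` tibble from [compute_feature_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot semg_features
#' @export
autoplot.semg_features <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("iemg_mVs", "rms_mV", "mpf_Hz"),
                              names_to = "feature", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_start_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~feature, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "window start (s)", y = NULL)
}

#' Plot a denoising benchmark
#'
#' SNR per threshold rule across replicates.
#'
#' @param object A `denoise_benchmark` tibble from [denoise_benchmark()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot denoise_benchmark
#' @export
autoplot.denoise_benchmark <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mode, y = .data$snr_db)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "threshold function", y = "SNR (dB)")
}

#' Plot evaluation metrics
#'
#' Bar chart of accuracy, sensitivity, specificity and precision.
#'
#' @param object An [eval_metrics()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eval_metrics
#' @export
autoplot.eval_metrics <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent")
}

#' Render one phantom frame
#'
#' @param sequence A `frame_sequence`.
#' @param frame Frame index (1-based).
#' @return A ggplot raster of the frame (depth increases downwards).
#' @export
plot_frame <- function(sequence, frame = 1L) {
  fr <- sequence$frames[[frame]]
  df <- tidyr::expand_grid(row = seq_len(nrow(fr)), col = seq_len(ncol(fr)))
  df$gray <- as.numeric(t(fr))[(df$row - 1) * ncol(fr) + df$col]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$gray)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral (px)", y = "depth (px)", fill = "gray")
}
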