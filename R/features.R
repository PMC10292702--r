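# Windowed fatigue features: integrated EMG (IEMG, time integral of the
# rectified signal), RMS amplitude, and mean power frequency (MPF, spectral
# centroid of the window's power spectrum within the analysis band).

#' Segment a signal into fixed-length windows
#'
#' Consecutive windows advance by `window_s * (1 - overlap)`; a trailing
#' partial window is dropped.
#'
#' @param x A [semg_signal()] or numeric vector (then supply `fs`).
#' @param window_s Window length in seconds.
#' @param overlap Overlap fraction in `[0, 1)`.
#' @param fs Sampling rate, if `x` is a bare vector.
#' @return A tibble with one row per window: `window`, `t_start_s` and a
#'   list-column `samples`.
#' @export
#' @examples
#' s <- semg_signal(rnorm(10000), fs = 1000)
#' nrow(segment_windows(s, 1, 0.5))  # 19
segment_windows <- function(x, window_s = 1, overlap = 0.5, fs = NULL) {
  if (overlap < 0 || overlap >= 1) rlang::abort("overlap must be in [0, 1)")
  vals <- .signal_values(x)
  fs <- .signal_fs(x, fs)
  len <- round(window_s * fs)
  if (len < 2) rlang::abort("window shorter than 2 samples")
  stride <- max(1L, round(len * (1 - overlap)))
  starts <- if (length(vals) < len) {
    integer(0)
  } else {
    seq(1L, length(vals) - len + 1L, by = stride)
  }
  tibble::tibble(
    window = seq_along(starts),
    t_start_s = (starts - 1) / fs,
    samples = purrr::map(starts, function(s) vals[s:(s + len - 1L)])
  )
}

#' Integrated EMG of a window
#'
#' Time integral of the rectified signal `|x(t)|` over the window,
#' evaluated as a Riemann sum at `1/fs` spacing, so a constant 2 mV window
#' of 1 s yields exactly 2 mV*s.
#'
#' @param x Numeric samples in mV.
#' @param fs Sampling rate in Hz.
#' @return IEMG in mV*s.
#' @export
#' @examples
#' iemg(rep(2, 1000), fs = 1000)  # 2
iemg <- function(x, fs) {
  stopifnot(length(x) >= 2, fs > 0)
  sum(abs(x)) / fs
}

#' RMS amplitude of a window
#'
#' `sqrt(mean(x^2))`, the discrete form of `sqrt((1/T) * integral(x^2))`.
#'
#' @inheritParams iemg
#' @return RMS in mV.
#' @export
rms_amplitude <- function(x, fs = NULL) {
  stopifnot(length(x) >= 2)
  sqrt(mean(x^2))
}

#' Mean power frequency of a window
#'
#' Spectral centroid `integral(f * PS) / integral(PS)` of the window's
#' power spectrum restricted to `band`, with `PS` estimated by a
#' Hann-windowed periodogram (a single-segment Welch estimate, appropriate
#' for 1 s windows).
#'
#' @inheritParams iemg
#' @param band Analysis band `c(min_Hz, max_Hz)`, inside `(0, fs/2)`.
#' @return MPF in Hz.
#' @export
#' @examples
#' t <- seq(0, 1 - 1e-3, by = 1e-3)
#' mpf(sin(2 * pi * 100 * t), fs = 1000)  # ~100
mpf <- function(x, fs, band = c(20, 500)) {
  n <- length(x)
  stopifnot(n >= 2, fs > 0)
  if (band[1] <= 0 || band[2] > fs / 2 || band[1] >= band[2]) {
    rlang::abort("band must lie within (0, fs/2]")
  }
  h <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  X <- stats::fft(x * h)
  nf <- floor(n / 2) + 1
  ps <- Mod(X[seq_len(nf)])^2
  f <- (seq_len(nf) - 1) * fs / n
  in_band <- f >= band[1] & f <= band[2]
  tot <- sum(ps[in_band])
  if (tot <= 0 || !any(in_band)) rlang::abort("zero in-band power")
  sum(f[in_band] * ps[in_band]) / tot
}

#' Windowed fatigue-feature series
#'
#' Applies [iemg()], [rms_amplitude()] and [mpf()] to every window of the
#' signal, in order.
#'
#' @inheritParams segment_windows
#' @param band MPF analysis band in Hz.
#' @return A tibble of class `semg_features` with columns `t_start_s`,
#'   `iemg_mVs`, `rms_mV`, `mpf_Hz`.
#' @export
#' @examples
#' s <- generate_clean_semg(fatigue_profile(duration_s = 10), seed = 2)
#' compute_feature_series(s)
compute_feature_series <- function(x, window_s = 1, overlap = 0.5,
                                   band = c(20, 500), fs = NULL) {
  fs <- .signal_fs(x, fs)
  win <- segment_windows(x, window_s = window_s, overlap = overlap, fs = fs)
  out <- tibble::tibble(
    t_start_s = win$t_start_s,
    iemg_mVs = purrr::map_dbl(win$samples, iemg, fs = fs),
    rms_mV = purrr::map_dbl(win$samples, rms_amplitude),
    mpf_Hz = purrr::map_dbl(win$samples, mpf, fs = fs, band = band)
  )
  class(out) <- c("semg_features", class(out))
  out
}

#' Write a fatigue-feature table as CSV
#'
#' Columns: `t_start_s`, `iemg_mVs`, `rms_mV`, `mpf_Hz`.
#'
#' @param x A `semg_features` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# per-window feature matrix (IEMG, RMS, MPF) for the classical classifiers
.window_features <- function(ds, band = c(20, 500)) {
  fs <- ds$fs
  t(apply(ds$windows, 1, function(w) {
    c(iemg = iemg(w, fs), rms = rms_amplitude(w),
      mpf = mpf(w, fs, band = c(max(1e-6, band[1]), min(band[2], fs / 2))))
  }))
}
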