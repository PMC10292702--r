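# Synthetic SEMG generation. The surrogate signal is band-limited Gaussian
# noise (4th-order Butterworth band-pass applied with filtfilt) whose local
# RMS is modulated along a linear fatigue ramp and whose spectral centre
# tracks a mean-power-frequency ramp. This reproduces the statistical
# structure the downstream analysis assumes -- amplitude (RMS/IEMG) rising
# with fatigue while MPF stays near-constant -- without modelling individual
# motor-unit action potentials.

# synthesis band: 20-450 Hz keeps a guard band below Nyquist at fs = 1000
.SYNTH_BAND <- c(20, 450)

#' Fatigue profile for synthetic SEMG
#'
#' Describes the amplitude and spectral trajectory of a synthetic SEMG
#' recording: windowed RMS ramps linearly `rms_start -> rms_end` and the
#' spectral centre drifts `mpf_start -> mpf_end` over `duration_s`.
#'
#' @param duration_s Recording length in seconds (> 0).
#' @param rms_start,rms_end Target RMS amplitude in mV (> 0).
#' @param mpf_start,mpf_end Target mean power frequency in Hz (within
#'   20-500 Hz).
#' @return A list of class `fatigue_profile`.
#' @export
fatigue_profile <- function(duration_s = 60, rms_start = 0.5, rms_end = 1.5,
                            mpf_start = 80, mpf_end = 80) {
  if (duration_s <= 0) rlang::abort("duration_s must be positive")
  if (rms_start <= 0 || rms_end <= 0) rlang::abort("rms values must be positive")
  if (any(c(mpf_start, mpf_end) < 20) || any(c(mpf_start, mpf_end) > 500)) {
    rlang::abort("mpf values must lie in [20, 500] Hz")
  }
  structure(list(duration_s = duration_s, rms_start = rms_start,
                 rms_end = rms_end, mpf_start = mpf_start,
                 mpf_end = mpf_end),
            class = "fatigue_profile")
}

#' Noise specification for synthetic SEMG contamination
#'
#' @param white_sigma Standard deviation of additive white Gaussian noise (mV).
#' @param powerline_amp Amplitude of 50 Hz power-line interference (mV).
#' @param baseline_amp Amplitude of 0.5 Hz baseline wander (mV).
#' @param seed Integer seed controlling the noise realisation and the
#'   power-line phase.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(white_sigma = 0.5, powerline_amp = 0.5,
                       baseline_amp = 0.2, seed = 1L) {
  if (any(c(white_sigma, powerline_amp, baseline_amp) < 0)) {
    rlang::abort("noise amplitudes must be non-negative")
  }
  structure(list(white_sigma = white_sigma, powerline_amp = powerline_amp,
                 baseline_amp = baseline_amp, seed = as.integer(seed)),
            class = "noise_spec")
}

# centred moving RMS with clamped edges, O(n) via cumulated squares
.local_rms <- function(x, w) {
  n <- length(x)
  w <- min(w, n)
  cs <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(0L, i - ceiling(w / 2))
  hi <- pmin(n, i + floor(w / 2))
  sqrt((cs[hi + 1] - cs[lo + 1]) / (hi - lo))
}

.bandpass <- function(x, fs, lo, hi, order = 4) {
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Generate a clean synthetic SEMG signal
#'
#' Band-limited (20-450 Hz) zero-mean Gaussian surrogate whose windowed RMS
#' follows the profile's linear amplitude ramp and whose spectral centre
#' follows its MPF ramp. Deterministic given `seed`.
#'
#' @param profile A [fatigue_profile()].
#' @param fs Sampling rate in Hz (default 1000, the acquisition rate the
#'   feature pipeline assumes).
#' @param seed Integer seed.
#' @param band Synthesis band in Hz; must lie inside (0, fs/2).
#' @return A [semg_signal()] tibble.
#' @export
#' @examples
#' s <- generate_clean_semg(fatigue_profile(duration_s = 2), seed = 7)
#' sqrt(mean(s$value_mV^2))
generate_clean_semg <- function(profile, fs = 1000, seed = 1L,
                                band = .SYNTH_BAND) {
  stopifnot(inherits(profile, "fatigue_profile"))
  if (band[1] <= 0 || band[2] >= fs / 2) {
    rlang::abort("synthesis band must lie inside (0, fs/2)")
  }
  n <- round(profile$duration_s * fs)
  if (n < 2) rlang::abort("duration too short at this sampling rate")
  half_bw <- 60  # half-width of the tracking band-pass around the MPF centre

  withr::with_seed(seed, {
    w <- stats::rnorm(n)
    centres <- if (profile$mpf_start == profile$mpf_end) {
      profile$mpf_start
    } else {
      seq(profile$mpf_start, profile$mpf_end, length.out = 8)
    }
    comps <- lapply(centres, function(fc) {
      .bandpass(w, fs, max(band[1], fc - half_bw), min(band[2], fc + half_bw))
    })
    if (length(comps) == 1L) {
      carrier <- comps[[1]]
    } else {
      # triangular cross-fade between the per-block filtered versions
      tt <- seq(0, 1, length.out = n)
      knots <- seq(0, 1, length.out = length(comps))
      carrier <- numeric(n)
      for (b in seq_along(comps)) {
        wt <- pmax(0, 1 - abs(tt - knots[b]) * (length(comps) - 1))
        carrier <- carrier + wt * comps[[b]]
      }
    }
    env <- .local_rms(carrier, w = min(n, fs))  # 1 s local-RMS normalisation
    ramp <- seq(profile$rms_start, profile$rms_end, length.out = n)
    semg_signal(ramp * carrier / env, fs = fs)
  })
}

#' Contaminate a clean signal with white, power-line and baseline noise
#'
#' Adds white Gaussian noise, 50 Hz power-line interference (random phase
#' drawn from the spec's seed) and a 0.5 Hz baseline-wander sinusoid. The
#' clean reference is returned untouched so denoising can be scored against
#' known truth.
#'
#' @param clean A [semg_signal()] (or numeric vector with `fs` attribute).
#' @param spec A [noise_spec()].
#' @return A list with elements `noisy` and `clean`, both `semg_signal`.
#' @export
add_noise <- function(clean, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  x <- .signal_values(clean)
  if (length(x) == 0) rlang::abort("clean signal is empty")
  fs <- .signal_fs(clean)
  t <- (seq_along(x) - 1) / fs
  withr::with_seed(spec$seed, {
    phi <- stats::runif(2, 0, 2 * pi)
    noisy <- x +
      stats::rnorm(length(x), 0, spec$white_sigma) +
      spec$powerline_amp * sin(2 * pi * 50 * t + phi[1]) +
      spec$baseline_amp * sin(2 * pi * 0.5 * t + phi[2])
  })
  list(noisy = semg_signal(noisy, fs = fs), clean = semg_signal(x, fs = fs))
}

#' Generate a labeled set of SEMG windows for classifier training
#'
#' For each class a continuous noisy recording is synthesised under that
#' class's fatigue profile and chopped into `n_per_class` consecutive
#' windows, mimicking pieces cut from a longer acquisition. Class 0 is the
#' non-fatigued profile, class 1 the fatigued (higher-RMS) one. The pooled
#' windows are shuffled deterministically by `seed`.
#'
#' @param n_per_class Windows per class (>= 1).
#' @param window_len Window length in samples (>= 2).
#' @param class_profiles List of two [fatigue_profile()]s:
#'   `list(nonfatigued, fatigued)`. Their `duration_s` is overridden so each
#'   recording spans `n_per_class * window_len` samples.
#' @param noise A [noise_spec()].
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @return A `labeled_window_set`: list with `windows`
#'   (matrix, one row per window), `labels` (0/1 integer vector) and `fs`.
#' @export
generate_labeled_windows <- function(n_per_class, window_len = 1000,
                                     class_profiles = list(
                                       fatigue_profile(rms_start = 0.5, rms_end = 0.5),
                                       fatigue_profile(rms_start = 2.0, rms_end = 2.0)
                                     ),
                                     noise = noise_spec(white_sigma = 0.1,
                                                        powerline_amp = 0,
                                                        baseline_amp = 0),
                                     fs = 1000, seed = 1L) {
  if (n_per_class < 1) rlang::abort("n_per_class must be >= 1")
  if (window_len < 2) rlang::abort("window_len must be >= 2")
  stopifnot(length(class_profiles) == 2)

  one_class <- function(profile, class_seed) {
    p <- profile
    p$duration_s <- n_per_class * window_len / fs
    clean <- generate_clean_semg(p, fs = fs, seed = class_seed)
    ns <- noise
    ns$seed <- class_seed + 1L
    noisy <- add_noise(clean, ns)$noisy$value_mV
    matrix(noisy[seq_len(n_per_class * window_len)],
           nrow = n_per_class, ncol = window_len, byrow = TRUE)
  }

  w0 <- one_class(class_profiles[[1]], as.integer(seed))
  w1 <- one_class(class_profiles[[2]], as.integer(seed) + 104729L)
  windows <- rbind(w0, w1)
  labels <- rep(c(0L, 1L), each = n_per_class)
  ord <- withr::with_seed(seed, sample.int(nrow(windows)))
  structure(list(windows = windows[ord, , drop = FALSE],
                 labels = labels[ord], fs = fs),
            class = "labeled_window_set")
}

#' @export
print.labeled_window_set <- function(x, ...) {
  cat("<labeled_window_set> ", nrow(x$windows), " windows of ",
      ncol(x$windows), " samples at ", x$fs, " Hz; class balance ",
      sum(x$labels == 0L), "/", sum(x$labels == 1L), "\n", sep = "")
  invisible(x)
}

# subset helper used by splitting and validation carve-outs
.lws_subset <- function(ds, idx) {
  structure(list(windows = ds$windows[idx, , drop = FALSE],
                 labels = ds$labels[idx], fs = ds$fs),
            class = "labeled_window_set")
}
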