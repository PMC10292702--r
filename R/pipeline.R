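# End-to-end orchestration: synthesize -> denoise -> features -> classify
# (SEMG arm) and synthesize phantoms -> track -> thickness/texture
# (ultrasound arm), plus the generic two-group comparison used for
# endpoint tables. Each run writes its artifacts under an output directory
# together with a manifest (config hash, seed, package version) so reruns
# with an identical config are reproducible.

.write_manifest <- function(out_dir, config, seed, stage_files) {
  manifest <- list(
    config_hash = rlang::hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("myofatigue")),
    files = stage_files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Run the SEMG analysis pipeline end to end
#'
#' Synthesizes a noisy fatigue recording, runs the denoising benchmark,
#' denoises the recording with the improved threshold, extracts the
#' windowed feature series, builds a labeled window set, splits it 7:3,
#' trains the requested classifiers and evaluates them. All artifacts are
#' written under `out_dir` (feature CSV, benchmark CSV, metrics JSON,
#' manifest).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param profile [fatigue_profile()] of the demonstration recording.
#' @param noise [noise_spec()] contaminating it.
#' @param n_per_class Windows per class for the classifier stage.
#' @param window_len Window length in samples.
#' @param models Character vector from `c("lstm", "svm", "bpnn", "cnn")`.
#' @param lstm A [lstm_config()] (its seed is overridden by `seed`).
#' @param cnn A [cnn_config()].
#' @param benchmark_replicates Replicates for the denoising benchmark.
#' @param window_s,overlap,band Feature-extraction settings.
#' @return A list with `features`, `benchmark`, `metrics` (tibble of
#'   per-model percentages) and `manifest`, invisibly also written to disk.
#' @export
run_semg_pipeline <- function(out_dir, seed = 1L,
                              profile = fatigue_profile(duration_s = 60,
                                                        rms_start = 0.5,
                                                        rms_end = 1.5),
                              noise = noise_spec(),
                              n_per_class = 200L, window_len = 1000L,
                              models = c("lstm", "svm", "bpnn", "cnn"),
                              lstm = lstm_config(max_epochs = 80L,
                                                 early_stopping_patience = 10L),
                              cnn = cnn_config(),
                              benchmark_replicates = 20L,
                              window_s = 1, overlap = 0.5,
                              band = c(20, 500)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(profile = profile, noise = noise, n_per_class = n_per_class,
                 window_len = window_len, models = models, lstm = lstm,
                 cnn = cnn, benchmark_replicates = benchmark_replicates,
                 window_s = window_s, overlap = overlap, band = band)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)))
    })
  }

  clean <- stage("synthesize", generate_clean_semg(profile, seed = seed))
  ns <- noise; ns$seed <- seed + 1L
  noisy <- stage("contaminate", add_noise(clean, ns)$noisy)

  bench <- stage("denoise-benchmark",
                 denoise_benchmark(replicates = benchmark_replicates,
                                   seed = seed, noise = noise))
  utils::write.csv(as.data.frame(summarise_benchmark(bench)),
                   file.path(out_dir, "denoise_benchmark.csv"),
                   row.names = FALSE)

  den <- stage("denoise", denoise_semg(noisy))
  feats <- stage("features",
                 compute_feature_series(den, window_s = window_s,
                                        overlap = overlap, band = band))
  write_feature_csv(feats, file.path(out_dir, "features.csv"))

  ds <- stage("label-windows",
              generate_labeled_windows(n_per_class, window_len = window_len,
                                       noise = noise, seed = seed + 2L))
  sp <- stage("split", split_dataset(ds, 0.7, seed = seed + 3L))

  metrics <- purrr::map(models, function(m) {
    fit <- stage(paste0("train-", m), switch(
      m,
      lstm = { cfg <- lstm; cfg$seed <- seed + 4L; train_lstm(sp$train, cfg) },
      svm = train_baseline("svm", sp$train, seed = seed + 4L),
      bpnn = train_baseline("bpnn", sp$train, seed = seed + 4L),
      cnn = train_baseline("cnn", sp$train, seed = seed + 4L, config = cnn),
      rlang::abort("unknown model kind")
    ))
    ev <- stage(paste0("evaluate-", m), evaluate_model(fit, sp$eval))
    dplyr::mutate(glance(ev), model = m, .before = 1)
  }) |> purrr::list_rbind()
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  manifest <- .write_manifest(out_dir, config, seed,
                              c("denoise_benchmark.csv", "features.csv",
                                "metrics.json"))
  invisible(list(features = feats, benchmark = bench, metrics = metrics,
                 manifest = manifest))
}

#' Run the ultrasound phantom pipeline end to end
#'
#' Generates a layered speckle phantom sequence, tracks an ROI in the
#' surface-muscle layer, estimates layer boundaries and thicknesses on
#' frame 0, computes per-ROI texture features and the per-frame response
#' amplitude, and writes tracking and feature CSVs plus a manifest.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param spec A [phantom_spec()] (its seed is overridden by `seed`).
#' @param track_roi0 The [roi()] tracked through the sequence; the default
#'   sits inside the surface-muscle layer of the default phantom.
#' @param search_margin Block-matching search half-width in pixels.
#' @param glcm_levels Gray levels for the texture stage.
#' @return A list with `tracking`, `thickness`, `texture`, `manifest`.
#' @export
run_usbi_pipeline <- function(out_dir, seed = 1L,
                              spec = phantom_spec(frame_displacement_mm = 1,
                                                  n_frames = 8L),
                              track_roi0 = roi(40, 60, 40, 40),
                              search_margin = 4L, glcm_levels = 32L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec$seed <- seed
  config <- list(spec = spec, track_roi0 = track_roi0,
                 search_margin = search_margin, glcm_levels = glcm_levels)

  ph <- generate_phantom_sequence(spec)
  trk <- track_roi(ph, track_roi0, search_margin = search_margin)
  amp <- purrr::map2_dbl(ph$frames, seq_along(ph$frames), function(fr, k) {
    row_k <- trk$roi_row[match(k, trk$frame)]
    col_k <- trk$roi_col[match(k, trk$frame)]
    if (is.na(row_k)) return(NA_real_)
    mean_response_amplitude(fr, roi(row_k, col_k, track_roi0$height,
                                    track_roi0$width))
  })
  tracking <- dplyr::mutate(trk, amplitude = amp[trk$frame])
  utils::write.csv(as.data.frame(tracking),
                   file.path(out_dir, "tracking.csv"), row.names = FALSE)

  b <- estimate_boundary_rows(ph$frames[[1]], n_boundaries = 3)
  thick <- thickness_from_boundaries(b[1], b[2], b[3], ph$pixel_spacing_mm)
  tex <- roi_texture(ph$frames[[1]], track_roi0, levels = glcm_levels)
  features <- dplyr::bind_cols(tex, thick)
  utils::write.csv(as.data.frame(features),
                   file.path(out_dir, "usbi_features.csv"), row.names = FALSE)

  manifest <- .write_manifest(out_dir, config, seed,
                              c("tracking.csv", "usbi_features.csv"))
  invisible(list(tracking = tracking, thickness = thick, texture = tex,
                 manifest = manifest))
}

#' Two-group comparison of an endpoint
#'
#' Welch's unequal-variance two-sided t-test with a significance flag at
#' `alpha = 0.05`, matching the per-endpoint convention of group-comparison
#' tables. If both arms are constant with different means the difference is
#' reported as infinitely significant (`statistic = Inf`, `p = 0`); equal
#' constant arms are rejected as degenerate.
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each).
#' @param endpoint Endpoint name carried into the output.
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble of class `group_comparison`: `endpoint`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `statistic`, `p_value`,
#'   `significant`.
#' @export
#' @examples
#' group_compare(rnorm(20), rnorm(20, 5), "thickness_mm")
group_compare <- function(values_a, values_b, endpoint = "endpoint",
                          alpha = 0.05) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    rlang::abort("each group needs at least 2 values")
  }
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va == 0 && vb == 0) {
    if (mean(values_a) == mean(values_b)) {
      rlang::abort("degenerate comparison: both groups constant and equal")
    }
    statistic <- Inf; p <- 0
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
    statistic <- unname(tt$statistic); p <- tt$p.value
  }
  out <- tibble::tibble(endpoint = endpoint,
                        mean_a = mean(values_a), sd_a = stats::sd(values_a),
                        mean_b = mean(values_b), sd_b = stats::sd(values_b),
                        statistic = statistic, p_value = p,
                        significant = p < alpha)
  class(out) <- c("group_comparison", class(out))
  out
}
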