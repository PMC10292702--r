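test_that("clean SEMG generator is deterministic with the right length and RMS", {
  prof <- fatigue_profile(duration_s = 10, rms_start = 1, rms_end = 1)
  s1 <- generate_clean_semg(prof, fs = 1000, seed = 7)
  s2 <- generate_clean_semg(prof, fs = 1000, seed = 7)
  expect_identical(s1$value_mV, s2$value_mV)
  expect_equal(nrow(s1), 10000L)
  expect_lt(abs(mean(s1$value_mV)), 0.05)

  # windowed RMS tracks the (flat) amplitude target within 10%
  f <- compute_feature_series(s1, window_s = 1, overlap = 0)
  expect_true(all(abs(f$rms_mV - 1) < 0.1))
})

test_that("clean SEMG is band-limited to the synthesis band", {
  s <- generate_clean_semg(fatigue_profile(duration_s = 8), seed = 21)
  ps <- Mod(stats::fft(s$value_mV))^2
  f <- (seq_along(ps) - 1) * 1000 / length(ps)
  half <- f <= 500
  in_band <- half & f >= 20 & f <= 450
  expect_gt(sum(ps[in_band]) / sum(ps[half]), 0.95)
})

test_that("clean SEMG generator rejects bad profiles and bands", {
  expect_error(fatigue_profile(duration_s = 0), "positive")
  expect_error(fatigue_profile(rms_start = -1), "positive")
  expect_error(fatigue_profile(mpf_start = 10), "\\[20, 500\\]")
  expect_error(generate_clean_semg(fatigue_profile(), fs = 1000,
                                   band = c(20, 600)), "fs/2")
})

test_that("add_noise injects exactly the requested contamination", {
  clean <- generate_clean_semg(fatigue_profile(duration_s = 10, rms_start = 1,
                                               rms_end = 1), seed = 2)
  # zero noise: identity
  z <- add_noise(clean, noise_spec(0, 0, 0, seed = 5))
  expect_equal(z$noisy$value_mV, clean$value_mV)
  expect_equal(z$clean$value_mV, clean$value_mV)

  # white-only: variance of the added noise ~ sigma^2 within 5% at N = 10000
  w <- add_noise(clean, noise_spec(0.5, 0, 0, seed = 6))
  expect_equal(stats::var(w$noisy$value_mV - clean$value_mV), 0.25,
               tolerance = 0.05)

  # deterministic given the spec seed
  w2 <- add_noise(clean, noise_spec(0.5, 0, 0, seed = 6))
  expect_identical(w$noisy$value_mV, w2$noisy$value_mV)

  expect_error(add_noise(semg_signal(numeric(0), 1000), noise_spec()),
               "empty")
  expect_error(noise_spec(white_sigma = -1), "non-negative")
})

test_that("labeled window generation balances classes and separates profiles", {
  ds <- generate_labeled_windows(5, window_len = 200, seed = 3)
  expect_equal(nrow(ds$windows), 10L)
  expect_equal(sum(ds$labels == 0), 5L)
  expect_equal(sum(ds$labels == 1), 5L)

  tiny <- generate_labeled_windows(1, window_len = 100, seed = 3)
  expect_equal(nrow(tiny$windows), 2L)

  # class 1 (fatigued profile) has higher per-window RMS by construction
  r <- apply(ds$windows, 1, function(w) sqrt(mean(w^2)))
  expect_gt(mean(r[ds$labels == 1]), 2 * mean(r[ds$labels == 0]))

  # identical class profiles: class-conditional mean RMS difference ~ 0
  same <- generate_labeled_windows(
    30, window_len = 500,
    class_profiles = list(fatigue_profile(rms_start = 1, rms_end = 1),
                          fatigue_profile(rms_start = 1, rms_end = 1)),
    seed = 4)
  rs <- apply(same$windows, 1, function(w) sqrt(mean(w^2)))
  d <- abs(mean(rs[same$labels == 1]) - mean(rs[same$labels == 0]))
  expect_lt(d / mean(rs), 0.05)

  expect_error(generate_labeled_windows(0, 100), ">= 1")
  expect_error(generate_labeled_windows(5, 1), ">= 2")
})

test_that("phantom generator honors its spec in the noiseless case", {
  sp <- phantom_spec(speckle_scale = 0, frame_displacement_mm = 0,
                     n_frames = 3, seed = 1)
  ph <- generate_phantom_sequence(sp)
  expect_identical(ph$frames[[1]], ph$frames[[2]])
  expect_identical(ph$frames[[1]], ph$frames[[3]])
  # piecewise-constant layers at the stated echogenicities
  expect_equal(sort(unique(as.numeric(ph$frames[[1]]))),
               sort(sp$layer_mean_echogenicity))
})

test_that("phantom ground truth follows depth + k * displacement and the image matches", {
  sp <- phantom_spec(frame_displacement_mm = 1, n_frames = 5, seed = 2)
  ph <- generate_phantom_sequence(sp)
  k <- ph$truth$frame - 1
  expect_equal(ph$truth$surface_mm, sp$surface_boundary_mm + k * 1)
  expect_equal(ph$truth$deep_mm, sp$deep_boundary_mm + k * 1)
  expect_equal(ph$truth$bottom_mm, sp$bottom_boundary_mm + k * 1)

  # gray-level discontinuity rows match metadata within 1 px (noiseless)
  sp0 <- phantom_spec(speckle_scale = 0, frame_displacement_mm = 1,
                      n_frames = 4, seed = 2)
  ph0 <- generate_phantom_sequence(sp0)
  for (j in seq_along(ph0$frames)) {
    b <- estimate_boundary_rows(ph0$frames[[j]])
    truth_px <- c(ph0$truth$surface_mm[j], ph0$truth$deep_mm[j],
                  ph0$truth$bottom_mm[j]) / sp0$pixel_spacing_mm
    expect_true(all(abs(b - truth_px) <= 1))
  }
})

test_that("phantom speckle is unit-mean and generation is deterministic", {
  sp <- phantom_spec(height_px = 220, width_px = 120, speckle_scale = 1,
                     surface_boundary_mm = 10, deep_boundary_mm = 60,
                     bottom_boundary_mm = 100,
                     layer_mean_echogenicity = c(128, 100, 120, 80),
                     n_frames = 1, seed = 9)
  ph <- generate_phantom_sequence(sp)
  # surface-muscle layer: rows 21..120 (100 x 120 px); mean gray within 3%
  layer <- ph$frames[[1]][21:120, ]
  expect_equal(mean(layer), 100, tolerance = 0.03)

  ph2 <- generate_phantom_sequence(sp)
  expect_identical(ph$frames, ph2$frames)

  expect_error(phantom_spec(frame_displacement_mm = 5, n_frames = 10),
               "leave the image")
  expect_error(phantom_spec(surface_boundary_mm = 50, deep_boundary_mm = 40),
               "surface < deep")
})
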