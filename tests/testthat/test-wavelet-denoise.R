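test_that("wavelet decomposition reconstructs the input exactly", {
  for (w in c("haar", "db2", "db4", "db8")) {
    for (n in c(100, 257, 4096)) {
      set.seed(n)
      x <- stats::rnorm(n)
      dec <- wt_decompose(x, wavelet = w, levels = 4)
      expect_lt(max(abs(wt_reconstruct(dec) - x)) / max(abs(x)), 1e-8)
    }
  }
  expect_error(wt_decompose(rnorm(8), levels = 4), "shorter")
  expect_error(wt_decompose(rnorm(100), wavelet = "nope"), "unknown wavelet")
})

test_that("noise sigma estimator implements the median rule", {
  expect_equal(estimate_noise_sigma(rep(0.6745, 5)), 1.0)
  expect_equal(estimate_noise_sigma(rep(0, 9)), 0)
  expect_equal(estimate_noise_sigma(c(1, -2, 3, -4, 5)), 3 / 0.6745)
  expect_error(estimate_noise_sigma(numeric(0)), "empty")
})

test_that("universal threshold follows sigma * sqrt(2 ln N)", {
  expect_equal(universal_threshold(0, 100), 0)
  expect_equal(universal_threshold(1, exp(2)), 2)
  expect_equal(universal_threshold(2, 1024), 2 * sqrt(2 * log(1024)))
  expect_error(universal_threshold(1, 1), ">= 2")
  expect_error(universal_threshold(-1, 100), "non-negative")
})

test_that("threshold functions match their closed forms", {
  expect_equal(apply_threshold(0, threshold_params(1, 1, "hard")), 0)
  expect_equal(apply_threshold(0, threshold_params(1, 1, "soft")), 0)
  expect_equal(apply_threshold(0, threshold_params(1, 1, "improved")), 0)
  expect_equal(apply_threshold(2, threshold_params(1, mode = "soft")), 1)
  expect_equal(apply_threshold(2, threshold_params(1, mode = "hard")), 2)
  # improved with k = 1: above lambda w - lambda^2/(2w); below w^2/(2 lambda)
  expect_equal(apply_threshold(2, threshold_params(1, 1, "improved")), 1.75)
  expect_equal(apply_threshold(0.5, threshold_params(1, 1, "improved")), 0.125)
  expect_error(threshold_params(-1), ">= 0")
  expect_error(threshold_params(1, k = 0), "> 0")
})

test_that("improved threshold sits between soft and hard where defined", {
  lam <- 1.3
  w <- seq(-5 * lam, 5 * lam, length.out = 4001)
  for (k in c(0.5, 1, 2, 10)) {
    s <- apply_threshold(w, threshold_params(lam, k, "soft"))
    h <- apply_threshold(w, threshold_params(lam, k, "hard"))
    im <- apply_threshold(w, threshold_params(lam, k, "improved"))
    expect_true(all(abs(s) <= abs(im) + 1e-12))
    expect_true(all(abs(im) <= abs(w) + 1e-12))
    above <- abs(w) >= lam
    expect_true(all(abs(im[above]) <= abs(h[above]) + 1e-12))
  }
})

test_that("improved threshold is continuous, odd, and tends to hard as k grows", {
  lam <- 2
  for (k in c(1, 2, 5)) {
    p <- threshold_params(lam, k, "improved")
    eps <- 1e-6
    expect_lt(abs(apply_threshold(lam + eps, p) - apply_threshold(lam - eps, p)),
              1e-5)
    # both branches meet at sign(w) * lambda / (k + 1)
    expect_equal(apply_threshold(lam, p), lam / (k + 1))
    w <- seq(-8, 8, length.out = 801)
    expect_identical(apply_threshold(-w, p), -apply_threshold(w, p))
  }
  p50 <- threshold_params(lam, 50, "improved")
  for (w in c(0.5 * lam, 2 * lam)) {
    expect_lt(abs(apply_threshold(w, p50) -
                    apply_threshold(w, threshold_params(lam, 50, "hard"))),
              1e-6)
  }
})

test_that("denoising reduces to the identity at lambda 0 and helps a noisy tone", {
  set.seed(11)
  x <- stats::rnorm(2000)
  expect_lt(max(abs(denoise_semg(x, lam = 0) - x)) / max(abs(x)), 1e-8)
  expect_equal(denoise_semg(rep(0, 1024)), rep(0, 1024))

  t <- seq(0, 2 - 1e-3, by = 1e-3)
  clean <- semg_signal(sin(2 * pi * 50 * t), fs = 1000)
  noisy <- add_noise(clean, noise_spec(0.5, 0, 0, seed = 5))$noisy
  den <- denoise_semg(noisy)
  expect_gt(snr(clean, den), snr(clean, noisy))
})

test_that("SNR and RMSE implement their definitions", {
  expect_identical(snr(c(1, 2, 3), c(1, 2, 3)), Inf)
  expect_equal(snr(c(1, 1, 1, 1), c(0, 0, 0, 0)), 0)
  # clean energy 100, error energy 1 -> 20 dB
  expect_equal(snr(c(10, 0), c(10, 1)), 20)
  expect_error(snr(c(0, 0), c(1, 2)), "zero")
  expect_error(snr(1:3, 1:4), "mismatch")

  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(1:10, 1:10 + 0.7), 0.7)
  expect_error(rmse(1:3, 1:4), "mismatch")
})

test_that("benchmark produces one scored row per mode and replicate", {
  b <- denoise_benchmark(replicates = 2, seed = 1)
  expect_s3_class(b, "denoise_benchmark")
  expect_equal(nrow(b), 6L)
  expect_true(all(is.finite(b$snr_db)))
  s <- summarise_benchmark(b)
  expect_equal(nrow(s), 3L)
  # rerun reproduces identical scores
  b2 <- denoise_benchmark(replicates = 2, seed = 1)
  expect_identical(b$snr_db, b2$snr_db)
})
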