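test_that("normalized cross-correlation matches hand computations", {
  x <- matrix(c(1, 3, 2, 4), 2)
  expect_equal(normalized_cross_correlation(x, x), 1.0)
  expect_equal(normalized_cross_correlation(x, 2.5 * x + 7), 1.0,
               tolerance = 1e-9)
  expect_equal(normalized_cross_correlation(x, -0.3 * x + 1), -1.0,
               tolerance = 1e-9)
  y <- matrix(c(4, 2, 3, 1), 2)  # rows (4,3),(2,1): reversed ramp
  expect_equal(normalized_cross_correlation(matrix(c(1, 3, 2, 4), 2), y), -1.0)
  expect_error(normalized_cross_correlation(x, matrix(5, 2, 2)), "constant")
  expect_error(normalized_cross_correlation(x, matrix(1, 3, 3)), "shape")
})

test_that("tracking is exact on noiseless phantoms and recovers known shifts", {
  # static noiseless phantom: ROI spans a boundary so the template has
  # structure; trajectory must stay put with Rd = 1
  ph0 <- generate_phantom_sequence(
    phantom_spec(speckle_scale = 0, frame_displacement_mm = 0, n_frames = 4,
                 seed = 1))
  trk0 <- track_roi(ph0, roi(80, 40, 30, 30), search_margin = 3)
  expect_equal(trk0$shift_row, rep(0L, 4))
  expect_equal(trk0$shift_col, rep(0L, 4))
  expect_equal(trk0$rd, rep(1, 4))
  expect_false(attr(trk0, "truncated"))

  # 2 px/frame axial shift with mild speckle
  ph <- generate_phantom_sequence(
    phantom_spec(speckle_scale = 0.3, frame_displacement_mm = 1,
                 n_frames = 6, seed = 2))
  trk <- track_roi(ph, roi(40, 60, 40, 40), search_margin = 4)
  expect_true(all(abs(trk$shift_row - ph$truth$shift_px) <= 1))
  expect_true(all(abs(trk$shift_col) <= 1))

  # margin smaller than the true shift: displacement saturates at the margin
  trk_sat <- track_roi(ph, roi(40, 60, 40, 40), search_margin = 1)
  expect_true(all(diff(trk_sat$shift_row) <= 1))

  expect_error(track_roi(ph0, roi(30, 30, 20, 20), 2), "constant")
  expect_error(track_roi(ph, roi(190, 60, 40, 40), 2), "fit inside")
})

test_that("thickness measurement follows the boundary arithmetic", {
  th <- thickness_from_boundaries(10, 60, 160, 0.1)
  expect_equal(th$surface_mm, 5.0)
  expect_equal(th$deep_mm, 10.0)
  expect_equal(th$total_mm, 15.0)
  expect_equal(th$total_mm, th$surface_mm + th$deep_mm)
  expect_error(thickness_from_boundaries(10, 60, 160, 0), "> 0")
  expect_error(thickness_from_boundaries(60, 10, 160, 0.1), "increasing")

  # end-to-end on a noiseless phantom: recovered thickness equals the spec
  sp <- phantom_spec(speckle_scale = 0, n_frames = 1, seed = 3)
  ph <- generate_phantom_sequence(sp)
  b <- estimate_boundary_rows(ph$frames[[1]])
  th2 <- thickness_from_boundaries(b[1], b[2], b[3], sp$pixel_spacing_mm)
  expect_equal(th2$surface_mm, sp$deep_boundary_mm - sp$surface_boundary_mm)
  expect_equal(th2$deep_mm, sp$bottom_boundary_mm - sp$deep_boundary_mm)
})

test_that("mean response amplitude rescales 8-bit gray to [0, 1]", {
  z <- matrix(0, 10, 10)
  expect_equal(mean_response_amplitude(z, roi(0, 0, 10, 10)), 0)
  expect_equal(mean_response_amplitude(z + 255, roi(0, 0, 10, 10)), 1)
  half <- rbind(matrix(0, 5, 10), matrix(255, 5, 10))
  expect_equal(mean_response_amplitude(half, roi(0, 0, 10, 10)), 0.5)
  expect_error(mean_response_amplitude(z, roi(5, 5, 10, 10)), "outside")
})

test_that("gray quantization bins the 8-bit range uniformly", {
  img <- matrix(c(0, 127, 128, 255), 2)
  expect_equal(as.numeric(gray_quantize(img, 2)), c(0, 0, 1, 1))
  expect_equal(as.numeric(gray_quantize(matrix(42, 3, 3), 8)),
               rep(1, 9))
  expect_identical(as.numeric(gray_quantize(img, 256)), as.numeric(img))
  expect_error(gray_quantize(img, 1), ">= 2")
  expect_error(gray_quantize(img, 300), "representable")
})

test_that("GLCM counts, symmetrization and features match hand results", {
  q <- matrix(c(0L, 1L, 1L, 0L), 2)  # checkerboard
  U <- compute_glcm(q, 2, offsets = list(c(0, 1)), symmetric = FALSE)
  expect_equal(unclass(U), matrix(c(0, 0.5, 0.5, 0), 2), ignore_attr = TRUE)
  tf <- texture_features(U)
  expect_equal(tf$asm, 0.5)
  expect_equal(tf$contrast, 1.0)
  expect_equal(tf$hom, 0.5)

  const <- compute_glcm(matrix(2L, 4, 4), 4)
  expect_equal(sum(diag(unclass(const))), 1)
  tc <- texture_features(const)
  expect_equal(c(tc$asm, tc$contrast, tc$hom), c(1, 0, 1))

  set.seed(7)
  qs <- matrix(sample(0:3, 36, TRUE), 6)
  Us <- compute_glcm(qs, 4, symmetric = TRUE)
  expect_equal(unclass(Us), t(unclass(Us)), ignore_attr = TRUE)

  L <- 4
  unif <- matrix(1 / L^2, L, L)
  expect_equal(texture_features(unif)$asm, 1 / L^2)
  expect_error(texture_features(unif * 2), "not normalized")
  expect_error(compute_glcm(qs, 4, offsets = list(c(0, 10))), "larger")
})

test_that("GLCM pipeline agrees exactly with the brute-force oracle", {
  set.seed(99)
  for (rep in 1:100) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    L <- sample(2:4, 1)
    q <- matrix(sample(0:(L - 1), nr * nc, TRUE), nr, nc)
    offs <- list(c(0, 1), c(-1, 0))[sample(1:2, sample(1:2, 1))]
    sym <- sample(c(TRUE, FALSE), 1)
    U <- compute_glcm(q, L, offsets = offs, symmetric = sym)
    U_ref <- glcm_oracle(q, L, offs, sym)
    expect_identical(unclass(U)[seq_len(L^2)], U_ref[seq_len(L^2)])
    tf <- texture_features(U)
    ref <- texture_oracle(U_ref)
    expect_equal(c(tf$asm, tf$contrast, tf$hom), unname(ref),
                 tolerance = 1e-12)
  }
})

test_that("coarser speckle grain lowers contrast and raises homogeneity", {
  feats <- function(grain, seed) {
    ph <- generate_phantom_sequence(
      phantom_spec(speckle_scale = 0.8, speckle_grain_px = grain,
                   n_frames = 1, seed = seed))
    roi_texture(ph$frames[[1]], roi(40, 60, 60, 60), levels = 16)
  }
  fine <- purrr::map(1:10, ~feats(1, .x)) |> purrr::list_rbind()
  coarse <- purrr::map(1:10, ~feats(3, .x)) |> purrr::list_rbind()
  expect_lt(stats::median(coarse$contrast), stats::median(fine$contrast))
  expect_gt(stats::median(coarse$hom), stats::median(fine$hom))
})
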