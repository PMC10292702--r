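# Ultrasound muscle-image analysis: normalized cross-correlation ROI
# tracking, muscle-thickness measurement, response-amplitude summary and
# gray-level co-occurrence matrix (GLCM) texture features.
#
# Coordinate convention: row-major, 0-based, origin top-left; depth grows
# with the row index. ROIs are half-open [row, row+height) x [col, col+width).

#' Rectangular region of interest
#'
#' @param row,col Top-left corner, 0-based.
#' @param height,width Extent in pixels (>= 2).
#' @return A list of class `roi`.
#' @export
roi <- function(row, col, height, width) {
  if (height < 2 || width < 2) rlang::abort("ROI must be at least 2x2")
  if (row < 0 || col < 0) rlang::abort("ROI must have non-negative origin")
  structure(list(row = as.integer(row), col = as.integer(col),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi")
}

.roi_in_frame <- function(r, frame) {
  r$row >= 0 && r$col >= 0 &&
    r$row + r$height <= nrow(frame) && r$col + r$width <= ncol(frame)
}

.extract_roi <- function(frame, r) {
  frame[(r$row + 1):(r$row + r$height), (r$col + 1):(r$col + r$width),
        drop = FALSE]
}

#' Normalized cross-correlation between two pixel blocks
#'
#' `Rd = sum((x - mean(x)) * (y - mean(y))) / sqrt(sum((x - mean(x))^2) *
#' sum((y - mean(y))^2))`, the zero-mean, variance-normalised similarity in
#' `[-1, 1]`. Invariant under positive affine rescaling of either block.
#'
#' @param x_patch,y_patch Numeric matrices of identical shape; neither may
#'   be constant.
#' @return The correlation Rd.
#' @export
#' @examples
#' normalized_cross_correlation(matrix(1:4, 2), matrix(c(4, 3, 2, 1), 2))
normalized_cross_correlation <- function(x_patch, y_patch) {
  if (!all(dim(x_patch) == dim(y_patch))) rlang::abort("shape mismatch")
  xc <- x_patch - mean(x_patch)
  yc <- y_patch - mean(y_patch)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) rlang::abort("constant block: correlation undefined")
  sum(xc * yc) / den
}

#' Track an ROI through a frame sequence by block matching
#'
#' The frame-0 patch is the template throughout (no update, avoiding
#' drift). In each subsequent frame the ROI is relocated to the integer
#' offset within `search_margin` pixels of its previous position that
#' maximises the normalized cross-correlation with the template; ties are
#' broken by smallest Euclidean displacement, then lexicographically by
#' (row, col). If no candidate position fits inside the frame, tracking
#' halts and the trajectory is flagged truncated.
#'
#' @param sequence A `frame_sequence`.
#' @param roi0 The [roi()] in frame 0.
#' @param search_margin Search half-width in pixels (>= 1).
#' @return A tibble of class `roi_track` with per-frame columns `frame`,
#'   `roi_row`, `roi_col`, `rd`, `shift_row`, `shift_col` (cumulative,
#'   relative to frame 0); attribute `truncated` is TRUE if tracking
#'   halted early.
#' @export
track_roi <- function(sequence, roi0, search_margin = 5L) {
  stopifnot(inherits(sequence, "frame_sequence"), inherits(roi0, "roi"),
            search_margin >= 1)
  frames <- sequence$frames
  if (!.roi_in_frame(roi0, frames[[1]])) {
    rlang::abort("roi0 does not fit inside frame 0")
  }
  template <- .extract_roi(frames[[1]], roi0)
  if (stats::sd(as.numeric(template)) == 0) {
    rlang::abort("template patch is constant; pick a textured ROI")
  }
  m <- as.integer(search_margin)
  cand <- expand.grid(dr = -m:m, dc = -m:m)
  cand <- cand[order(cand$dr^2 + cand$dc^2, cand$dr, cand$dc), ]

  cur <- roi0
  rows <- vector("list", length(frames))
  rows[[1]] <- tibble::tibble(frame = 1L, roi_row = roi0$row,
                              roi_col = roi0$col, rd = 1,
                              shift_row = 0L, shift_col = 0L)
  truncated <- FALSE
  for (k in seq_along(frames)[-1]) {
    fr <- frames[[k]]
    best <- NULL
    for (ci in seq_len(nrow(cand))) {
      r2 <- cur
      r2$row <- cur$row + cand$dr[ci]
      r2$col <- cur$col + cand$dc[ci]
      if (!.roi_in_frame(r2, fr)) next
      patch <- .extract_roi(fr, r2)
      if (stats::sd(as.numeric(patch)) == 0) next
      rd <- normalized_cross_correlation(template, patch)
      # candidates pre-sorted by displacement then (row, col): strict '>'
      # implements the tie-break
      if (is.null(best) || rd > best$rd + 1e-12) best <- list(roi = r2, rd = rd)
    }
    if (is.null(best)) {
      truncated <- TRUE
      break
    }
    cur <- best$roi
    rows[[k]] <- tibble::tibble(frame = k, roi_row = cur$row,
                                roi_col = cur$col, rd = best$rd,
                                shift_row = cur$row - roi0$row,
                                shift_col = cur$col - roi0$col)
  }
  out <- purrr::list_rbind(purrr::compact(rows))
  class(out) <- c("roi_track", class(out))
  attr(out, "truncated") <- truncated
  out
}

#' Muscle thicknesses from boundary rows
#'
#' Surface-muscle thickness spans the surface boundary to the deep
#' boundary, deep-muscle thickness the deep boundary to the bottom
#' boundary; total is their sum.
#'
#' @param surface_row,deep_row,bottom_row Boundary pixel rows, strictly
#'   increasing.
#' @param pixel_spacing_mm Pixel spacing in mm (> 0).
#' @return A tibble with columns `surface_mm`, `deep_mm`, `total_mm`.
#' @export
#' @examples
#' thickness_from_boundaries(10, 60, 160, 0.1)
thickness_from_boundaries <- function(surface_row, deep_row, bottom_row,
                                      pixel_spacing_mm) {
  if (!(surface_row < deep_row && deep_row < bottom_row)) {
    rlang::abort("boundary rows must be strictly increasing")
  }
  if (pixel_spacing_mm <= 0) rlang::abort("pixel_spacing_mm must be > 0")
  surface <- (deep_row - surface_row) * pixel_spacing_mm
  deep <- (bottom_row - deep_row) * pixel_spacing_mm
  tibble::tibble(surface_mm = surface, deep_mm = deep,
                 total_mm = surface + deep)
}

#' Estimate layer-boundary rows from a frame
#'
#' Boundary rows are the locations of the largest axial gradients of the
#' laterally averaged intensity profile -- the gray-level discontinuities
#' between layers.
#'
#' @param frame Numeric matrix (one frame).
#' @param n_boundaries Number of boundaries to return.
#' @param min_separation_px Minimum row separation between reported
#'   boundaries.
#' @return Integer vector of 0-based boundary rows, sorted increasing.
#' @export
estimate_boundary_rows <- function(frame, n_boundaries = 3L,
                                   min_separation_px = 5L) {
  prof <- rowMeans(frame)
  grad <- abs(diff(prof))
  ord <- order(grad, decreasing = TRUE)
  picked <- integer(0)
  for (i in ord) {
    if (all(abs(i - picked) >= min_separation_px)) picked <- c(picked, i)
    if (length(picked) == n_boundaries) break
  }
  sort(picked)  # diff index i = transition between rows i and i+1 -> 0-based row i
}

#' Mean response amplitude of an ROI
#'
#' Mean pixel magnitude within the ROI after rescaling the 8-bit gray range
#' to `[0, 1]`.
#'
#' @param frame Numeric matrix, gray levels 0-255.
#' @param r An [roi()].
#' @return Dimensionless amplitude in `[0, 1]`.
#' @export
mean_response_amplitude <- function(frame, r) {
  stopifnot(inherits(r, "roi"))
  if (!.roi_in_frame(r, frame)) rlang::abort("ROI outside frame")
  mean(abs(.extract_roi(frame, r))) / 255
}

#' Quantize gray levels into L uniform bins
#'
#' Uniform binning of the full 8-bit representable range 0-255 into `L`
#' equal bins; output values lie in `{0, ..., L-1}`.
#'
#' @param image Numeric matrix with values in 0-255.
#' @param levels Number of gray levels `L` (2-256).
#' @return Integer matrix of quantized values.
#' @export
#' @examples
#' gray_quantize(matrix(c(0, 127, 128, 255), 2), levels = 2)
gray_quantize <- function(image, levels = 32L) {
  if (levels < 2) rlang::abort("levels must be >= 2")
  if (levels > 256) rlang::abort("levels exceeds the 8-bit representable range")
  q <- floor(image * levels / 256)
  q[q > levels - 1] <- levels - 1L
  q[q < 0] <- 0L
  mode(q) <- "integer"
  q
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of gray-level pairs `(value at p, value at
#' p + offset)` over all valid pixels `p`, accumulated over the given
#' offsets, optionally symmetrized (adding the transpose), and normalized
#' to sum 1.
#'
#' @param quantized Integer matrix with values in `{0, ..., levels-1}`
#'   (see [gray_quantize()]).
#' @param levels Number of gray levels `L`.
#' @param offsets List of `c(drow, dcol)` pixel offsets; the default is the
#'   four distance-1 directions (0, 45, 90, 135 degrees).
#' @param symmetric Add the transpose before normalizing (default TRUE).
#' @return A `glcm` object: the L x L normalized matrix with attributes
#'   `levels`, `offsets`, `symmetric`.
#' @export
#' @examples
#' q <- matrix(c(0L, 1L, 1L, 0L), 2)  # checkerboard
#' compute_glcm(q, levels = 2, offsets = list(c(0, 1)), symmetric = FALSE)
compute_glcm <- function(quantized, levels,
                         offsets = list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1)),
                         symmetric = TRUE) {
  stopifnot(length(offsets) >= 1)
  if (any(quantized < 0) || any(quantized >= levels)) {
    rlang::abort("image values must lie in {0, ..., levels-1}")
  }
  nr <- nrow(quantized); nc <- ncol(quantized)
  U <- matrix(0, levels, levels)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    if (abs(dr) >= nr || abs(dc) >= nc) {
      rlang::abort("offset larger than the image")
    }
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    a <- quantized[rs, cs, drop = FALSE]
    b <- quantized[rs + dr, cs + dc, drop = FALSE]
    idx <- as.numeric(a) * levels + as.numeric(b) + 1
    counts <- tabulate(idx, nbins = levels * levels)
    U <- U + matrix(counts, levels, levels, byrow = TRUE)
  }
  if (symmetric) U <- U + t(U)
  U <- U / sum(U)
  structure(U, class = "glcm", levels = levels, offsets = offsets,
            symmetric = symmetric)
}

#' GLCM texture features: ASM, contrast, homogeneity
#'
#' Angular second moment `sum(U^2)` (energy/uniformity), contrast
#' `sum((i-j)^2 * U)` (local variation) and homogeneity
#' `sum(U / (1 + (i-j)^2))` (inverse difference moment), computed on a
#' normalized co-occurrence matrix.
#'
#' @param U A `glcm` object or normalized L x L matrix (sum 1 within 1e-6).
#' @return A tibble with columns `asm`, `contrast`, `hom`.
#' @export
#' @examples
#' q <- matrix(c(0L, 1L, 1L, 0L), 2)
#' texture_features(compute_glcm(q, 2, list(c(0, 1)), symmetric = FALSE))
texture_features <- function(U) {
  Um <- unclass(U)
  if (abs(sum(Um) - 1) > 1e-6) rlang::abort("co-occurrence matrix not normalized")
  L <- nrow(Um)
  d <- outer(seq_len(L), seq_len(L), "-")
  tibble::tibble(
    asm = sum(Um^2),
    contrast = sum(d^2 * Um),
    hom = sum(Um / (1 + d^2))
  )
}

#' Per-ROI texture features of a frame
#'
#' Quantizes the ROI patch and averages the three GLCM features over the
#' four distance-1 directions (each computed from its own symmetrized
#' co-occurrence matrix).
#'
#' @param frame Numeric matrix, gray 0-255.
#' @param r An [roi()]; `NULL` uses the whole frame.
#' @param levels Gray levels for quantization (default 32).
#' @return A tibble with columns `asm`, `contrast`, `hom`.
#' @export
roi_texture <- function(frame, r = NULL, levels = 32L) {
  patch <- if (is.null(r)) frame else .extract_roi(frame, r)
  q <- gray_quantize(patch, levels)
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  feats <- purrr::map(dirs, function(d) {
    texture_features(compute_glcm(q, levels, offsets = list(d),
                                  symmetric = TRUE))
  }) |> purrr::list_rbind()
  dplyr::summarise(feats, asm = mean(.data$asm),
                   contrast = mean(.data$contrast), hom = mean(.data$hom))
}
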