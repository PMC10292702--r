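# Layered B-mode speckle phantoms. A phantom is a stack of 8-bit-range
# grayscale frames showing (top to bottom) a superficial tissue layer, the
# surface muscle, the deep muscle and a basal layer, separated by boundaries
# at known depths. Speckle is a multiplicative Rayleigh field scaled to unit
# mean -- the canonical fully-developed B-mode speckle surrogate. One master
# field translates axially with the tissue, so consecutive frames are
# coherent integer-pixel crops: block matching has a stable pattern to
# track, and per-frame ground truth is known exactly.

#' Phantom specification
#'
#' @param height_px,width_px Frame size in pixels.
#' @param pixel_spacing_mm Axial/lateral pixel spacing (mm per pixel).
#' @param surface_boundary_mm,deep_boundary_mm,bottom_boundary_mm Depths of
#'   the top of the surface muscle, the surface/deep interface and the
#'   bottom of the deep muscle; must be strictly increasing and inside the
#'   imaged depth over the whole sequence.
#' @param layer_mean_echogenicity Mean gray level (0-255) of the four
#'   layers, top to bottom.
#' @param speckle_scale Speckle strength in `[0, 1]`: 0 gives noiseless
#'   piecewise-constant layers, 1 full Rayleigh speckle.
#' @param speckle_grain_px Speckle correlation length in pixels (>= 1);
#'   larger values give a coarser texture.
#' @param frame_displacement_mm Axial tissue shift per frame (mm; applied
#'   at integer-pixel resolution).
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(height_px = 200L, width_px = 160L,
                         pixel_spacing_mm = 0.5,
                         surface_boundary_mm = 10, deep_boundary_mm = 45,
                         bottom_boundary_mm = 90,
                         layer_mean_echogenicity = c(170, 90, 130, 60),
                         speckle_scale = 0.3, speckle_grain_px = 1,
                         frame_displacement_mm = 0, n_frames = 10L,
                         seed = 1L) {
  b <- c(surface_boundary_mm, deep_boundary_mm, bottom_boundary_mm)
  if (any(diff(b) <= 0) || b[1] <= 0) {
    rlang::abort("boundaries must satisfy 0 < surface < deep < bottom")
  }
  depth <- height_px * pixel_spacing_mm
  max_shift <- abs(frame_displacement_mm) * (n_frames - 1)
  if (b[3] + max_shift > depth) {
    rlang::abort("boundaries would leave the image during the sequence")
  }
  if (n_frames < 1) rlang::abort("n_frames must be >= 1")
  if (speckle_scale < 0 || speckle_scale > 1) {
    rlang::abort("speckle_scale must be in [0, 1]")
  }
  stopifnot(length(layer_mean_echogenicity) == 4, speckle_grain_px >= 1)
  structure(as.list(environment())[c(
    "height_px", "width_px", "pixel_spacing_mm", "surface_boundary_mm",
    "deep_boundary_mm", "bottom_boundary_mm", "layer_mean_echogenicity",
    "speckle_scale", "speckle_grain_px", "frame_displacement_mm",
    "n_frames", "seed")], class = "phantom_spec")
}

# unit-mean Rayleigh field, optionally smoothed to a coarser grain and
# rescaled back to unit mean
.speckle_field <- function(nr, nc, grain) {
  sigma <- 1 / sqrt(pi / 2)  # Rayleigh sigma giving mean 1
  f <- matrix(sigma * sqrt(-2 * log(stats::runif(nr * nc))), nr, nc)
  if (grain > 1) {
    k <- max(3L, 2L * round(grain) + 1L)
    kern <- stats::dnorm(seq(-3, 3, length.out = k))
    kern <- kern / sum(kern)
    f <- apply(f, 2, function(col) stats::filter(col, kern, circular = TRUE))
    f <- t(apply(f, 1, function(row) stats::filter(row, kern, circular = TRUE)))
    f <- f / mean(f)
  }
  f
}

#' Generate a layered speckle phantom sequence
#'
#' Each frame is the per-layer echogenicity map multiplied by unit-mean
#' speckle, with layers (and speckle) shifted axially by
#' `frame_displacement_mm` per frame. Ground-truth boundary depths are
#' attached per frame as `initial depth + k * frame_displacement_mm`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `frame_sequence`: list with `frames` (list of
#'   height x width numeric matrices, gray range 0-255),
#'   `pixel_spacing_mm`, and `truth`, a tibble with per-frame columns
#'   `frame`, `surface_mm`, `deep_mm`, `bottom_mm`, `shift_px`.
#' @export
#' @examples
#' ph <- generate_phantom_sequence(phantom_spec(n_frames = 3, seed = 2))
#' ph$truth
generate_phantom_sequence <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height_px; w <- spec$width_px; sp <- spec$pixel_spacing_mm
  disp_px <- spec$frame_displacement_mm / sp
  shifts <- round((seq_len(spec$n_frames) - 1) * disp_px)
  # tissue moves down by shift_k px: frame_k(r) = master(r + pad_lo - shift_k)
  pad_lo <- max(0, max(shifts)); pad_hi <- max(0, -min(shifts))
  Hm <- h + pad_lo + pad_hi

  # master echogenicity profile; master row r corresponds to frame-0 depth
  # (r - pad_lo) * spacing
  depth0 <- (seq_len(Hm) - pad_lo - 0.5) * sp
  layer <- findInterval(depth0, c(spec$surface_boundary_mm,
                                  spec$deep_boundary_mm,
                                  spec$bottom_boundary_mm)) + 1
  echo_col <- spec$layer_mean_echogenicity[layer]

  master <- withr::with_seed(spec$seed, {
    base <- matrix(echo_col, Hm, w)
    if (spec$speckle_scale > 0) {
      fld <- .speckle_field(Hm, w, spec$speckle_grain_px)
      base * ((1 - spec$speckle_scale) + spec$speckle_scale * fld)
    } else {
      base
    }
  })
  master <- pmin(pmax(master, 0), 255)

  frames <- lapply(shifts, function(s) {
    master[(pad_lo - s + 1):(pad_lo - s + h), , drop = FALSE]
  })
  truth <- tibble::tibble(
    frame = seq_len(spec$n_frames),
    surface_mm = spec$surface_boundary_mm + (seq_len(spec$n_frames) - 1) * spec$frame_displacement_mm,
    deep_mm = spec$deep_boundary_mm + (seq_len(spec$n_frames) - 1) * spec$frame_displacement_mm,
    bottom_mm = spec$bottom_boundary_mm + (seq_len(spec$n_frames) - 1) * spec$frame_displacement_mm,
    shift_px = shifts
  )
  structure(list(frames = frames, pixel_spacing_mm = sp, truth = truth,
                 spec = spec),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat("<frame_sequence> ", length(x$frames), " frame(s) of ",
      nrow(x$frames[[1]]), "x", ncol(x$frames[[1]]), " px at ",
      x$pixel_spacing_mm, " mm/px\n", sep = "")
  invisible(x)
}

#' Write / read a phantom sequence as multi-page TIFF plus JSON sidecar
#'
#' The TIFF stores the frames (gray levels rescaled to `[0, 1]`); the
#' sidecar carries `pixel_spacing_mm` and the per-frame ground-truth
#' boundary table.
#'
#' @param x A `frame_sequence`.
#' @param tiff_path,sidecar_path Output paths.
#' @return `tiff_path`, invisibly.
#' @export
write_phantom_tiff <- function(x, tiff_path,
                               sidecar_path = sub("\\.tiff?$", ".json", tiff_path)) {
  stopifnot(inherits(x, "frame_sequence"))
  tiff::writeTIFF(lapply(x$frames, function(f) f / 255), tiff_path,
                  bits.per.sample = 8L)
  jsonlite::write_json(list(pixel_spacing_mm = x$pixel_spacing_mm,
                            truth = x$truth),
                       sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_phantom_tiff
#' @export
read_phantom_tiff <- function(tiff_path,
                              sidecar_path = sub("\\.tiff?$", ".json", tiff_path)) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!file.exists(sidecar_path)) {
    rlang::abort("missing JSON sidecar (pixel_spacing_mm is required)")
  }
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(side$pixel_spacing_mm)) {
    rlang::abort("sidecar lacks required field 'pixel_spacing_mm'")
  }
  structure(list(frames = lapply(pages, function(p) round(p * 255)),
                 pixel_spacing_mm = side$pixel_spacing_mm,
                 truth = if (!is.null(side$truth)) tibble::as_tibble(side$truth) else NULL,
                 spec = NULL),
            class = "frame_sequence")
}
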