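# Discrete wavelet transform (Mallat pyramid) with symmetric half-sample
# boundary extension. Implemented here because the denoising stage needs
# direct access to per-level detail coefficients and exact-length
# reconstruction; filters are the standard Daubechies orthonormal banks.

.db_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134,
          0.8365163037378079, 0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db8 = c(-0.00011747678400228192, 0.0006754494059985568,
          -0.0003917403729959771, -0.00487035299301066,
          0.008746094047015655, 0.013981027917015516, -0.04408825393106472,
          -0.01736930100202211, 0.128747426620186, 0.00047248457399797254,
          -0.2840155429624281, -0.015829105256023893, 0.5853546836548691,
          0.6756307362980128, 0.3128715909144659, 0.05441584224308161)
)

wavelet_filters <- function(wavelet) {
  dec_lo <- .db_filters[[wavelet]]
  if (is.null(dec_lo)) {
    rlang::abort(paste0("unknown wavelet '", wavelet, "'; available: ",
                        paste(names(.db_filters), collapse = ", ")))
  }
  L <- length(dec_lo)
  rec_lo <- rev(dec_lo)
  # quadrature mirror relation between the low- and high-pass banks
  dec_hi <- rec_lo * (-1)^seq_len(L)
  rec_hi <- rev(dec_hi)
  list(dec_lo = dec_lo, dec_hi = dec_hi, rec_lo = rec_lo, rec_hi = rec_hi,
       length = L)
}

# symmetric (half-sample) extension by L-1 samples on each side
.sym_ext <- function(x, m) {
  n <- length(x)
  if (m >= n) rlang::abort("signal too short for this wavelet/level")
  c(rev(x[seq_len(m)]), x, rev(x[seq(n - m + 1, n)]))
}

# one analysis step: returns list(approx, detail), each floor((n + L - 1)/2)
.dwt_step <- function(x, filt) {
  L <- filt$length
  ext <- .sym_ext(x, L - 1)
  a_full <- stats::convolve(ext, rev(filt$dec_lo), type = "open")
  d_full <- stats::convolve(ext, rev(filt$dec_hi), type = "open")
  n_out <- floor((length(x) + L - 1) / 2)
  idx <- L + 2 * seq_len(n_out) - 1
  list(approx = a_full[idx], detail = d_full[idx])
}

# one synthesis step; out_len is the length of the signal that was analysed
.idwt_step <- function(approx, detail, filt, out_len) {
  L <- filt$length
  la <- length(approx)
  up_a <- numeric(2 * la); up_a[seq(1, 2 * la, by = 2)] <- approx
  up_d <- numeric(2 * la); up_d[seq(1, 2 * la, by = 2)] <- detail
  ya <- stats::convolve(up_a, rev(filt$rec_lo), type = "open")
  yd <- stats::convolve(up_d, rev(filt$rec_hi), type = "open")
  y <- ya + yd
  full_len <- 2 * la - L + 2
  y <- y[seq(L - 1, L - 2 + full_len)]
  y[seq_len(out_len)]
}

#' Multilevel discrete wavelet decomposition
#'
#' Decomposes a numeric vector into `levels` detail bands plus a final
#' approximation band using the Mallat pyramid with symmetric signal
#' extension. Reconstruction of untouched coefficients via
#' [wt_reconstruct()] reproduces the input to numerical precision.
#'
#' @param x Numeric vector (the signal samples).
#' @param wavelet Wavelet name: one of `"haar"`, `"db2"`, `"db4"`, `"db8"`.
#' @param levels Number of decomposition levels (>= 1).
#'
#' @return An object of class `wavelet_decomposition`: a list with
#'   `wavelet`, `levels`, `approx` (coarsest approximation coefficients),
#'   `details` (list, finest level first), `input_lengths` (per-level
#'   bookkeeping used by reconstruction) and `N` (original length).
#' @seealso [wt_reconstruct()], [denoise_semg()]
#' @export
#' @examples
#' dec <- wt_decompose(sin(seq(0, 10, length.out = 256)), "db4", 3)
#' str(dec$details, max.level = 1)
wt_decompose <- function(x, wavelet = "db4", levels = 4L) {
  x <- as.numeric(x)
  stopifnot(levels >= 1L)
  if (length(x) < 2^levels) {
    rlang::abort("signal shorter than the decomposition requires")
  }
  filt <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  input_lengths <- integer(levels)
  a <- x
  for (j in seq_len(levels)) {
    input_lengths[j] <- length(a)
    st <- .dwt_step(a, filt)
    details[[j]] <- st$detail
    a <- st$approx
  }
  structure(
    list(wavelet = wavelet, levels = levels, approx = a, details = details,
         input_lengths = input_lengths, N = length(x)),
    class = "wavelet_decomposition"
  )
}

#' Reconstruct a signal from a wavelet decomposition
#'
#' Inverse of [wt_decompose()]; output length equals the original `N`.
#'
#' @param dec A `wavelet_decomposition` object.
#' @return Numeric vector of length `dec$N`.
#' @export
wt_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  filt <- wavelet_filters(dec$wavelet)
  a <- dec$approx
  for (j in rev(seq_len(dec$levels))) {
    a <- .idwt_step(a, dec$details[[j]], filt, dec$input_lengths[j])
  }
  a
}
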