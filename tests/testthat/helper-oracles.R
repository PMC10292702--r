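# Independent brute-force GLCM oracle: enumerate every pixel pair for every
# offset with explicit loops, then normalize. Used to cross-check the
# vectorised compute_glcm()/texture_features() path.
glcm_oracle <- function(q, levels, offsets, symmetric) {
  U <- matrix(0, levels, levels)
  for (off in offsets) {
    for (r in seq_len(nrow(q))) {
      for (cc in seq_len(ncol(q))) {
        r2 <- r + off[1]; c2 <- cc + off[2]
        if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
          U[q[r, cc] + 1, q[r2, c2] + 1] <- U[q[r, cc] + 1, q[r2, c2] + 1] + 1
        }
      }
    }
  }
  if (symmetric) U <- U + t(U)
  U / sum(U)
}

texture_oracle <- function(U) {
  L <- nrow(U)
  asm <- 0; contrast <- 0; hom <- 0
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      asm <- asm + U[i, j]^2
      contrast <- contrast + (i - j)^2 * U[i, j]
      hom <- hom + U[i, j] / (1 + (i - j)^2)
    }
  }
  c(asm = asm, contrast = contrast, hom = hom)
}

# small labeled window set of pure sinusoid windows with per-class
# amplitudes; cheap deterministic fixture for the classical classifiers
sinusoid_window_set <- function(amps0, amps1, len = 200, fs = 1000) {
  t <- (seq_len(len) - 1) / fs
  mk <- function(a) a * sin(2 * pi * 100 * t)
  windows <- do.call(rbind, lapply(c(amps0, amps1), mk))
  structure(list(windows = windows,
                 labels = rep(c(0L, 1L), c(length(amps0), length(amps1))),
                 fs = fs),
            class = "labeled_window_set")
}
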