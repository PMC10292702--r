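# 1-D convolutional baseline on the raw window, written in matrix code:
# one convolutional layer (ReLU) -> global average pooling -> dense sigmoid
# output, trained with Adam on binary cross-entropy. The convolution is
# evaluated as a single matrix product against the matrix of sliding
# windows, which keeps both passes to a handful of BLAS calls.

#' CNN training configuration
#'
#' @param filters Number of convolutional filters.
#' @param kernel Kernel width in (downsampled) time steps.
#' @param timesteps Input windows are block-averaged to this many steps.
#' @param batch_size,learning_rate,max_epochs As in [lstm_config()].
#' @param early_stopping_patience,validation_fraction As in [lstm_config()].
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(filters = 8L, kernel = 9L, timesteps = 200L,
                       batch_size = 70L, learning_rate = 0.01,
                       max_epochs = 150L, early_stopping_patience = 15L,
                       validation_fraction = 0.1) {
  stopifnot(filters >= 1, kernel >= 2, timesteps > kernel, batch_size >= 1,
            learning_rate > 0, max_epochs >= 1)
  structure(as.list(environment()), class = "cnn_config")
}

# rows of M -> stacked sliding windows: ((n * P) x kernel), P = T - k + 1
.sliding_windows <- function(M, kernel) {
  Tt <- ncol(M); P <- Tt - kernel + 1
  out <- matrix(0, nrow(M) * P, kernel)
  for (j in seq_len(kernel)) {
    out[, j] <- as.numeric(t(M[, j:(j + P - 1), drop = FALSE]))
  }
  out
}

.cnn_forward <- function(Xw, n, P, par) {
  pre <- Xw %*% par$K + rep(par$bk, each = nrow(Xw))
  act <- pmax(pre, 0)
  # global average pool over the P positions of each sample
  grp <- rep(seq_len(n), each = P)
  pooled <- rowsum(act, grp) / P
  p <- .sigmoid(as.numeric(pooled %*% par$v) + par$b_out)
  list(p = p, pre = pre, pooled = pooled, grp = grp)
}

#' Train the 1-D CNN fatigue classifier
#'
#' @param train A `labeled_window_set` with both classes.
#' @param seed Integer seed.
#' @param config A [cnn_config()].
#' @return A `fatigue_cnn` model handle supporting [predict_labels()].
#' @export
train_cnn <- function(train, seed = 1L, config = cnn_config()) {
  stopifnot(inherits(train, "labeled_window_set"),
            inherits(config, "cnn_config"))
  carve <- split_dataset(train, 1 - config$validation_fraction,
                         seed = seed + 1L, stratified = TRUE)
  Xf <- .downsample_rows(carve$train$windows, config$timesteps)
  mu <- mean(Xf); sdv <- stats::sd(as.numeric(Xf))
  if (sdv == 0) rlang::abort("degenerate constant training input")
  Xf <- (Xf - mu) / sdv
  Xv <- (.downsample_rows(carve$eval$windows, config$timesteps) - mu) / sdv
  yf <- carve$train$labels; yv <- carve$eval$labels
  kk <- config$kernel; P <- ncol(Xf) - kk + 1
  Wv <- .sliding_windows(Xv, kk)

  withr::with_seed(seed, {
    par <- list(K = .glorot(kk, config$filters), bk = numeric(config$filters),
                v = as.numeric(.glorot(config$filters, 1)), b_out = 0)
    opt <- .adam_init_named(par)
    best <- list(par = par, loss = Inf, epoch = 0L)
    wait <- 0L; epochs_run <- 0L
    n <- nrow(Xf)
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (bi in batches) {
        Xb <- Xf[bi, , drop = FALSE]
        Wb <- .sliding_windows(Xb, kk)
        nb <- length(bi)
        fw <- .cnn_forward(Wb, nb, P, par)
        dlogit <- (fw$p - yf[bi]) / nb
        gv <- as.numeric(crossprod(fw$pooled, dlogit))
        gb_out <- sum(dlogit)
        dpooled <- tcrossprod(dlogit, par$v)
        dact <- dpooled[fw$grp, , drop = FALSE] / P
        dpre <- dact * (fw$pre > 0)
        gK <- crossprod(Wb, dpre)
        gbk <- colSums(dpre)
        up <- .adam_step(par, list(K = gK, bk = gbk, v = gv, b_out = gb_out),
                         opt, config$learning_rate)
        par <- up$par; opt <- up$state
      }
      val_loss <- .bce(.cnn_forward(Wv, nrow(Xv), P, par)$p, yv)
      epochs_run <- ep
      if (val_loss < best$loss - 1e-6) {
        best <- list(par = par, loss = val_loss, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stopping_patience) break
      }
    }
  })

  structure(list(par = best$par, config = config, mu = mu, sd = sdv,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 epochs_run = epochs_run),
            class = c("fatigue_cnn", "fatigue_model"))
}

.adam_init_named <- function(par) {
  z <- lapply(par, function(p) p * 0)
  list(m = z, v = z, t = 0)
}

#' @export
predict_labels.fatigue_cnn <- function(model, newdata) {
  X <- (.downsample_rows(newdata$windows, model$config$timesteps) -
          model$mu) / model$sd
  kk <- model$config$kernel
  P <- ncol(X) - kk + 1
  fw <- .cnn_forward(.sliding_windows(X, kk), nrow(X), P, model$par)
  as.integer(fw$p >= 0.5)
}
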