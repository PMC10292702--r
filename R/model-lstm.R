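# LSTM fatigue-state classifier, implemented from scratch in matrix code:
# a single recurrent layer of LSTM cells over the (downsampled,
# standardised) raw window, ReLU on the final hidden state, dense sigmoid
# output, binary cross-entropy loss, Adam optimiser with
# backpropagation-through-time, and early stopping with checkpoint restore
# on a validation carve-out.

#' LSTM training configuration
#'
#' Defaults follow the fatigue-recognition setup this package implements:
#' 100 hidden units, ReLU activation on the recurrent layer's output, Adam
#' with learning rate 0.001, batch size 70, and early stopping.
#'
#' @param hidden_units LSTM units in the single recurrent layer.
#' @param activation Activation applied to the final hidden state before
#'   the output layer: `"relu"` or `"linear"`.
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping (>= 1).
#' @param max_epochs Training-epoch cap.
#' @param timesteps Input windows are block-averaged down to this many time
#'   steps (one feature per step).
#' @param validation_fraction Fraction of the training set carved out for
#'   early stopping.
#' @param seed Integer seed governing initialisation and data order.
#' @return A list of class `lstm_config`.
#' @export
lstm_config <- function(hidden_units = 100L, activation = c("relu", "linear"),
                        batch_size = 70L, learning_rate = 0.001,
                        early_stopping_patience = 10L, max_epochs = 200L,
                        timesteps = 200L, validation_fraction = 0.1,
                        seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(hidden_units >= 1, batch_size >= 1, learning_rate > 0,
            early_stopping_patience >= 1, max_epochs >= 1, timesteps >= 1,
            validation_fraction > 0, validation_fraction < 0.5)
  structure(as.list(environment()), class = "lstm_config")
}

# block-average each row down to `steps` time steps
.downsample_rows <- function(M, steps) {
  W <- ncol(M)
  steps <- min(steps, W)
  bounds <- floor(seq(0, W, length.out = steps + 1))
  out <- matrix(0, nrow(M), steps)
  for (j in seq_len(steps)) {
    idx <- (bounds[j] + 1):bounds[j + 1]
    out[, j] <- if (length(idx) == 1) M[, idx] else rowMeans(M[, idx, drop = FALSE])
  }
  out
}

.glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.lstm_init <- function(H) {
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias 1 stabilises early training
  list(H = H,
       Wx = as.numeric(.glorot(1, 4 * H)),
       Wh = .glorot(H, 4 * H),
       b = b,
       v = as.numeric(.glorot(H, 1)),
       b_out = 0)
}

.lstm_forward <- function(X, par, act, cache = FALSE) {
  n <- nrow(X); Tt <- ncol(X); H <- par$H
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  steps <- if (cache) vector("list", Tt) else NULL
  for (t in seq_len(Tt)) {
    h_prev <- h; c_prev <- cc
    z <- tcrossprod(X[, t], par$Wx) + h %*% par$Wh
    z <- z + rep(par$b, each = n)
    i <- .sigmoid(z[, 1:H, drop = FALSE])
    f <- .sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    if (cache) steps[[t]] <- list(i = i, f = f, g = g, o = o, tc = tc,
                                  c_prev = c_prev, h_prev = h_prev)
  }
  a <- if (act == "relu") pmax(h, 0) else h
  p <- .sigmoid(as.numeric(a %*% par$v) + par$b_out)
  list(p = p, h = h, a = a, steps = steps)
}

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

.lstm_backward <- function(X, y, fw, par, act) {
  n <- nrow(X); Tt <- ncol(X); H <- par$H
  dlogit <- (fw$p - y) / n
  gv <- as.numeric(crossprod(fw$a, dlogit))
  gb_out <- sum(dlogit)
  da <- tcrossprod(dlogit, par$v)
  dh <- if (act == "relu") da * (fw$h > 0) else da
  dc <- matrix(0, n, H)
  gWx <- numeric(4 * H); gWh <- matrix(0, H, 4 * H); gb <- numeric(4 * H)
  for (t in rev(seq_len(Tt))) {
    s <- fw$steps[[t]]
    do <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g; df <- dc * s$c_prev; dg <- dc * s$i
    dZ <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do * s$o * (1 - s$o))
    gWx <- gWx + as.numeric(crossprod(X[, t], dZ))
    gWh <- gWh + crossprod(s$h_prev, dZ)
    gb <- gb + colSums(dZ)
    dh <- tcrossprod(dZ, par$Wh)
    dc <- dc * s$f
  }
  list(Wx = gWx, Wh = gWh, b = gb, v = gv, b_out = gb_out)
}

.adam_init <- function(par) {
  z <- lapply(par[c("Wx", "Wh", "b", "v", "b_out")], function(p) p * 0)
  list(m = z, v = z, t = 0)
}

.adam_step <- function(par, grads, st, lr, clip = 5) {
  gn <- sqrt(sum(unlist(lapply(grads, function(g) sum(g^2)))))
  if (is.finite(gn) && gn > clip) grads <- lapply(grads, function(g) g * clip / gn)
  st$t <- st$t + 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(grads)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * grads[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = st)
}

#' Train the LSTM fatigue-state classifier
#'
#' A single recurrent layer of LSTM cells reads the raw denoised window
#' (block-averaged to `config$timesteps` steps and standardised with
#' training-set statistics); the final hidden state passes through the
#' configured activation into a dense sigmoid output. Training minimises
#' binary cross-entropy with Adam and stops early when the validation loss
#' (on a stratified carve-out) fails to improve for
#' `early_stopping_patience` epochs, restoring the best checkpoint.
#'
#' @param train A `labeled_window_set` containing both classes.
#' @param config An [lstm_config()].
#' @return A `fatigue_lstm` model handle supporting [predict_labels()],
#'   [generics::tidy()] (per-epoch losses) and [generics::glance()].
#' @export
train_lstm <- function(train, config = lstm_config()) {
  stopifnot(inherits(train, "labeled_window_set"),
            inherits(config, "lstm_config"))
  if (length(unique(train$labels)) < 2) {
    rlang::abort("training set must contain both classes")
  }

  carve <- split_dataset(train, train_fraction = 1 - config$validation_fraction,
                         seed = config$seed + 1L, stratified = TRUE)
  fit <- carve$train; val <- carve$eval

  Xf <- .downsample_rows(fit$windows, config$timesteps)
  mu <- mean(Xf); sdv <- stats::sd(as.numeric(Xf))
  if (sdv == 0) rlang::abort("degenerate constant training input")
  Xf <- (Xf - mu) / sdv
  Xv <- (.downsample_rows(val$windows, config$timesteps) - mu) / sdv
  yf <- fit$labels; yv <- val$labels
  H <- config$hidden_units

  withr::with_seed(config$seed, {
    par <- .lstm_init(H)
    opt <- .adam_init(par)
    best <- list(par = par, loss = Inf, epoch = 0L)
    history <- vector("list", config$max_epochs)
    wait <- 0L
    n <- nrow(Xf)
    epochs_run <- 0L
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tr_loss <- 0
      for (bi in batches) {
        Xb <- Xf[bi, , drop = FALSE]
        fw <- .lstm_forward(Xb, par, config$activation, cache = TRUE)
        tr_loss <- tr_loss + .bce(fw$p, yf[bi]) * length(bi)
        gr <- .lstm_backward(Xb, yf[bi], fw, par, config$activation)
        up <- .adam_step(par, gr, opt, config$learning_rate)
        par <- up$par; opt <- up$state
      }
      val_loss <- .bce(.lstm_forward(Xv, par, config$activation)$p, yv)
      history[[ep]] <- tibble::tibble(epoch = ep, train_loss = tr_loss / n,
                                      val_loss = val_loss)
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

  history <- purrr::list_rbind(history[seq_len(epochs_run)])
  structure(list(par = best$par, config = config, mu = mu, sd = sdv,
                 history = history, best_epoch = best$epoch,
                 best_val_loss = best$loss, epochs_run = epochs_run),
            class = c("fatigue_lstm", "fatigue_model"))
}

#' Predicted fatigue probability from the LSTM
#'
#' @param object A `fatigue_lstm` model.
#' @param newdata A `labeled_window_set`.
#' @param ... Unused.
#' @return Numeric vector of class-1 probabilities.
#' @export
predict.fatigue_lstm <- function(object, newdata, ...) {
  X <- (.downsample_rows(newdata$windows, object$config$timesteps) -
          object$mu) / object$sd
  .lstm_forward(X, object$par, object$config$activation)$p
}

#' @export
predict_labels.fatigue_lstm <- function(model, newdata) {
  as.integer(predict(model, newdata) >= 0.5)
}

#' @export
print.fatigue_lstm <- function(x, ...) {
  cat(sprintf(
    "<fatigue_lstm> %d units, %d epochs run (best epoch %d, val loss %.4f)\n",
    x$config$hidden_units, x$epochs_run, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @method tidy fatigue_lstm
#' @export
tidy.fatigue_lstm <- function(x, ...) x$history

#' @method glance fatigue_lstm
#' @export
glance.fatigue_lstm <- function(x, ...) {
  tibble::tibble(hidden_units = x$config$hidden_units,
                 epochs_run = x$epochs_run, best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss,
                 stopped_early = x$epochs_run < x$config$max_epochs)
}
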