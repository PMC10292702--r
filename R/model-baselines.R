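# Classical baselines for fatigue recognition: an RBF-kernel SVM and a
# one-hidden-layer back-propagation network (BPNN) on the per-window
# (IEMG, RMS, MPF) feature triple, and a 1-D convolutional network on the
# raw window (implemented in model-cnn.R).

#' Train a baseline fatigue classifier
#'
#' * `"svm"`: RBF-kernel support vector machine ([e1071::svm()]) on the
#'   standardised (IEMG, RMS, MPF) feature triple per window.
#' * `"bpnn"`: one-hidden-layer back-propagation network ([nnet::nnet()])
#'   on the same features.
#' * `"cnn"`: 1-D convolutional network on the raw window (see
#'   [cnn_config()]).
#'
#' All baselines are deterministic given `seed`. Constant-feature training
#' input is rejected as degenerate.
#'
#' @param kind One of `"svm"`, `"bpnn"`, `"cnn"`.
#' @param train A `labeled_window_set` with both classes.
#' @param seed Integer seed.
#' @param ... Passed to the underlying fitter (e.g. `config` for the CNN,
#'   `size`/`decay` for the BPNN).
#' @return A model handle of class `fatigue_svm`, `fatigue_bpnn` or
#'   `fatigue_cnn` supporting [predict_labels()].
#' @export
train_baseline <- function(kind = c("svm", "bpnn", "cnn"), train, seed = 1L,
                           ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(train, "labeled_window_set"))
  if (length(unique(train$labels)) < 2) {
    rlang::abort("training set must contain both classes")
  }
  switch(kind,
         svm = .train_svm(train, seed, ...),
         bpnn = .train_bpnn(train, seed, ...),
         cnn = train_cnn(train, seed = seed, ...))
}

.feature_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (all(sdv == 0)) rlang::abort("degenerate constant-feature training set")
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

.scale_features <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

.train_svm <- function(train, seed, ...) {
  X <- .window_features(train)
  sc <- .feature_scaler(X)
  fit <- withr::with_seed(seed, {
    e1071::svm(.scale_features(X, sc), factor(train$labels, levels = c(0, 1)),
               kernel = "radial", ...)
  })
  structure(list(fit = fit, scaler = sc),
            class = c("fatigue_svm", "fatigue_model"))
}

#' @export
predict_labels.fatigue_svm <- function(model, newdata) {
  X <- .scale_features(.window_features(newdata), model$scaler)
  as.integer(as.character(stats::predict(model$fit, X)))
}

.train_bpnn <- function(train, seed, size = 10, decay = 1e-4, maxit = 300,
                        ...) {
  X <- .window_features(train)
  sc <- .feature_scaler(X)
  fit <- withr::with_seed(seed, {
    nnet::nnet(.scale_features(X, sc), train$labels, size = size,
               decay = decay, maxit = maxit, entropy = TRUE, trace = FALSE,
               ...)
  })
  structure(list(fit = fit, scaler = sc),
            class = c("fatigue_bpnn", "fatigue_model"))
}

#' @export
predict_labels.fatigue_bpnn <- function(model, newdata) {
  X <- .scale_features(.window_features(newdata), model$scaler)
  as.integer(stats::predict(model$fit, X) >= 0.5)
}
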