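# Dataset splitting and confusion-matrix evaluation for the fatigue
# classifiers. Metrics follow the standard binary definitions with the
# fatigued state (label 1) as the positive class, reported as percentages.

#' Split a labeled window set into training and evaluation partitions
#'
#' Disjoint, exhaustive partition with `|train| = round(train_fraction * n)`.
#' Stratified splitting keeps the class balance of the full set in both
#' partitions (per-class counts allocated by largest fractional remainder so
#' the total still matches). Deterministic given `seed`.
#'
#' @param dataset A `labeled_window_set` (see [generate_labeled_windows()]).
#' @param train_fraction Fraction assigned to training, in (0, 1);
#'   default 0.7 (a 7:3 split, e.g. 1400/600 from 2000 windows).
#' @param seed Integer seed.
#' @param stratified Stratify by label (default TRUE).
#' @return A list with `labeled_window_set` elements `train` and `eval`.
#' @export
split_dataset <- function(dataset, train_fraction = 0.7, seed = 1L,
                          stratified = TRUE) {
  stopifnot(inherits(dataset, "labeled_window_set"))
  n <- length(dataset$labels)
  if (n == 0) rlang::abort("empty dataset")
  if (train_fraction <= 0 || train_fraction >= 1) {
    rlang::abort("train_fraction must be in (0, 1)")
  }
  n_train <- round(train_fraction * n)
  if (stratified) {
    if (n < 2) rlang::abort("stratified split needs at least 2 windows")
    classes <- sort(unique(dataset$labels))
    raw <- vapply(classes, function(cl) sum(dataset$labels == cl) * train_fraction,
                  numeric(1))
    take <- floor(raw)
    rem <- n_train - sum(take)
    if (rem > 0) {
      ord <- order(raw - take, decreasing = TRUE)
      take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
    }
    train_idx <- withr::with_seed(seed, {
      unlist(lapply(seq_along(classes), function(i) {
        idx <- which(dataset$labels == classes[i])
        sample(idx, take[i])
      }))
    })
  } else {
    train_idx <- withr::with_seed(seed, sample.int(n, n_train))
  }
  train_idx <- sort(train_idx)
  list(train = .lws_subset(dataset, train_idx),
       eval = .lws_subset(dataset, setdiff(seq_len(n), train_idx)))
}

#' Confusion-matrix metrics for binary fatigue recognition
#'
#' Accuracy `(tp+tn)/total`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)` and precision `tp/(tp+fp)`, each expressed in percent.
#'
#' @param tp,fp,tn,fn Confusion-matrix counts (fatigued = positive class).
#' @return An object of class `eval_metrics`: list with the four counts and
#'   the four percentage metrics.
#' @export
#' @examples
#' m <- eval_metrics(tp = 47, fn = 3, tn = 45, fp = 5)
#' m$accuracy  # 92
eval_metrics <- function(tp, fp, tn, fn) {
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  if (tp + fn == 0 || tn + fp == 0) {
    rlang::abort("both classes must be present in the evaluation set")
  }
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = 100 * (tp + tn) / (tp + fp + tn + fn),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    precision = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  ), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "<eval_metrics> acc %.2f%% | sens %.2f%% | spec %.2f%% | prec %.2f%% (tp %d fp %d tn %d fn %d)\n",
    x$accuracy, x$sensitivity, x$specificity, x$precision,
    x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' @method tidy eval_metrics
#' @export
tidy.eval_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy", "sensitivity", "specificity", "precision"),
    value = c(x$accuracy, x$sensitivity, x$specificity, x$precision)
  )
}

#' @method glance eval_metrics
#' @export
glance.eval_metrics <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
                 accuracy = x$accuracy, sensitivity = x$sensitivity,
                 specificity = x$specificity, precision = x$precision)
}

#' Evaluate a trained fatigue model on a labeled window set
#'
#' Predicts labels for every window and derives the confusion-matrix
#' metrics.
#'
#' @param model A trained model handle from [train_lstm()] or
#'   [train_baseline()].
#' @param eval_set A `labeled_window_set` containing both classes.
#' @return An [eval_metrics()] object.
#' @export
evaluate_model <- function(model, eval_set) {
  stopifnot(inherits(eval_set, "labeled_window_set"))
  y <- eval_set$labels
  if (length(unique(y)) < 2) {
    rlang::abort("evaluation set must contain both classes")
  }
  pred <- predict_labels(model, eval_set)
  eval_metrics(tp = sum(pred == 1 & y == 1), fp = sum(pred == 1 & y == 0),
               tn = sum(pred == 0 & y == 0), fn = sum(pred == 0 & y == 1))
}

#' Predict fatigue labels for a window set
#'
#' Generic dispatching on the trained model type.
#'
#' @param model A trained model handle.
#' @param newdata A `labeled_window_set` (labels are ignored).
#' @return Integer vector of 0/1 predictions.
#' @export
predict_labels <- function(model, newdata) UseMethod("predict_labels")
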