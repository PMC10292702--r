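test_that("7:3 splitting yields the expected partition sizes", {
  ds <- generate_labeled_windows(10, window_len = 50, seed = 1)
  sp <- split_dataset(ds, 0.7, seed = 2)
  expect_equal(length(sp$train$labels), 14L)
  expect_equal(length(sp$eval$labels), 6L)
  # disjoint and exhaustive: window rows partition the original matrix
  expect_equal(nrow(sp$train$windows) + nrow(sp$eval$windows), 20L)
  # stratified: class balance preserved
  expect_equal(sum(sp$train$labels == 1), 7L)
  expect_equal(sum(sp$eval$labels == 1), 3L)
  # deterministic
  sp2 <- split_dataset(ds, 0.7, seed = 2)
  expect_identical(sp$train$labels, sp2$train$labels)
  expect_identical(sp$train$windows, sp2$train$windows)

  one <- generate_labeled_windows(1, window_len = 50, seed = 1)
  one$windows <- one$windows[1, , drop = FALSE]; one$labels <- one$labels[1]
  expect_error(split_dataset(one, 0.7), "at least 2")
})

test_that("confusion-matrix metrics implement their identities", {
  m <- eval_metrics(tp = 47, fn = 3, tn = 45, fp = 5)
  expect_equal(m$accuracy, 92.0)
  expect_equal(m$sensitivity, 94.0)
  expect_equal(m$specificity, 90.0)
  expect_equal(m$precision, 90.38, tolerance = 1e-3)
  # identities hold exactly, recomputed from the stored counts
  expect_equal(m$accuracy, 100 * (m$tp + m$tn) / (m$tp + m$fp + m$tn + m$fn))
  expect_equal(m$sensitivity, 100 * m$tp / (m$tp + m$fn))
  expect_equal(m$specificity, 100 * m$tn / (m$tn + m$fp))
  expect_equal(m$precision, 100 * m$tp / (m$tp + m$fp))

  perfect <- eval_metrics(tp = 10, fp = 0, tn = 10, fn = 0)
  expect_equal(tidy(perfect)$value, rep(100, 4))

  all_pos <- eval_metrics(tp = 10, fp = 10, tn = 0, fn = 0)
  expect_equal(all_pos$sensitivity, 100)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$accuracy, 50)

  expect_error(eval_metrics(tp = 5, fp = 0, tn = 0, fn = 0), "both classes")
})

test_that("SVM separates hand-placed points and degenerate input is rejected", {
  toy <- sinusoid_window_set(amps0 = c(0.1, 0.2), amps1 = c(5, 6))
  fit <- train_baseline("svm", toy, seed = 1)
  expect_equal(predict_labels(fit, toy), toy$labels)

  flat <- toy
  flat$windows <- matrix(1, 4, 200)
  expect_error(train_baseline("svm", flat, seed = 1))
  expect_error(train_baseline("forest", toy, seed = 1))
})

test_that("classical baselines learn an easy amplitude discrimination", {
  ds <- generate_labeled_windows(40, window_len = 500, seed = 5)
  sp <- split_dataset(ds, 0.7, seed = 6)
  for (kind in c("svm", "bpnn")) {
    fit <- train_baseline(kind, sp$train, seed = 7)
    expect_gte(evaluate_model(fit, sp$eval)$accuracy, 90)
  }
})

test_that("LSTM training is deterministic and honors early stopping", {
  ds <- generate_labeled_windows(40, window_len = 250, seed = 15)
  sp <- split_dataset(ds, 0.7, seed = 16)
  cfg <- lstm_config(hidden_units = 16L, timesteps = 50L, batch_size = 20L,
                     max_epochs = 15L, early_stopping_patience = 3L,
                     seed = 17)
  m1 <- train_lstm(sp$train, cfg)
  m2 <- train_lstm(sp$train, cfg)
  expect_identical(predict(m1, sp$eval), predict(m2, sp$eval))

  expect_lte(m1$epochs_run, cfg$max_epochs)
  hist <- tidy(m1)
  expect_equal(nrow(hist), m1$epochs_run)
  # restored checkpoint is at least as good as the final epoch
  expect_lte(m1$best_val_loss, hist$val_loss[m1$epochs_run])
  expect_gte(evaluate_model(m1, sp$eval)$accuracy, 90)

  single <- .lws_subset(ds, which(ds$labels == 1))
  expect_error(train_lstm(single, cfg), "both classes")
})

test_that("accuracy does not degrade as class separation grows (SVM, 5 seeds)", {
  gaps <- c(0.1, 0.75, 1.5)
  med_acc <- vapply(gaps, function(gap) {
    accs <- vapply(1:5, function(s) {
      ds <- generate_labeled_windows(
        30, window_len = 400,
        class_profiles = list(
          fatigue_profile(rms_start = 0.5, rms_end = 0.5),
          fatigue_profile(rms_start = 0.5 + gap, rms_end = 0.5 + gap)),
        noise = noise_spec(white_sigma = 0.3, powerline_amp = 0,
                           baseline_amp = 0),
        seed = 100 + s)
      sp <- split_dataset(ds, 0.7, seed = s)
      evaluate_model(train_baseline("svm", sp$train, seed = s), sp$eval)$accuracy
    }, numeric(1))
    stats::median(accs)
  }, numeric(1))
  expect_true(all(diff(med_acc) >= 0))
})

test_that("label permutation drives accuracy to chance", {
  ds <- generate_labeled_windows(50, window_len = 400, seed = 31)
  accs <- vapply(1:5, function(s) {
    shuffled <- ds
    shuffled$labels <- withr::with_seed(s, sample(ds$labels))
    sp <- split_dataset(shuffled, 0.7, seed = s)
    evaluate_model(train_baseline("svm", sp$train, seed = s), sp$eval)$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 40)
  expect_lte(mean(accs), 60)
})
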