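test_that("confusion counts follow the positive-class-1 convention", {
  y_true <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  y_pred <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  cc <- confusion_counts(y_true, y_pred)
  expect_equal(cc$TP, 3)
  expect_equal(cc$FN, 2)
  expect_equal(cc$TN, 4)
  expect_equal(cc$FP, 1)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 10)
  perfect <- confusion_counts(y_true, y_true)
  expect_equal(perfect$FP + perfect$FN, 0)
  expect_error(confusion_counts(c(1, 0), c(1)), "equal length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "\\{0, 1\\}")
})

test_that("metrics reproduce the worked example and degenerate cases", {
  m <- compute_metrics(structure(list(TP = 3, FP = 1, TN = 4, FN = 2),
                                 class = "confusion_counts"))
  expect_equal(m$accuracy, 0.70)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.60)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-10)  # 0.66667
  perfect <- compute_metrics(structure(list(TP = 5, FP = 0, TN = 5, FN = 0),
                                       class = "confusion_counts"))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # no positive predictions and no positives: precision absent, not zero
  deg <- compute_metrics(structure(list(TP = 0, FP = 0, TN = 3, FN = 2),
                                   class = "confusion_counts"))
  expect_true(is.na(deg$precision))
  expect_match(deg$undefined[["precision"]], "undefined")
  expect_equal(deg$accuracy, 0.6)
  expect_error(compute_metrics(structure(list(TP = 0, FP = 0, TN = 0, FN = 0),
                                         class = "confusion_counts")),
               "zero")
})

test_that("metrics match an independent implementation on random tables", {
  # independent oracle: direct formulas on randomly drawn counts
  set.seed(1234)
  for (trial in 1:1000) {
    cts <- as.list(stats::rmultinom(1, size = sample(1:200, 1),
                                    prob = runif(4, 0.05, 1))[, 1])
    names(cts) <- c("TP", "FP", "TN", "FN")
    got <- compute_metrics(structure(cts, class = "confusion_counts"))
    total <- with(cts, TP + FP + TN + FN)
    if (total == 0) next
    expect_equal(got$accuracy, (cts$TP + cts$TN) / total)
    if (cts$TP + cts$FP > 0)
      expect_equal(got$precision, cts$TP / (cts$TP + cts$FP))
    else expect_true(is.na(got$precision))
    if (cts$TP + cts$FN > 0)
      expect_equal(got$recall, cts$TP / (cts$TP + cts$FN))
    else expect_true(is.na(got$recall))
    if (!is.na(got$precision) && !is.na(got$recall) &&
        got$precision + got$recall > 0) {
      expect_equal(got$f1, 2 * got$precision * got$recall /
                             (got$precision + got$recall))
      expect_gte(got$f1 + 1e-12, min(got$precision, got$recall))
      expect_lte(got$f1 - 1e-12, max(got$precision, got$recall))
    }
  }
})

test_that("macro averaging and label-swap symmetry behave as expected", {
  set.seed(31)
  y_true <- sample(0:1, 60, replace = TRUE)
  y_pred <- ifelse(runif(60) < 0.8, y_true, 1 - y_true)
  per <- per_class_metrics(y_true, y_pred)
  mac <- aggregate_metrics(per)
  expect_equal(mac$precision, (per[["1"]]$precision + per[["0"]]$precision) / 2)
  expect_equal(mac$accuracy, per[["1"]]$accuracy)
  # swapping labels swaps per-class reports, macro unchanged
  per_sw <- per_class_metrics(1 - y_true, 1 - y_pred)
  mac_sw <- aggregate_metrics(per_sw)
  expect_equal(per_sw[["1"]]$precision, per[["0"]]$precision)
  expect_equal(per_sw[["0"]]$recall, per[["1"]]$recall)
  expect_equal(mac_sw$precision, mac$precision)
  expect_equal(mac_sw$accuracy, mac$accuracy)
  expect_error(aggregate_metrics(per["1"]), "both classes")
  # classes with precision 1.0 and 0.5 average to 0.75
  a <- structure(list(accuracy = 0.8, precision = 1, recall = 0.6, f1 = 0.75,
                      undefined = character()), class = "metrics_report")
  b <- structure(list(accuracy = 0.8, precision = 0.5, recall = 0.9, f1 = 0.64,
                      undefined = character()), class = "metrics_report")
  expect_equal(aggregate_metrics(list(a, b))$precision, 0.75)
})

test_that("training validates inputs and epochs = 0 keeps the initialization", {
  X <- matrix(rnorm(40 * 20), 40, 20)
  y <- rep(0:1, 20)
  expect_error(train_classifier(build_lstm(input_len = 20), X, c(y[-1], 2)),
               "\\{0, 1\\}")
  expect_error(train_classifier(build_lstm(input_len = 25), X, y),
               "does not match")
  m0 <- train_classifier(build_lstm(input_len = 20), X, y,
                         train_config(epochs = 0, seed = 4))
  expect_true(m0$trained)
  expect_equal(nrow(m0$log), 0L)
  # balanced accuracy of an untrained model hovers around chance
  set.seed(90)
  Xbig <- matrix(rnorm(400 * 20), 400, 20)
  ybig <- rep(0:1, 200)
  acc <- mean(predict(m0, Xbig) == ybig)
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)
})

test_that("a separable synthetic task is learned to perfect training accuracy", {
  # 200 thawed spectra, no replicate noise, large class offset
  ds <- small_synth(seed = 2, n_samples = 2, n_rep = 50, end_nm = 500,
                    noise_sd = 0, instrument_noise_sd = 0,
                    sample_effect_sd = 0.002,
                    class_offset_thawed = 0.08, class_offset_from_nm = 400)
  th <- subset_by_state(ds, "thawed")
  expect_equal(n_spectra(th), 200L)
  std <- fit_standardizer(th)
  feats <- apply_standardizer(th$reflectance, std)
  m <- build_cnn1d(input_len = ncol(feats))
  m <- train_classifier(m, feats, th$meta$product_class,
                        train_config(epochs = 12, seed = 6))
  expect_equal(tail(m$log$accuracy, 1), 1.0)
  expect_equal(predict(m, feats), th$meta$product_class)
})
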