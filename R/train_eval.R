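#' Training configuration
#'
#' Defaults follow the study regime: mini-batches of 32 spectra, the Adam
#' optimizer, learning rate 0.001. The epoch budget is not part of the
#' published regime; the package default is 100.
#'
#' @param batch_size Spectra per optimization step.
#' @param learning_rate Adam step size.
#' @param epochs Full passes over the training set (an upper bound when
#'   `converge_stop` is enabled).
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param converge_stop If `TRUE`, stop early once the model has fit the
#'   training set (accuracy 1 and loss below `converge_loss`) for
#'   `converge_patience` consecutive epochs. Off by default; no
#'   validation data is consulted.
#' @param converge_patience Consecutive converged epochs required.
#' @param converge_loss Training-loss threshold for convergence.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 32, learning_rate = 0.001,
                         epochs = 100, seed = 1, converge_stop = FALSE,
                         converge_patience = 8, converge_loss = 0.01) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 converge_stop = isTRUE(converge_stop),
                 converge_patience = as.integer(converge_patience),
                 converge_loss = converge_loss),
            class = "train_config")
}

as_feature_matrix <- function(features) {
  if (inherits(features, "spectra_features")) features$x
  else if (inherits(features, "spectra_dataset")) features$reflectance
  else as.matrix(features)
}

model_input <- function(model, features) {
  X <- as_feature_matrix(features)
  if (ncol(X) != model$input_len)
    stop(sprintf("feature width %d does not match model input length %d",
                 ncol(X), model$input_len))
  array(X, c(nrow(X), ncol(X), 1L))
}

#' Train a classifier with mini-batch Adam and cross-entropy loss
#'
#' Fully reproducible given `cfg$seed`: parameter initialization, epoch
#' shuffling and dropout masks all draw from one seeded stream. With
#' `epochs = 0` the returned model carries its freshly initialized
#' parameters.
#'
#' @param model An untrained `spectral_model` from one of the builders.
#' @param features Training features: a `spectra_features` table,
#'   `spectra_dataset` or numeric matrix.
#' @param labels Integer labels in \{0, 1\}; defaults to the product class
#'   carried by `features`.
#' @param cfg A [train_config()].
#' @return The trained `spectral_model`, with a per-epoch `log`
#'   data.frame (`epoch`, `loss`, `accuracy`).
#' @export
train_classifier <- function(model, features, labels = NULL,
                             cfg = train_config()) {
  if (is.null(labels) && inherits(features, "spectra_features"))
    labels <- feature_labels(features)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must all lie in {0, 1}")
  x <- model_input(model, features)
  n <- dim(x)[1]
  if (length(labels) != n) stop("label count does not match feature rows")
  set.seed(cfg$seed)
  layers <- nn_init(model$layers)
  state <- adam_init(layers)
  log <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  step <- 0L
  converged_for <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    tot_loss <- 0; tot_correct <- 0L
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- x[idx, , , drop = FALSE]
      yb <- labels[idx]
      fw <- nn_forward(layers, xb, training = TRUE)
      layers <- fw$layers
      ce <- softmax_xent(fw$out, yb)
      grads <- nn_backward(layers, fw$caches, ce$dlogits)
      step <- step + 1L
      upd <- adam_step(layers, grads, state, cfg$learning_rate, step)
      layers <- upd$layers; state <- upd$state
      tot_loss <- tot_loss + ce$loss * length(idx)
      tot_correct <- tot_correct + sum(max.col(ce$prob) - 1L == yb)
    }
    ep_loss <- tot_loss / n
    ep_acc <- tot_correct / n
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss,
                                 accuracy = ep_acc))
    if (isTRUE(cfg$converge_stop)) {
      converged_for <- if (ep_acc >= 1 && ep_loss < cfg$converge_loss)
        converged_for + 1L else 0L
      if (converged_for >= cfg$converge_patience) break
    }
  }
  model$layers <- layers
  model$trained <- TRUE
  model$log <- log
  model
}

#' Predict class labels for new spectra
#'
#' Inference is deterministic: dropout is disabled and batch
#' normalization uses its running statistics.
#'
#' @param object A trained `spectral_model`.
#' @param features Feature table, dataset or matrix matching the model
#'   input width.
#' @param type `"class"` for 0/1 labels or `"prob"` for class
#'   probabilities.
#' @param ... Unused.
#' @return Integer label vector, or an `n x 2` probability matrix.
#' @export
predict.spectral_model <- function(object, features, type = c("class", "prob"),
                                   ...) {
  type <- match.arg(type)
  if (!object$trained) stop("model has no parameters; train it first")
  x <- model_input(object, features)
  fw <- nn_forward(object$layers, x, training = FALSE)
  p <- softmax_xent(fw$out, integer(dim(x)[1]))$prob
  if (type == "prob") p else max.col(p, ties.method = "first") - 1L
}

# ---- metrics ----

#' Confusion counts for binary labels
#'
#' Positive class is label 1 (Pennette72): TP = true 1 predicted 1,
#' FP = true 0 predicted 1, TN = true 0 predicted 0, FN = true 1
#' predicted 0.
#'
#' @param y_true,y_pred Equal-length vectors of labels in \{0, 1\}.
#' @param positive The label treated as positive (default 1).
#' @return Object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred, positive = 1) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (!all(c(y_true, y_pred) %in% c(0, 1)))
    stop("labels must all lie in {0, 1}")
  pos_t <- y_true == positive
  pos_p <- y_pred == positive
  structure(list(TP = sum(pos_t & pos_p), FP = sum(!pos_t & pos_p),
                 TN = sum(!pos_t & !pos_p), FN = sum(pos_t & !pos_p)),
            class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+FP+TN+FN)`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `f1 = 2*precision*recall/(precision+recall)`.
#' A metric whose denominator is zero is reported as `NA` with an entry
#' in the `undefined` field naming the reason, never as 0.
#'
#' @param c A [confusion_counts()] object.
#' @return Object of class `metrics_report` with fields `accuracy`,
#'   `precision`, `recall`, `f1` (proportions in \[0, 1\]) and
#'   `undefined` (named character vector of reasons, possibly empty).
#' @export
compute_metrics <- function(c) {
  total <- c$TP + c$FP + c$TN + c$FN
  if (total == 0) stop("all confusion counts are zero")
  undefined <- character()
  ratio <- function(num, den, what) {
    if (den == 0) {
      undefined[[what]] <<- sprintf("%s undefined: denominator is zero", what)
      NA_real_
    } else num / den
  }
  precision <- ratio(c$TP, c$TP + c$FP, "precision")
  recall <- ratio(c$TP, c$TP + c$FN, "recall")
  f1 <- if (is.na(precision) || is.na(recall)) {
    undefined[["f1"]] <- "f1 undefined: precision or recall undefined"
    NA_real_
  } else ratio(2 * precision * recall, precision + recall, "f1")
  structure(list(accuracy = (c$TP + c$TN) / total, precision = precision,
                 recall = recall, f1 = f1, undefined = undefined),
            class = "metrics_report")
}

#' Per-class metrics reports
#' @param y_true,y_pred Label vectors in \{0, 1\}.
#' @return Named list of `metrics_report` objects for class `"1"` and
#'   class `"0"` (each treated as positive in turn).
#' @export
per_class_metrics <- function(y_true, y_pred) {
  list(`1` = compute_metrics(confusion_counts(y_true, y_pred, positive = 1)),
       `0` = compute_metrics(confusion_counts(y_true, y_pred, positive = 0)))
}

#' Macro-average two per-class reports
#'
#' Unweighted mean of precision, recall and F1 over the two classes;
#' accuracy is class-symmetric and passes through unchanged.
#'
#' @param per_class List with `metrics_report` entries for both classes
#'   (as returned by [per_class_metrics()]).
#' @return A `metrics_report` with macro-averaged values.
#' @export
aggregate_metrics <- function(per_class) {
  if (length(per_class) < 2 || any(vapply(per_class, is.null, logical(1))))
    stop("reports for both classes are required")
  avg <- function(field) mean(vapply(per_class, `[[`, numeric(1), field))
  structure(list(accuracy = per_class[[1]]$accuracy,
                 precision = avg("precision"), recall = avg("recall"),
                 f1 = avg("f1"),
                 undefined = unlist(lapply(per_class, `[[`, "undefined"))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  if (length(x$undefined)) cat("  (", paste(x$undefined, collapse = "; "), ")\n")
  invisible(x)
}

# ---- classical baselines (library implementations, default settings) ----

fit_predict_baseline <- function(kind, xtr, ytr, xte) {
  ytr_f <- factor(ytr, levels = c(0, 1))
  pred <- switch(kind,
    knn = class::knn(xtr, xte, cl = ytr_f, k = 1),
    dt = {
      df_tr <- data.frame(y = ytr_f, xtr)
      df_te <- data.frame(xte); names(df_te) <- names(df_tr)[-1]
      fit <- rpart::rpart(y ~ ., data = df_tr, method = "class")
      predict(fit, df_te, type = "class")
    },
    nb = {
      fit <- e1071::naiveBayes(xtr, ytr_f)
      predict(fit, xte)
    },
    svm = {
      fit <- e1071::svm(xtr, ytr_f)
      predict(fit, xte)
    },
    stop("unknown baseline kind: ", kind)
  )
  as.integer(as.character(pred))
}

DEEP_KINDS <- c("cnn", "lstm", "cnn_lstm", "alexnet1d", "alexnet_lstm")
BASELINE_KINDS <- c("knn", "dt", "nb", "svm")

apply_processing <- function(train, test, processing, pca_k = 100) {
  switch(processing,
    raw = list(
      train = structure(list(x = train$reflectance, meta = train$meta),
                        class = "spectra_features"),
      test = structure(list(x = test$reflectance, meta = test$meta),
                       class = "spectra_features")),
    standardization = {
      std <- fit_standardizer(train)
      list(train = structure(list(x = apply_standardizer(train$reflectance, std),
                                  meta = train$meta), class = "spectra_features"),
           test = structure(list(x = apply_standardizer(test$reflectance, std),
                                 meta = test$meta), class = "spectra_features"),
           standardizer = std)
    },
    pca = {
      std <- fit_standardizer(train)
      tr_s <- apply_standardizer(train, std)
      te_s <- apply_standardizer(test, std)
      pca <- fit_pca(tr_s, k = pca_k)
      list(train = apply_pca(tr_s, pca), test = apply_pca(te_s, pca),
           standardizer = std, pca = pca)
    },
    stop("unknown processing: ", processing)
  )
}

#' Run the model x preprocessing x physical-state benchmark grid
#'
#' For every combination of physical state, preprocessing
#' (`raw`, `standardization`, `pca`) and model kind: subset the dataset
#' to the state, split 7:3 with the systematic splitter, fit the
#' preprocessing on the training side only, train or fit the model, and
#' evaluate accuracy plus macro-averaged precision/recall/F1 on the test
#' side. Deep models are retrained once per entry of `seeds`; classical
#' baselines (KNN k=1, rpart decision tree, naive Bayes, radial SVM, all
#' library defaults) are deterministic and run once per seed for grid
#' symmetry.
#'
#' @param ds A `spectra_dataset` containing both physical states (or a
#'   subset of `states`).
#' @param models Character vector of model kinds from
#'   `c("knn","dt","nb","svm","cnn","lstm","cnn_lstm","alexnet1d","alexnet_lstm")`.
#' @param processings Subset of `c("raw", "standardization", "pca")`.
#' @param cfg A [train_config()] for the deep models.
#' @param states Physical states to cover.
#' @param seeds Integer vector of training seeds; defaults to `cfg$seed`.
#' @param pca_k Retained components for the `pca` processing.
#' @return `data.frame` with one row per (state, processing, model, seed):
#'   columns `state`, `processing`, `model`, `seed`, `accuracy`,
#'   `precision`, `recall`, `f1`, `n_train`, `n_test`.
#' @export
run_benchmark <- function(ds, models = c(BASELINE_KINDS, "cnn", "lstm", "cnn_lstm"),
                          processings = c("raw", "standardization", "pca"),
                          cfg = train_config(), states = PHYSICAL_STATES,
                          seeds = NULL, pca_k = 100) {
  unknown <- setdiff(models, c(DEEP_KINDS, BASELINE_KINDS))
  if (length(unknown)) stop("unknown model kind: ", paste(unknown, collapse = ", "))
  if (is.null(seeds)) seeds <- cfg$seed
  rows <- list()
  for (state in states) {
    sub <- subset_by_state(ds, state)
    parts <- systematic_split(sub, split_spec())
    for (processing in processings) {
      proc <- apply_processing(parts$train, parts$test, processing, pca_k)
      ytr <- feature_labels(proc$train); yte <- feature_labels(proc$test)
      for (kind in models) {
        for (seed in seeds) {
          pred <- if (kind %in% DEEP_KINDS) {
            cfg_s <- cfg; cfg_s$seed <- as.integer(seed)
            mdl <- build_model(kind, ncol(proc$train$x))
            mdl <- train_classifier(mdl, proc$train, ytr, cfg_s)
            predict(mdl, proc$test)
          } else {
            set.seed(seed)
            fit_predict_baseline(kind, proc$train$x, ytr, proc$test$x)
          }
          rep <- aggregate_metrics(per_class_metrics(yte, pred))
          rows[[length(rows) + 1L]] <- data.frame(
            state = state, processing = processing, model = kind,
            seed = seed, accuracy = rep$accuracy, precision = rep$precision,
            recall = rep$recall, f1 = rep$f1,
            n_train = length(ytr), n_test = length(yte))
        }
      }
    }
  }
  do.call(rbind, rows)
}
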