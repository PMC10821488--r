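# Model selection, training, evaluation and feature importance. Five
# classifier families (logistic regression, SVM, random forest, naive
# Bayes, gradient-boosted trees) are compared by mean F1 over stratified
# 10-fold cross-validation on the training set; the winner is refit on the
# whole training set and scored on the held-out test set. All families run
# at library defaults; boosted trees use nrounds = 100, eta = 0.3,
# max_depth = 6.

CLASSIFIER_FAMILIES <- c("logistic", "svm", "random_forest", "naive_bayes",
                         "xgboost")

#' Confusion counts from true and predicted binary labels
#'
#' @param truth,pred Integer/logical vectors of 0/1 labels (1 = active =
#'   positive class by default).
#' @param positive Which label is the positive class (default 1).
#' @return Named vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred, positive = 1L) {
  truth <- as.integer(truth == positive)
  pred <- as.integer(pred == positive)
  c(TP = sum(truth == 1L & pred == 1L),
    TN = sum(truth == 0L & pred == 0L),
    FP = sum(truth == 0L & pred == 1L),
    FN = sum(truth == 1L & pred == 0L))
}

#' Classification metrics from confusion counts
#'
#' `accuracy = (TP+TN)/total`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `F1 = 2 P R / (P + R)`. A ratio with zero
#' denominator is defined as 0.
#'
#' @param counts Named vector or list with `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
evaluate_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  total <- tp + tn + fp + fn
  if (total <= 0) stop("no evaluated cases")
  safe_div <- function(a, b) if (b > 0) a / b else 0
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  c(accuracy = (tp + tn) / total,
    precision = precision,
    recall = recall,
    f1 = safe_div(2 * precision * recall, precision + recall))
}

# ---- family fit/predict wrappers ------------------------------------------

#' @noRd
fit_family_ <- function(family, X, y, seed = 1L) {
  X <- as.matrix(X)
  switch(family,
    logistic = {
      df <- as.data.frame(X); df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    svm = e1071::svm(X, factor(y, levels = c(0, 1)),
                     type = "C-classification"),
    random_forest = local_seed_(seed,
      randomForest::randomForest(X, factor(y, levels = c(0, 1)))),
    naive_bayes = e1071::naiveBayes(X, factor(y, levels = c(0, 1))),
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 6,
                      eta = 0.3, nthread = 1, seed = seed),
        data = dtrain, nrounds = 100, verbose = 0)
    },
    stop("unknown classifier family: ", family)
  )
}

#' @noRd
predict_family_ <- function(family, fit, X) {
  X <- as.matrix(X)
  switch(family,
    logistic = {
      p <- suppressWarnings(
        stats::predict(fit, newdata = as.data.frame(X), type = "response"))
      as.integer(p > 0.5)
    },
    svm = as.integer(as.character(stats::predict(fit, X))),
    random_forest = as.integer(as.character(stats::predict(fit, X))),
    naive_bayes = as.integer(as.character(stats::predict(fit, as.data.frame(X)))),
    xgboost = as.integer(stats::predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)) > 0.5)
  )
}

# ---- splitting and cross-validation ---------------------------------------

#' Stratified train/test split
#'
#' Strata are the label x diagnosis cells. The test set receives
#' `test_fraction` of each stratum, rounded to nearest and at least 1 row;
#' assignment is deterministic given `seed` and does not disturb the
#' caller's RNG state.
#'
#' @param fm A `feature_matrix`.
#' @param test_fraction Fraction of each stratum held out (default 0.2).
#' @param seed Integer seed.
#' @return List with `train` and `test` feature matrices.
#' @export
stratified_split <- function(fm, test_fraction = 0.2, seed = 1L) {
  strata <- interaction(fm$y, fm$diagnosis, drop = TRUE)
  sizes <- table(strata)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    stop("stratum too small to split (need >= 2 rows): ",
         paste(small, collapse = ", "))
  }
  test_idx <- local_seed_(seed, {
    unlist(lapply(levels(strata), function(s) {
      idx <- which(strata == s)
      n_test <- max(1L, round(test_fraction * length(idx)))
      sample(idx, n_test)
    }))
  })
  keep_attrs <- function(d) {
    structure(d, variant = attr(fm, "variant"),
              predictors = attr(fm, "predictors"),
              class = class(fm))
  }
  list(train = keep_attrs(fm[-test_idx, , drop = FALSE]),
       test = keep_attrs(fm[test_idx, , drop = FALSE]))
}

#' @noRd
stratified_folds_ <- function(y, k, seed) {
  folds <- integer(length(y))
  local_seed_(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated model selection over five classifier families
#'
#' Each family is scored by mean F1 over stratified 10-fold
#' cross-validation on the training data (folds stratified by label, the
#' positive class being active). The best family is refit on the entire
#' training set.
#'
#' @param train Training `feature_matrix`.
#' @param predictors Character vector of predictor columns to use
#'   (typically the output of [prune_correlated]).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fits.
#' @param k Number of CV folds (default 10).
#' @param families Families to compare (default all five).
#' @return List with `family` (winner), `fit`, `cv_f1` (named mean scores)
#'   and `predictors`.
#' @export
select_model <- function(train, predictors = attr(train, "predictors"),
                         seed = 1L, k = 10L,
                         families = CLASSIFIER_FAMILIES) {
  y <- train$y
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class; cannot fit a classifier")
  }
  X <- as.matrix(train[, predictors, drop = FALSE])
  folds <- stratified_folds_(y, k, child_seed_(seed, "folds"))
  cv_f1 <- vapply(families, function(fam) {
    scores <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      fit <- fit_family_(fam, X[tr, , drop = FALSE], y[tr],
                         seed = child_seed_(seed, paste0(fam, f)))
      pred <- predict_family_(fam, fit, X[!tr, , drop = FALSE])
      unname(evaluate_metrics(confusion_counts(y[!tr], pred))["f1"])
    }, 0)
    mean(scores, na.rm = TRUE)
  }, 0)
  best <- families[which.max(cv_f1)]
  fit <- fit_family_(best, X, y, seed = child_seed_(seed, best))
  list(family = best, fit = fit, cv_f1 = cv_f1, predictors = predictors)
}

#' Predict active/passive labels with a selected model
#'
#' @param model Output of [select_model].
#' @param fm A `feature_matrix` of segments to classify.
#' @return Integer vector of 0/1 predictions.
#' @export
predict_segments <- function(model, fm) {
  predict_family_(model$family, model$fit,
                  as.matrix(fm[, model$predictors, drop = FALSE]))
}

# ---- benchmark -------------------------------------------------------------

#' Repeated-split benchmark of the propulsion-type classifier
#'
#' Correlated predictors are pruned once on the full matrix; then for each
#' of `n_splits` random stratified 80/20 splits the five families are
#' compared by 10-fold CV on the training part, the winner is refit and
#' scored on the held-out part. Metrics are averaged arithmetically over
#' splits.
#'
#' @param fm A `feature_matrix`.
#' @param n_splits Number of random splits (default 25).
#' @param seed Root seed; each split derives its own substreams.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param prune_threshold Correlation-pruning threshold (default 0.7).
#' @param families Families to compare.
#' @return An `evaluation_report`: list with `per_split` (data frame of
#'   split, chosen family, accuracy/precision/recall/f1), `means`,
#'   `variant`, `n_splits`, `retained` predictors.
#' @export
run_benchmark <- function(fm, n_splits = 25L, seed = 1L, test_fraction = 0.2,
                          prune_threshold = 0.7,
                          families = CLASSIFIER_FAMILIES) {
  retained <- prune_correlated(fm, prune_threshold)
  rows <- vector("list", n_splits)
  for (i in seq_len(n_splits)) {
    sp <- stratified_split(fm, test_fraction, child_seed_(seed, paste0("split", i)))
    model <- select_model(sp$train, retained,
                          seed = child_seed_(seed, paste0("select", i)),
                          families = families)
    pred <- predict_segments(model, sp$test)
    m <- evaluate_metrics(confusion_counts(sp$test$y, pred))
    rows[[i]] <- data.frame(split = i, family = model$family,
                            accuracy = m["accuracy"], precision = m["precision"],
                            recall = m["recall"], f1 = m["f1"],
                            row.names = NULL)
  }
  per_split <- do.call(rbind, rows)
  structure(
    list(per_split = per_split,
         means = colMeans(per_split[, c("accuracy", "precision", "recall", "f1")]),
         variant = attr(fm, "variant"),
         n_splits = n_splits,
         retained = retained,
         seed = seed),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Propulsion-type benchmark (%s, %d splits, %d predictors retained)\n",
              if (is.null(x$variant)) "?" else x$variant,
              x$n_splits, length(x$retained)))
  m <- x$means
  cat(sprintf("  %-10s %-10s %-10s %-10s\n", "Accuracy", "Precision", "Recall", "F1"))
  cat(sprintf("  %-10.3f %-10.3f %-10.3f %-10.3f\n",
              m["accuracy"], m["precision"], m["recall"], m["f1"]))
  fam <- sort(table(x$per_split$family), decreasing = TRUE)
  cat("  chosen families: ",
      paste(sprintf("%s (%d)", names(fam), fam), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Gain-based feature importance of the final model
#'
#' Refits a gradient-boosted tree model (the benchmark's usual winner) on
#' all rows and reports per-predictor gain importance normalised to sum 1,
#' with the sign of each predictor's Pearson correlation with the target
#' (1 = active). Predictors unused by the trees score 0.
#'
#' @param fm A `feature_matrix` with both classes present.
#' @param predictors Predictor columns (default: pruned set).
#' @param seed Integer seed.
#' @return Data frame `predictor`, `importance`, `correlation_sign`,
#'   sorted by decreasing importance.
#' @export
feature_importance <- function(fm, predictors = NULL, seed = 1L) {
  if (length(unique(fm$y)) < 2L) stop("need both classes for importance")
  if (is.null(predictors)) predictors <- prune_correlated(fm)
  X <- as.matrix(fm[, predictors, drop = FALSE])
  fit <- fit_family_("xgboost", X, fm$y, seed = seed)
  imp <- xgboost::xgb.importance(model = fit)
  score <- stats::setNames(rep(0, length(predictors)), predictors)
  score[imp$Feature] <- imp$Gain
  score <- score / sum(score)
  sgn <- vapply(predictors, function(p) {
    r <- suppressWarnings(stats::cor(fm[[p]], fm$y))
    if (is.na(r) || r >= 0) "+" else "-"
  }, "")
  out <- data.frame(predictor = predictors, importance = unname(score),
                    correlation_sign = unname(sgn))
  out[order(-out$importance), , drop = FALSE]
}
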