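# helpers to fabricate small feature matrices with known structure
mk_fm <- function(X, y, diagnosis = NULL) {
  fm <- as.data.frame(X)
  fm$y <- y
  fm$diagnosis <- diagnosis %||%
    rep(c("stroke", "amputation"), length.out = length(y))
  fm$participant_id <- "P0"
  structure(fm, variant = "S1", predictors = colnames(X),
            class = c("feature_matrix", "data.frame"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("metrics match the closed-form confusion-matrix cases", {
  m <- evaluate_metrics(c(TP = 9, TN = 8, FP = 1, FN = 2))
  expect_equal(unname(m["accuracy"]), 0.85, tolerance = 1e-9)
  expect_equal(unname(m["precision"]), 0.9, tolerance = 1e-9)
  expect_equal(unname(m["recall"]), 9 / 11, tolerance = 1e-9)
  expect_equal(unname(m["f1"]), 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11),
               tolerance = 1e-9)
  perfect <- evaluate_metrics(c(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_true(all(perfect == 1))
  # zero-denominator convention
  degenerate <- evaluate_metrics(c(TP = 0, TN = 10, FP = 0, FN = 2))
  expect_equal(unname(degenerate["precision"]), 0)
  expect_equal(unname(degenerate["f1"]), 0)
})

test_that("confusion counts agree with an independent re-count", {
  set.seed(2)
  truth <- rbinom(200, 1, 0.55)
  pred <- ifelse(runif(200) < 0.8, truth, 1L - truth)
  cc <- confusion_counts(truth, pred)
  expect_equal(sum(cc), 200)
  expect_equal(unname(cc["TP"]), sum(truth & pred))
  expect_equal(unname(cc["FN"]), sum(truth == 1 & pred == 0))
  m <- evaluate_metrics(cc)
  expect_equal(unname(m["accuracy"]), mean(truth == pred))
})

test_that("stratified split takes the rounded share of every stratum, deterministically", {
  sizes <- c(40, 30, 20, 10)
  y <- rep(c(1, 1, 0, 0), sizes)
  diag <- rep(c("stroke", "amputation", "stroke", "amputation"), sizes)
  fm <- mk_fm(matrix(rnorm(100 * 3), 100, 3,
                     dimnames = list(NULL, c("a", "b", "c"))), y, diag)
  sp <- stratified_split(fm, 0.2, seed = 9)
  tab <- table(sp$test$y, sp$test$diagnosis)
  expect_equal(sort(as.vector(tab)), c(2, 4, 6, 8))
  sp2 <- stratified_split(fm, 0.2, seed = 9)
  expect_identical(rownames(sp$test), rownames(sp2$test))
  expect_error(stratified_split(fm[1:41, ], 0.2, 1), "stratum")
})

test_that("per-stratum test share stays within one row of nominal on random cohorts", {
  set.seed(33)
  for (rep in 1:200) {
    sizes <- sample(2:40, 4, replace = TRUE)
    y <- rep(c(1, 1, 0, 0), sizes)
    diag <- rep(c("stroke", "amputation", "stroke", "amputation"), sizes)
    n <- sum(sizes)
    fm <- mk_fm(matrix(rnorm(n), n, 1, dimnames = list(NULL, "a")), y, diag)
    sp <- stratified_split(fm, 0.2, seed = rep)
    got <- table(factor(sp$test$y, c(0, 1)), factor(sp$test$diagnosis,
                                                    c("stroke", "amputation")))
    want <- c(sizes[3], sizes[4], sizes[1], sizes[2]) * 0.2
    expect_true(all(abs(as.vector(t(got)) - want) <= 1))
  }
})

test_that("model selection finds a perfect family on linearly separable data", {
  set.seed(6)
  n <- 120L
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(sig = y * 4 + rnorm(n, 0, 0.1),
             noise = rnorm(n))
  fm <- mk_fm(X, y)
  model <- select_model(fm, c("sig", "noise"), seed = 3)
  expect_gte(max(model$cv_f1), 1 - 1e-9)
  expect_equal(predict_segments(model, fm), y)
})

test_that("permuted labels drive cross-validated F1 to the base rate", {
  set.seed(17)
  n <- 300L
  y <- rbinom(n, 1, 0.55)
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  fm <- mk_fm(X, sample(y))          # labels carry no signal
  model <- select_model(fm, colnames(X), seed = 8)
  p <- mean(fm$y)
  base_f1 <- 2 * p / (1 + p)         # always-predict-active reference
  expect_lt(abs(mean(model$cv_f1) - base_f1), 0.25)
  expect_lt(max(model$cv_f1), 0.85)
})

test_that("single-class training data is rejected", {
  fm <- mk_fm(matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b"))),
              rep(1L, 10))
  expect_error(select_model(fm, c("a", "b"), seed = 1), "single class")
})

test_that("training output is unaffected by the held-out labels (no leakage)", {
  fm <- small_features("S1")
  ret <- prune_correlated(fm)
  sp <- stratified_split(fm, 0.2, seed = 21)
  model1 <- select_model(sp$train, ret, seed = 5)
  test_shuffled <- sp$test
  test_shuffled$y <- sample(test_shuffled$y)
  model2 <- select_model(sp$train, ret, seed = 5)
  expect_identical(model1$family, model2$family)
  expect_equal(model1$cv_f1, model2$cv_f1, tolerance = 1e-12)
  expect_identical(predict_segments(model1, sp$test),
                   predict_segments(model2, test_shuffled[, ret, drop = FALSE]))
})

test_that("the benchmark composes split, selection and evaluation reproducibly", {
  fm <- small_features("S1")
  rep1 <- run_benchmark(fm, n_splits = 2, seed = 31)
  expect_s3_class(rep1, "evaluation_report")
  expect_equal(nrow(rep1$per_split), 2L)
  expect_true(all(rep1$per_split[, c("accuracy", "precision", "recall", "f1")] >= 0 &
                  rep1$per_split[, c("accuracy", "precision", "recall", "f1")] <= 1))
  expect_equal(unname(rep1$means["f1"]), mean(rep1$per_split$f1))
  rep2 <- run_benchmark(fm, n_splits = 2, seed = 31)
  expect_identical(rep1$per_split, rep2$per_split)
  # n_splits = 1 equals one manual split + select + evaluate run
  rep3 <- run_benchmark(fm, n_splits = 1, seed = 47)
  sp <- stratified_split(fm, 0.2, child_seed_for_test(47, "split1"))
  model <- select_model(sp$train, rep3$retained,
                        seed = child_seed_for_test(47, "select1"))
  m <- evaluate_metrics(confusion_counts(sp$test$y, predict_segments(model, sp$test)))
  expect_equal(unname(rep3$per_split$f1), unname(m["f1"]), tolerance = 1e-12)
})

test_that("importance scores sum to one, rank a dominant predictor first, and carry correlation signs", {
  set.seed(13)
  n <- 200L
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(oracle = y + rnorm(n, 0, 0.05),
             anti = -y + rnorm(n, 0, 0.4),
             junk1 = rnorm(n), junk2 = rnorm(n))
  fm <- mk_fm(X, y)
  imp <- feature_importance(fm, colnames(X), seed = 2)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-6)
  expect_equal(imp$predictor[1], "oracle")
  expect_gt(imp$importance[1], 0.5)
  expect_equal(imp$correlation_sign[imp$predictor == "anti"], "-")
  expect_equal(imp$correlation_sign[imp$predictor == "oracle"], "+")
  expect_error(feature_importance(mk_fm(X, rep(1L, n)), colnames(X)), "class")
})

test_that("a tree-ensemble family wins model selection on most benchmark splits", {
  fm <- small_features("S1")
  rep <- run_benchmark(fm, n_splits = 5, seed = 19)
  share <- mean(rep$per_split$family %in% c("random_forest", "xgboost"))
  expect_gte(share, 0.6)
})
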