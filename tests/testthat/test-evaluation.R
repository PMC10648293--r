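# Cross-validation, holdout testing, tournament mechanics, and the
# no-leakage audit.

test_that("a perfect feature yields near-zero CV error and R2 near 1", {
  set.seed(51)
  y <- rnorm(100)
  X <- data.frame(copy = y, junk = rnorm(100))
  folds <- rep(1:5, 20)
  cv <- crossValidate(modelSpec("linear"), X, y, folds)
  expect_lt(cv$metrics[["rmse"]], 1e-8)
  expect_gt(cv$metrics[["r2"]], 1 - 1e-8)
})

test_that("a forced mean-only predictor matches its closed-form CV metrics", {
  set.seed(52)
  y <- rnorm(60, mean = 2)
  X <- data.frame(x = rnorm(60))
  folds <- rep(1:5, 12)
  # coarse preset cannot split 48-row training folds (min_parent 72)
  cv <- crossValidate(modelSpec("coarse_tree"), X, y, folds)
  # independent oracle: out-of-fold prediction is the fold-complement mean
  pred <- numeric(60)
  for (f in 1:5) pred[folds == f] <- mean(y[folds != f])
  expect_equal(cv$predictions, pred, tolerance = 1e-12)
  expect_equal(cv$metrics[["rmse"]], sqrt(mean((pred - y)^2)))
  expect_lte(cv$metrics[["r2"]], 0)
  expect_equal(cv$metrics[["rmse"]], sd(y), tolerance = 0.1)
})

test_that("metric identities hold on any run", {
  set.seed(53)
  y <- rnorm(80)
  X <- data.frame(a = y + rnorm(80), b = rnorm(80))
  cv <- crossValidate(modelSpec("medium_tree"), X, y, rep(1:5, 16))
  expect_equal(cv$metrics[["rmse"]]^2, cv$metrics[["mse"]],
               tolerance = 1e-12)
  expect_gte(cv$metrics[["rmse"]], 0)
  expect_gte(cv$metrics[["mae"]], 0)
  expect_length(cv$per_fold, 5)
  expect_error(crossValidate(modelSpec("linear"), X, y,
                             c(rep(1, 79), 2)), "fewer than 2")
})

test_that("holdout on the training rows reproduces the training error", {
  set.seed(54)
  X <- data.frame(x = rnorm(50))
  y <- 3 * X$x + rnorm(50, 0, 0.2)
  fit <- trainModel(modelSpec("linear"), X, y)
  ht <- holdoutTest(fit, X, y)
  expect_equal(ht$rmse_test, sqrt(mean((predict(fit, X) - y)^2)))
  expect_error(holdoutTest(fit, X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("fold assignment is seed-deterministic and partitions training rows", {
  plan <- makeSplitPlan(paste0("P", 1:10), n_test = 2, cv_folds = 5,
                        seed = 5)
  expect_length(plan$train_patients, 8)
  expect_length(plan$test_patients, 2)
  expect_length(intersect(plan$train_patients, plan$test_patients), 0)
  rp <- rep(paste0("P", 1:10), each = 12)
  f1 <- assignFolds(plan, rp)
  f2 <- assignFolds(plan, rp)
  expect_identical(f1, f2)
  expect_true(all(f1[rp %in% plan$test_patients] == 0))
  expect_setequal(unique(f1[rp %in% plan$train_patients]), 1:5)
  # grouped folds keep each patient's rows together
  plang <- makeSplitPlan(paste0("P", 1:10), seed = 5, grouped_cv = TRUE)
  fg <- assignFolds(plang, rp)
  for (p in plang$train_patients)
    expect_length(unique(fg[rp == p]), 1)
})

test_that("tournament runs all presets, crowns one winner, reports all metrics", {
  ft <- tinyFeatureTable()
  plan <- makeSplitPlan(unique(ft$patient_id), n_test = 1, cv_folds = 5,
                        seed = 2)
  rep <- modelTournament(ft, "left_ulnar", plan,
                         presets = c("linear", "coarse_tree",
                                     "quadratic_svm"), k = 5)
  expect_s3_class(rep, "EvalReport")
  expect_equal(rep$validation$preset,
               c("linear", "coarse_tree", "quadratic_svm"))
  expect_true(all(c("rmse", "mse", "mae", "r2") %in% names(rep$validation)))
  expect_true(rep$winner %in% rep$validation$preset)
  expect_equal(min(rep$validation$rmse),
               rep$validation$rmse[rep$validation$preset == rep$winner])
  expect_true(is.finite(rep$rmse_test))
  expect_lte(length(rep$selected_features), 5)
})

test_that("a cheating feature equal to the target makes linear regression win", {
  ft <- tinyFeatureTable()
  ft2 <- ft[ft$nerve == "left_ulnar", ]
  ft2[[featureColumns("left_ulnar")[1]]] <- ft2$et_sevo_pct
  plan <- makeSplitPlan(unique(ft2$patient_id), n_test = 1, seed = 2)
  rep <- modelTournament(ft2, "left_ulnar", plan,
                         presets = c("linear", "coarse_tree"), k = 3)
  expect_equal(rep$winner, "linear")
  expect_lt(min(rep$validation$rmse), 0.05)
})

test_that("deleting test-patient rows changes no fitted parameter (no leakage)", {
  ft <- tinyFeatureTable()
  plan <- makeSplitPlan(unique(ft$patient_id), n_test = 1, cv_folds = 5,
                        seed = 2)
  lu_full <- ft[ft$nerve == "left_ulnar", ]
  lu_train <- lu_full[lu_full$patient_id %in% plan$train_patients, ]
  cols <- featureColumns("left_ulnar")
  n1 <- fitIqrNormalizer(lu_full, cols,
                         fit_rows = which(lu_full$patient_id %in%
                                          plan$train_patients))
  n2 <- fitIqrNormalizer(lu_train, cols)
  expect_equal(n1$median, n2$median)
  expect_equal(n1$iqr, n2$iqr)
  X1 <- applyNormalizer(lu_full, n1)
  X2 <- applyNormalizer(lu_train, n2)
  tr1 <- X1$patient_id %in% plan$train_patients
  r1 <- mrmrRank(X1[tr1, intersect(cols, names(X1))], X1$et_sevo_pct[tr1],
                 k = 10)
  r2 <- mrmrRank(X2[, intersect(cols, names(X2))], X2$et_sevo_pct, k = 10)
  expect_identical(r1$features, r2$features)
  expect_equal(r1$scores, r2$scores)
  m1 <- trainModel(modelSpec("quadratic_svm"),
                   X1[tr1, r1$features], X1$et_sevo_pct[tr1], seed = 3)
  m2 <- trainModel(modelSpec("quadratic_svm"),
                   X2[, r2$features], X2$et_sevo_pct, seed = 3)
  expect_equal(predict(m1, X1[tr1, r1$features]),
               predict(m2, X2[, r2$features]))
})
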