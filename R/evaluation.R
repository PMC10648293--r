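# Cross-validated training, patient-level holdout, and the model report
# card. Two patients are held out for testing; the remaining patients'
# rows are cross-validated in five folds. Metrics on pooled out-of-fold
# predictions: RMSE, MSE, MAE, and R-squared (1 - SSE/SST, computable
# below zero).

#' Build a patient-level split plan
#'
#' Selects `n_test` test patients (seed-deterministic) and fixes the
#' cross-validation fold count for the remaining training patients.
#'
#' @param patients character vector of patient ids
#' @param n_test number of held-out test patients (default 2)
#' @param cv_folds number of cross-validation folds (default 5)
#' @param seed integer seed
#' @param grouped_cv if TRUE, folds are drawn at the patient level
#'   (grouped); default FALSE draws folds at the trial level
#' @return a `SplitPlan`
#' @export
makeSplitPlan <- function(patients, n_test = 2, cv_folds = 5, seed = 1L,
                          grouped_cv = FALSE) {
  patients <- unique(as.character(patients))
  if (n_test < 1 || n_test >= length(patients))
    stop("n_test must leave at least one training patient")
  test <- withr::with_seed(as.integer(seed),
                           sort(sample(patients, n_test)))
  structure(list(train_patients = setdiff(patients, test),
                 test_patients = test, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), grouped_cv = grouped_cv),
            class = "SplitPlan")
}

#' @export
print.SplitPlan <- function(x, ...) {
  cat("SplitPlan: ", length(x$train_patients), " train / ",
      length(x$test_patients), " test patients, ", x$cv_folds,
      if (x$grouped_cv) " patient-grouped" else " trial-level",
      " folds (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Assign cross-validation folds to training rows
#'
#' Seed-deterministic. Trial-level folds shuffle rows across the training
#' patients; grouped folds assign whole patients to folds. Test-patient
#' rows receive fold 0.
#'
#' @param plan a [makeSplitPlan()]
#' @param row_patients patient id per table row
#' @return integer fold per row (0 for test-patient rows)
#' @export
assignFolds <- function(plan, row_patients) {
  idx_train <- which(row_patients %in% plan$train_patients)
  folds <- integer(length(row_patients))
  withr::with_seed(plan$seed + 1L, {
    if (plan$grouped_cv) {
      pts <- plan$train_patients
      fp <- setNames(
        rep_len(seq_len(plan$cv_folds), length(pts))[sample(length(pts))],
        pts)
      folds[idx_train] <- fp[row_patients[idx_train]]
    } else {
      folds[idx_train] <- rep_len(seq_len(plan$cv_folds),
                                  length(idx_train))[sample(length(idx_train))]
    }
  })
  folds   # 0 marks test-patient rows
}

.metrics <- function(truth, pred) {
  err <- pred - truth
  mse <- mean(err^2)
  sst <- sum((truth - mean(truth))^2)
  c(rmse = sqrt(mse), mse = mse, mae = mean(abs(err)),
    r2 = if (sst > 0) 1 - sum(err^2) / sst else NA_real_)
}

#' Cross-validate one preset on the training rows
#'
#' Trains on each fold complement and predicts the held fold; metrics are
#' computed on the pooled out-of-fold predictions.
#'
#' @param spec a [modelSpec()]
#' @param X,y training predictors and target
#' @param folds integer fold id per row (1..cv_folds)
#' @param seed seed forwarded to [trainModel()]
#' @return list with `metrics` (rmse/mse/mae/r2), `per_fold` (rmse per
#'   fold), `predictions` (pooled out-of-fold, original row order)
#' @export
crossValidate <- function(spec, X, y, folds, seed = 1L) {
  X <- as.data.frame(X)
  ids <- sort(unique(folds))
  stopifnot(length(folds) == nrow(X), all(ids >= 1))
  for (f in ids) if (sum(folds == f) < 2)
    stop("fold ", f, " has fewer than 2 rows")
  pred <- rep(NA_real_, nrow(X))
  per_fold <- numeric(0)
  for (f in ids) {
    hold <- folds == f
    fit <- trainModel(spec, X[!hold, , drop = FALSE], y[!hold],
                      seed = seed + f)
    pred[hold] <- predict(fit, X[hold, , drop = FALSE])
    per_fold <- c(per_fold, sqrt(mean((pred[hold] - y[hold])^2)))
  }
  list(metrics = .metrics(y, pred), per_fold = per_fold,
       predictions = pred)
}

#' Holdout-test a trained model
#'
#' @param model an `ssepModel` trained on the training patients
#' @param X_test,y_test held-out test rows
#' @return list with `rmse_test` and the test `predictions`
#' @export
holdoutTest <- function(model, X_test, y_test) {
  if (nrow(as.data.frame(X_test)) == 0) stop("empty test set")
  p <- predict(model, X_test)
  list(rmse_test = sqrt(mean((p - y_test)^2)), predictions = p)
}

#' Run the model tournament for one nerve
#'
#' The complete leakage-safe per-nerve pipeline: frame the nerve's
#' reverse-regression problem, fit the IQR normalizer on the training
#' patients' rows (unless `fit_on_all`), rank features by MRMR on the
#' training rows, cross-validate every preset on the selected features,
#' crown the preset with the lowest validation RMSE (ties break toward the
#' earlier preset in listing order), refit it on all training rows, and
#' report its holdout RMSE on the test patients.
#'
#' @param table feature table from [assembleFeatureTable()] (raw,
#'   unnormalized)
#' @param nerve one of [monitoredNerves()]
#' @param plan a [makeSplitPlan()]
#' @param presets preset names to enter (default all ten)
#' @param k MRMR selection size (default 10)
#' @param fit_on_all if TRUE, fit the normalizer on the consolidated
#'   cohort (all ten patients) instead of the training patients only
#' @return an `EvalReport`: list with `nerve`, `winner`, `validation`
#'   (per-preset metric data.frame), `rmse_test`, `selected_features`,
#'   `test_truth`, `test_predictions`, `plan`
#' @export
modelTournament <- function(table, nerve, plan, presets = modelPresets(),
                            k = 10, fit_on_all = FALSE) {
  if (length(presets) < 2) stop("need at least 2 presets")
  prob <- makeRegressionProblem(table, nerve)
  pid <- prob$meta$patient_id
  is_train <- pid %in% plan$train_patients
  is_test <- pid %in% plan$test_patients
  if (!any(is_test)) stop("no rows for the test patients")
  norm <- fitIqrNormalizer(
    cbind(prob$X, et_sevo_pct = prob$y), feature_cols = names(prob$X),
    fit_rows = if (fit_on_all) seq_along(pid) else which(is_train))
  Xn <- applyNormalizer(cbind(prob$X, et_sevo_pct = prob$y), norm)
  Xn$et_sevo_pct <- NULL
  rank <- mrmrRank(Xn[is_train, , drop = FALSE], prob$y[is_train],
                   k = min(k, ncol(Xn)))
  Xsel <- selectFeatures(rank, Xn)
  folds <- assignFolds(plan, pid)
  Xtr <- Xsel[is_train, , drop = FALSE]
  ytr <- prob$y[is_train]
  ftr <- folds[is_train]
  val <- lapply(presets, function(p)
    crossValidate(modelSpec(p), Xtr, ytr, ftr, seed = plan$seed))
  names(val) <- presets
  vtab <- do.call(rbind, lapply(presets, function(p)
    data.frame(preset = p, t(val[[p]]$metrics))))
  win_i <- which.min(vtab$rmse)          # ties: earlier listing order
  winner <- presets[win_i]
  final <- trainModel(modelSpec(winner), Xtr, ytr, seed = plan$seed)
  ht <- holdoutTest(final, Xsel[is_test, , drop = FALSE], prob$y[is_test])
  structure(list(
    nerve = nerve, winner = winner, validation = vtab,
    rmse_test = ht$rmse_test, selected_features = names(Xsel),
    ranking = rank, model = final,
    test_truth = prob$y[is_test], test_predictions = ht$predictions,
    normalizer = norm, plan = plan), class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("EvalReport [", x$nerve, "]: winner '", x$winner,
      "' (validation RMSE ",
      signif(min(x$validation$rmse), 4), ", test RMSE ",
      signif(x$rmse_test, 4), ")\n", sep = "")
  print(x$validation, row.names = FALSE)
  invisible(x)
}
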