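# IQR normalization and reverse-regression framing. The concentration is
# the regression target ("reverse" because the anesthetic dose, physically
# the exposure, is predicted from the waveform response); the target is
# kept in physical % units and never normalized.

#' Fit an interquartile-range normalizer
#'
#' Per feature, computes the median and IQR (third minus first quartile,
#' linear-interpolation quartiles, [stats::quantile()] type 7) over the
#' designated fitting rows only. Features with zero IQR are flagged for
#' exclusion. In the default leakage-safe workflow the fitting rows are the
#' training patients' rows.
#'
#' @param table feature table (data.frame)
#' @param feature_cols character, the columns to normalize
#' @param fit_rows integer/logical row index of the fitting rows (default
#'   all rows, reproducing a consolidated-cohort fit)
#' @return an `IqrNormalizer`: data.frame with feature, median, iqr, flagged
#' @export
fitIqrNormalizer <- function(table, feature_cols = NULL, fit_rows = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(featureColumns(), names(table))
    # the fixed 132-column universe leaves other nerves' features NA on a
    # nerve's rows; default to the columns actually observed here
    feature_cols <- feature_cols[vapply(feature_cols, function(f)
      any(!is.na(table[[f]])), logical(1))]
  }
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(table))
  params <- do.call(rbind, lapply(feature_cols, function(f) {
    if (!f %in% names(table)) stop("unknown column: ", f)
    x <- table[fit_rows, f]
    x <- x[!is.na(x)]
    if (length(x) == 0) stop("feature '", f, "' is all-missing in fit rows")
    if (length(x) < 4)
      stop("feature '", f, "': need >= 4 non-missing fit rows")
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(feature = f, median = q[2], iqr = q[3] - q[1],
               stringsAsFactors = FALSE)
  }))
  params$flagged <- params$iqr == 0
  rownames(params) <- NULL
  class(params) <- c("IqrNormalizer", "data.frame")
  params
}

#' Apply an IQR normalizer
#'
#' Transforms each covered feature as `(x - median) / IQR`; flagged
#' (zero-IQR) features are dropped from the table. The target column and
#' metadata columns are untouched. Errors if the normalizer names a column
#' absent from the table or if a feature column lacks parameters.
#'
#' @param table feature table
#' @param params an `IqrNormalizer` from [fitIqrNormalizer()]
#' @return the normalized table, flagged columns removed
#' @export
applyNormalizer <- function(table, params) {
  missing_cols <- setdiff(params$feature, names(table))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  present_feats <- intersect(featureColumns(), names(table))
  present_feats <- present_feats[vapply(present_feats, function(f)
    any(!is.na(table[[f]])), logical(1))]     # NA-only columns are exempt
  uncovered <- setdiff(present_feats, params$feature)
  if (length(uncovered))
    stop("normalizer does not cover column(s): ",
         paste(uncovered, collapse = ", "))
  keep <- params[!params$flagged, , drop = FALSE]
  for (i in seq_len(nrow(keep))) {
    f <- keep$feature[i]
    table[[f]] <- (table[[f]] - keep$median[i]) / keep$iqr[i]
  }
  drop <- params$feature[params$flagged]
  table[, setdiff(names(table), drop), drop = FALSE]
}

#' Frame the reverse-regression problem for one nerve
#'
#' Restricts the predictors to the nerve's 33 qualified feature columns
#' (or all 132 with `nerve = "all"`), keeps rows where those features are
#' observed, and returns the concentration as the target.
#'
#' @param table feature table from [assembleFeatureTable()] (normalized or
#'   not)
#' @param nerve one of [monitoredNerves()] or `"all"`
#' @return list with `X` (predictor data.frame), `y` (concentration, %),
#'   `meta` (patient_id/nerve/event/timestamp rows)
#' @export
makeRegressionProblem <- function(table, nerve) {
  if (identical(nerve, "all")) {
    cols <- intersect(featureColumns(), names(table))
    rows <- seq_len(nrow(table))
  } else {
    nerve <- match.arg(nerve, .NERVES)
    if (!any(table$nerve == nerve)) stop("nerve '", nerve, "' absent")
    cols <- intersect(featureColumns(nerve), names(table))
    rows <- which(table$nerve == nerve)
  }
  X <- table[rows, cols, drop = FALSE]
  if (anyNA(table$et_sevo_pct[rows])) stop("missing target values")
  meta_cols <- intersect(c("patient_id", "nerve", "event", "timestamp_s"),
                         names(table))
  list(X = X, y = table$et_sevo_pct[rows],
       meta = table[rows, meta_cols, drop = FALSE])
}
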