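# Minimum-redundancy maximum-relevance feature ranking on a plug-in
# mutual-information estimator with equal-frequency binning. Greedy
# quotient scheme: the first pick maximizes relevance MI(f; y); each later
# pick maximizes relevance / (mean MI with the already-selected set).

#' Plug-in mutual information with equal-frequency binning
#'
#' Discretizes each variable into equal-frequency bins (linear-interpolation
#' quantile edges) and returns the plug-in mutual information of the joint
#' histogram, in nats. Symmetric and non-negative; a constant vector has MI
#' 0 by convention.
#'
#' @param x,y equal-length sample vectors (length >= 8)
#' @param bins number of bins per variable; default
#'   `min(10, ceiling(sqrt(n)))`
#' @return mutual information in nats
#' @examples
#' x <- seq_len(100)
#' mutualInformation(x, x)   # log(10) with 10 equal-frequency bins
#' @export
mutualInformation <- function(x, y, bins = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 8) stop("need at least 8 samples")
  if (is.null(bins)) bins <- min(10L, ceiling(sqrt(n)))
  bx <- .eqFreqBin(x, bins)
  by <- .eqFreqBin(y, bins)
  if (is.null(bx) || is.null(by)) return(0)   # constant vector convention
  joint <- table(bx, by) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

.eqFreqBin <- function(x, bins) {
  edges <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                           type = 7, names = FALSE))
  if (length(edges) < 2) return(NULL)
  cut(x, breaks = edges, include.lowest = TRUE, labels = FALSE)
}

#' Greedy MRMR feature ranking
#'
#' Ranks up to `k` features by greedy forward selection: the first pick is
#' the feature with maximal relevance `MI(f; y)`; each subsequent pick
#' maximizes the quotient score `relevance / (mean MI with the selected
#' set + eps)`. Ties break toward the earlier column. Features whose
#' relevance does not exceed `significance_threshold` are counted as
#' insignificant.
#'
#' @param X predictor data.frame/matrix
#' @param y target vector
#' @param k number of features to rank (default 10)
#' @param bins passed to [mutualInformation()]
#' @param significance_threshold relevance at or below which a feature is
#'   insignificant (default 0)
#' @param eps redundancy-denominator guard
#' @return an `MRMRResult`: list with `features` (selection order),
#'   `scores` (greedy score at selection), `relevance` (named, all
#'   features), `n_significant`, `k`, `significance_threshold`
#' @export
mrmrRank <- function(X, y, k = 10, bins = NULL,
                     significance_threshold = 0, eps = 1e-12) {
  X <- as.data.frame(X)
  if (k <= 0) stop("k must be positive")
  if (k > ncol(X)) stop("k exceeds the number of columns")
  feats <- names(X)
  relevance <- vapply(feats, function(f)
    mutualInformation(X[[f]], y, bins = bins), numeric(1))
  n_significant <- sum(relevance > significance_threshold)
  selected <- integer(0)
  scores <- numeric(0)
  # cache pairwise MI with selected features as they are needed
  red_sum <- numeric(length(feats))
  for (step in seq_len(k)) {
    cand <- setdiff(seq_along(feats), selected)
    sc <- if (length(selected) == 0) relevance[cand] else
      relevance[cand] / (red_sum[cand] / length(selected) + eps)
    best <- cand[which.max(sc)]          # ties: earlier column
    selected <- c(selected, best)
    scores <- c(scores, unname(sc[match(best, cand)]))
    if (step < k) {
      cand2 <- setdiff(seq_along(feats), selected)
      for (j in cand2)
        red_sum[j] <- red_sum[j] +
          mutualInformation(X[[j]], X[[best]], bins = bins)
    }
  }
  structure(list(features = feats[selected], scores = scores,
                 relevance = relevance, n_significant = n_significant,
                 k = k, significance_threshold = significance_threshold),
            class = "MRMRResult")
}

#' @export
print.MRMRResult <- function(x, ...) {
  cat("MRMR ranking (", x$n_significant, " significant of ",
      length(x$relevance), " features)\n", sep = "")
  print(data.frame(rank = seq_along(x$features), feature = x$features,
                   score = signif(x$scores, 4),
                   relevance = signif(unname(x$relevance[x$features]), 4)))
  invisible(x)
}

#' Reduce a predictor table to the significant MRMR selection
#'
#' Retains `min(k, n_significant)` columns in ranked order: ranked features
#' whose relevance exceeds the significance threshold. Emits a warning and
#' returns zero columns when nothing is significant.
#'
#' @param result an `MRMRResult` from [mrmrRank()]
#' @param X the predictor table the ranking was computed on
#' @return `X` restricted to the selected columns, in ranked order
#' @export
selectFeatures <- function(result, X) {
  X <- as.data.frame(X)
  if (!all(result$features %in% names(X)))
    stop("ranking does not match the table's columns")
  sig <- result$features[
    result$relevance[result$features] > result$significance_threshold]
  keep <- head(sig, min(result$k, result$n_significant))
  if (length(keep) == 0)
    warning("no significant features: empty selection")
  X[, keep, drop = FALSE]
}
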