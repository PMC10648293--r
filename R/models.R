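# Ten-preset regression bank under a single train/predict contract.
# Presets mirror a conventional regression-learner bank: ordinary least
# squares; variance-reduction binary trees at three granularities;
# eps-insensitive polynomial-kernel support-vector regression at degrees
# 1-3 with automatic box constraint IQR(y)/1.349 and epsilon IQR(y)/13.49;
# and single-hidden-layer feed-forward networks at three widths.

.PRESETS <- c("linear", "fine_tree", "medium_tree", "coarse_tree",
              "linear_svm", "quadratic_svm", "cubic_svm",
              "narrow_nn", "medium_nn", "wide_nn")

#' The ten model presets, in canonical listing order
#'
#' @return character vector of preset names
#' @export
modelPresets <- function() .PRESETS

#' Build a model specification
#'
#' Returns the preset's family and hyperparameters, overridable via `...`.
#' Tree presets fix `min_leaf` fine/medium/coarse = 4/12/36 with
#' `min_parent = 2 * min_leaf`; SVM presets fix the polynomial kernel
#' degree 1/2/3 with automatic `box_constraint = IQR(y)/1.349` and
#' `epsilon = IQR(y)/13.49` resolved at training time; network presets fix
#' `hidden_units` narrow/medium/wide = 10/25/100.
#'
#' @param preset one of [modelPresets()]
#' @param ... hyperparameter overrides (e.g. `min_leaf`, `box_constraint`,
#'   `epsilon`, `kernel_scale`, `hidden_units`, `max_iter`, `max_splits`)
#' @return a `ModelSpec` list with `preset`, `family`, `hyper`
#' @export
modelSpec <- function(preset = .PRESETS, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    linear = list(family = "linear"),
    fine_tree = list(family = "tree", min_leaf = 4, min_parent = 8,
                     max_splits = Inf),
    medium_tree = list(family = "tree", min_leaf = 12, min_parent = 24,
                       max_splits = Inf),
    coarse_tree = list(family = "tree", min_leaf = 36, min_parent = 72,
                       max_splits = Inf),
    linear_svm = list(family = "svm", degree = 1, box_constraint = NA,
                      epsilon = NA, kernel_scale = "auto",
                      standardize = TRUE),
    quadratic_svm = list(family = "svm", degree = 2, box_constraint = NA,
                         epsilon = NA, kernel_scale = "auto",
                         standardize = TRUE),
    cubic_svm = list(family = "svm", degree = 3, box_constraint = NA,
                     epsilon = NA, kernel_scale = "auto",
                     standardize = TRUE),
    narrow_nn = list(family = "nn", hidden_units = 10, max_iter = 200,
                     decay = 1e-4),
    medium_nn = list(family = "nn", hidden_units = 25, max_iter = 200,
                     decay = 1e-4),
    wide_nn = list(family = "nn", hidden_units = 100, max_iter = 200,
                   decay = 1e-4)
  )
  hyper <- utils::modifyList(base[-1], list(...))
  if (identical(base$family, "tree") && !"min_parent" %in% names(list(...)))
    hyper$min_parent <- 2 * hyper$min_leaf
  structure(list(preset = preset, family = base$family, hyper = hyper),
            class = "ModelSpec")
}

#' Automatic SVM regression constants from the response spread
#'
#' The automatic box constraint is `IQR(y)/1.349` and the automatic
#' epsilon `IQR(y)/13.49` (so a response with IQR 1 yields the pair
#' 0.7413 / 0.0741). A zero-IQR response falls back to 1 and 0.1.
#'
#' @param y response vector
#' @return named numeric with `box_constraint` and `epsilon`
#' @export
svmAutoConstants <- function(y) {
  iqr <- unname(diff(quantile(y, c(0.25, 0.75), type = 7, names = FALSE)))
  if (iqr == 0) return(c(box_constraint = 1, epsilon = 0.1))
  c(box_constraint = iqr / 1.349, epsilon = iqr / 13.49)
}

.asMatrix <- function(X) {
  X <- as.data.frame(X)
  stopifnot(!anyNA(X))
  m <- as.matrix(X)
  storage.mode(m) <- "double"
  m
}

#' Train one preset model
#'
#' Dispatches on the spec's family: linear = ordinary least squares; tree =
#' MSE-criterion binary regression tree honoring `min_leaf` /
#' `min_parent` / `max_splits`; svm = eps-insensitive polynomial-kernel
#' support-vector regression on standardized predictors, kernel scale
#' `"auto"` = median pairwise Euclidean distance among the standardized
#' training predictors; nn = single-hidden-layer sigmoid network with a
#' linear output, seed-deterministic initialization. A constant response
#' trains to the constant.
#'
#' @param spec a [modelSpec()]
#' @param X predictor data.frame/matrix (no missing values)
#' @param y numeric response
#' @param seed integer seed (consumed by the network initializer; other
#'   families are deterministic)
#' @return an `ssepModel` supporting [predict()]
#' @export
trainModel <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "ModelSpec"))
  m <- .asMatrix(X)
  stopifnot(nrow(m) == length(y), !anyNA(y))
  cols <- colnames(m)
  internal <- paste0("x", seq_len(ncol(m)))
  colnames(m) <- internal
  h <- spec$hyper
  if (length(unique(y)) == 1) {
    # degenerate constant response: every family trains to the constant
    return(structure(list(spec = spec, columns = cols, internal = internal,
                          const = y[1]), class = "ssepModel"))
  }
  fit_obj <- switch(spec$family,
    linear = {
      df <- data.frame(.y = y, m, check.names = FALSE)
      list(fit = lm(.y ~ ., data = df))
    },
    tree = {
      if (nrow(m) < 2 * h$min_leaf && nrow(m) < h$min_parent) {
        # cannot split at all: degenerate single-leaf model
        list(fit = NULL, leaf_mean = mean(y))
      } else {
        df <- data.frame(.y = y, m, check.names = FALSE)
        ctl <- rpart::rpart.control(
          minbucket = h$min_leaf, minsplit = h$min_parent, cp = 0,
          maxdepth = 30, xval = 0, maxsurrogate = 0, usesurrogate = 0)
        fit <- rpart::rpart(.y ~ ., data = df, method = "anova",
                            control = ctl)
        if (is.finite(h$max_splits) && !is.null(fit$cptable)) {
          tab <- fit$cptable
          ok <- tab[, "nsplit"] <= h$max_splits
          if (any(ok)) {
            target <- max(tab[ok, "nsplit"])
            cp_cut <- tab[tab[, "nsplit"] == target, "CP"][1]
            fit <- rpart::prune(fit, cp = cp_cut)
          }
        }
        list(fit = fit)
      }
    },
    svm = {
      ctr <- colMeans(m)
      scl <- apply(m, 2, sd)
      scl[scl == 0] <- 1
      ms <- scale(m, center = ctr, scale = scl)
      ks <- h$kernel_scale
      if (identical(ks, "auto")) {
        dd <- as.numeric(dist(ms))
        ks <- median(dd[dd > 0])
        if (!is.finite(ks) || ks == 0) ks <- 1
      }
      auto <- svmAutoConstants(y)
      C <- if (is.na(h$box_constraint)) auto[["box_constraint"]] else
        h$box_constraint
      epsv <- if (is.na(h$epsilon)) auto[["epsilon"]] else h$epsilon
      fit <- e1071::svm(x = ms, y = y, type = "eps-regression",
                        kernel = "polynomial", degree = h$degree,
                        gamma = 1 / ks^2, coef0 = 1, cost = C,
                        epsilon = epsv, scale = FALSE)
      list(fit = fit, center = ctr, scale = scl, kernel_scale = ks,
           box_constraint = C, epsilon = epsv)
    },
    nn = {
      ctr <- colMeans(m)
      scl <- apply(m, 2, sd)
      scl[scl == 0] <- 1
      ms <- scale(m, center = ctr, scale = scl)
      y_ctr <- mean(y)
      y_scl <- sd(y)
      if (!is.finite(y_scl) || y_scl == 0) y_scl <- 1
      fit <- withr::with_seed(as.integer(seed), nnet::nnet(
        x = ms, y = (y - y_ctr) / y_scl, size = h$hidden_units,
        linout = TRUE, maxit = h$max_iter, decay = h$decay,
        trace = FALSE, MaxNWts = 100000))
      list(fit = fit, center = ctr, scale = scl, y_center = y_ctr,
           y_scale = y_scl)
    },
    stop("unknown family: ", spec$family)
  )
  structure(c(list(spec = spec, columns = cols, internal = internal),
              fit_obj), class = "ssepModel")
}

#' @export
print.ssepModel <- function(x, ...) {
  cat("ssepModel preset '", x$spec$preset, "' (", x$spec$family, "), ",
      length(x$columns), " predictors\n", sep = "")
  invisible(x)
}

#' Predict from a trained preset model
#'
#' The new data must carry exactly the training columns, in the same
#' order; otherwise the error lists the missing and extra names.
#'
#' @param object an `ssepModel`
#' @param newdata predictor data.frame/matrix
#' @param ... unused
#' @return numeric predictions, one per row
#' @export
predict.ssepModel <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  if (!identical(names(nd), object$columns)) {
    miss <- setdiff(object$columns, names(nd))
    extra <- setdiff(names(nd), object$columns)
    if (length(miss) || length(extra))
      stop("column mismatch; missing: [",
           paste(miss, collapse = ", "), "], extra: [",
           paste(extra, collapse = ", "), "]")
    nd <- nd[, object$columns, drop = FALSE]   # same set, wrong order
  }
  m <- .asMatrix(nd)
  colnames(m) <- object$internal
  if (!is.null(object$const)) return(rep(object$const, nrow(m)))
  fam <- object$spec$family
  out <- if (fam == "linear") {
    unname(predict(object$fit, newdata = as.data.frame(m)))
  } else if (fam == "tree") {
    if (is.null(object$fit)) rep(object$leaf_mean, nrow(m)) else
      unname(predict(object$fit, newdata = as.data.frame(m)))
  } else if (fam == "svm") {
    ms <- scale(m, center = object$center, scale = object$scale)
    unname(predict(object$fit, newdata = ms))
  } else {
    ms <- scale(m, center = object$center, scale = object$scale)
    as.numeric(predict(object$fit, ms)) * object$y_scale + object$y_center
  }
  stopifnot(all(is.finite(out)))
  out
}

# Number of training rows in each leaf of a fitted tree model (test aid).
#' Leaf sizes of a fitted tree model
#'
#' @param model an `ssepModel` with family `"tree"`
#' @return integer vector of training-row counts per leaf
#' @export
treeLeafSizes <- function(model) {
  stopifnot(inherits(model, "ssepModel"), model$spec$family == "tree")
  if (is.null(model$fit)) return(NA_integer_)
  fr <- model$fit$frame
  fr$n[fr$var == "<leaf>"]
}
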