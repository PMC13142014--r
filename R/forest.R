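#' Grow a random forest with weighted split-candidate sampling
#'
#' CART-style bagged trees in which, at every node, the candidate split
#' features are drawn without replacement with probability proportional to a
#' per-feature weight vector. With uniform weights this reduces exactly to
#' the standard random forest; features with zero weight are eliminated and
#' can never be used for splitting. Splitting uses Gini impurity
#' (classification) or variance reduction (regression); thresholds are
#' midpoints between adjacent distinct observed values, and ties in impurity
#' decrease break toward the lower feature index, then the lower threshold,
#' so growth is deterministic given the seed.
#'
#' @param X numeric matrix, samples in rows, features in columns. No missing
#'   values; column names (if present) are stored as feature names.
#' @param y outcome: factor/character/logical for classification (coerced to
#'   a factor with sorted levels), numeric for regression.
#' @param task `"classification"` or `"regression"`.
#' @param n_trees number of trees.
#' @param mtry number of candidate features per node. Defaults to
#'   `floor(sqrt(p))` for classification and `max(floor(p/3), 1)` for
#'   regression.
#' @param weights per-feature selection probabilities; non-negative, at least
#'   one positive. Normalized to sum to one. Default uniform.
#' @param min_node_size nodes of this size or smaller are not split.
#'   Defaults to 1 (classification) or 5 (regression).
#' @param seed integer seed; the forest is bit-reproducible given the seed
#'   and does not touch R's RNG state.
#' @param bootstrap if `FALSE`, every tree is fit to the full sample instead
#'   of a bootstrap resample (no out-of-bag samples; intended for
#'   diagnostics such as comparing splits against exhaustive enumeration).
#' @return an object of class `pirf_forest`.
#' @export
grow_forest <- function(X, y, task = c("classification", "regression"),
                        n_trees = 500, mtry = NULL, weights = NULL,
                        min_node_size = NULL, seed = 1L, bootstrap = TRUE) {
  task <- match.arg(task)
  X <- as_feature_matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop_validation("need at least 2 samples to grow a forest")
  if (length(y) != n)
    stop_validation("length of 'y' (", length(y), ") does not match nrow(X) (", n, ")")
  if (n_trees < 1L) stop_validation("'n_trees' must be >= 1")

  if (task == "classification") {
    y <- as.factor(y)
    y <- factor(y, levels = sort(levels(y)))
    if (nlevels(y) < 2L)
      stop_validation("classification outcome has a single class: ",
                      levels(y)[1L])
    y_num <- as.numeric(y) - 1
    classes <- levels(y)
    if (is.null(min_node_size)) min_node_size <- 1L
  } else {
    y_num <- as.numeric(y)
    if (anyNA(y_num)) stop_validation("regression outcome contains NA")
    classes <- NULL
    if (is.null(min_node_size)) min_node_size <- 5L
  }

  if (is.null(weights)) weights <- rep(1 / p, p)
  weights <- validate_weights(weights, p)
  if (is.null(mtry)) {
    mtry <- if (task == "classification") max(1L, floor(sqrt(p)))
            else max(1L, floor(p / 3))
  }
  if (mtry < 1L) stop_validation("'mtry' must be >= 1")

  trees <- cpp_grow_forest(X, y_num, task == "classification",
                           if (is.null(classes)) 0L else length(classes),
                           as.integer(mtry), as.integer(n_trees),
                           weights, as.integer(min_node_size),
                           as.numeric(seed), isTRUE(bootstrap))
  structure(list(
    trees = trees,
    task = task,
    classes = classes,
    n_trees = as.integer(n_trees),
    mtry = as.integer(mtry),
    min_node_size = as.integer(min_node_size),
    weights = weights,
    feature_names = colnames(X),
    n = n, p = p,
    seed = as.integer(seed)
  ), class = "pirf_forest")
}

validate_weights <- function(weights, p) {
  weights <- as.numeric(weights)
  if (length(weights) != p)
    stop_validation("'weights' must have one entry per feature")
  if (anyNA(weights) || any(weights < 0))
    stop_validation("'weights' must be non-negative and finite")
  s <- sum(weights)
  if (s <= 0) stop_validation("all feature selection weights are zero")
  weights / s
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop_validation("'X' must be a numeric matrix or data frame")
  if (anyNA(X)) stop_validation("'X' contains missing values")
  X
}

#' @export
print.pirf_forest <- function(x, ...) {
  cat("Weighted random forest (", x$task, ")\n", sep = "")
  cat("  trees: ", x$n_trees, "   mtry: ", x$mtry,
      "   min node size: ", x$min_node_size, "\n", sep = "")
  cat("  features: ", x$p, " (", sum(x$weights > 0), " with positive weight)\n",
      sep = "")
  invisible(x)
}

align_newdata <- function(object, newdata) {
  newdata <- as_feature_matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata))) {
    missing <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing) > 0L)
      stop_validation("new data lacks model features: ",
                      paste(missing, collapse = ", "))
    extra <- setdiff(colnames(newdata), object$feature_names)
    if (length(extra) > 0L)
      warning("dropping ", length(extra),
              " feature(s) absent from the model: ",
              paste(utils::head(extra, 5L), collapse = ", "),
              if (length(extra) > 5L) ", ..." else "")
    newdata <- newdata[, object$feature_names, drop = FALSE]
  } else if (ncol(newdata) != object$p) {
    stop_validation("new data has ", ncol(newdata),
                    " features; the model expects ", object$p)
  }
  newdata
}

#' Predict from a weighted random forest
#'
#' Classification predictions are majority votes over the averaged per-tree
#' class proportions (ties toward the lexicographically smaller class
#' label); `type = "prob"` returns the averaged proportions themselves,
#' suitable for AUC computation. Regression predictions are means of the
#' per-tree leaf means.
#'
#' @param object a `pirf_forest`.
#' @param newdata numeric matrix with the model's features (matched by
#'   column name when available, otherwise by position).
#' @param type `"response"` or, for classification, `"prob"`.
#' @param ... unused.
#' @export
predict.pirf_forest <- function(object, newdata,
                                type = c("response", "prob"), ...) {
  type <- match.arg(type)
  newdata <- align_newdata(object, newdata)
  if (object$task == "classification") {
    pr <- cpp_predict_forest(object$trees, newdata, TRUE,
                             length(object$classes))
    colnames(pr) <- object$classes
    rownames(pr) <- rownames(newdata)
    if (type == "prob") return(pr)
    factor(object$classes[max.col(pr, ties.method = "first")],
           levels = object$classes)
  } else {
    out <- as.numeric(cpp_predict_forest(object$trees, newdata, FALSE, 0L))
    names(out) <- rownames(newdata)
    out
  }
}

#' Out-of-bag error of a weighted random forest
#'
#' Each sample is predicted by aggregating over the trees for which it was
#' out-of-bag (averaged class proportions for classification, averaged leaf
#' means for regression). Returns the misclassification rate
#' (classification) or mean squared error (regression) over all samples that
#' are out-of-bag for at least one tree; samples in every bootstrap sample
#' are excluded with a warning.
#'
#' @param forest a `pirf_forest`.
#' @param X,y the training data the forest was grown on.
#' @export
oob_error <- function(forest, X, y) {
  X <- as_feature_matrix(X)
  classification <- forest$task == "classification"
  agg <- cpp_oob_aggregate(forest$trees, X, classification,
                           if (classification) length(forest$classes) else 0L)
  cnt <- agg$count
  if (all(cnt == 0L)) stop("no sample is out-of-bag for any tree")
  if (any(cnt == 0L))
    warning(sum(cnt == 0L), " sample(s) in-bag for every tree; ",
            "excluded from the OOB error")
  keep <- cnt > 0L
  if (classification) {
    y <- factor(y, levels = forest$classes)
    pred_cls <- max.col(agg$agg[keep, , drop = FALSE], ties.method = "first")
    mean(pred_cls != as.integer(y)[keep])
  } else {
    pred <- agg$agg[keep, 1L] / cnt[keep]
    mean((pred - as.numeric(y)[keep])^2)
  }
}

#' Out-of-bag permutation importance
#'
#' For every tree and every feature used by that tree, the feature's values
#' among the tree's out-of-bag samples are permuted and the increase in the
#' tree's OOB loss (error rate for classification, MSE for regression) is
#' recorded, averaged over `n_permutations` repetitions. Per-feature scores
#' are the average over all trees; a feature used by no tree scores exactly
#' 0. Scores may be negative (permuting the feature reduced the loss), which
#' downstream probability construction treats as evidence of no importance.
#'
#' @param forest a `pirf_forest`.
#' @param X,y the training data the forest was grown on.
#' @param n_permutations permutations per tree and feature (default 1).
#' @param seed integer seed for the permutations (independent of R's RNG).
#' @return named numeric vector of importance scores, one per feature.
#' @export
permutation_importance <- function(forest, X, y, n_permutations = 1L,
                                   seed = 1L) {
  if (n_permutations < 1L) stop_validation("'n_permutations' must be >= 1")
  X <- as_feature_matrix(X)
  classification <- forest$task == "classification"
  if (classification) {
    y <- factor(y, levels = forest$classes)
    y_num <- as.numeric(y) - 1
  } else {
    y_num <- as.numeric(y)
  }
  imp <- cpp_permutation_importance(forest$trees, X, y_num, classification,
                                    if (classification) length(forest$classes) else 0L,
                                    as.integer(n_permutations),
                                    as.numeric(seed))
  names(imp) <- forest$feature_names
  imp
}

#' Features used as split variables anywhere in a forest
#'
#' @param forest a `pirf_forest`.
#' @return integer vector of feature indices (1-based).
#' @export
forest_used_features <- function(forest) {
  used <- unique(unlist(lapply(forest$trees, function(t) t$feature)))
  sort(used[used >= 0L]) + 1L
}
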