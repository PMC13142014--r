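#' Rank-based AUC from classification scores
#'
#' Mann--Whitney AUC of `scores` (probability of the positive class) against
#' binary labels, with the standard half-credit for ties.
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param labels factor or logical; the second factor level (or `TRUE`) is
#'   positive.
#' @return AUC in `[0, 1]`; `NA` if a class is absent.
#' @export
rank_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2L]
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Seeded cross-validation fold assignment
#'
#' Classification folds are stratified by class (each class is shuffled and
#' dealt round-robin across folds) so every training fold retains both
#' classes; regression folds are plain random.
#'
#' @param y outcome vector.
#' @param n_folds number of folds (default 5).
#' @param task `"classification"` or `"regression"`.
#' @param seed integer seed.
#' @return integer vector of fold indices in `1..n_folds`, one per sample.
#' @export
make_folds <- function(y, n_folds = 5L, task = c("classification", "regression"),
                       seed = 1L) {
  task <- match.arg(task)
  n <- length(y)
  if (n < n_folds) stop_validation("fewer samples than folds")
  folds <- integer(n)
  with_rng_seed(derive_seed(seed, "folds"), {
    if (task == "classification") {
      y <- as.factor(y)
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        folds[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
  })
  if (task == "classification") {
    y <- as.factor(y)
    for (f in seq_len(n_folds)) {
      train_classes <- unique(y[folds != f])
      if (length(train_classes) < nlevels(y))
        stop_validation("class absent from the training folds for fold ", f,
                        "; reduce the number of folds or rebalance the data")
    }
  }
  folds
}

#' Five-fold cross-validated performance of the full pipeline
#'
#' For each fold, the entire pipeline -- localized importance, probability
#' integration, mtry tuning, and final forest training -- is fit on the
#' training folds only, and the held-out fold is scored. The phylogeny
#' enters only through the tree (no outcome information), so clustering is
#' computed per fold from the training features as well. Quality filtering
#' and normalization of raw counts are applied to the full table up front
#' (they are per-sample operations plus a prevalence filter, applied
#' uniformly as in standard practice); set `control$preprocess = FALSE` to
#' skip.
#'
#' Metrics: misclassification rate and rank-based AUC of the averaged class
#' proportions (classification), or RMSE and MAE (regression); the report
#' carries per-fold values plus their mean and standard deviation.
#'
#' @param table feature table (samples x features; raw counts unless
#'   `control$preprocess` is `FALSE`).
#' @param tree phylogenetic tree covering the table's features.
#' @param y outcome vector.
#' @param task `"classification"` or `"regression"`.
#' @param n_folds number of folds (default 5).
#' @param control a [pirf_control()]; `clustering` selects the variant.
#' @param seed integer seed governing folds and per-fold pipeline seeds.
#' @param folds optional precomputed fold assignment (overrides `n_folds`).
#' @return an object of class `pirf_cv`: `metrics` (per-fold data frame),
#'   `summary` (mean and sd per metric), `folds`, `prob_variance` (variance
#'   of the selection-probability vector per fold), and `task`.
#' @export
run_cv <- function(table, tree, y, task = c("classification", "regression"),
                   n_folds = 5L, control = pirf_control(), seed = 1L,
                   folds = NULL) {
  task <- match.arg(task)
  table <- as_feature_matrix(table)
  if (is.null(colnames(table)))
    colnames(table) <- paste0("f", seq_len(ncol(table)))
  if (is.null(rownames(table)))
    rownames(table) <- paste0("s", seq_len(nrow(table)))
  if (nrow(table) < 10L) stop_validation("need at least 10 samples for CV")

  if (control$preprocess) {
    prep <- preprocess_table(table, min_reads = control$min_reads,
                             min_mean_abundance = control$min_mean_abundance)
    y <- y[rownames(table) %in% rownames(prep$table)]
    X <- prep$table
  } else {
    X <- table
  }
  inner <- control
  inner$preprocess <- FALSE

  if (!inherits(tree, "phylo")) tree <- read_tree_newick(tree)
  if (is.null(folds)) folds <- make_folds(y, n_folds, task, seed)
  n_folds <- max(folds)

  per_fold <- vector("list", n_folds)
  prob_var <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    train <- folds != f
    fit <- pirf_fit(X[train, , drop = FALSE], tree, y[train], task = task,
                    control = inner, seed = derive_seed(seed, "fold", f))
    prob_var[f] <- stats::var(fit$probabilities$w)
    Xtest <- X[!train, , drop = FALSE]
    if (task == "classification") {
      pr <- predict(fit, Xtest, type = "prob")
      pred <- factor(fit$classes[max.col(pr, ties.method = "first")],
                     levels = fit$classes)
      ytest <- factor(y[!train], levels = fit$classes)
      per_fold[[f]] <- data.frame(
        fold = f,
        error_rate = mean(pred != ytest),
        auc = rank_auc(pr[, 2L], ytest))
    } else {
      pred <- predict(fit, Xtest)
      err <- pred - as.numeric(y[!train])
      per_fold[[f]] <- data.frame(
        fold = f,
        rmse = sqrt(mean(err^2)),
        mae = mean(abs(err)))
    }
  }
  metrics <- do.call(rbind, per_fold)
  vals <- metrics[, -1L, drop = FALSE]
  structure(list(metrics = metrics,
                 summary = data.frame(metric = colnames(vals),
                                      mean = colMeans(vals),
                                      sd = apply(vals, 2L, stats::sd),
                                      row.names = NULL),
                 folds = folds,
                 prob_variance = prob_var,
                 task = task,
                 variant = control$clustering,
                 seed = as.integer(seed)),
            class = "pirf_cv")
}

#' @export
print.pirf_cv <- function(x, ...) {
  cat("Cross-validation (", length(unique(x$folds)), " folds, ", x$task,
      ", variant: ", x$variant, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare forest variants under shared cross-validation folds
#'
#' Runs [run_cv()] for the three probabilistic mechanisms -- the standard
#' uniform forest (fully disjoint clusters, k = p), globalized feature
#' weighting (one cluster, k = 1), and phylogeny-informed weighting
#' (silhouette-selected phylogenetic clusters) -- under identical fold
#' assignments and per-fold seeds, and reports the per-fold metrics together
#' with the variance of each variant's selection-probability vector. The
#' uniform variant's probability vector is exactly `1/p`, so its variance is
#' exactly zero; the one-cluster variant concentrates mass globally and
#' shows the largest variance; phylogenetic clusters sit in between.
#'
#' @inheritParams run_cv
#' @param variants subset of `c("pirf", "uniform", "onecluster")`.
#' @return list with `report` (long data frame: variant, fold, metrics,
#'   `prob_variance`), `summary` (per-variant means/sds), `folds`, and the
#'   per-variant `pirf_cv` objects in `cv`.
#' @export
compare_variants <- function(table, tree, y,
                             task = c("classification", "regression"),
                             n_folds = 5L, control = pirf_control(),
                             seed = 1L,
                             variants = c("pirf", "uniform", "onecluster")) {
  task <- match.arg(task)
  variants <- match.arg(variants, several.ok = TRUE)
  modes <- c(pirf = "phylo", uniform = "disjoint", onecluster = "single")
  folds <- make_folds(y, n_folds, task, seed)
  cv <- list()
  rows <- list()
  for (v in variants) {
    ctl <- control
    ctl$clustering <- modes[[v]]
    cv[[v]] <- run_cv(table, tree, y, task = task, control = ctl,
                      seed = seed, folds = folds)
    m <- cv[[v]]$metrics
    m$prob_variance <- cv[[v]]$prob_variance
    m <- cbind(variant = v, m)
    rows[[v]] <- m
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  vals <- setdiff(colnames(report), c("variant", "fold"))
  summary <- do.call(rbind, lapply(variants, function(v) {
    sub <- report[report$variant == v, vals, drop = FALSE]
    data.frame(variant = v, metric = vals, mean = colMeans(sub),
               sd = apply(sub, 2L, stats::sd), row.names = NULL)
  }))
  list(report = report, summary = summary, folds = folds, cv = cv)
}
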