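#' Control parameters for a phylogeny-informed random forest
#'
#' @param n_trees trees in the final, globally tuned forest. The default of
#'   10,000 matches common practice for OOB-based tuning on real microbiome
#'   tables; simulation studies and examples use far fewer.
#' @param n_trees_cluster trees per cluster-level forest used for localized
#'   permutation importance (default 1,000).
#' @param n_permutations permutations per tree and feature when computing
#'   importance (default 1).
#' @param k_range inclusive search range for the number of phylogenetic
#'   clusters (default `c(2, 10)`).
#' @param clustering `"phylo"` (default; PAM on the cophenetic distance
#'   matrix with silhouette-selected k), `"single"` (one community-level
#'   cluster, k = 1: globalized feature weighting), or `"disjoint"` (every
#'   feature its own cluster, k = p: this is exactly the standard uniform
#'   random forest, so the probability vector is set to 1/p directly and no
#'   localized importance is computed).
#' @param mtry_middle interpretation of the middle mtry candidate:
#'   `"sqrt"` (default) uses `ceiling(sqrt(q))`; `"literal"` uses
#'   `ceiling(q)`, i.e. all features, which collapses the candidate set and
#'   is provided only for comparison.
#' @param min_node_size minimal node size to split; `NULL` means the task
#'   default (1 for classification, 5 for regression).
#' @param preprocess apply the raw-count quality filters and
#'   relative-abundance normalization in [preprocess_table()]. Set to
#'   `FALSE` when the table is already filtered/normalized.
#' @param min_reads,min_mean_abundance preprocessing thresholds, see
#'   [preprocess_table()].
#' @param tree_missing how [align_tree_to_table()] treats table features
#'   absent from the tree (`"error"` or `"warn"`).
#' @return a list of class `pirf_control`.
#' @export
pirf_control <- function(n_trees = 10000L,
                         n_trees_cluster = 1000L,
                         n_permutations = 1L,
                         k_range = c(2L, 10L),
                         clustering = c("phylo", "single", "disjoint"),
                         mtry_middle = c("sqrt", "literal"),
                         min_node_size = NULL,
                         preprocess = TRUE,
                         min_reads = 2000,
                         min_mean_abundance = 1e-5,
                         tree_missing = c("error", "warn")) {
  structure(list(n_trees = as.integer(n_trees),
                 n_trees_cluster = as.integer(n_trees_cluster),
                 n_permutations = as.integer(n_permutations),
                 k_range = as.integer(k_range),
                 clustering = match.arg(clustering),
                 mtry_middle = match.arg(mtry_middle),
                 min_node_size = min_node_size,
                 preprocess = isTRUE(preprocess),
                 min_reads = min_reads,
                 min_mean_abundance = min_mean_abundance,
                 tree_missing = match.arg(tree_missing)),
            class = "pirf_control")
}

#' Quality-filter and normalize a raw-count feature table
#'
#' Applies the standard microbiome quality-control filters: samples with
#' 2,000 total reads or fewer are removed (retention requires strictly more
#' than `min_reads`), counts are converted to relative abundances (each row
#' sums to one), and features whose mean relative abundance is
#' `min_mean_abundance` or less are removed (strictly-greater retention).
#' Rows are renormalized over the retained features so the output rows sum
#' to one.
#'
#' @param counts numeric matrix of non-negative counts, samples in rows.
#' @param min_reads read-depth threshold (default 2,000; exclusive).
#' @param min_mean_abundance mean relative-abundance threshold (default
#'   0.00001; exclusive).
#' @return list with elements `table` (normalized matrix),
#'   `removed_samples`, `removed_features`, and `params`.
#' @export
preprocess_table <- function(counts, min_reads = 2000,
                             min_mean_abundance = 1e-5) {
  counts <- as_feature_matrix(counts)
  if (any(counts < 0)) stop_validation("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("f", seq_len(ncol(counts)))

  depth <- rowSums(counts)
  keep_s <- depth > min_reads
  if (!any(keep_s))
    stop_validation("every sample has ", min_reads,
                    " total reads or fewer; nothing left after filtering")
  removed_samples <- rownames(counts)[!keep_s]
  counts <- counts[keep_s, , drop = FALSE]

  rel <- counts / rowSums(counts)
  keep_f <- colMeans(rel) > min_mean_abundance
  if (!any(keep_f))
    stop_validation("every feature falls at or below the mean ",
                    "relative-abundance threshold; nothing left")
  removed_features <- colnames(rel)[!keep_f]
  rel <- rel[, keep_f, drop = FALSE]
  rel <- rel / rowSums(rel)

  list(table = rel,
       removed_samples = removed_samples,
       removed_features = removed_features,
       params = list(min_reads = min_reads,
                     min_mean_abundance = min_mean_abundance))
}

#' Candidate numbers of split-candidate features
#'
#' The three candidates for a feature set of size `q` are
#' `ceiling(q/10)`, `ceiling(sqrt(q))`, and `ceiling(log2(q))`, each clamped
#' to `[1, q]`, deduplicated, and sorted ascending. The middle candidate can
#' optionally be read literally as `ceiling(q)` (all features) via
#' `middle = "literal"`; see [pirf_control()].
#'
#' @param q number of features.
#' @param middle `"sqrt"` (default) or `"literal"`.
#' @return sorted integer vector of distinct candidates.
#' @export
mtry_candidates <- function(q, middle = c("sqrt", "literal")) {
  middle <- match.arg(middle)
  if (q < 1L) stop_validation("'q' must be >= 1")
  mid <- if (middle == "sqrt") ceiling(sqrt(q)) else ceiling(q)
  cand <- c(ceiling(q / 10), mid, if (q > 1) ceiling(log2(q)) else 1)
  sort(unique(pmin(pmax(as.integer(cand), 1L), as.integer(q))))
}

#' Localized permutation importance within each phylogenetic cluster
#'
#' For each cluster, the table is restricted to the cluster's features and
#' one forest per mtry candidate (see [mtry_candidates()]) is grown with
#' uniform within-cluster weights; OOB permutation importance is computed
#' per forest and averaged across the candidates. A singleton cluster gets
#' its score from a one-feature forest (the score may be near zero or
#' negative; the probability construction handles that downstream).
#'
#' @param X numeric matrix (samples x features), already normalized.
#' @param y outcome.
#' @param task `"classification"` or `"regression"`.
#' @param clusters a `pirf_clusters` assignment over the columns of `X`.
#' @param n_trees trees per cluster-level forest.
#' @param n_permutations permutations per tree and feature.
#' @param mtry_middle see [mtry_candidates()].
#' @param min_node_size passed to [grow_forest()].
#' @param seed integer seed; expanded deterministically per cluster and
#'   candidate.
#' @return named numeric vector of importance scores, one per column of `X`,
#'   with attribute `"per_cluster"` listing the per-cluster score vectors.
#' @export
cluster_importance_scores <- function(X, y, task, clusters,
                                      n_trees = 1000L, n_permutations = 1L,
                                      mtry_middle = "sqrt",
                                      min_node_size = NULL, seed = 1L) {
  X <- as_feature_matrix(X)
  if (length(clusters$cluster_of) != ncol(X) ||
      !identical(clusters$labels, colnames(X)))
    stop_validation("cluster assignment does not match the table's features")
  scores <- stats::setNames(numeric(ncol(X)), colnames(X))
  per_cluster <- vector("list", clusters$k)
  for (k in seq_len(clusters$k)) {
    members <- which(clusters$cluster_of == k)
    q <- length(members)
    Xk <- X[, members, drop = FALSE]
    cands <- mtry_candidates(q, middle = mtry_middle)
    acc <- numeric(q)
    for (ci in seq_along(cands)) {
      fs <- derive_seed(seed, "cluster_importance", k * 131L + ci)
      forest <- grow_forest(Xk, y, task = task, n_trees = n_trees,
                            mtry = cands[ci], min_node_size = min_node_size,
                            seed = fs)
      acc <- acc + permutation_importance(forest, Xk, y,
                                          n_permutations = n_permutations,
                                          seed = fs)
    }
    sk <- acc / length(cands)
    scores[members] <- sk
    per_cluster[[k]] <- sk
  }
  attr(scores, "per_cluster") <- per_cluster
  scores
}

#' Community-level feature selection probabilities
#'
#' Converts cluster-local importance scores into the unit-sum probability
#' vector that drives weighted split-candidate sampling. Negative scores are
#' clipped to zero (feature elimination); within each cluster the clipped
#' scores are normalized to cluster-specific probabilities
#' `v_j = s_j / sum(s)`, and each is then multiplied by the cluster's size
#' share `q_k / p`, so every feature has an equal opportunity of being
#' weighted regardless of its cluster's size and the community-level vector
#' `w` sums to one.
#'
#' A cluster whose clipped scores are all zero is degenerate: its features
#' receive probability zero, and the full vector is renormalized at the end,
#' preserving the relative masses of the remaining clusters. If every
#' cluster is degenerate the vector falls back to uniform `1/p` with a
#' warning.
#'
#' Boundary cases: with fully disjoint clusters (k = p) every `v_j = 1` and
#' `w` is exactly uniform (the standard random forest); with one cluster
#' (k = 1) `w` is the clipped, normalized global importance vector.
#'
#' @param scores named numeric vector of importance scores (one per feature,
#'   in table column order).
#' @param clusters the `pirf_clusters` assignment the scores were computed
#'   under.
#' @return an object of class `pirf_probs` with elements `labels`, `w`,
#'   `v`, `cluster_of`, `cluster_sizes`, `p`, `p_prime`, and
#'   `degenerate_clusters`.
#' @export
compute_probabilities <- function(scores, clusters) {
  p <- length(clusters$cluster_of)
  if (length(scores) != p)
    stop_validation("need exactly one score per feature")
  s <- pmax(as.numeric(scores), 0)
  v <- numeric(p)
  w <- numeric(p)
  degenerate <- integer(0)
  for (k in seq_len(clusters$k)) {
    members <- which(clusters$cluster_of == k)
    if (clusters$k == p) {
      # fully disjoint clusters: uniform selection regardless of scores
      v[members] <- 1
      w[members] <- 1 / p
      next
    }
    tot <- sum(s[members])
    if (tot > 0) {
      v[members] <- s[members] / tot
      w[members] <- v[members] * (length(members) / p)
    } else {
      degenerate <- c(degenerate, k)
    }
  }
  if (sum(w) <= 0) {
    warning("all clusters have non-positive importance everywhere; ",
            "falling back to uniform selection probabilities")
    w <- rep(1 / p, p)
    v <- rep(1, p) # degenerate fallback: no within-cluster contrast
  } else {
    w <- w / sum(w)
  }
  structure(list(labels = clusters$labels,
                 w = stats::setNames(w, clusters$labels),
                 v = stats::setNames(v, clusters$labels),
                 cluster_of = clusters$cluster_of,
                 cluster_sizes = clusters$cluster_sizes,
                 p = p,
                 p_prime = sum(w > 0),
                 degenerate_clusters = degenerate),
            class = "pirf_probs")
}

#' @export
print.pirf_probs <- function(x, ...) {
  cat("Community-level selection probabilities over ", x$p, " features\n",
      "  non-zero: ", x$p_prime, "   sum: ", format(sum(x$w)),
      "   variance: ", format(stats::var(x$w)), "\n", sep = "")
  invisible(x)
}

#' Tune the global mtry by out-of-bag error
#'
#' Evaluates the candidates from [mtry_candidates()] computed on `p'` (the
#' number of features with non-zero selection probability) by growing one
#' forest per candidate with the community-level weights and comparing OOB
#' error; returns the candidate with minimal OOB error, ties toward the
#' smaller candidate.
#'
#' @param X,y,task training data and task.
#' @param probs a `pirf_probs` object.
#' @param n_trees trees per candidate forest.
#' @param mtry_middle see [mtry_candidates()].
#' @param min_node_size passed to [grow_forest()].
#' @param seed integer seed.
#' @return the selected mtry (integer) with attribute `"oob_by_candidate"`.
#' @export
tune_global_mtry <- function(X, y, task, probs, n_trees = 1000L,
                             mtry_middle = "sqrt", min_node_size = NULL,
                             seed = 1L) {
  if (probs$p_prime < 1L) stop_validation("no feature has positive probability")
  cands <- mtry_candidates(probs$p_prime, middle = mtry_middle)
  oob <- numeric(length(cands))
  for (ci in seq_along(cands)) {
    fs <- derive_seed(seed, "tune_mtry", ci)
    forest <- grow_forest(X, y, task = task, n_trees = n_trees,
                          mtry = cands[ci], weights = probs$w,
                          min_node_size = min_node_size, seed = fs)
    oob[ci] <- oob_error(forest, X, y)
  }
  best <- cands[which.min(oob)] # candidates ascending: ties toward smaller
  attr(best, "oob_by_candidate") <- stats::setNames(oob, cands)
  best
}

#' Fit a phylogeny-informed random forest
#'
#' The full pipeline: (optional) quality filtering and relative-abundance
#' normalization, pruning the tree to the table's features, cophenetic
#' distances, silhouette-selected PAM clustering, localized permutation
#' importance per cluster, integration into community-level selection
#' probabilities, OOB tuning of the global mtry, and growing the final
#' weighted forest.
#'
#' Only binary classification and numeric regression are supported;
#' multiclass outcomes are rejected.
#'
#' @param table numeric matrix, samples in rows, features in columns (raw
#'   counts by default; set `control$preprocess = FALSE` for pre-normalized
#'   input).
#' @param tree phylogenetic tree ([ape::phylo] or a path/string accepted by
#'   [read_tree_newick()]) whose leaves cover the table's features.
#' @param y outcome vector, one per table row (before filtering).
#' @param task `"classification"` or `"regression"`.
#' @param control a [pirf_control()] list.
#' @param seed single integer seed; expanded deterministically into
#'   per-stage seeds so any stage is independently reproducible.
#' @return an object of class `pirf` containing the cluster assignment,
#'   selection probabilities, tuned mtry, and final forest.
#' @export
pirf_fit <- function(table, tree, y, task = c("classification", "regression"),
                     control = pirf_control(), seed = 1L) {
  task <- match.arg(task)
  stopifnot(inherits(control, "pirf_control"))
  table <- as_feature_matrix(table)
  if (is.null(colnames(table)))
    colnames(table) <- paste0("f", seq_len(ncol(table)))
  if (length(y) != nrow(table))
    stop_validation("length of 'y' (", length(y),
                    ") does not match the number of samples (", nrow(table), ")")
  if (task == "classification") {
    y <- as.factor(y)
    y <- factor(y, levels = sort(levels(y)))
    if (nlevels(y) != 2L)
      stop_validation("only binary classification is supported; outcome has ",
                      nlevels(y), " class(es): ",
                      paste(levels(y), collapse = ", "))
  } else {
    y <- as.numeric(y)
  }

  # stage: preprocessing
  if (is.null(rownames(table)))
    rownames(table) <- paste0("s", seq_len(nrow(table)))
  if (control$preprocess) {
    prep <- preprocess_table(table, min_reads = control$min_reads,
                             min_mean_abundance = control$min_mean_abundance)
    y <- y[rownames(table) %in% rownames(prep$table)]
    X <- prep$table
  } else {
    prep <- list(removed_samples = character(0),
                 removed_features = character(0), params = NULL)
    X <- table
  }
  if (task == "classification" && nlevels(droplevels(y)) != 2L)
    stop_validation("preprocessing removed all samples of one class")

  # stage: tree alignment and distances
  if (!inherits(tree, "phylo")) tree <- read_tree_newick(tree)
  tree <- align_tree_to_table(tree, colnames(X), missing = control$tree_missing)
  X <- X[, intersect(colnames(X), tree$tip.label), drop = FALSE]
  D <- cophenetic_matrix(tree)[colnames(X), colnames(X)]

  # stage: clustering
  p <- ncol(X)
  clusters <- switch(control$clustering,
    phylo = select_k_phylo(D, k_range = control$k_range),
    single = pam_clusters(D, 1L),
    disjoint = pam_clusters(D, p))

  # stages: localized importance and probability integration
  if (control$clustering == "disjoint") {
    # exact boundary reduction: k = p is the standard uniform forest
    scores <- stats::setNames(rep(NA_real_, p), colnames(X))
    probs <- compute_probabilities(rep(1, p), clusters)
  } else {
    scores <- cluster_importance_scores(
      X, y, task, clusters,
      n_trees = control$n_trees_cluster,
      n_permutations = control$n_permutations,
      mtry_middle = control$mtry_middle,
      min_node_size = control$min_node_size,
      seed = derive_seed(seed, "importance"))
    probs <- compute_probabilities(scores, clusters)
  }

  # stage: global mtry tuning
  mtry <- tune_global_mtry(X, y, task, probs,
                           n_trees = control$n_trees,
                           mtry_middle = control$mtry_middle,
                           min_node_size = control$min_node_size,
                           seed = derive_seed(seed, "tuning"))

  # stage: final forest
  forest <- grow_forest(X, y, task = task, n_trees = control$n_trees,
                        mtry = mtry, weights = probs$w,
                        min_node_size = control$min_node_size,
                        seed = derive_seed(seed, "final_forest"))

  structure(list(clusters = clusters,
                 probabilities = probs,
                 importance_scores = scores,
                 mtry = as.integer(mtry),
                 mtry_oob = attr(mtry, "oob_by_candidate"),
                 forest = forest,
                 task = task,
                 feature_names = colnames(X),
                 classes = if (task == "classification") levels(y) else NULL,
                 preprocessing = list(applied = control$preprocess,
                                      removed_samples = prep$removed_samples,
                                      removed_features = prep$removed_features,
                                      params = prep$params),
                 control = control,
                 seed = as.integer(seed),
                 version = as.character(utils::packageVersion("pirf"))),
            class = "pirf")
}

#' @export
print.pirf <- function(x, ...) {
  cat("Phylogeny-informed random forest (", x$task, ")\n", sep = "")
  cat("  features: ", length(x$feature_names),
      "   clusters: k = ", x$clusters$k, sep = "")
  if (!is.na(x$clusters$avg_silhouette))
    cat(" (avg silhouette ", signif(x$clusters$avg_silhouette, 4), ")", sep = "")
  cat("\n  non-zero selection probabilities: ", x$probabilities$p_prime,
      "   tuned mtry: ", x$mtry,
      "   trees: ", x$forest$n_trees, "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted phylogeny-informed random forest
#'
#' Applies the model's stored normalization convention (rows of the new
#' table are renormalized to relative abundances over the model's features)
#' and the final forest; clusters, probabilities, and mtry are reused, not
#' recomputed. Extra features in the new table are dropped with a warning;
#' missing model features are an error.
#'
#' @param object a fitted `pirf` model.
#' @param newdata numeric matrix, samples in rows.
#' @param type `"response"` or, for classification, `"prob"`.
#' @param ... unused.
#' @export
predict.pirf <- function(object, newdata, type = c("response", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as_feature_matrix(newdata)
  if (is.null(colnames(newdata)) && ncol(newdata) == length(object$feature_names))
    colnames(newdata) <- object$feature_names
  missing <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing) > 0L)
    stop_validation("new table lacks model features: ",
                    paste(utils::head(missing, 10L), collapse = ", "),
                    if (length(missing) > 10L) ", ..." else "")
  extra <- setdiff(colnames(newdata), object$feature_names)
  if (length(extra) > 0L)
    warning("dropping ", length(extra), " feature(s) not in the model")
  newdata <- newdata[, object$feature_names, drop = FALSE]
  if (isTRUE(object$preprocessing$applied)) {
    rs <- rowSums(newdata)
    if (any(rs <= 0)) stop_validation("new table has sample(s) with zero total abundance")
    newdata <- newdata / rs
  }
  predict(object$forest, newdata, type = type)
}
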