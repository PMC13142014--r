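# Independent oracles and small fixtures used across the suite. These
# deliberately re-derive quantities by brute force / direct formula rather
# than calling the code paths they check.

# path-sum oracle: distance between two leaves is the total length of the
# edges in the symmetric difference of their root paths
brute_cophenetic <- function(tree) {
  p <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  parent <- integer(n_nodes)
  elen <- numeric(n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path_of <- function(tip) {
    out <- integer(0)
    node <- tip
    while (node != root) {
      out <- c(out, node)
      node <- parent[node]
    }
    out
  }
  paths <- lapply(seq_len(p), path_of)
  D <- matrix(0, p, p, dimnames = list(tree$tip.label, tree$tip.label))
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      sym <- c(setdiff(paths[[a]], paths[[b]]),
               setdiff(paths[[b]], paths[[a]]))
      D[a, b] <- D[b, a] <- sum(elen[sym])
    }
  }
  D
}

# total distance of every point to the medoid of its cluster
pam_cost <- function(dist, medoid_idx) {
  sum(apply(dist[, medoid_idx, drop = FALSE], 1, min))
}

# globally optimal 2-medoid cost by enumerating all medoid pairs
exhaustive_pam2_cost <- function(dist) {
  p <- nrow(dist)
  best <- Inf
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      cost <- pam_cost(dist, c(a, b))
      if (cost < best) best <- cost
    }
  }
  best
}

# per-point silhouette recomputation with explicit loops
silhouette_oracle <- function(dist, cluster_of) {
  p <- nrow(dist)
  s <- numeric(p)
  for (i in seq_len(p)) {
    own <- setdiff(which(cluster_of == cluster_of[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(dist[i, own])
    b <- Inf
    for (g in setdiff(unique(cluster_of), cluster_of[i])) {
      b <- min(b, mean(dist[i, cluster_of == g]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# exhaustive best split over all features and midpoints, mirroring the
# engine's objective and tie rules (lower feature, then lower threshold)
best_split_oracle <- function(X, y, task) {
  n <- nrow(X)
  best <- list(dec = -Inf, feature = NA_integer_, threshold = NA_real_)
  impurity <- function(yy) {
    if (task == "classification") {
      pr <- table(yy) / length(yy)
      1 - sum(pr^2)
    } else {
      mean((yy - mean(yy))^2)
    }
  }
  parent <- impurity(y)
  for (f in seq_len(ncol(X))) {
    v <- sort(unique(X[, f]))
    if (length(v) < 2) next
    for (i in seq_len(length(v) - 1)) {
      thr <- v[i] + (v[i + 1] - v[i]) / 2
      left <- X[, f] <= thr
      dec <- parent - sum(left) / n * impurity(y[left]) -
        sum(!left) / n * impurity(y[!left])
      if (dec > best$dec + 1e-12) {
        best <- list(dec = dec, feature = f, threshold = thr)
      }
    }
  }
  best
}

# pure-R traversal of a stored tree, for checking C++ predictions
predict_tree_r <- function(tree, X, task, classes = NULL) {
  n <- nrow(X)
  out <- if (task == "classification") character(n) else numeric(n)
  for (i in seq_len(n)) {
    node <- 1L
    while (tree$feature[node] >= 0L) {
      f <- tree$feature[node] + 1L
      node <- if (X[i, f] <= tree$threshold[node]) tree$left[node] + 1L
              else tree$right[node] + 1L
    }
    out[i] <- if (task == "classification") classes[tree$pred[node] + 1L]
              else tree$pred[node]
  }
  out
}

# manual cluster assignment builder for probability-algebra fixtures
make_clusters <- function(cluster_of, labels = names(cluster_of),
                          medoids = NULL) {
  if (is.null(labels)) labels <- paste0("f", seq_along(cluster_of))
  names(cluster_of) <- labels
  if (is.null(medoids))
    medoids <- labels[!duplicated(cluster_of)][order(unique(cluster_of))]
  pirf:::new_clusters(labels, as.integer(cluster_of), medoids)
}

# six points on a line in two tight groups; distances are absolute
# differences
line_groups_dist <- function() {
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(paste0("f", 1:6), paste0("f", 1:6))
  d
}

# random distance matrix from points on a line (valid metric, generic ties)
random_line_dist <- function(p, seed) {
  x <- withr::with_seed(seed, stats::runif(p, 0, 10))
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(paste0("f", seq_len(p)), paste0("f", seq_len(p)))
  d
}

random_tree <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 2)
    tr
  })
}
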