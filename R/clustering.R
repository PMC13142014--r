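#' Partition features into clusters around medoids
#'
#' Thin wrapper around the Kaufman--Rousseeuw PAM algorithm (BUILD
#' initialization followed by SWAP passes; deterministic, no random
#' restarts) from the \pkg{cluster} package, applied to a precomputed
#' distance matrix. The two boundary values of `k` are handled directly:
#' `k = 1` places every feature in one cluster around the medoid minimizing
#' total distance (exhaustively optimal), and `k = p` makes every feature
#' its own cluster/medoid.
#'
#' @param dist square symmetric distance matrix with zero diagonal, labelled
#'   rows/columns.
#' @param k number of clusters, `1 <= k <= p`.
#' @return an object of class `pirf_clusters` with elements `labels`,
#'   `cluster_of` (named integer vector in `1..k`), `medoids` (one feature
#'   label per cluster), `k`, `cluster_sizes`, and `avg_silhouette`
#'   (`NA` until computed).
#' @export
pam_clusters <- function(dist, k) {
  dist <- validate_distance_matrix(dist)
  p <- nrow(dist)
  labels <- rownames(dist)
  if (k < 1L || k > p)
    stop_validation("'k' must be between 1 and the number of features (", p, ")")

  if (k == p) {
    cluster_of <- seq_len(p)
    medoids <- labels
  } else if (k == 1L) {
    medoid_idx <- which.min(rowSums(dist))
    cluster_of <- rep(1L, p)
    medoids <- labels[medoid_idx]
  } else {
    fit <- cluster::pam(stats::as.dist(dist), k = k, diss = TRUE)
    cluster_of <- as.integer(fit$clustering)
    medoids <- labels[fit$id.med]
  }
  names(cluster_of) <- labels
  new_clusters(labels, cluster_of, medoids)
}

new_clusters <- function(labels, cluster_of, medoids,
                         avg_silhouette = NA_real_) {
  sizes <- as.integer(tabulate(cluster_of, nbins = length(medoids)))
  if (any(sizes == 0L)) stop("empty cluster in assignment")
  structure(list(labels = labels,
                 cluster_of = cluster_of,
                 medoids = medoids,
                 k = length(medoids),
                 cluster_sizes = sizes,
                 avg_silhouette = avg_silhouette),
            class = "pirf_clusters")
}

validate_distance_matrix <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    stop_validation("'dist' must be a square distance matrix")
  if (anyNA(dist) || any(dist < 0))
    stop_validation("'dist' must be non-negative with no missing values")
  if (max(abs(dist - t(dist))) > 1e-8)
    stop_validation("'dist' must be symmetric")
  if (is.null(rownames(dist)))
    rownames(dist) <- colnames(dist) <- paste0("f", seq_len(nrow(dist)))
  dist
}

#' Average silhouette width of a cluster assignment
#'
#' For each feature i, `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, where
#' `a(i)` is the mean distance from i to the other members of its cluster
#' and `b(i)` is the smallest mean distance from i to the members of any
#' other cluster. Features in singleton clusters contribute `s(i) = 0`
#' (Rousseeuw's convention). The average over all features measures how well
#' each feature fits its own cluster relative to the others and always lies
#' in `[-1, 1]`.
#'
#' @param dist square symmetric distance matrix.
#' @param clusters a `pirf_clusters` assignment with `k >= 2`.
#' @return the mean silhouette width (scalar).
#' @export
avg_silhouette_width <- function(dist, clusters) {
  dist <- validate_distance_matrix(dist)
  cl <- clusters$cluster_of
  k <- clusters$k
  if (k < 2L)
    stop_validation("silhouette width is undefined for a single cluster")
  p <- nrow(dist)
  # mean distance from each point to each cluster
  sizes <- tabulate(cl, nbins = k)
  cluster_sums <- sapply(seq_len(k), function(g)
    rowSums(dist[, cl == g, drop = FALSE]))
  s <- numeric(p)
  for (i in seq_len(p)) {
    g <- cl[i]
    if (sizes[g] == 1L) { s[i] <- 0; next }
    a <- cluster_sums[i, g] / (sizes[g] - 1L)
    b <- min(cluster_sums[i, -g] / sizes[-g])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Choose the number of phylogenetic clusters by silhouette
#'
#' Runs PAM for each candidate number of clusters and returns the assignment
#' maximizing the average silhouette width; ties break toward the smaller
#' number of clusters. The default search range of 2--10 clusters reflects
#' the regime of feature tables much wider than 10; for small tables the
#' upper end is capped at `p - 1` (at `k = p` every feature is its own
#' singleton and the silhouette degenerates).
#'
#' @param dist square symmetric distance matrix over `p >= 3` features.
#' @param k_range integer vector of length 2, the inclusive search range
#'   (default `c(2, 10)`).
#' @return a `pirf_clusters` assignment with `avg_silhouette` filled in and
#'   attribute `"silhouette_by_k"` holding the profile over the range.
#' @export
select_k_phylo <- function(dist, k_range = c(2L, 10L)) {
  dist <- validate_distance_matrix(dist)
  p <- nrow(dist)
  if (p < 3L)
    stop_validation("need at least 3 features to select a clustering; got ", p)
  ks <- seq.int(max(2L, k_range[1]), min(k_range[2], p - 1L))
  if (length(ks) == 0L)
    stop_validation("empty cluster-number search range")
  fits <- lapply(ks, function(k) pam_clusters(dist, k))
  sil <- vapply(fits, function(f) avg_silhouette_width(dist, f), numeric(1))
  best <- which.max(sil) # first maximum: ties toward smaller k
  out <- fits[[best]]
  out$avg_silhouette <- sil[best]
  attr(out, "silhouette_by_k") <- stats::setNames(sil, ks)
  out
}

#' @export
print.pirf_clusters <- function(x, ...) {
  cat("Feature clustering: k = ", x$k, ", sizes = ",
      paste(x$cluster_sizes, collapse = "/"), sep = "")
  if (!is.na(x$avg_silhouette))
    cat(", avg silhouette = ", signif(x$avg_silhouette, 4), sep = "")
  cat("\n")
  invisible(x)
}

#' Export a feature-to-cluster assignment as a data frame
#'
#' @param clusters a `pirf_clusters` assignment.
#' @return data frame with columns `feature`, `cluster`, `is_medoid`.
#' @export
clusters_as_data_frame <- function(clusters) {
  data.frame(feature = clusters$labels,
             cluster = as.integer(clusters$cluster_of),
             is_medoid = clusters$labels %in% clusters$medoids,
             row.names = NULL, stringsAsFactors = FALSE)
}
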