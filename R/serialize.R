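# JSON model serialization. Numbers are written with 17 significant digits
# so double-precision values round-trip exactly and a reloaded model gives
# bit-identical predictions.

forest_to_serializable <- function(forest) {
  list(object = "pirf_forest",
       task = forest$task,
       classes = forest$classes,
       n_trees = forest$n_trees,
       mtry = forest$mtry,
       min_node_size = forest$min_node_size,
       weights = as.numeric(forest$weights),
       feature_names = forest$feature_names,
       n = forest$n, p = forest$p,
       seed = forest$seed,
       trees = lapply(forest$trees, function(t) {
         out <- list(feature = as.integer(t$feature),
                     threshold = as.numeric(t$threshold),
                     left = as.integer(t$left),
                     right = as.integer(t$right),
                     pred = as.numeric(t$pred),
                     oob = as.integer(t$oob))
         if (!is.null(t$probs)) out$probs <- t$probs
         out
       }))
}

forest_from_serializable <- function(x) {
  classification <- identical(x$task, "classification")
  trees <- lapply(x$trees, function(t) {
    tl <- list(feature = as.integer(t$feature),
               threshold = as.numeric(t$threshold),
               left = as.integer(t$left),
               right = as.integer(t$right),
               pred = as.numeric(t$pred))
    if (classification) {
      pm <- t$probs
      if (!is.matrix(pm)) pm <- matrix(unlist(pm), nrow = length(tl$feature))
      tl$probs <- pm
    }
    tl$oob <- as.integer(t$oob)
    tl
  })
  structure(list(trees = trees,
                 task = x$task,
                 classes = unlist_or_null(x$classes),
                 n_trees = as.integer(x$n_trees),
                 mtry = as.integer(x$mtry),
                 min_node_size = as.integer(x$min_node_size),
                 weights = as.numeric(x$weights),
                 feature_names = unlist_or_null(x$feature_names),
                 n = as.integer(x$n), p = as.integer(x$p),
                 seed = as.integer(x$seed)),
            class = "pirf_forest")
}

unlist_or_null <- function(x) if (is.null(x) || length(x) == 0L) NULL else unlist(x)

clusters_to_serializable <- function(cl) {
  list(labels = cl$labels,
       cluster_of = as.integer(cl$cluster_of),
       medoids = cl$medoids,
       k = cl$k,
       avg_silhouette = cl$avg_silhouette)
}

clusters_from_serializable <- function(x) {
  cl_of <- stats::setNames(as.integer(x$cluster_of), unlist(x$labels))
  out <- new_clusters(unlist(x$labels), cl_of, unlist(x$medoids),
                      avg_silhouette = as.numeric(x$avg_silhouette))
  out
}

#' Save a fitted model to a JSON file
#'
#' Serializes a `pirf` model (or a bare `pirf_forest`) to a documented
#' JSON format: tree node arrays (split feature, threshold, children, leaf
#' predictions and class proportions, out-of-bag indices), the selection
#' probability vector, cluster assignment, tuned parameters, and seeds.
#' Doubles are written with 17 significant digits so reloaded models
#' reproduce predictions bit-for-bit.
#'
#' @param model a `pirf` or `pirf_forest` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [pirf_load()]
#' @export
pirf_save <- function(model, path) {
  if (inherits(model, "pirf_forest")) {
    payload <- forest_to_serializable(model)
  } else if (inherits(model, "pirf")) {
    payload <- list(object = "pirf",
                    task = model$task,
                    classes = model$classes,
                    feature_names = model$feature_names,
                    mtry = model$mtry,
                    mtry_oob = as.list(model$mtry_oob),
                    seed = model$seed,
                    version = model$version,
                    clusters = clusters_to_serializable(model$clusters),
                    probabilities = list(
                      w = as.numeric(model$probabilities$w),
                      v = as.numeric(model$probabilities$v),
                      p_prime = model$probabilities$p_prime,
                      degenerate_clusters = model$probabilities$degenerate_clusters),
                    importance_scores = as.numeric(model$importance_scores),
                    preprocessing = model$preprocessing,
                    control = unclass(model$control),
                    forest = forest_to_serializable(model$forest))
  } else {
    stop_validation("'model' must be a 'pirf' or 'pirf_forest' object")
  }
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a model saved by [pirf_save()]
#'
#' @param path path to a JSON model file.
#' @return the reconstructed `pirf` or `pirf_forest` object.
#' @export
pirf_load <- function(path) {
  if (!file.exists(path)) stop_validation("model file not found: ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                          simplifyDataFrame = FALSE)
  if (identical(x$object, "pirf_forest")) return(forest_from_serializable(x))
  if (!identical(x$object, "pirf"))
    stop_validation("not a recognized model file: ", path)
  clusters <- clusters_from_serializable(x$clusters)
  labels <- unlist(x$feature_names)
  probs <- structure(list(labels = labels,
                          w = stats::setNames(as.numeric(x$probabilities$w), labels),
                          v = stats::setNames(as.numeric(x$probabilities$v), labels),
                          cluster_of = clusters$cluster_of,
                          cluster_sizes = clusters$cluster_sizes,
                          p = length(labels),
                          p_prime = as.integer(x$probabilities$p_prime),
                          degenerate_clusters =
                            as.integer(unlist_or_null(x$probabilities$degenerate_clusters))),
                     class = "pirf_probs")
  control <- x$control
  control$k_range <- as.integer(control$k_range)
  class(control) <- "pirf_control"
  structure(list(clusters = clusters,
                 probabilities = probs,
                 importance_scores = stats::setNames(
                   as.numeric(x$importance_scores), labels),
                 mtry = as.integer(x$mtry),
                 mtry_oob = unlist(x$mtry_oob),
                 forest = forest_from_serializable(x$forest),
                 task = x$task,
                 feature_names = labels,
                 classes = unlist_or_null(x$classes),
                 preprocessing = x$preprocessing,
                 control = control,
                 seed = as.integer(x$seed),
                 version = x$version),
            class = "pirf")
}
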