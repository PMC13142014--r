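#' Read and validate a phylogenetic tree from a Newick file or string
#'
#' Parses a single Newick tree (via \pkg{ape}) and validates it for use as a
#' phylogeny over microbial features: leaf labels must be unique and
#' non-empty (labels are whitespace-trimmed), and every edge must carry a
#' non-negative branch length -- cophenetic distances are undefined
#' otherwise, so missing lengths are an error rather than silently defaulted.
#' Unrooted trees (basal polytomy) and polytomies in general are accepted:
#' path-length distances do not depend on the root placement.
#'
#' @param source path to a Newick file, or a character string containing a
#'   Newick tree terminated by `";"`.
#' @return an [ape::phylo] tree.
#' @export
read_tree_newick <- function(source) {
  txt <- if (length(source) == 1L && !grepl("(", source, fixed = TRUE) &&
             file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "")
  } else {
    paste(as.character(source), collapse = "")
  }
  check_newick_syntax(txt)
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop_validation("failed to parse Newick: ",
                                        conditionMessage(e)))
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop_validation("failed to parse Newick: no tree found in input")
  validate_tree(tree)
}

# cheap structural pre-check so malformed input gets a positional message
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop_validation("malformed Newick: unmatched ')' at position ", i)
    }
  }
  if (depth > 0L)
    stop_validation("malformed Newick: ", depth,
                    " unclosed '(' by end of input")
  if (!grepl(";", txt, fixed = TRUE))
    stop_validation("malformed Newick: no terminating ';' found")
  invisible(txt)
}

#' Validate a phylogenetic tree for distance computation
#'
#' @param tree an [ape::phylo] object.
#' @return the tree, with whitespace-trimmed tip labels.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop_validation("'tree' must be an ape 'phylo' object")
  tree$tip.label <- trimws(tree$tip.label)
  if (any(!nzchar(tree$tip.label)))
    stop_validation("tree has empty leaf labels")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L)
    stop_validation("duplicate leaf labels in tree: ",
                    paste(dup, collapse = ", "))
  if (is.null(tree$edge.length))
    stop_validation("tree has no branch lengths; cophenetic distances are undefined")
  if (length(tree$edge.length) != nrow(tree$edge) || anyNA(tree$edge.length))
    stop_validation("tree has edges without branch lengths; ",
                    "cophenetic distances are undefined")
  if (any(tree$edge.length < 0))
    stop_validation("tree has negative branch lengths")
  tree
}

#' Cophenetic (patristic) distance matrix among the leaves of a tree
#'
#' Entry (a, b) is the total branch length along the unique path connecting
#' leaves a and b through their most recent common ancestor. Rows and
#' columns follow the tree's tip-label order.
#'
#' @param tree a validated [ape::phylo] tree with at least two leaves.
#' @return symmetric numeric matrix with zero diagonal, labelled by leaf.
#' @export
cophenetic_matrix <- function(tree) {
  tree <- validate_tree(tree)
  if (length(tree$tip.label) < 2L)
    stop_validation("tree has fewer than 2 leaves; no pairwise distances exist")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Prune a tree to the features of an abundance table
#'
#' @param tree a validated [ape::phylo] tree.
#' @param features character vector of feature identifiers (table columns).
#' @param missing what to do when some features are absent from the tree:
#'   `"error"` (default; the absent features are named) or `"warn"` (they
#'   are dropped from consideration with a warning).
#' @return the tree pruned to exactly the features present in both.
#' @export
align_tree_to_table <- function(tree, features,
                                missing = c("error", "warn")) {
  missing <- match.arg(missing)
  tree <- validate_tree(tree)
  features <- trimws(as.character(features))
  common <- intersect(tree$tip.label, features)
  if (length(common) == 0L)
    stop_validation("no overlap between tree leaves and table features")
  absent <- setdiff(features, tree$tip.label)
  if (length(absent) > 0L) {
    msg <- paste0(length(absent), " table feature(s) absent from the tree: ",
                  paste(utils::head(absent, 10L), collapse = ", "),
                  if (length(absent) > 10L) ", ..." else "")
    if (missing == "error") stop_validation(msg) else warning(msg)
  }
  if (length(common) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, common)
}
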