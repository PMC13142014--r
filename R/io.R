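#' Read a feature abundance table from TSV/CSV
#'
#' The first column holds sample identifiers and the header row holds
#' feature identifiers (use `orientation = "features_in_rows"` for the
#' transposed layout). The delimiter is inferred from the file extension
#' (`.csv` means comma, anything else tab).
#'
#' @param path file path.
#' @param orientation `"samples_in_rows"` (default) or
#'   `"features_in_rows"`.
#' @return numeric matrix, samples in rows, features in columns.
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_in_rows",
                                               "features_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop_validation("feature table needs an ID column plus >= 1 feature: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop_validation("non-numeric values in feature table: ", path)
  rownames(m) <- ids
  if (orientation == "features_in_rows") m <- t(m)
  m
}

#' Read an outcome vector from a TSV/CSV metadata file
#'
#' @param path file path; the delimiter is inferred from the extension.
#' @param outcome name of the outcome column.
#' @param sample_col name of the sample-ID column (default: first column).
#' @return vector of outcomes named by sample identifier.
#' @export
read_outcome <- function(path, outcome, sample_col = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(sample_col)) sample_col <- colnames(df)[1L]
  if (!sample_col %in% colnames(df))
    stop_validation("sample column '", sample_col, "' not found in ", path)
  if (!outcome %in% colnames(df))
    stop_validation("outcome column '", outcome, "' not found in ", path,
                    " (available: ", paste(colnames(df), collapse = ", "), ")")
  stats::setNames(df[[outcome]], as.character(df[[sample_col]]))
}

# match an outcome vector to a table's samples, by name when possible
match_outcome <- function(y, table) {
  if (!is.null(names(y)) && !is.null(rownames(table))) {
    missing <- setdiff(rownames(table), names(y))
    if (length(missing) > 0L)
      stop_validation("no outcome for sample(s): ",
                      paste(utils::head(missing, 5L), collapse = ", "))
    y <- y[rownames(table)]
  } else if (length(y) != nrow(table)) {
    stop_validation("outcome length does not match the number of samples")
  }
  y
}
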