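#' Construct a two-class expression dataset
#'
#' The universal input container of the package: a numeric matrix with samples
#' as rows and genes as columns, a binary class label per sample, and unique
#' identifiers for both dimensions. All downstream scoring, selection and
#' evaluation functions operate on this object.
#'
#' @param values numeric matrix, samples x genes; all entries must be finite.
#' @param labels vector of length `nrow(values)` with exactly two distinct
#'   values. Non-numeric labels are mapped to \{0, 1\} by sorted order (the
#'   mapping is recorded in the `label_map` attribute); numeric 0/1 labels are
#'   used as-is.
#' @param gene_ids character vector of unique gene identifiers, one per
#'   column. Defaults to the column names of `values`, or `g1..gG`.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row. Defaults to the row names of `values`, or `s1..sN`.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `labels` (integer 0/1), `gene_ids`, `sample_ids`, and an
#'   attribute `label_map` giving the original label for each class code.
#'
#' @examples
#' x <- matrix(rnorm(40), nrow = 8)
#' d <- expression_dataset(x, labels = rep(c("healthy", "tumour"), each = 4))
#' d
#' @export
expression_dataset <- function(values, labels, gene_ids = NULL,
                               sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x genes)", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at row %d, column %d; missing values are not supported",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  if (length(labels) != nrow(values)) {
    stop(sprintf("length(labels) [%d] != number of samples [%d]",
                 length(labels), nrow(values)), call. = FALSE)
  }
  uniq <- sort(unique(labels))
  if (length(uniq) != 2L) {
    stop(sprintf("labels must take exactly 2 distinct values, found %d: %s",
                 length(uniq), paste(utils::head(uniq, 5L), collapse = ", ")),
         call. = FALSE)
  }
  lab <- as.integer(match(labels, uniq) - 1L)
  n_per <- tabulate(lab + 1L, nbins = 2L)
  if (any(n_per < 2L)) {
    stop(sprintf("each class needs at least 2 samples; class '%s' has %d",
                 uniq[which.min(n_per)], min(n_per)), call. = FALSE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != ncol(values)) {
    stop("length(gene_ids) must equal ncol(values)", call. = FALSE)
  }
  if (length(sample_ids) != nrow(values)) {
    stop("length(sample_ids) must equal nrow(values)", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop(sprintf("duplicate gene ids: %s",
                 paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 3L),
                       collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(
    list(values = values, labels = lab, gene_ids = gene_ids,
         sample_ids = sample_ids),
    label_map = stats::setNames(as.character(uniq), c("0", "1")),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  map <- attr(x, "label_map")
  n <- tabulate(x$labels + 1L, nbins = 2L)
  cat(sprintf("expression_dataset: %d samples x %d genes\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  class 0 ('%s'): %d samples; class 1 ('%s'): %d samples\n",
              map[["0"]], n[1L], map[["1"]], n[2L]))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read a two-class expression dataset from delimited text
#'
#' Expects one header row and one label column; every other column (or row,
#' with `orientation = "genes"`) is a gene. The delimiter is auto-detected
#' (comma vs tab) unless given. Label values are mapped to \{0, 1\} in sorted
#' order and the mapping is reported via `message()`.
#'
#' @param path path to a readable CSV/TSV file.
#' @param label_column name of the column holding the class label
#'   (default `"class"`). With `orientation = "genes"` this is the name of the
#'   row holding the labels (first column = row identifiers).
#' @param orientation `"samples"` (samples as rows, the native layout) or
#'   `"genes"` (genes as rows, the common transposed dialect).
#' @param sep field delimiter; `NULL` (default) auto-detects `","` vs `"\t"`
#'   from the header line.
#' @return An [expression_dataset].
#' @seealso [write_expression()] for the inverse operation.
#' @export
read_expression <- function(path, label_column = "class",
                            orientation = c("samples", "genes"), sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, row.names = NULL,
                          comment.char = "")
  if (orientation == "genes") {
    # first column = gene ids / the label row's name; remaining = samples
    ids <- as.character(df[[1L]])
    body <- df[, -1L, drop = FALSE]
    lab_row <- which(ids == label_column)
    if (length(lab_row) != 1L) {
      stop(sprintf("label row '%s' not found (or duplicated) in first column",
                   label_column), call. = FALSE)
    }
    labels <- unlist(body[lab_row, ], use.names = FALSE)
    expr <- body[-lab_row, , drop = FALSE]
    values <- t(as.matrix(data.frame(lapply(expr, .as_numeric_strict),
                                     check.names = FALSE)))
    colnames(values) <- ids[-lab_row]
    rownames(values) <- colnames(body)
  } else {
    if (!label_column %in% names(df)) {
      stop(sprintf("label column '%s' not found; columns: %s", label_column,
                   paste(utils::head(names(df), 6L), collapse = ", ")),
           call. = FALSE)
    }
    labels <- df[[label_column]]
    expr <- df[, setdiff(names(df), label_column), drop = FALSE]
    values <- as.matrix(data.frame(lapply(expr, .as_numeric_strict),
                                   check.names = FALSE))
    colnames(values) <- setdiff(names(df), label_column)
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  }
  out <- expression_dataset(values, labels)
  map <- attr(out, "label_map")
  message(sprintf("label mapping: '%s' -> 0, '%s' -> 1", map[["0"]], map[["1"]]))
  out
}

.as_numeric_strict <- function(col) {
  if (is.numeric(col)) return(col)
  num <- suppressWarnings(as.numeric(col))
  if (anyNA(num)) {
    stop(sprintf("non-numeric expression value '%s'",
                 col[which(is.na(num))[1L]]), call. = FALSE)
  }
  num
}

#' Write an expression dataset to delimited text
#'
#' Writes the samples-as-rows layout read back by [read_expression()]:
#' a header of gene ids plus the label column, one row per sample. Original
#' label values (before the 0/1 mapping) are restored.
#'
#' @param data an [expression_dataset].
#' @param path output file path.
#' @param label_column name for the label column (default `"class"`).
#' @param sep field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path, label_column = "class", sep = ",") {
  stopifnot(inherits(data, "expression_dataset"))
  map <- attr(data, "label_map")
  # %.17g round-trips doubles exactly; write.table's default 15 digits does not
  chr <- matrix(sprintf("%.17g", data$values), nrow = nrow(data$values),
                dimnames = dimnames(data$values))
  df <- as.data.frame(chr, check.names = FALSE, stringsAsFactors = FALSE)
  df[[label_column]] <- unname(map[as.character(data$labels)])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
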