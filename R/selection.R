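#' Select the top-k genes under one ranking method
#'
#' Implements the selection protocol: after scoring, the k best-ranked genes
#' are kept. Ranking direction is method-specific (descending score for md,
#' snr and fisher; ascending P for wilcoxon) and ties are broken stably by
#' gene column order, so selection is deterministic.
#'
#' @param fit an `mdselect` fit (or its `scores` data frame).
#' @param method one of `"md"`, `"snr"`, `"fisher"`, `"wilcoxon"`.
#' @param k number of genes to keep. If `k` exceeds the number of genes a
#'   warning is issued and all genes are returned.
#' @return An object of class `selection_result`: list with `method`, `k`,
#'   `gene_ids` (in rank order) and `scores` (the method's statistic for each
#'   selected gene; a P-value for wilcoxon).
#' @export
select_top_k <- function(fit, method, k) {
  s <- if (inherits(fit, "mdselect")) fit$scores else fit
  methods <- c("md", "snr", "fisher", "wilcoxon")
  if (length(method) != 1L || !method %in% methods) {
    stop(sprintf("unknown method '%s'; valid: %s", method,
                 paste(methods, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  G <- nrow(s)
  if (k > G) {
    warning(sprintf("k = %d exceeds the %d available genes; returning all", k, G))
    k <- G
  }
  rank_col <- paste0("rank_", method)
  score_col <- if (method == "wilcoxon") "wilcoxon_p" else method
  idx <- order(s[[rank_col]])[seq_len(k)]
  structure(
    list(method = method, k = as.integer(k),
         gene_ids = s$gene_id[idx], scores = s[[score_col]][idx]),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("top-%d genes by %s: %s\n", x$k, x$method,
              paste(utils::head(x$gene_ids, 10L), collapse = ", ")))
  invisible(x)
}

#' The methods x k selection grid
#'
#' One [select_top_k()] call per (method, k) pair, methods-major — the grid
#' behind the usual "error at k = 5, 10, 15, 20 per method" report.
#'
#' @param fit an `mdselect` fit.
#' @param methods character vector of ranking methods.
#' @param ks integer vector of subset sizes (default `c(5, 10, 15, 20)`).
#' @return A list of `selection_result`, length `length(methods) * length(ks)`.
#' @export
selection_grid <- function(fit, methods = c("md", "snr", "fisher", "wilcoxon"),
                           ks = c(5L, 10L, 15L, 20L)) {
  if (!length(methods) || !length(ks)) {
    stop("`methods` and `ks` must be non-empty", call. = FALSE)
  }
  out <- list()
  for (m in methods) {
    for (k in ks) {
      out[[length(out) + 1L]] <- select_top_k(fit, m, k)
    }
  }
  out
}

#' Write a selection grid to delimited text
#'
#' Long format: one row per selected gene with columns
#' `method, k, rank, gene_id, score`.
#'
#' @param selections list of `selection_result` (from [selection_grid()]).
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_selections <- function(selections, path, sep = ",") {
  rows <- do.call(rbind, lapply(selections, function(sel) {
    data.frame(method = sel$method, k = sel$k, rank = seq_along(sel$gene_ids),
               gene_id = sel$gene_ids, score = sel$scores)
  }))
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write one gene-list file (one id per line) per selection
#'
#' @param selections list of `selection_result`.
#' @param dir output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_gene_lists <- function(selections, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(selections, function(sel) {
    p <- file.path(dir, sprintf("genes_%s_k%d.txt", sel$method, sel$k))
    writeLines(sel$gene_ids, p)
    p
  }, character(1L))
  invisible(paths)
}
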