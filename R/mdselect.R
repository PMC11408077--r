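#' Score every gene with the Md statistic and its comparators
#'
#' The package's central fitting function. Given a two-class expression
#' dataset it computes, per gene: the signal-to-noise ratio (SNR), the Fisher
#' score, the two-sided Wilcoxon rank-sum P-value, the Mood's median test
#' P-value, and the hybrid Md score `SNR / P_mood`. Each method also gets a
#' rank vector (1 = best): descending for snr, fisher and md, ascending for
#' the Wilcoxon P, with ties broken stably by gene column order.
#'
#' @param x an [expression_dataset], a samples-x-genes numeric matrix
#'   (with `labels`), or a formula such as `class ~ .` with a `data` frame.
#' @param ... passed on to methods.
#' @return An object of class `mdselect`: a list with `scores` (a data frame
#'   with columns gene_id, snr, fisher, wilcoxon_p, mood_p, md, rank_snr,
#'   rank_fisher, rank_wilcoxon, rank_md), `mood_tables` (the per-gene 2x2
#'   audit tables), `n0`, `n1`, `config` and `call`.
#'
#' @examples
#' sim <- simulate_expression(n0 = 10, n1 = 10, G = 50, n_informative = 3,
#'                            effect = 3, seed = 1)
#' fit <- mdselect(sim$data)
#' fit
#' head(coef(fit))
#' select_top_k(fit, "md", 5)
#' @export
mdselect <- function(x, ...) UseMethod("mdselect")

#' @rdname mdselect
#' @param labels class labels, one per row of the matrix (two distinct values).
#' @param eps_sd denominator guard for the SNR and Fisher scores.
#' @param p_floor P-value floor in the Md denominator.
#' @param exact_threshold largest `n0 + n1` using the exact Wilcoxon path.
#' @param continuity use the Yates correction in Mood's test.
#' @export
mdselect.default <- function(x, labels, eps_sd = 1e-12, p_floor = 1e-300,
                             exact_threshold = 12L, continuity = FALSE, ...) {
  data <- expression_dataset(as.matrix(x), labels)
  mdselect.expression_dataset(data, eps_sd = eps_sd, p_floor = p_floor,
                              exact_threshold = exact_threshold,
                              continuity = continuity, ...)
}

#' @rdname mdselect
#' @param data a data frame holding the expression values and the label
#'   column named on the left-hand side of the formula.
#' @export
mdselect.formula <- function(x, data, ...) {
  lhs <- all.vars(x[[2L]])
  if (length(lhs) != 1L || !lhs %in% names(data)) {
    stop("formula must name one label column present in `data`, e.g. class ~ .",
         call. = FALSE)
  }
  rhs <- x[[3L]]
  if (identical(rhs, as.name("."))) {
    genes <- setdiff(names(data), lhs)
  } else {
    genes <- all.vars(rhs)
    missing <- setdiff(genes, names(data))
    if (length(missing)) {
      stop(sprintf("genes not in `data`: %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
  }
  fit <- mdselect.default(data[, genes, drop = FALSE], labels = data[[lhs]], ...)
  fit$call <- match.call()
  fit
}

#' @rdname mdselect
#' @export
mdselect.expression_dataset <- function(x, eps_sd = 1e-12, p_floor = 1e-300,
                                        exact_threshold = 12L,
                                        continuity = FALSE, ...) {
  st <- class_stats(x)
  snr <- snr_score(st, eps_sd = eps_sd)
  fisher <- fisher_score(st, eps_sd = eps_sd)
  wilx <- wilcoxon_score(x, exact_threshold = exact_threshold)
  mood <- mood_median_pvalue(x, continuity = continuity)
  md <- md_score(snr, mood$p, p_floor = p_floor)
  scores <- data.frame(
    gene_id = x$gene_ids,
    snr = unname(snr), fisher = unname(fisher),
    wilcoxon_p = unname(wilx), mood_p = unname(mood$p), md = unname(md),
    rank_snr = .stable_rank(snr, decreasing = TRUE),
    rank_fisher = .stable_rank(fisher, decreasing = TRUE),
    rank_wilcoxon = .stable_rank(wilx, decreasing = FALSE),
    rank_md = .stable_rank(md, decreasing = TRUE),
    row.names = NULL
  )
  structure(
    list(scores = scores, mood_tables = mood$tables, n0 = st$n0, n1 = st$n1,
         config = list(eps_sd = eps_sd, p_floor = p_floor,
                       exact_threshold = exact_threshold,
                       continuity = continuity),
         call = match.call()),
    class = "mdselect"
  )
}

# rank with 1 = best; ties broken by original (column) order
.stable_rank <- function(x, decreasing) {
  idx <- order(if (decreasing) -x else x)   # order() is stable under ties
  r <- integer(length(x))
  r[idx] <- seq_along(x)
  r
}

#' @export
print.mdselect <- function(x, n = 5L, ...) {
  cat(sprintf("Md gene ranking: %d genes, %d + %d samples\n",
              nrow(x$scores), x$n0, x$n1))
  top <- x$scores[order(x$scores$rank_md), , drop = FALSE]
  cat(sprintf("Top %d genes by Md:\n", min(n, nrow(top))))
  show <- utils::head(top[, c("gene_id", "snr", "mood_p", "md", "rank_snr")], n)
  print(format(show, digits = 4L), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mdselect <- function(object, ...) {
  s <- object$scores
  out <- list(
    n_genes = nrow(s), n0 = object$n0, n1 = object$n1,
    score_summary = rbind(snr = summary(s$snr), fisher = summary(s$fisher),
                          md = summary(s$md)),
    p_summary = rbind(wilcoxon_p = summary(s$wilcoxon_p),
                      mood_p = summary(s$mood_p)),
    rank_agreement = stats::cor(s$rank_md, s$rank_snr, method = "spearman")
  )
  class(out) <- "summary.mdselect"
  out
}

#' @export
print.summary.mdselect <- function(x, ...) {
  cat(sprintf("mdselect fit: %d genes scored on %d + %d samples\n",
              x$n_genes, x$n0, x$n1))
  cat("\nScores:\n"); print(signif(x$score_summary, 4L))
  cat("\nP-values:\n"); print(signif(x$p_summary, 4L))
  cat(sprintf("\nSpearman agreement of Md and SNR ranks: %.3f\n",
              x$rank_agreement))
  invisible(x)
}

#' @export
#' @describeIn mdselect matrix of per-gene statistics (columns snr, fisher,
#'   wilcoxon_p, mood_p, md), rownames = gene ids.
coef.mdselect <- function(object, ...) {
  s <- object$scores
  m <- as.matrix(s[, c("snr", "fisher", "wilcoxon_p", "mood_p", "md")])
  rownames(m) <- s$gene_id
  m
}

#' @export
as.data.frame.mdselect <- function(x, ...) x$scores

#' Diagnostic plot of an Md fit
#'
#' Scatter of each gene's SNR against its Mood's-test P-value (log10 scale),
#' the two ingredients of Md. Genes in the Md top-k are highlighted; the
#' upper-left region (large gap, strong median-level support) is where Md
#' ranks genes highly.
#'
#' @param x an `mdselect` fit.
#' @param k number of top-Md genes to highlight (default 10).
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.mdselect <- function(x, k = 10L, ...) {
  s <- x$scores
  top <- s$rank_md <= k
  plot(log10(s$mood_p), s$snr, pch = 16L,
       col = ifelse(top, "firebrick", "grey60"),
       xlab = "log10 Mood's median test P", ylab = "SNR score",
       main = sprintf("Md ingredients (top %d by Md in red)", k), ...)
  if (any(top)) {
    graphics::text(log10(s$mood_p[top]), s$snr[top], labels = s$gene_id[top],
                   pos = 4L, cex = 0.7, col = "firebrick")
  }
  invisible(x)
}

#' Write a score table to delimited text
#'
#' @param fit an `mdselect` fit (or its `scores` data frame).
#' @param path output file path.
#' @param sep field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(fit, path, sep = ",") {
  s <- if (inherits(fit, "mdselect")) fit$scores else fit
  utils::write.table(s, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
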