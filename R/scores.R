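#' Per-gene, per-class summary statistics
#'
#' Shared first stage of the SNR and Fisher scores: per gene, the sample count,
#' mean and standard deviation (n-1 denominator) within each class, plus the
#' overall mean.
#'
#' @param data an [expression_dataset].
#' @return A list of class `gene_class_stats` with per-gene numeric vectors
#'   `mu0`, `mu1`, `sd0`, `sd1`, `mu` and scalars `n0`, `n1`.
#' @export
class_stats <- function(data) {
  stopifnot(inherits(data, "expression_dataset"))
  X <- data$values
  i0 <- data$labels == 0L
  n0 <- sum(i0); n1 <- sum(!i0)
  if (n0 < 2L) stop("class 0 has fewer than 2 samples; SD undefined", call. = FALSE)
  if (n1 < 2L) stop("class 1 has fewer than 2 samples; SD undefined", call. = FALSE)
  X0 <- X[i0, , drop = FALSE]
  X1 <- X[!i0, , drop = FALSE]
  mu0 <- colMeans(X0)
  mu1 <- colMeans(X1)
  sd0 <- sqrt(colSums(sweep(X0, 2L, mu0)^2) / (n0 - 1))
  sd1 <- sqrt(colSums(sweep(X1, 2L, mu1)^2) / (n1 - 1))
  structure(
    list(n0 = n0, n1 = n1, mu0 = mu0, mu1 = mu1, sd0 = sd0, sd1 = sd1,
         mu = (n0 * mu0 + n1 * mu1) / (n0 + n1), gene_ids = data$gene_ids),
    class = "gene_class_stats"
  )
}

#' Signal-to-noise ratio (S2N) score
#'
#' The classical two-class separation statistic: the absolute gap between the
#' class means over the sum of the within-class standard deviations,
#' `|mu0 - mu1| / (sd0 + sd1 + eps_sd)`. Larger values indicate genes whose
#' expression separates the classes more cleanly.
#'
#' @param stats output of [class_stats()].
#' @param eps_sd denominator guard added to the summed SDs so that
#'   zero-variance genes yield finite (very large, if separated) scores.
#' @return Named nonnegative numeric vector, one score per gene.
#' @export
snr_score <- function(stats, eps_sd = 1e-12) {
  stopifnot(inherits(stats, "gene_class_stats"))
  out <- abs(stats$mu0 - stats$mu1) / (stats$sd0 + stats$sd1 + eps_sd)
  stats::setNames(out, stats$gene_ids)
}

#' Fisher score
#'
#' Ratio of between-class to within-class scatter:
#' `sum_k n_k (mu_k - mu)^2 / (sum_k n_k sd_k^2 + eps_sd)`.
#' Scale-invariant; zero when the class means coincide.
#'
#' @inheritParams snr_score
#' @return Named nonnegative numeric vector, one score per gene.
#' @export
fisher_score <- function(stats, eps_sd = 1e-12) {
  stopifnot(inherits(stats, "gene_class_stats"))
  num <- stats$n0 * (stats$mu0 - stats$mu)^2 + stats$n1 * (stats$mu1 - stats$mu)^2
  den <- stats$n0 * stats$sd0^2 + stats$n1 * stats$sd1^2 + eps_sd
  stats::setNames(num / den, stats$gene_ids)
}

#' Wilcoxon rank-sum (Mann-Whitney) P-values per gene
#'
#' Two-sided rank-sum test of each gene against the class labels. For small
#' totals (`n0 + n1 <= exact_threshold`) the null distribution of the
#' class-0 midrank sum is enumerated exhaustively over all C(N, n0) group
#' assignments (valid under ties); otherwise the normal approximation with
#' tie-corrected variance is used (no continuity correction). Genes are
#' conventionally ranked by ascending P.
#'
#' @param data an [expression_dataset].
#' @param exact_threshold largest total sample count for which the exact
#'   enumeration path is taken (default 12).
#' @return Named numeric vector of P-values in (0, 1].
#' @export
wilcoxon_score <- function(data, exact_threshold = 12L) {
  stopifnot(inherits(data, "expression_dataset"))
  X <- data$values
  i0 <- data$labels == 0L
  n0 <- sum(i0); N <- nrow(X)
  if (N <= exact_threshold) {
    subsets <- utils::combn(N, n0)
    p <- apply(X, 2L, function(v) {
      r <- rank(v)
      w <- sum(r[i0])
      all_w <- colSums(matrix(r[subsets], nrow = n0))
      lo <- mean(all_w <= w + 1e-9)
      hi <- mean(all_w >= w - 1e-9)
      min(1, 2 * min(lo, hi))
    })
  } else {
    n1 <- N - n0
    mu <- n0 * (N + 1) / 2
    p <- apply(X, 2L, function(v) {
      r <- rank(v)
      w <- sum(r[i0])
      ties <- table(v)
      sig2 <- n0 * n1 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
      if (sig2 <= 0) return(1)           # all values tied
      min(1, 2 * stats::pnorm(-abs(w - mu) / sqrt(sig2)))
    })
  }
  stats::setNames(pmax(p, 1e-300), data$gene_ids)
}

#' Mood's median test per gene
#'
#' The robust nonparametric test at the core of the Md score. For each gene
#' the pooled grand median over all samples is computed, each sample is
#' dichotomized as strictly above vs at-or-below it, and a Pearson chi-square
#' test (1 df, upper tail) is applied to the resulting 2x2 class-by-side
#' table. Values exactly equal to the grand median count as "at-or-below".
#' Degenerate tables (an all-zero row or column, e.g. a constant gene) return
#' P = 1 by convention, marking the gene uninformative.
#'
#' @param data an [expression_dataset].
#' @param continuity apply the Yates continuity correction (default `FALSE`).
#' @return A list with `p` (named vector of P-values in (0, 1]) and `tables`,
#'   a data frame with one row per gene: `grand_median` and the counts
#'   `a` (class 0 above), `b` (class 1 above), `c` (class 0 at-or-below),
#'   `d` (class 1 at-or-below).
#' @export
mood_median_pvalue <- function(data, continuity = FALSE) {
  stopifnot(inherits(data, "expression_dataset"))
  X <- data$values
  i0 <- data$labels == 0L
  n0 <- sum(i0); n1 <- sum(!i0)
  if (n0 < 2L || n1 < 2L) stop("both classes need at least 2 samples", call. = FALSE)
  N <- n0 + n1
  med <- apply(X, 2L, stats::median)
  above <- sweep(X, 2L, med, `>`)
  a <- colSums(above[i0, , drop = FALSE])
  b <- colSums(above[!i0, , drop = FALSE])
  cc <- n0 - a
  d <- n1 - b
  num <- a * d - b * cc
  if (continuity) {
    num <- pmax(abs(num) - N / 2, 0)
  }
  den <- (a + b) * (cc + d) * n0 * n1
  stat <- ifelse(den == 0, 0, N * num^2 / den)
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  p <- pmax(pmin(p, 1), 1e-300)
  p[den == 0] <- 1                       # degenerate table convention
  list(
    p = stats::setNames(p, data$gene_ids),
    tables = data.frame(gene_id = data$gene_ids, grand_median = med,
                        a = a, b = b, c = cc, d = d, row.names = NULL)
  )
}

#' The hybrid Md score
#'
#' `Md = SNR / P`: the signal-to-noise ratio of a gene divided by its Mood's
#' median test P-value. A gene scores highly only if it shows both a large
#' standardized mean gap (high SNR) and a robust, median-level group
#' difference (small P); an outlier-driven mean gap that the median test does
#' not corroborate is penalized.
#'
#' @param snr nonnegative SNR scores, as from [snr_score()].
#' @param mood_p Mood's-test P-values, as from [mood_median_pvalue()].
#' @param p_floor smallest P used in the denominator (default `1e-300`),
#'   keeping the score finite when P underflows.
#' @return Named nonnegative numeric vector of Md scores.
#' @export
md_score <- function(snr, mood_p, p_floor = 1e-300) {
  if (length(snr) != length(mood_p)) {
    stop("`snr` and `mood_p` must have the same length", call. = FALSE)
  }
  if (any(snr < 0)) stop("negative SNR score: upstream bug", call. = FALSE)
  stopifnot(p_floor > 0)
  snr / pmax(mood_p, p_floor)
}
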