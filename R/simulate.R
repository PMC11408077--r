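#' Simulate a seeded two-class expression matrix with planted signal
#'
#' Generates the p >> n setting the package targets: a small set of
#' informative genes carrying a between-class mean shift, drowned in a large
#' majority of pure-noise genes, with optional right-skewed (lognormal) noise
#' and optional outlier contamination. Fully reproducible from `seed`; the
#' set of truly informative gene ids is returned for recovery benchmarks.
#'
#' Baseline noise is standard normal, so `effect` and `outlier_magnitude` are
#' in within-class SD units. The first `n_informative` genes are informative:
#' class-1 samples are shifted up by `effect`. With `noise = "lognormal"` the
#' (shifted) normal draws are exponentiated, producing right skew; the shift
#' then acts multiplicatively. Contamination is applied last: a fraction
#' `outlier_fraction` of matrix cells, chosen uniformly at random, gets
#' `outlier_magnitude` added to its base value — per-cell, not per-sample, so
#' a single gene can be hit in isolation.
#'
#' @param n0,n1 samples in class 0 / class 1 (each >= 2). Samples are ordered
#'   class 0 first; stratified CV makes the order irrelevant.
#' @param G total number of genes.
#' @param n_informative number of planted informative genes (`<= G`).
#' @param effect between-class mean shift of informative genes, in SD units
#'   (`>= 0`).
#' @param noise `"normal"` or `"lognormal"`.
#' @param outlier_fraction fraction of cells contaminated, in `[0, 1)`.
#' @param outlier_magnitude size of the added outlier offset, in SD units
#'   (default 20: a single cell becomes an extreme point).
#' @param seed integer seed.
#' @return List with `data` (an [expression_dataset]; labels 0/1, gene ids
#'   `g1..gG`) and `truth` (character vector of informative gene ids).
#'
#' @examples
#' sim <- simulate_expression(n0 = 20, n1 = 20, G = 100, n_informative = 5,
#'                            effect = 2, seed = 42)
#' sim$truth
#' @export
simulate_expression <- function(n0 = 20L, n1 = 20L, G = 100L,
                                n_informative = 5L, effect = 1,
                                noise = c("normal", "lognormal"),
                                outlier_fraction = 0,
                                outlier_magnitude = 20, seed = 1L) {
  noise <- match.arg(noise)
  if (n_informative > G) stop("n_informative must be <= G", call. = FALSE)
  if (n0 < 2L || n1 < 2L) stop("need n0 >= 2 and n1 >= 2", call. = FALSE)
  if (effect < 0) stop("effect must be >= 0", call. = FALSE)
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    stop("outlier_fraction must be in [0, 1)", call. = FALSE)
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  n <- n0 + n1
  X <- matrix(stats::rnorm(n * G), nrow = n, ncol = G)
  labels <- rep(c(0L, 1L), times = c(n0, n1))
  if (n_informative > 0L) {
    X[labels == 1L, seq_len(n_informative)] <-
      X[labels == 1L, seq_len(n_informative)] + effect
  }
  if (noise == "lognormal") X <- exp(X)
  if (outlier_fraction > 0) {
    n_cells <- round(outlier_fraction * length(X))
    cells <- sample.int(length(X), n_cells)
    X[cells] <- X[cells] + outlier_magnitude
  }
  gene_ids <- paste0("g", seq_len(G))
  data <- expression_dataset(X, labels, gene_ids = gene_ids,
                             sample_ids = paste0("s", seq_len(n)))
  list(data = data, truth = gene_ids[seq_len(n_informative)])
}

#' Hand-computable fixture datasets
#'
#' A named collection of tiny datasets whose statistics are known in closed
#' form, used throughout the test suite and handy for interactive sanity
#' checks. Each element is a list with `data` (an [expression_dataset]) and
#' `expected` (the hand-derived statistics).
#'
#' Fixtures:
#' \describe{
#'   \item{`sep_gene`}{one gene, class 0 = (0, 2), class 1 = (4, 6):
#'     SNR = 4 / (2 sqrt 2), Fisher = 2, Mood chi-square = 4.}
#'   \item{`sym_mood`}{one gene with identical class distributions
#'     (1..4 vs 1..4): every statistic degenerate, Mood P = 1.}
#'   \item{`split_mood`}{one gene, 1..5 vs 11..15: a perfect median split,
#'     Mood chi-square = 10.}
#'   \item{`toy`}{4 samples x 3 genes in which gene `g2` is the separable
#'     gene and ranks first under all four methods.}
#' }
#' @return Named list of fixtures.
#' @export
fixture_suite <- function() {
  one_gene <- function(v0, v1, id = "g1") {
    expression_dataset(matrix(c(v0, v1), ncol = 1L,
                              dimnames = list(NULL, id)),
                       labels = rep(c(0L, 1L), times = c(length(v0), length(v1))))
  }
  list(
    sep_gene = list(
      data = one_gene(c(0, 2), c(4, 6)),
      expected = list(snr = 4 / (2 * sqrt(2)), fisher = 2,
                      mood_chisq = 4,
                      mood_p = stats::pchisq(4, 1, lower.tail = FALSE))
    ),
    sym_mood = list(
      data = one_gene(c(1, 2, 3, 4), c(1, 2, 3, 4)),
      expected = list(mood_p = 1, snr = 0, fisher = 0, wilcoxon_p = 1,
                      mood_table = c(a = 2, b = 2, c = 2, d = 2),
                      grand_median = 2.5)
    ),
    split_mood = list(
      data = one_gene(c(1, 2, 3, 4, 5), c(11, 12, 13, 14, 15)),
      expected = list(mood_chisq = 10, grand_median = 8,
                      mood_p = stats::pchisq(10, 1, lower.tail = FALSE),
                      mood_table = c(a = 0, b = 5, c = 5, d = 0))
    ),
    toy = list(
      data = expression_dataset(
        matrix(c(1, 5, 1, 5,    # g1: identical class multisets
                 0, 2, 4, 6,    # g2: separable
                 1, 3, 2, 4),   # g3: weakly shifted
               nrow = 4L, dimnames = list(NULL, c("g1", "g2", "g3"))),
        labels = c(0L, 0L, 1L, 1L)),
      expected = list(best_gene = "g2")
    )
  )
}
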