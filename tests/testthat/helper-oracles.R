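# Independent straight-from-formula oracles used to cross-check the
# vectorized implementations. Deliberately naive: per-gene loops, stats::sd,
# stats::chisq.test, and a U-statistic permutation enumeration for Wilcoxon.

oracle_snr <- function(v, labels, eps = 1e-12) {
  v0 <- v[labels == 0]; v1 <- v[labels == 1]
  abs(mean(v0) - mean(v1)) / (stats::sd(v0) + stats::sd(v1) + eps)
}

oracle_fisher <- function(v, labels, eps = 1e-12) {
  v0 <- v[labels == 0]; v1 <- v[labels == 1]
  mu <- mean(v)
  num <- length(v0) * (mean(v0) - mu)^2 + length(v1) * (mean(v1) - mu)^2
  den <- length(v0) * stats::sd(v0)^2 + length(v1) * stats::sd(v1)^2 + eps
  num / den
}

oracle_mood <- function(v, labels) {
  med <- stats::median(v)
  tab <- rbind(
    c(sum(v > med & labels == 0), sum(v > med & labels == 1)),
    c(sum(v <= med & labels == 0), sum(v <= med & labels == 1))
  )
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

# exact two-sided rank-sum P by exhausting all C(N, n0) group assignments,
# formulated through the Mann-Whitney U statistic (ties count 1/2)
oracle_wilcoxon_exact <- function(v0, v1) {
  v <- c(v0, v1)
  n0 <- length(v0); N <- length(v)
  u_stat <- function(a, b) {
    sum(outer(a, b, `>`)) + 0.5 * sum(outer(a, b, `==`))
  }
  u_obs <- u_stat(v0, v1)
  subsets <- utils::combn(N, n0)
  u_all <- apply(subsets, 2L, function(idx) u_stat(v[idx], v[-idx]))
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

# small random dataset builder for property tests
random_dataset <- function(n0, n1, G, values = NULL) {
  if (is.null(values)) values <- matrix(rnorm((n0 + n1) * G), ncol = G)
  expression_dataset(values, labels = rep(c(0L, 1L), times = c(n0, n1)))
}
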