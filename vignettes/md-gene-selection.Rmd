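---
title: "Robust hybrid gene selection with the Md score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust hybrid gene selection with the Md score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdselect)
```

## The problem

In two-class expression studies the number of genes `G` routinely exceeds the
number of samples `n` by two to three orders of magnitude, and most genes are
noise with respect to the phenotype. Filter-style feature selection scores
each gene independently of any classifier, keeps the top-ranked subset, and
hands that subset to a downstream classifier. This package implements one
such filter family around a hybrid statistic, **Md**, and the harness needed
to benchmark it.

## The statistics

For gene $j$ with class means $\mu_{0j}, \mu_{1j}$, class standard
deviations $\sigma_{0j}, \sigma_{1j}$ (denominator $n-1$) and class sizes
$n_0, n_1$:

* **SNR (signal-to-noise / S2N) score**
  $\mathrm{SNR}_j = |\mu_{0j} - \mu_{1j}| \,/\, (\sigma_{0j} + \sigma_{1j})$.
  The absolute value is used because ranking needs a magnitude, not a
  direction.
* **Fisher score**
  $S_j = \sum_k n_k (\mu_{kj} - \mu_j)^2 \,/\, \sum_k n_k \sigma_{kj}^2$,
  the classical between-class over within-class scatter ratio, with
  $\mu_j$ the overall mean.
* **Wilcoxon rank-sum**: the two-sided Mann–Whitney P-value of gene $j$
  against the labels; genes are ranked by ascending P.
* **Mood's median test**: all $N = n_0 + n_1$ values of gene $j$ are pooled,
  the grand median is taken, each sample is dichotomized as strictly above
  vs at-or-below it, and the Pearson chi-square statistic (1 df, upper tail)
  of the resulting 2×2 class-by-side table gives the P-value $P_j$. Because
  only the side of the median enters, a single wild value can move the
  statistic by at most one table count: the test is robust to outliers and
  to skewed, heavy-tailed noise.
* **Md score**
  $\mathrm{Md}_j = \mathrm{SNR}_j \,/\, P_j$.
  A gene ranks highly only if it has *both* a large standardized mean gap
  and a median-level group difference that the robust test corroborates. A
  mean gap manufactured by one outlier inflates SNR but not $1/P_j$, so Md
  demotes such genes relative to SNR — the robustness rationale the test
  suite checks explicitly.

`mdselect()` computes all five quantities and per-method ranks in one pass;
`select_top_k()` / `selection_grid()` implement the top-$k$ protocol
(default $k \in \{5, 10, 15, 20\}$); `cv_error()` / `error_grid()` estimate
classification error for the selected subsets.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `eps_sd` | `1e-12` | added to the SNR/Fisher denominators so zero-variance genes stay finite (a separated zero-variance gene scores huge, as it should) |
| `p_floor` | `1e-300` | lower bound on the Mood P inside Md; division by an underflowed 0 would otherwise produce `Inf` |
| `exact_threshold` | `12` | largest $N$ for which the Wilcoxon null is enumerated exhaustively ($\binom{12}{6} = 924$ assignments); above it, the normal approximation with tie-corrected variance (no continuity correction) |
| `continuity` | `FALSE` | Yates correction in Mood's chi-square; off by default, exposed as a flag |
| `knn_neighbors` | `3` | Euclidean K-NN; odd avoids vote ties in two classes |
| `rf_trees` | `500` | Random Forest size; default split heuristics, no tuning |
| `cv_folds`, `cv_repeats` | `5`, `10` | stratified k-fold scheme, repeated to stabilize the error estimate |
| `selection_mode` | `"pre_cv"` | see below |

Values exactly equal to the grand median count "at-or-below"; a degenerate
2×2 table (an all-zero row or column, e.g. a constant gene) returns $P = 1$,
marking the gene uninformative instead of propagating `NaN` into Md. Rank
ties (possible for the discrete Wilcoxon P, measure-zero for the continuous
scores) are broken stably by gene column order, so every ranking and
selection is deterministic; note this means a column permutation can reorder
*tied* genes, while all score vectors themselves are permutation-equivariant.

## Selection timing and its bias

The conventional protocol — and this package's default, `pre_cv` — selects
genes once on the full dataset and then cross-validates a classifier on the
selected columns. Because the test folds participated in selection, the
resulting error is optimistically biased, which matters exactly when signal
is weak. `selection_mode = "nested"` re-runs selection inside every training
fold and is the honest estimate; the test suite verifies on pure-noise data
that `nested` is no more optimistic than `pre_cv` (one-sided sign test over
20 simulated cohorts). The default remains `pre_cv` so that results are
comparable with the common practice this package benchmarks; switch to
`nested` for any claim about generalization error.

## What the synthetic generator emulates

`simulate_expression()` draws iid standard-normal noise for `G` genes,
shifts the first `n_informative` genes upward by `effect` SD units in class
1, optionally exponentiates the draws (`noise = "lognormal"`, giving
right-skewed data with a multiplicative shift), and finally adds
`outlier_magnitude` SD to a uniformly chosen fraction of single cells.
Contamination is per-cell rather than per-sample on purpose: per-gene
robustness is the property on which Md and SNR differ, and a whole
contaminated sample would confound it. Labels are sorted (class 0 first);
the stratified CV harness makes the order irrelevant.

The generator deliberately does **not** mimic real microarray intensity
distributions, gene–gene correlation, batch effects, or normalization
pipelines. Passing tests therefore demonstrate correctness of the statistics
and the claimed robustness ordering under controlled contamination — not
performance on any real cohort, where correlated blocks and technical
artifacts can change the picture.

## Problem sizes used by the checks

The package's own verification uses cohorts of 20 + 20 samples × 100 genes
with 5 planted genes (recovery: at `effect = 10` all five land in the Md
top-5; recovery is monotone over effects 0–4, 30 cohorts per effect), and an
unbalanced 12 + 90 cohort for the robustness ordering: one noise gene gets a
single +40 SD cell in the small class, and its Md rank is compared with its
SNR rank across 50 replicates. The unbalanced design was fixed once, by
simulation, because a lone outlier in a large balanced class shifts the
class mean by only `magnitude/n` while inflating the class SD by
`~magnitude/sqrt(n)` — the spurious SNR boost that Md is meant to veto is
small there, and the demotion probability plateaus near 0.7. In a small
class the boost is large and the demotion fraction stabilizes near 0.9.
Small outlier-hit cohorts are common in practice (rare subtypes), so this is
the regime where the robustness claim is both testable and relevant. The
end-to-end check runs the full pipeline (4 methods × k ∈ {5,10,15,20} × RF
and K-NN, 5-fold × 2 repeats) on a separable cohort and on label-shuffled
data.

## Worked example

```{r example}
sim <- simulate_expression(n0 = 20, n1 = 20, G = 100, n_informative = 5,
                           effect = 2, seed = 42)
fit <- mdselect(sim$data)
fit
summary(fit)
select_top_k(fit, "md", 10)

report <- error_grid(sim$data,
                     selection_grid(fit, methods = c("md", "snr"), ks = c(5L, 10L)),
                     config = eval_config(cv_repeats = 2L, seed = 1L))
report
```

## Known limitations

* Strictly two-class; no multi-class extension.
* Raw P-values feed Md by design — no multiple-testing correction, since Md
  uses P as a weighting denominator, not as an inference.
* No missing-value handling: loaders reject non-finite cells.
* Exact numeric error rates depend on the (unstated in general) resampling
  protocol; compare methods within one configuration, not across papers.
* Random Forest determinism holds for a fixed seed within one R/randomForest
  build and is environment-dependent across builds; K-NN is deterministic
  given the seed everywhere.
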