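# mdselect

Robust filter-based gene selection for two-class, high-dimensional
expression data (`G` genes ≫ `n` samples), built around the hybrid **Md
score**, plus the classical comparator filters and a cross-validated
classification-error harness. Intended for anyone ranking genes (or any
features) between two phenotype groups — microarray or bulk/single-cell
expression matrices with a binary label — and for benchmarking such filters
against each other.

## The statistics

Per gene *j*, with class means μ₀ⱼ, μ₁ⱼ, class SDs σ₀ⱼ, σ₁ⱼ and class
sizes n₀, n₁:

| method | statistic | ranked by |
|---|---|---|
| SNR (S2N) | `\|μ₀ⱼ − μ₁ⱼ\| / (σ₀ⱼ + σ₁ⱼ)` | descending |
| Fisher | `Σₖ nₖ(μₖⱼ − μⱼ)² / Σₖ nₖ σₖⱼ²` | descending |
| Wilcoxon | two-sided Mann–Whitney rank-sum P | ascending P |
| Mood | chi-square P of the 2×2 above/below-grand-median table | (feeds Md) |
| **Md** | **SNRⱼ / Pⱼ(Mood)** | descending |

Md couples the mean-gap signal with a median-based test that a single
outlier can move by at most one count of the 2×2 table: genes whose SNR is
inflated by outliers lack a small Mood P and are demoted, while genuinely
separated genes get both a large numerator and a tiny denominator. After
scoring, the top k = 5, 10, 15, 20 genes per method are selected and their
average misclassification error is estimated with Random Forest and
Euclidean 3-NN under seeded, stratified, repeated cross-validation.

## Worked example

```r
library(mdselect)

sim <- simulate_expression(n0 = 20, n1 = 20, G = 100, n_informative = 5,
                           effect = 2, seed = 42)
fit <- mdselect(sim$data)   # also accepts a formula: mdselect(class ~ ., df)
fit
#> Md gene ranking: 100 genes, 20 + 20 samples
#> Top 5 genes by Md:
#>  gene_id    snr    mood_p        md rank_snr
#>       g2 1.1769 4.200e-07 2801937.7        2
#>       g4 1.2039 9.547e-06  126099.3        1
#>       g5 1.0516 9.547e-06  110148.4        3
#>       g3 0.9881 9.547e-06  103501.8        4
#>       g1 0.6346 1.141e-02      55.6        5
```

The five planted genes (`g1`–`g5`, a 2-SD mean shift) occupy the top five Md
ranks: each combines a large standardized mean gap (`snr`) with a tiny
Mood's-test P-value (`mood_p`), and their ratio (`md`) separates them from
the 95 noise genes by orders of magnitude.

```r
select_top_k(fit, "md", 10)
#> top-10 genes by md: g2, g4, g5, g3, g1, g79, g81, g64, g61, g75

report <- error_grid(sim$data,
                     selection_grid(fit, methods = c("md", "snr"), ks = c(5L, 10L)),
                     config = eval_config(cv_repeats = 2L, seed = 1L))
report
#> Average CV misclassification error
#>  method  k classifier mean_error sd_error
#>      md  5         rf     0.0250  0.05270
#>      md  5        knn     0.0000  0.00000
#>      md 10         rf     0.0125  0.03953
#>      md 10        knn     0.0375  0.06038
#>     snr  5         rf     0.0250  0.05270
#>     snr  5        knn     0.0000  0.00000
#>     snr 10         rf     0.0000  0.00000
#>     snr 10        knn     0.0125  0.03953
```

`mean_error` is the fraction of held-out samples misclassified, averaged
over the stratified folds (here 5 folds × 2 repeats); `sd_error` is its SD
across folds. With a 2-SD planted shift both filters find the signal and
errors sit near zero.

A full run (load → score → select → evaluate, with a manifest) is
`run_pipeline(run_config("expr.csv", "out/"))`, or from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "mdselect.R", package = "mdselect"))') \
    run --input expr.csv --output-dir out --seed 1
```

The CLI also exposes `simulate`, `score`, `select`, `evaluate` and
`fetch-uci` subcommands (`--help` on each). See the methods vignette
(`vignettes/md-gene-selection.Rmd`) for the model, parameter rationale and
limitations.

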