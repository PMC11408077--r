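test_that("strongly separated data is classified almost perfectly", {
  sim <- simulate_expression(n0 = 20, n1 = 20, G = 100, n_informative = 5,
                             effect = 10, seed = 17)
  for (clf in c("rf", "knn")) {
    cfg <- eval_config(clf, cv_repeats = 2L, rf_trees = 200L, seed = 1L)
    res <- cv_error(sim$data, genes = sim$truth, config = cfg)
    expect_lte(res$mean_error, 0.05)
    expect_identical(res$n_folds_total, 10L)
    expect_gte(res$sd_error, 0)
  }
})

test_that("shuffled labels give chance-level error with a priori genes", {
  sim <- simulate_expression(n0 = 20, n1 = 20, G = 100, n_informative = 5,
                             effect = 10, seed = 19)
  set.seed(20)
  shuffled <- expression_dataset(sim$data$values, sample(sim$data$labels),
                                 gene_ids = sim$data$gene_ids)
  res <- cv_error(shuffled, genes = sim$truth,
                  config = eval_config("knn", cv_repeats = 4L, seed = 2L))
  # 3 x the binomial SD of the mean fold error around 1/2
  band <- 3 * sqrt(0.25 / 8) / sqrt(20)
  expect_lt(abs(res$mean_error - 0.5), max(band, 0.15))
})

test_that("cv_error is deterministic given the seed and restores the RNG", {
  sim <- simulate_expression(n0 = 10, n1 = 10, G = 30, effect = 2, seed = 23)
  cfg <- eval_config("rf", cv_repeats = 2L, rf_trees = 100L, seed = 5L)
  set.seed(77); before <- .Random.seed
  a <- cv_error(sim$data, genes = sim$truth, config = cfg)
  expect_identical(.Random.seed, before)
  b <- cv_error(sim$data, genes = sim$truth, config = cfg)
  expect_identical(a, b)
})

test_that("invalid evaluation requests fail loudly", {
  sim <- simulate_expression(n0 = 6, n1 = 6, G = 10, seed = 29)
  cfg <- eval_config("knn", cv_repeats = 1L)
  expect_error(cv_error(sim$data, genes = character(0), config = cfg),
               "empty gene list")
  expect_error(cv_error(sim$data, genes = "gX", config = cfg), "not in dataset")
  tiny <- eval_config("knn", cv_folds = 8L)
  expect_error(cv_error(sim$data, genes = sim$truth, config = tiny),
               "cv_folds")
  expect_error(eval_config("svm"))
})

test_that("error_grid covers the selections x classifiers grid and serializes losslessly", {
  sim <- simulate_expression(n0 = 12, n1 = 12, G = 40, n_informative = 3,
                             effect = 8, seed = 31)
  fit <- mdselect(sim$data)
  grid <- selection_grid(fit, methods = c("md", "snr"), ks = c(3L, 5L))
  cfg <- eval_config(cv_repeats = 1L, rf_trees = 100L, seed = 3L)
  report <- error_grid(sim$data, grid, config = cfg,
                       classifiers = c("rf", "knn"))
  expect_identical(nrow(report), 8L)      # 4 selections x 2 classifiers
  expect_true(all(report$mean_error >= 0 & report$mean_error <= 1))
  expect_identical(report$classifier, rep(c("rf", "knn"), 4L))

  path <- withr::local_tempfile(fileext = ".csv")
  write_error_report(report, path)
  back <- read_error_report(path)
  expect_equal(as.data.frame(back), as.data.frame(report))

  wide <- pivot_error_report(report)
  expect_identical(names(wide), c("rf", "knn"))
  expect_identical(dim(wide$rf), c(2L, 2L))
})

test_that("nested selection is no more optimistic than pre-CV selection on pure noise", {
  # pre-CV selection (genes chosen on all samples) leaks test information;
  # on noise-only data its error dips below chance while nested stays at 1/2
  diffs <- vapply(1:20, function(s) {
    sim <- simulate_expression(n0 = 20, n1 = 20, G = 150, n_informative = 0,
                               effect = 0, seed = 4000 + s)
    fit <- mdselect(sim$data)
    top <- select_top_k(fit, "md", 5)$gene_ids
    pre <- cv_error(sim$data, genes = top,
                    config = eval_config("knn", cv_repeats = 1L, seed = s))
    nested <- cv_error(sim$data,
                       config = eval_config("knn", cv_repeats = 1L, seed = s,
                                            selection_mode = "nested"),
                       method = "md", k = 5)
    nested$mean_error - pre$mean_error
  }, numeric(1))
  test <- stats::binom.test(sum(diffs > 0), sum(diffs != 0),
                            alternative = "greater")
  expect_lt(test$p.value, 0.05)
})
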