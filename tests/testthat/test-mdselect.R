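test_that("the separable toy gene ranks first under all four methods", {
  fit <- mdselect(fixture_suite()$toy$data)
  g2 <- fit$scores[fit$scores$gene_id == "g2", ]
  expect_identical(
    unlist(g2[, c("rank_snr", "rank_fisher", "rank_wilcoxon", "rank_md")]),
    c(rank_snr = 1L, rank_fisher = 1L, rank_wilcoxon = 1L, rank_md = 1L))
})

test_that("ranks are a permutation of 1..G for every method", {
  set.seed(71)
  fit <- mdselect(random_dataset(6, 6, 15))
  for (col in c("rank_snr", "rank_fisher", "rank_wilcoxon", "rank_md")) {
    expect_setequal(fit$scores[[col]], 1:15)
  }
})

test_that("permuting gene columns permutes every score vector identically", {
  set.seed(72)
  d <- random_dataset(5, 7, 12)
  perm <- sample(12)
  dp <- expression_dataset(d$values[, perm], d$labels,
                           gene_ids = d$gene_ids[perm])
  s1 <- mdselect(d)$scores
  s2 <- mdselect(dp)$scores
  s2 <- s2[match(s1$gene_id, s2$gene_id), ]
  for (col in c("snr", "fisher", "wilcoxon_p", "mood_p", "md")) {
    expect_equal(s2[[col]], s1[[col]], tolerance = 1e-12, label = col)
  }
})

test_that("location shift and positive scaling leave all four statistics unchanged", {
  set.seed(73)
  d <- random_dataset(6, 8, 10)
  base <- mdselect(d)$scores
  for (tf in list(function(x) x + 17.3, function(x) x * 4.2)) {
    s <- mdselect(expression_dataset(tf(d$values), d$labels,
                                     gene_ids = d$gene_ids))$scores
    for (col in c("snr", "fisher", "wilcoxon_p", "mood_p")) {
      expect_equal(s[[col]], base[[col]], tolerance = 1e-9, label = col)
    }
  }
})

test_that("shuffled labels make the planted gene's rank uniform over 1..G", {
  set.seed(74)
  G <- 20
  ranks <- vapply(1:200, function(i) {
    sim <- simulate_expression(n0 = 6, n1 = 6, G = G, n_informative = 1,
                               effect = 5, seed = 6000 + i)
    lab <- sample(sim$data$labels)
    d <- expression_dataset(sim$data$values, lab, gene_ids = sim$data$gene_ids)
    mdselect(d)$scores$rank_md[1L]
  }, numeric(1))
  # KS sanity check against discrete uniform on 1..G (jittered to break ties)
  ks <- suppressWarnings(
    stats::ks.test((ranks - runif(200)) / G, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(ranks), G / 2 - 3)
  expect_lt(mean(ranks), G / 2 + 3)
})

test_that("formula and default interfaces agree with the dataset method", {
  set.seed(75)
  d <- random_dataset(5, 5, 6)
  df <- as.data.frame(d$values)
  df$class <- d$labels
  f1 <- mdselect(d)
  f2 <- mdselect(class ~ ., data = df)
  f3 <- mdselect(d$values, labels = d$labels)
  expect_equal(f2$scores, f1$scores)
  expect_equal(f3$scores, f1$scores)
})

test_that("print, summary, coef and plot methods work", {
  set.seed(76)
  fit <- mdselect(random_dataset(5, 5, 8))
  expect_output(print(fit), "Top 5 genes by Md")
  expect_output(print(summary(fit)), "Spearman agreement")
  cf <- coef(fit)
  expect_identical(dim(cf), c(8L, 5L))
  expect_identical(colnames(cf), c("snr", "fisher", "wilcoxon_p", "mood_p", "md"))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit, k = 3))
})
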