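# minimal score table for direct-sort checks
mini_table <- data.frame(
  gene_id = c("g1", "g2", "g3"),
  snr = c(5, 1, 9), fisher = c(5, 1, 9),
  wilcoxon_p = c(0.5, 0.9, 0.1), mood_p = c(0.5, 0.9, 0.1),
  md = c(5, 1, 9),
  rank_snr = c(2L, 3L, 1L), rank_fisher = c(2L, 3L, 1L),
  rank_wilcoxon = c(2L, 3L, 1L), rank_md = c(2L, 3L, 1L))

test_that("top-k is a direct sort by the method's rank", {
  sel <- select_top_k(mini_table, "md", 2)
  expect_identical(sel$gene_ids, c("g3", "g1"))
  expect_identical(sel$scores, c(9, 5))

  all3 <- select_top_k(mini_table, "wilcoxon", 3)
  expect_identical(all3$gene_ids, c("g3", "g1", "g2"))
  expect_true(all(diff(all3$scores) >= 0))   # P-values non-decreasing
})

test_that("k > G truncates with a warning; bad inputs error", {
  expect_warning(sel <- select_top_k(mini_table, "md", 10), "exceeds")
  expect_identical(sel$k, 3L)
  expect_error(select_top_k(mini_table, "pca", 2), "md, snr, fisher, wilcoxon")
  expect_error(select_top_k(mini_table, "md", 0), "positive")
})

test_that("ties go to the earlier gene column", {
  set.seed(81)
  d <- random_dataset(4, 4, 3)
  d$values[, 2] <- d$values[, 1]          # g2 duplicates g1: all scores tie
  fit <- mdselect(expression_dataset(d$values, d$labels))
  for (m in c("md", "snr", "fisher", "wilcoxon")) {
    sel <- select_top_k(fit, m, 3)
    expect_lt(match("g1", sel$gene_ids), match("g2", sel$gene_ids))
  }
})

test_that("grid has methods x ks cardinality and the prefix property", {
  set.seed(82)
  fit <- mdselect(random_dataset(8, 8, 25))
  grid <- selection_grid(fit, ks = c(5L, 10L, 15L, 20L))
  expect_length(grid, 16L)
  for (m in c("md", "snr", "fisher", "wilcoxon")) {
    sub <- Filter(function(s) s$method == m, grid)
    ks <- vapply(sub, `[[`, integer(1), "k")
    sub <- sub[order(ks)]
    for (i in seq_len(length(sub) - 1L)) {
      expect_identical(sub[[i]]$gene_ids,
                       sub[[i + 1L]]$gene_ids[seq_len(sub[[i]]$k)])
    }
  }
  expect_error(selection_grid(fit, methods = character(0)), "non-empty")
})

test_that("selection is invariant to gene column order and reruns", {
  set.seed(83)
  d <- random_dataset(6, 6, 12)
  perm <- sample(12)
  dp <- expression_dataset(d$values[, perm], d$labels,
                           gene_ids = d$gene_ids[perm])
  # continuous scores: ids match exactly (ties have probability zero)
  g1 <- selection_grid(mdselect(d), methods = c("md", "snr", "fisher"),
                       ks = c(3L, 6L))
  g2 <- selection_grid(mdselect(dp), methods = c("md", "snr", "fisher"),
                       ks = c(3L, 6L))
  g3 <- selection_grid(mdselect(d), methods = c("md", "snr", "fisher"),
                       ks = c(3L, 6L))
  expect_identical(lapply(g1, `[[`, "gene_ids"), lapply(g2, `[[`, "gene_ids"))
  expect_identical(g1, g3)
  # the Wilcoxon P is discrete at this n: tied genes reorder with the columns
  # (column-order tie rule), but the selected P-value multiset is invariant
  w1 <- select_top_k(mdselect(d), "wilcoxon", 6)
  w2 <- select_top_k(mdselect(dp), "wilcoxon", 6)
  expect_equal(sort(w1$scores), sort(w2$scores), tolerance = 1e-12)
})

test_that("selection writers produce the documented layouts", {
  set.seed(84)
  fit <- mdselect(random_dataset(5, 5, 10))
  grid <- selection_grid(fit, methods = c("md", "snr"), ks = c(2L, 4L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_selections(grid, path)
  tab <- read.csv(path)
  expect_identical(names(tab), c("method", "k", "rank", "gene_id", "score"))
  expect_identical(nrow(tab), 12L)        # 2+4 rows per method

  dir <- withr::local_tempdir()
  paths <- write_gene_lists(grid, dir)
  expect_length(paths, 4L)
  expect_identical(readLines(file.path(dir, "genes_md_k2.txt")),
                   grid[[1L]]$gene_ids)
})
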