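#' Cross-validation configuration
#'
#' Bundles the knobs of the error harness. Defaults: stratified 5-fold CV
#' repeated 10 times, K-NN with 3 neighbours and the Euclidean metric,
#' Random Forest with 500 trees and default split heuristics.
#'
#' @param classifier `"rf"` (Random Forest) or `"knn"`.
#' @param knn_neighbors neighbours for K-NN (default 3; odd avoids vote ties
#'   in two classes).
#' @param rf_trees trees for Random Forest (default 500).
#' @param cv_folds folds per repeat (default 5; must be >= 2 and no larger
#'   than the smaller class).
#' @param cv_repeats repeats of the whole fold split (default 10).
#' @param seed integer seed making fold assignment and RF growth reproducible.
#' @param selection_mode `"pre_cv"` (genes chosen once on the full data —
#'   the conventional, optimistically biased protocol) or `"nested"` (genes
#'   re-selected inside every training fold; unbiased).
#' @param standardize z-score each gene using training-fold mean/SD before
#'   K-NN (default `FALSE`; never applied to RF).
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(classifier = c("rf", "knn"), knn_neighbors = 3L,
                        rf_trees = 500L, cv_folds = 5L, cv_repeats = 10L,
                        seed = 1L, selection_mode = c("pre_cv", "nested"),
                        standardize = FALSE) {
  classifier <- match.arg(classifier)
  selection_mode <- match.arg(selection_mode)
  stopifnot(cv_folds >= 2L, cv_repeats >= 1L, knn_neighbors >= 1L,
            rf_trees >= 1L)
  structure(list(classifier = classifier,
                 knn_neighbors = as.integer(knn_neighbors),
                 rf_trees = as.integer(rf_trees),
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats),
                 seed = as.integer(seed), selection_mode = selection_mode,
                 standardize = isTRUE(standardize)),
            class = "eval_config")
}

# stratified fold ids for one repeat: within each class, shuffle and deal
# samples round-robin so every fold keeps both classes
.stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    if (length(idx) < folds) {
      stop(sprintf("class %d has %d samples; needs >= cv_folds = %d for stratification",
                   cl, length(idx), folds), call. = FALSE)
    }
    fold[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

.fit_predict <- function(train_x, train_y, test_x, config) {
  if (config$classifier == "knn") {
    if (config$standardize) {
      mu <- colMeans(train_x)
      sd <- apply(train_x, 2L, stats::sd)
      sd[sd == 0] <- 1
      train_x <- sweep(sweep(train_x, 2L, mu), 2L, sd, `/`)
      test_x <- sweep(sweep(test_x, 2L, mu), 2L, sd, `/`)
    }
    as.integer(as.character(
      class::knn(train_x, test_x, cl = factor(train_y),
                 k = config$knn_neighbors)))
  } else {
    fit <- randomForest::randomForest(x = train_x, y = factor(train_y),
                                      ntree = config$rf_trees)
    as.integer(as.character(stats::predict(fit, test_x)))
  }
}

#' Cross-validated misclassification error of a gene subset
#'
#' Mean and SD of the held-out misclassification fraction over
#' `cv_folds x cv_repeats` stratified folds, for one classifier. In the
#' default `pre_cv` mode the supplied `genes` (typically chosen on the full
#' data) are used in every fold; in `nested` mode the subset is re-selected
#' on each training fold with the given `method` and `k`, removing selection
#' bias. Deterministic given `config$seed`.
#'
#' @param data an [expression_dataset].
#' @param genes character vector of gene ids to use (`pre_cv` mode).
#' @param config an [eval_config()].
#' @param method,k ranking method and subset size for `nested` mode.
#' @return List with `mean_error`, `sd_error` (across folds) and
#'   `n_folds_total`.
#' @export
cv_error <- function(data, genes = NULL, config = eval_config(),
                     method = NULL, k = NULL) {
  stopifnot(inherits(data, "expression_dataset"),
            inherits(config, "eval_config"))
  nested <- config$selection_mode == "nested"
  if (nested) {
    if (is.null(method) || is.null(k)) {
      stop("nested selection needs `method` and `k`", call. = FALSE)
    }
  } else {
    if (is.null(genes) || !length(genes)) {
      stop("empty gene list", call. = FALSE)
    }
    missing <- setdiff(genes, data$gene_ids)
    if (length(missing)) {
      stop(sprintf("genes not in dataset: %s",
                   paste(utils::head(missing, 3L), collapse = ", ")),
           call. = FALSE)
    }
  }
  y <- data$labels
  errs <- numeric(0L)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(config$seed)
  for (rep in seq_len(config$cv_repeats)) {
    fold <- .stratified_folds(y, config$cv_folds)
    for (f in seq_len(config$cv_folds)) {
      test <- fold == f
      if (length(unique(y[!test])) < 2L || length(unique(y[test])) < 1L) {
        stop("a fold lost a class after stratification; data too small for config",
             call. = FALSE)
      }
      use <- if (nested) {
        train_data <- expression_dataset(data$values[!test, , drop = FALSE],
                                         y[!test])
        select_top_k(mdselect(train_data), method, k)$gene_ids
      } else {
        genes
      }
      train_x <- data$values[!test, use, drop = FALSE]
      test_x <- data$values[test, use, drop = FALSE]
      pred <- .fit_predict(train_x, y[!test], test_x, config)
      errs <- c(errs, mean(pred != y[test]))
    }
  }
  list(mean_error = mean(errs), sd_error = stats::sd(errs),
       n_folds_total = length(errs))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Error report over a selection grid
#'
#' Runs [cv_error()] for every (selection, classifier) pair — the shape of
#' the usual per-method, per-k average-error tables.
#'
#' @param data an [expression_dataset].
#' @param selections list of `selection_result` (from [selection_grid()]).
#' @param config an [eval_config()]; its `classifier` field is overridden per
#'   row by `classifiers`.
#' @param classifiers character vector, subset of `c("rf", "knn")`.
#' @return A data frame of class `error_report` with columns
#'   `method, k, classifier, mean_error, sd_error, n_folds_total`,
#'   selections-major then classifier.
#' @export
error_grid <- function(data, selections, config = eval_config(),
                       classifiers = c("rf", "knn")) {
  if (!length(selections)) stop("`selections` must be non-empty", call. = FALSE)
  stopifnot(all(classifiers %in% c("rf", "knn")))
  rows <- list()
  for (sel in selections) {
    for (clf in classifiers) {
      cfg <- config
      cfg$classifier <- clf
      res <- tryCatch(
        cv_error(data, genes = sel$gene_ids, config = cfg,
                 method = sel$method, k = sel$k),
        error = function(e) {
          stop(sprintf("cv_error failed for method=%s k=%d classifier=%s: %s",
                       sel$method, sel$k, clf, conditionMessage(e)),
               call. = FALSE)
        })
      rows[[length(rows) + 1L]] <- data.frame(
        method = sel$method, k = sel$k, classifier = clf,
        mean_error = res$mean_error, sd_error = res$sd_error,
        n_folds_total = res$n_folds_total)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("error_report", "data.frame")
  out
}

#' @export
print.error_report <- function(x, ...) {
  cat("Average CV misclassification error\n")
  print.data.frame(cbind(x[, c("method", "k", "classifier")],
                         mean_error = signif(x$mean_error, 4L),
                         sd_error = signif(x$sd_error, 4L)),
                   row.names = FALSE)
  invisible(x)
}

#' Pivot an error report to the wide per-classifier layout
#'
#' Rows = k, columns = method, one matrix per classifier — the visual layout
#' of the usual results tables.
#'
#' @param report an `error_report`.
#' @return Named list of matrices, one per classifier present.
#' @export
pivot_error_report <- function(report) {
  out <- list()
  for (clf in unique(report$classifier)) {
    sub <- report[report$classifier == clf, , drop = FALSE]
    ks <- sort(unique(sub$k))
    ms <- unique(sub$method)
    m <- matrix(NA_real_, length(ks), length(ms), dimnames = list(ks, ms))
    for (i in seq_len(nrow(sub))) {
      m[as.character(sub$k[i]), sub$method[i]] <- sub$mean_error[i]
    }
    out[[clf]] <- m
  }
  out
}

#' Write / read an error report as delimited text
#'
#' @param report an `error_report`.
#' @param path file path.
#' @param sep field delimiter.
#' @return `path` invisibly (write); an `error_report` (read).
#' @export
write_error_report <- function(report, path, sep = ",") {
  df <- as.data.frame(report)
  df$mean_error <- sprintf("%.17g", df$mean_error)
  df$sd_error <- sprintf("%.17g", df$sd_error)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_error_report
#' @export
read_error_report <- function(path, sep = ",") {
  out <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  class(out) <- c("error_report", "data.frame")
  out
}
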