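#' Configuration for an end-to-end run
#'
#' @param input path to a delimited expression file (see [read_expression()]).
#' @param output_dir directory for all artifacts (created if needed).
#' @param label_column label column (or row) name.
#' @param orientation `"samples"` or `"genes"` (see [read_expression()]).
#' @param sep delimiter, `NULL` to auto-detect.
#' @param methods ranking methods to run.
#' @param ks subset sizes.
#' @param classifiers classifiers for the error harness.
#' @param eval an [eval_config()].
#' @param force overwrite existing output files (default `FALSE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, output_dir, label_column = "class",
                       orientation = "samples", sep = NULL,
                       methods = c("md", "snr", "fisher", "wilcoxon"),
                       ks = c(5L, 10L, 15L, 20L), classifiers = c("rf", "knn"),
                       eval = eval_config(), force = FALSE) {
  bad <- setdiff(methods, c("md", "snr", "fisher", "wilcoxon"))
  if (length(bad)) {
    stop(sprintf("[config] unknown method(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(classifiers %in% c("rf", "knn"))) {
    stop("[config] classifiers must be a subset of rf, knn", call. = FALSE)
  }
  structure(list(input = input, output_dir = output_dir,
                 label_column = label_column, orientation = orientation,
                 sep = sep, methods = methods, ks = as.integer(ks),
                 classifiers = classifiers, eval = eval,
                 force = isTRUE(force)),
            class = "run_config")
}

#' Run the full score -> select -> evaluate pipeline
#'
#' Loads the dataset, scores every gene with all requested methods, selects
#' the top-k grids, estimates cross-validated classification error for every
#' (method, k, classifier) cell, and writes all artifacts as delimited text:
#' `scores.csv`, `selections.csv`, per-selection gene lists under
#' `gene_lists/`, `errors.csv`, a wide `errors_wide_<classifier>.csv` per
#' classifier, and a `manifest.txt` (config echo + seed + versions) that
#' suffices to reproduce the run.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the fitted `mdselect` object, the
#'   selections, the `error_report`, and the output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(paste0("[%s] ", fmt),
                                                        format(Sys.time(), "%H:%M:%S"), ...))
  if (!file.exists(config$input)) {
    stop(sprintf("[load] input not found: %s", config$input), call. = FALSE)
  }
  if (!dir.exists(config$output_dir)) dir.create(config$output_dir, recursive = TRUE)
  paths <- list(
    scores = file.path(config$output_dir, "scores.csv"),
    selections = file.path(config$output_dir, "selections.csv"),
    gene_lists = file.path(config$output_dir, "gene_lists"),
    errors = file.path(config$output_dir, "errors.csv"),
    manifest = file.path(config$output_dir, "manifest.txt")
  )
  existing <- unlist(paths[c("scores", "selections", "errors")])
  if (!config$force && any(file.exists(existing))) {
    stop(sprintf("[setup] output exists (use force = TRUE): %s",
                 existing[file.exists(existing)][1L]), call. = FALSE)
  }

  say("loading %s", config$input)
  data <- withCallingHandlers(
    read_expression(config$input, label_column = config$label_column,
                    orientation = config$orientation, sep = config$sep),
    message = function(m) { say("%s", sub("\n$", "", conditionMessage(m)))
                            invokeRestart("muffleMessage") })
  say("scoring %d genes on %d samples", ncol(data$values), nrow(data$values))
  fit <- mdselect(data)
  write_score_table(fit, paths$scores)

  say("selecting top-k grids (%s x k=%s)", paste(config$methods, collapse = ","),
      paste(config$ks, collapse = ","))
  selections <- selection_grid(fit, methods = config$methods, ks = config$ks)
  write_selections(selections, paths$selections)
  write_gene_lists(selections, paths$gene_lists)

  say("estimating CV error (%d selections x %d classifiers)",
      length(selections), length(config$classifiers))
  report <- error_grid(data, selections, config = config$eval,
                       classifiers = config$classifiers)
  write_error_report(report, paths$errors)
  wide <- pivot_error_report(report)
  for (clf in names(wide)) {
    p <- file.path(config$output_dir, sprintf("errors_wide_%s.csv", clf))
    utils::write.table(data.frame(k = rownames(wide[[clf]]), wide[[clf]],
                                  check.names = FALSE),
                       p, sep = ",", row.names = FALSE, quote = FALSE)
    paths[[paste0("wide_", clf)]] <- p
  }

  manifest <- c(
    sprintf("mdselect_version: %s", as.character(utils::packageVersion("mdselect"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("input: %s", config$input),
    sprintf("label_column: %s", config$label_column),
    sprintf("orientation: %s", config$orientation),
    sprintf("methods: %s", paste(config$methods, collapse = ",")),
    sprintf("ks: %s", paste(config$ks, collapse = ",")),
    sprintf("classifiers: %s", paste(config$classifiers, collapse = ",")),
    sprintf("seed: %d", config$eval$seed),
    sprintf("cv_folds: %d", config$eval$cv_folds),
    sprintf("cv_repeats: %d", config$eval$cv_repeats),
    sprintf("knn_neighbors: %d", config$eval$knn_neighbors),
    sprintf("rf_trees: %d", config$eval$rf_trees),
    sprintf("selection_mode: %s", config$eval$selection_mode),
    sprintf("standardize: %s", config$eval$standardize)
  )
  writeLines(manifest, paths$manifest)
  say("done; artifacts in %s", config$output_dir)
  invisible(list(fit = fit, selections = selections, report = report,
                 paths = paths))
}
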