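#' Experiment configuration for an STR-versus-MTSC comparison
#'
#' @param learners character vector of base learners to run (any subset of
#'   PLS, Ridge, Lasso, SVM-linear, RF).
#' @param k outer cross-validation fold count (default 10).
#' @param test_fraction held-out test fraction (default 0.1).
#' @param threshold candidate-pool filter: minimum mean CV R^2 an element's
#'   best STR model must reach to be usable as a chain feature (default
#'   0.55; scores exactly at the threshold are kept).
#' @param pool_aggregate how the filter aggregates an element's STR scores:
#'   `"best"` (its best learner's mean CV R^2, default) or `"mean"` (mean
#'   over all learners).
#' @param tolerance acceptance tolerance of the chaining loop (default 0).
#' @param inner_k inner fold count for leakage-safe chained features.
#' @param seed master seed: drives the split, fold assignment, RF fits and
#'   inner folds.
#' @param grids optional named list (by learner name) of hyperparameter
#'   grids overriding [default_grid()].
#' @param preprocess a [preprocess_config()].
#' @param naive use in-sample (non-leakage-safe) chained features; see
#'   [mtsc_control()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(learners = SUPPORTED_LEARNERS, k = 10,
                              test_fraction = 0.1, threshold = 0.55,
                              pool_aggregate = c("best", "mean"),
                              tolerance = 0, inner_k = 5, seed = 1L,
                              grids = NULL,
                              preprocess = preprocess_config(),
                              naive = FALSE) {
  stopifnot(all(learners %in% SUPPORTED_LEARNERS), length(learners) >= 1,
            threshold >= 0, threshold <= 1, tolerance >= 0)
  structure(list(learners = learners, k = k, test_fraction = test_fraction,
                 threshold = threshold,
                 pool_aggregate = match.arg(pool_aggregate),
                 tolerance = tolerance, inner_k = inner_k,
                 seed = as.integer(seed), grids = grids,
                 preprocess = preprocess, naive = isTRUE(naive)),
            class = "experiment_config")
}

make_spec <- function(config, learner) {
  grid <- if (!is.null(config$grids[[learner]])) config$grids[[learner]]
          else default_grid(learner)
  learner_spec(learner, grid, seed = config$seed)
}

#' Run the full STR-versus-MTSC comparison
#'
#' End-to-end experiment: (1) train/test split and preprocessing (states
#' fitted on the training split, applied to the test split); (2) exhaustive
#' grid search per (element, learner); (3) STR for every pair; (4) best STR
#' learner per element; (5) candidate-pool filter; (6) MTSC per (element,
#' learner); (7) best MTSC per element; (8) paired two-sided Wilcoxon
#' signed-rank test on the k fold R^2 values of best-STR vs best-MTSC; (9)
#' final models refit on the full training split and scored on the held-out
#' test split.
#'
#' @param dataset an `ion_dataset` of raw reflectance spectra and element
#'   concentrations.
#' @param config an [experiment_config()].
#' @return An object of class `comparison_report`; see
#'   [print.comparison_report()] and [write_report()].
#' @export
run_experiment <- function(dataset, config = experiment_config()) {
  stopifnot(inherits(dataset, "ion_dataset"),
            inherits(config, "experiment_config"))
  elements <- dataset$elements$element_names
  split <- split_dataset(dataset, config$test_fraction, config$k, config$seed)

  train <- subset_dataset(dataset, split$train_ids)
  test <- subset_dataset(dataset, split$test_ids)
  pp <- preprocess_spectra(train$spectra, config$preprocess)
  kept_ids <- pp$spectra$sample_ids
  train_el <- element_table(
    train$elements$values[match(kept_ids, train$elements$sample_ids), ,
                          drop = FALSE], kept_ids, elements)
  dtrain <- ion_dataset(pp$spectra, train_el)
  ptest <- preprocess_spectra(test$spectra, config$preprocess, state = pp$state)
  dtest <- ion_dataset(ptest$spectra, test$elements)
  folds <- unname(split$fold_assignments[kept_ids])

  message("Tuning ", length(elements), " element(s) x ",
          length(config$learners), " learner(s) ...")
  tuned <- list(); str_fits <- list()
  for (ln in config$learners) {
    tuned[[ln]] <- list(); str_fits[[ln]] <- list()
    for (el in elements) {
      sp <- grid_search(make_spec(config, ln), dtrain$spectra$values,
                        dtrain$elements$values[, el], folds)
      tuned[[ln]][[el]] <- sp
      str_fits[[ln]][[el]] <- fit_str(dtrain, el, sp, folds)
    }
  }

  str_r2 <- sapply(config$learners, function(ln)
    vapply(str_fits[[ln]], `[[`, numeric(1), "mean_r2"))
  str_r2 <- matrix(str_r2, nrow = length(elements),
                   dimnames = list(elements, config$learners))
  str_rmse <- sapply(config$learners, function(ln)
    vapply(str_fits[[ln]], `[[`, numeric(1), "mean_rmse"))
  str_rmse <- matrix(str_rmse, nrow = length(elements),
                     dimnames = list(elements, config$learners))
  best_str <- vapply(elements, function(el) {
    config$learners[order(-str_r2[el, ], str_rmse[el, ])[1]]
  }, character(1))

  pool_scores <- switch(config$pool_aggregate,
    best = apply(str_r2, 1, max),
    mean = rowMeans(str_r2))
  pool <- filter_candidates(pool_scores, config$threshold)
  message("Chain candidate pool: ",
          if (length(pool)) paste(pool, collapse = ", ") else "(empty)")

  control <- mtsc_control(tolerance = config$tolerance,
                          inner_k = config$inner_k, naive = config$naive,
                          seed = config$seed)
  mtsc_fits <- list()
  for (ln in config$learners) {
    mtsc_fits[[ln]] <- list()
    for (el in elements) {
      message("MTSC [", ln, "] target ", el)
      mtsc_fits[[ln]][[el]] <- fit_mtsc(dtrain, el, setdiff(pool, el),
                                        tuned[[ln]], folds, control)
    }
  }
  mtsc_r2 <- sapply(config$learners, function(ln)
    vapply(mtsc_fits[[ln]], `[[`, numeric(1), "mean_r2"))
  mtsc_r2 <- matrix(mtsc_r2, nrow = length(elements),
                    dimnames = list(elements, config$learners))
  mtsc_rmse <- sapply(config$learners, function(ln)
    vapply(mtsc_fits[[ln]], `[[`, numeric(1), "mean_rmse"))
  mtsc_rmse <- matrix(mtsc_rmse, nrow = length(elements),
                      dimnames = list(elements, config$learners))
  best_mtsc <- vapply(elements, function(el) {
    config$learners[order(-mtsc_r2[el, ], mtsc_rmse[el, ])[1]]
  }, character(1))

  rows <- lapply(elements, function(el) {
    sfit <- str_fits[[best_str[el]]][[el]]
    mfit <- mtsc_fits[[best_mtsc[el]]][[el]]
    wc <- wilcoxon_paired(mfit$fold_r2, sfit$fold_r2)
    # test-split scoring of the two selected models
    str_final <- fit_scaled(tuned[[best_str[el]]][[el]],
                            dtrain$spectra$values,
                            dtrain$elements$values[, el])
    yhat_s <- predict(str_final, dtest$spectra$values)
    yhat_m <- predict(mfit, dtest$spectra)
    yte <- dtest$elements$values[, el]
    data.frame(
      element = el,
      str_model = best_str[[el]], str_r2 = sfit$mean_r2,
      str_rmse = sfit$mean_rmse,
      mtsc_model = best_mtsc[[el]],
      chain = paste(mfit$chain, collapse = "-"),
      mtsc_r2 = mfit$mean_r2, mtsc_rmse = mfit$mean_rmse,
      delta_r2_pct = mean(delta_percent(mfit$fold_r2, sfit$fold_r2)),
      delta_rmse_pct = mean(delta_percent(mfit$fold_rmse, sfit$fold_rmse)),
      delta_r2_pct_of_means = delta_percent(mfit$mean_r2, sfit$mean_r2),
      delta_rmse_pct_of_means = delta_percent(mfit$mean_rmse, sfit$mean_rmse),
      wilcoxon_p = wc$p.value,
      significance = significance_label(wc$p.value),
      test_str_r2 = r_squared(yte, yhat_s),
      test_str_rmse = rmse(yte, yhat_s),
      test_mtsc_r2 = r_squared(yte, yhat_m),
      test_mtsc_rmse = rmse(yte, yhat_m),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  table3 <- do.call(rbind, rows)

  fold_rows <- list()
  for (ln in config$learners) for (el in elements) {
    s <- str_fits[[ln]][[el]]; m <- mtsc_fits[[ln]][[el]]
    fold_rows[[paste(ln, el)]] <- data.frame(
      element = el, learner = ln, fold = seq_along(s$fold_r2),
      str_r2 = s$fold_r2, str_rmse = s$fold_rmse,
      mtsc_r2 = m$fold_r2, mtsc_rmse = m$fold_rmse,
      stringsAsFactors = FALSE)
  }
  per_fold <- do.call(rbind, c(fold_rows, list(make.row.names = FALSE)))

  manifest <- list(
    seed = config$seed, k = config$k, test_fraction = config$test_fraction,
    threshold = config$threshold, pool_aggregate = config$pool_aggregate,
    tolerance = config$tolerance, inner_k = config$inner_k,
    naive = config$naive,
    n_total = length(dataset$spectra$sample_ids),
    n_train = length(kept_ids), n_test = length(split$test_ids),
    removed_outlier_ids = pp$removed_ids,
    pool = pool,
    tuned = lapply(tuned, function(by_el)
      lapply(by_el, function(sp) sp$tuned)),
    chains = lapply(mtsc_fits, function(by_el)
      lapply(by_el, `[[`, "chain")))

  structure(list(table = table3, per_fold = per_fold, pool = pool,
                 split = split, manifest = manifest,
                 str_fits = str_fits, mtsc_fits = mtsc_fits,
                 config = config),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("STR vs MTSC comparison (", x$manifest$n_train, " train / ",
      x$manifest$n_test, " test samples, k = ", x$manifest$k, ")\n", sep = "")
  cat("Chain candidate pool:",
      if (length(x$pool)) paste(x$pool, collapse = ", ") else "(empty)", "\n\n")
  df <- x$table[, c("element", "str_model", "str_r2", "str_rmse",
                    "mtsc_model", "chain", "mtsc_r2", "mtsc_rmse",
                    "wilcoxon_p", "significance")]
  df$str_r2 <- round(df$str_r2, 3); df$mtsc_r2 <- round(df$mtsc_r2, 3)
  df$str_rmse <- signif(df$str_rmse, 4); df$mtsc_rmse <- signif(df$mtsc_rmse, 4)
  df$wilcoxon_p <- signif(df$wilcoxon_p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits `comparison.csv` (one row per element, the Table-3-style summary
#' with cross-validation and test metrics), `per_fold.csv` (long format:
#' element x learner x fold metrics), and `manifest.json` (seeds, tuned
#' configurations, pool and chains) so a run can be replayed exactly. Output
#' is deterministic: identical configuration and seed give byte-identical
#' files.
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table, file.path(dir, "comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$per_fold, file.path(dir, "per_fold.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
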