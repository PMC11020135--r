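#' Control parameters of the sequential chaining loop
#'
#' @param tolerance minimum improvement in mean CV R^2 required to accept a
#'   chained element (default 0: strict improvement).
#' @param inner_k inner fold count used to build leakage-safe out-of-fold
#'   chained features inside each outer training fold (default 5).
#' @param naive if `TRUE`, chained features for training rows are in-sample
#'   predictions of a candidate model fitted on the whole outer training
#'   fold (a literal reading of the chaining scheme, kept for comparison);
#'   default `FALSE` (stacked-generalization safeguard).
#' @param seed integer seed controlling inner fold assignment.
#' @return An object of class `mtsc_control`.
#' @export
mtsc_control <- function(tolerance = 0, inner_k = 5, naive = FALSE, seed = 1L) {
  stopifnot(tolerance >= 0, inner_k >= 2)
  structure(list(tolerance = tolerance, inner_k = as.integer(inner_k),
                 naive = isTRUE(naive), seed = as.integer(seed)),
            class = "mtsc_control")
}

# Fit a learner on a min-max-scaled response; returns an object that
# predicts on the ppm scale.
fit_scaled <- function(spec, X, y) {
  sc <- minmax_scale(matrix(y, dimnames = list(NULL, ".y")))
  fit <- fit_learner(spec, X, sc$elements[, 1])
  structure(list(fit = fit, scaler = sc$state), class = "scaled_learner")
}

#' @export
predict.scaled_learner <- function(object, newdata, ...) {
  minmax_invert(predict(object$fit, newdata), object$scaler, ".y")
}

add_col <- function(M, v, name) {
  M2 <- cbind(M, v)
  colnames(M2)[ncol(M2)] <- name
  M2
}

pick_spec <- function(specs, element) {
  if (inherits(specs, "learner_spec")) return(specs)
  sp <- specs[[element]]
  if (is.null(sp)) stop("no learner spec supplied for element '", element, "'")
  sp
}

#' Single-target regression baseline
#'
#' Fits one learner to predict a single element from the spectral features
#' alone, evaluated by k-fold out-of-fold prediction. This is the STR
#' baseline that sequential chaining is compared against.
#'
#' @param dataset an `ion_dataset` whose spectra are the model features
#'   (normally the preprocessed derivative spectra).
#' @param target element name to predict.
#' @param spec a tuned [learner_spec()].
#' @param folds integer fold ids, one per dataset sample.
#' @return An object of class `str_fit` with per-fold and mean R^2/RMSE (ppm)
#'   and the out-of-fold prediction vector.
#' @export
fit_str <- function(dataset, target, spec, folds) {
  stopifnot(inherits(dataset, "ion_dataset"))
  if (!target %in% dataset$elements$element_names)
    stop("unknown target element '", target, "'")
  X <- dataset$spectra$values
  y <- dataset$elements$values[, target]
  op <- oof_predict(spec, X, y, folds)
  structure(list(target = target, spec = spec, folds = as.integer(folds),
                 fold_r2 = op$fold_r2, fold_rmse = op$fold_rmse,
                 mean_r2 = mean(op$fold_r2), mean_rmse = mean(op$fold_rmse),
                 oof = op$oof, n = length(y)),
            class = "str_fit")
}

#' @export
print.str_fit <- function(x, ...) {
  cat("STR fit for ", x$target, " (", x$spec$name, ", ",
      length(x$fold_r2), "-fold CV)\n", sep = "")
  cat(sprintf("  mean R2 = %.3f, mean RMSE = %.4g (ppm)\n",
              x$mean_r2, x$mean_rmse))
  invisible(x)
}

#' Filter the pool of chainable elements
#'
#' Elements whose cross-validated STR accuracy falls below `threshold` are
#' excluded from the pool of candidate chain features (they are still
#' predicted as targets; only their use as augmenting inputs is dropped).
#' The boundary is kept: a score exactly at the threshold stays in the pool.
#'
#' @param str_results named numeric vector of mean CV R^2 per element, or a
#'   list of `str_fit` objects.
#' @param threshold minimum mean CV R^2 (default 0.55).
#' @return Character vector of pool element names.
#' @export
filter_candidates <- function(str_results, threshold = 0.55) {
  if (is.list(str_results) && all(vapply(str_results, inherits, logical(1),
                                         "str_fit"))) {
    scores <- vapply(str_results, `[[`, numeric(1), "mean_r2")
    names(scores) <- vapply(str_results, `[[`, character(1), "target")
  } else scores <- str_results
  if (length(scores) == 0) stop("no STR results to filter")
  if (is.null(names(scores))) stop("scores must be named by element")
  names(scores)[scores >= threshold]
}

# Build the chained feature column for candidate `cand` under outer fold f:
# validation rows get predictions from a candidate model fitted on the other
# folds; training rows get inner out-of-fold predictions (or in-sample
# predictions in naive mode), so the target model never sees a feature value
# informed by that row's own concentration.
candidate_column <- function(cand, f, X, chain_col_f, E, folds, spec_c,
                             control) {
  tr <- folds != f
  Fc <- cbind(X, chain_col_f)
  e <- rep(NA_real_, nrow(X))
  if (control$naive) {
    m <- fit_scaled(spec_c, Fc[tr, , drop = FALSE], E[tr, cand])
    e[tr] <- predict(m, Fc[tr, , drop = FALSE])
  } else {
    inner <- make_folds(sum(tr), control$inner_k,
                        seed = control$seed + 1000L * f)
    e[tr] <- oof_predict(spec_c, Fc[tr, , drop = FALSE], E[tr, cand],
                         inner)$oof
    m <- fit_scaled(spec_c, Fc[tr, , drop = FALSE], E[tr, cand])
  }
  e[!tr] <- predict(m, Fc[!tr, , drop = FALSE])
  e
}

#' Multi-target sequential chaining
#'
#' The forward-selection regressor chain: starting from the spectra-only STR
#' baseline, each iteration (1) produces, for every remaining pool element,
#' a leakage-safe out-of-fold prediction feature from the current feature
#' set, (2) re-evaluates the target model with that feature appended, by the
#' same k folds, and (3) appends the element whose augmented model attains
#' the highest mean CV R^2 — provided it improves on the current best (ties
#' broken by lower mean RMSE, then element name). The loop stops at the
#' first iteration with no improvement.
#'
#' @param dataset an `ion_dataset` (preprocessed spectra as features).
#' @param target element to predict; never part of the pool.
#' @param pool character vector of candidate chain elements (normally from
#'   [filter_candidates()]).
#' @param specs a tuned [learner_spec()] used for target and candidate
#'   models alike, or a named list of tuned specs per element.
#' @param folds integer fold ids, one per sample.
#' @param control an [mtsc_control()].
#' @return An object of class `mtsc_fit`: accepted `chain` (in order), the
#'   per-iteration candidate `log`, per-fold and mean metrics, the strictly
#'   increasing accepted-score `trajectory` (starting at the STR baseline),
#'   the `str` baseline fit, and final models refit on all samples for
#'   test-time prediction via [predict.mtsc_fit()].
#' @export
fit_mtsc <- function(dataset, target, pool, specs, folds,
                     control = mtsc_control()) {
  stopifnot(inherits(dataset, "ion_dataset"), inherits(control, "mtsc_control"))
  pool <- setdiff(as.character(pool), target)
  bad <- setdiff(pool, dataset$elements$element_names)
  if (length(bad)) stop("pool elements not in dataset: ",
                        paste(bad, collapse = ", "))
  X <- dataset$spectra$values
  E <- dataset$elements$values
  folds <- as.integer(folds)
  fold_ids <- sort(unique(folds))
  spec_t <- pick_spec(specs, target)

  str0 <- fit_str(dataset, target, spec_t, folds)
  best_r2 <- str0$mean_r2
  best_fold_r2 <- str0$fold_r2
  best_fold_rmse <- str0$fold_rmse
  trajectory <- best_r2
  chain <- character(0)
  # accepted chain feature columns, one matrix per outer fold (values differ
  # by fold because the leakage-safe construction is fold-specific)
  chain_cols <- replicate(length(fold_ids),
                          matrix(numeric(0), nrow(X), 0), simplify = FALSE)
  log <- list()
  remaining <- pool

  while (length(remaining) > 0) {
    cand_cols <- list(); cand_r2 <- list(); cand_rmse <- list()
    for (cand in remaining) {
      spec_c <- pick_spec(specs, cand)
      ecols <- lapply(seq_along(fold_ids), function(fi)
        candidate_column(cand, fold_ids[fi], X, chain_cols[[fi]], E, folds,
                         spec_c, control))
      fr2 <- numeric(length(fold_ids)); frmse <- numeric(length(fold_ids))
      for (fi in seq_along(fold_ids)) {
        f <- fold_ids[fi]
        tr <- folds != f
        Ff <- add_col(cbind(X, chain_cols[[fi]]), ecols[[fi]],
                      paste0("Ehat_", cand))
        m <- fit_scaled(spec_t, Ff[tr, , drop = FALSE], E[tr, target])
        yhat <- predict(m, Ff[!tr, , drop = FALSE])
        fr2[fi] <- r_squared(E[!tr, target], yhat)
        frmse[fi] <- rmse(E[!tr, target], yhat)
      }
      if (any(!is.finite(fr2)))
        stop("non-finite metric for candidate '", cand, "' at chain length ",
             length(chain))
      cand_cols[[cand]] <- ecols
      cand_r2[[cand]] <- fr2
      cand_rmse[[cand]] <- frmse
    }
    mean_r2 <- vapply(cand_r2, mean, numeric(1))
    mean_rmse <- vapply(cand_rmse, mean, numeric(1))
    ord <- order(-mean_r2, mean_rmse, names(mean_r2))
    star <- names(mean_r2)[ord[1]]
    log[[length(log) + 1]] <- data.frame(
      iteration = length(log) + 1L, candidate = names(mean_r2),
      mean_r2 = unname(mean_r2), mean_rmse = unname(mean_rmse),
      accepted = names(mean_r2) == star & mean_r2[star] > best_r2 + control$tolerance,
      row.names = NULL, stringsAsFactors = FALSE)
    if (mean_r2[star] > best_r2 + control$tolerance) {
      chain <- c(chain, star)
      for (fi in seq_along(fold_ids))
        chain_cols[[fi]] <- add_col(chain_cols[[fi]], cand_cols[[star]][[fi]],
                                    paste0("Ehat_", star))
      best_r2 <- mean_r2[[star]]
      best_fold_r2 <- cand_r2[[star]]
      best_fold_rmse <- cand_rmse[[star]]
      trajectory <- c(trajectory, best_r2)
      remaining <- setdiff(remaining, star)
    } else break
  }

  # final refit on all samples for held-out prediction: chain features for
  # the rows at hand come from inner out-of-fold prediction; the stored
  # candidate models are refit on all rows for new-data feature generation
  chain_models <- list()
  Ftr <- X
  for (cand in chain) {
    spec_c <- pick_spec(specs, cand)
    inner <- make_folds(nrow(X), control$inner_k, seed = control$seed)
    ecol <- oof_predict(spec_c, Ftr, E[, cand], inner)$oof
    chain_models[[cand]] <- fit_scaled(spec_c, Ftr, E[, cand])
    Ftr <- add_col(Ftr, ecol, paste0("Ehat_", cand))
  }
  target_model <- fit_scaled(spec_t, Ftr, E[, target])

  structure(list(target = target, chain = chain, pool = pool,
                 spec = spec_t, control = control, folds = folds,
                 log = do.call(rbind, log),
                 trajectory = unname(trajectory),
                 fold_r2 = unname(best_fold_r2),
                 fold_rmse = unname(best_fold_rmse),
                 mean_r2 = unname(best_r2), mean_rmse = mean(best_fold_rmse),
                 str = str0,
                 chain_models = chain_models, target_model = target_model,
                 n = nrow(X)),
            class = "mtsc_fit")
}

#' @export
print.mtsc_fit <- function(x, ...) {
  cat("MTSC fit for ", x$target, " (", x$spec$name, ", ",
      length(x$fold_r2), "-fold CV)\n", sep = "")
  cat("  chain: ", if (length(x$chain)) paste(x$chain, collapse = "-")
      else "(empty; equals STR)", "\n", sep = "")
  cat(sprintf("  mean R2 = %.3f (STR baseline %.3f), mean RMSE = %.4g ppm\n",
              x$mean_r2, x$str$mean_r2, x$mean_rmse))
  invisible(x)
}

#' @export
summary.mtsc_fit <- function(object, ...) {
  cat("Multi-target sequential chaining -- target:", object$target, "\n")
  cat("Learner:", object$spec$name, "| pool:",
      paste(object$pool, collapse = ", "), "\n")
  cat("Accepted-score trajectory:",
      paste(sprintf("%.4f", object$trajectory), collapse = " -> "), "\n\n")
  if (!is.null(object$log)) {
    cat("Per-iteration candidate scores:\n")
    print(object$log, digits = 4)
  }
  invisible(object)
}

#' Accepted-score trajectory plot
#'
#' Plots the mean CV R^2 of the target model at the STR baseline and after
#' each accepted chain element; the curve is strictly increasing by
#' construction of the acceptance rule.
#'
#' @param x an `mtsc_fit`.
#' @param ... passed to [plot()].
#' @export
plot.mtsc_fit <- function(x, ...) {
  steps <- c("STR", x$chain)
  plot(seq_along(x$trajectory) - 1, x$trajectory, type = "b", xaxt = "n",
       xlab = "chain length", ylab = expression(mean ~ CV ~ R^2),
       main = paste("MTSC trajectory:", x$target), ...)
  graphics::axis(1, at = seq_along(x$trajectory) - 1, labels = steps)
  invisible(x)
}

#' Predict element concentrations for new spectra from a chained model
#'
#' Sequentially reconstructs the chained prediction features for the new
#' samples using the stored candidate models, then applies the final target
#' model. New spectra must be preprocessed the same way as the training
#' spectra (same derivative bands).
#'
#' @param object an `mtsc_fit`.
#' @param newdata a `spectral_table` or numeric matrix with the training
#'   bands as columns.
#' @param ... unused.
#' @return Numeric vector of predicted target concentrations (ppm).
#' @export
predict.mtsc_fit <- function(object, newdata, ...) {
  Fnew <- if (inherits(newdata, "spectral_table")) newdata$values
          else as.matrix(newdata)
  for (cand in object$chain) {
    e <- predict(object$chain_models[[cand]], Fnew)
    Fnew <- add_col(Fnew, e, paste0("Ehat_", cand))
  }
  predict(object$target_model, Fnew)
}
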