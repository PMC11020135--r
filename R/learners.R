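SUPPORTED_LEARNERS <- c("PLS", "Ridge", "Lasso", "SVM-linear", "RF")

#' Default hyperparameter grid for a base learner
#'
#' Materializes the tuning ranges of the five supported learners as concrete
#' grids (one row per candidate configuration):
#' PLS components 1..20; Ridge/Lasso regularization strength `10^x` for 8
#' evenly spaced exponents on \[-4, -0.5\]; SVM-linear gamma in 4 log-spaced
#' points on \[1e-4, 0.1\] crossed with cost in 5 log-spaced points on
#' \[0.1, 1000\]; RF with 300 trees and a cross of feature fraction
#' \{0.15, 0.3, 0.45, 0.6\}, max depth \{2, 8, 16, 32\}, minimum node size
#' \{2, 4, 8\} and bagging fraction \{0.7, 0.8, 0.9\}. Point densities are
#' package defaults within those ranges and can be overridden via
#' [learner_spec()].
#'
#' @param name one of `"PLS"`, `"Ridge"`, `"Lasso"`, `"SVM-linear"`, `"RF"`.
#' @return A data frame, one row per configuration.
#' @export
default_grid <- function(name) {
  switch(name,
    "PLS"   = data.frame(ncomp = 1:20),
    "Ridge" = data.frame(lambda = 10^seq(-4, -0.5, length.out = 8)),
    "Lasso" = data.frame(lambda = 10^seq(-4, -0.5, length.out = 8)),
    "SVM-linear" = expand.grid(gamma = 10^seq(-4, -1, length.out = 4),
                               cost = 10^seq(-1, 3, length.out = 5)),
    "RF" = expand.grid(num_trees = 300,
                       mtry_frac = c(0.15, 0.3, 0.45, 0.6),
                       max_depth = c(2, 8, 16, 32),
                       min_node = c(2, 4, 8),
                       sample_frac = c(0.7, 0.8, 0.9)),
    stop("unsupported learner '", name, "'; supported: ",
         paste(SUPPORTED_LEARNERS, collapse = ", ")))
}

#' Base-learner specification
#'
#' @param name one of `"PLS"`, `"Ridge"`, `"Lasso"`, `"SVM-linear"`, `"RF"`.
#' @param grid hyperparameter grid (data frame, one row per configuration);
#'   defaults to [default_grid()].
#' @param seed integer seed for stochastic learners (RF).
#' @param tuned optional named list fixing a configuration (must be a row of
#'   the grid); set by [grid_search()].
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(name, grid = default_grid(name), seed = 1L,
                         tuned = NULL) {
  if (!name %in% SUPPORTED_LEARNERS)
    stop("unsupported learner '", name, "'; supported: ",
         paste(SUPPORTED_LEARNERS, collapse = ", "))
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  if (!is.null(tuned) && !config_in_grid(tuned, grid))
    stop("tuned configuration is not a row of the grid")
  structure(list(name = name, grid = grid, seed = as.integer(seed),
                 tuned = tuned),
            class = "learner_spec")
}

config_in_grid <- function(cfg, grid) {
  if (!all(names(grid) %in% names(cfg))) return(FALSE)
  any(vapply(seq_len(nrow(grid)), function(i)
    isTRUE(all.equal(as.numeric(grid[i, names(grid)]),
                     as.numeric(cfg[names(grid)]))), logical(1)))
}

#' @export
print.learner_spec <- function(x, ...) {
  cat("Learner spec:", x$name, "| grid:", nrow(x$grid), "configuration(s)")
  if (!is.null(x$tuned))
    cat(" | tuned:", paste(names(x$tuned), unlist(x$tuned), sep = "=",
                           collapse = ", "))
  cat("\n")
  invisible(x)
}

# Resolve the configuration to fit with: tuned if set, else the single grid
# row, else error.
resolved_config <- function(spec) {
  if (!is.null(spec$tuned)) return(spec$tuned)
  if (nrow(spec$grid) == 1) return(as.list(spec$grid[1, , drop = FALSE]))
  stop("learner spec for ", spec$name,
       " is untuned with a multi-point grid; run grid_search() first")
}

#' Fit a base learner
#'
#' One uniform fitting contract over the five backends. The configuration is
#' the spec's tuned one (or its single grid row).
#'
#' @param spec a [learner_spec()].
#' @param X numeric feature matrix with column names (derivative bands, plus
#'   any chained element-prediction features).
#' @param y numeric response vector.
#' @return An object of class `fitted_learner`; predict with
#'   [predict.fitted_learner()].
#' @export
fit_learner <- function(spec, X, y) {
  stopifnot(inherits(spec, "learner_spec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cfg <- resolved_config(spec)
  model <- switch(spec$name,
    "PLS" = fit_pls_capped(X, y, cfg$ncomp),
    "Ridge" = fit_glmnet(X, y, alpha = 0, lambda = cfg$lambda),
    "Lasso" = fit_glmnet(X, y, alpha = 1, lambda = cfg$lambda),
    "SVM-linear" = e1071::svm(x = X, y = y, type = "eps-regression",
                              kernel = "linear", cost = cfg$cost,
                              gamma = cfg$gamma, scale = TRUE),
    "RF" = {
      d <- data.frame(.y = y, X, check.names = FALSE)
      ranger::ranger(
        dependent.variable.name = ".y", data = d,
        num.trees = cfg$num_trees,
        mtry = max(1L, floor(cfg$mtry_frac * ncol(X))),
        max.depth = cfg$max_depth, min.node.size = cfg$min_node,
        sample.fraction = cfg$sample_frac, replace = TRUE,
        seed = spec$seed, num.threads = 1)
    })
  structure(list(spec = spec, config = cfg, model = model,
                 features = colnames(X)),
            class = "fitted_learner")
}

# PLS with the component count capped at what the data's rank supports: a
# component count beyond the rank makes the prediction rotation singular, so
# back off until prediction is well-posed.
fit_pls_capped <- function(X, y, ncomp) {
  ncomp <- max(1L, min(ncomp, ncol(X), nrow(X) - 1))
  repeat {
    fit <- mixOmics::pls(X, y, ncomp = ncomp, mode = "regression",
                         scale = TRUE)
    ok <- tryCatch({
      predict(fit, X[1, , drop = FALSE])
      TRUE
    }, error = function(e) FALSE)
    if (ok || ncomp == 1L) return(fit)
    ncomp <- ncomp - 1L
  }
}

# glmnet wants >= 2 columns; pad single-feature problems with a zero column.
fit_glmnet <- function(X, y, alpha, lambda) {
  padded <- ncol(X) < 2
  if (padded) X <- cbind(X, .pad = 0)
  fit <- glmnet::glmnet(X, y, alpha = alpha,
                        lambda = sort(unique(lambda * c(16, 8, 4, 2, 1)),
                                      decreasing = TRUE),
                        standardize = TRUE)
  list(fit = fit, lambda = lambda, padded = padded)
}

#' Predict from a fitted base learner
#'
#' @param object a `fitted_learner`.
#' @param newdata numeric matrix whose columns are exactly the training
#'   features, in order.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.fitted_learner <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) colnames(newdata) <- object$features
  if (!identical(colnames(newdata), object$features))
    stop("newdata columns must match the training features, in order")
  switch(object$spec$name,
    "PLS" = {
      pr <- predict(object$model, newdata)$predict
      as.numeric(pr[, 1, dim(pr)[3]])
    },
    "Ridge" = ,
    "Lasso" = {
      m <- object$model
      nd <- if (m$padded) cbind(newdata, .pad = 0) else newdata
      as.numeric(predict(m$fit, nd, s = m$lambda))
    },
    "SVM-linear" = as.numeric(predict(object$model, newdata)),
    "RF" = as.numeric(predict(object$model, data.frame(newdata, check.names = FALSE),
                              num.threads = 1)$predictions))
}

#' @export
print.fitted_learner <- function(x, ...) {
  cat("Fitted", x$spec$name, "learner on", length(x$features), "features (",
      paste(names(x$config), unlist(x$config), sep = "=", collapse = ", "),
      ")\n")
  invisible(x)
}

# Complexity score used to break grid-search ties toward the simpler model:
# fewer PLS components, stronger shrinkage, smaller SVM cost, shallower RF.
config_complexity <- function(name, cfg) {
  switch(name,
    "PLS" = cfg$ncomp,
    "Ridge" = ,
    "Lasso" = 1 / cfg$lambda,
    "SVM-linear" = cfg$cost,
    "RF" = cfg$max_depth)
}

#' Exhaustive grid search by mean cross-validated R-squared
#'
#' Evaluates every grid configuration by k-fold out-of-fold R^2 (the target
#' min-max scaler is refit inside each fold) and returns the spec with
#' `tuned` set to the best configuration. Ties are broken toward lower model
#' complexity, then grid order.
#'
#' @param spec a [learner_spec()].
#' @param X feature matrix.
#' @param y response vector (ppm).
#' @param folds integer fold ids (1..k), one per row of `X`; see
#'   [make_folds()].
#' @return The tuned `learner_spec`, with attribute `"cv_scores"` holding
#'   the mean CV R^2 of every configuration.
#' @export
grid_search <- function(spec, X, y, folds) {
  stopifnot(inherits(spec, "learner_spec"))
  X <- as.matrix(X)
  folds <- as.integer(folds)
  stopifnot(length(folds) == nrow(X), length(y) == nrow(X))
  if (length(unique(folds)) < 2) stop("grid search needs >= 2 folds")
  if (stats::sd(y) == 0) stop("response has zero variance; nothing to tune")
  grid <- spec$grid
  if (nrow(grid) == 1)
    return(learner_spec(spec$name, grid, spec$seed,
                        tuned = as.list(grid[1, , drop = FALSE])))
  fold_ids <- sort(unique(folds))

  if (spec$name == "PLS") {
    # one max-ncomp fit per fold yields predictions for every component count
    ncomps <- grid$ncomp
    scores <- matrix(NA_real_, length(fold_ids), length(ncomps))
    for (fi in seq_along(fold_ids)) {
      f <- fold_ids[fi]
      tr <- folds != f
      fit <- fit_pls_capped(X[tr, , drop = FALSE], y[tr], max(ncomps))
      pr <- predict(fit, X[!tr, , drop = FALSE])$predict
      maxc <- dim(pr)[3]
      for (ci in seq_along(ncomps))
        scores[fi, ci] <- r_squared(y[!tr], pr[, 1, min(ncomps[ci], maxc)])
    }
    mean_scores <- colMeans(scores)
  } else {
    mean_scores <- vapply(seq_len(nrow(grid)), function(i) {
      cfg_spec <- learner_spec(spec$name, grid[i, , drop = FALSE], spec$seed,
                               tuned = as.list(grid[i, , drop = FALSE]))
      mean(vapply(fold_ids, function(f) {
        tr <- folds != f
        sc <- minmax_scale(matrix(y[tr], dimnames = list(NULL, ".y")))
        fit <- fit_learner(cfg_spec, X[tr, , drop = FALSE], sc$elements[, 1])
        yhat <- minmax_invert(predict(fit, X[!tr, , drop = FALSE]),
                              sc$state, ".y")
        r_squared(y[!tr], yhat)
      }, numeric(1)))
    }, numeric(1))
  }
  cx <- vapply(seq_len(nrow(grid)), function(i)
    config_complexity(spec$name, as.list(grid[i, , drop = FALSE])), numeric(1))
  best <- order(-mean_scores, cx, seq_len(nrow(grid)))[1]
  out <- learner_spec(spec$name, grid, spec$seed,
                      tuned = as.list(grid[best, , drop = FALSE]))
  attr(out, "cv_scores") <- mean_scores
  out
}

#' Out-of-fold prediction
#'
#' For each fold, fits the tuned learner on the remaining folds (the target
#' min-max scaler is refit on those folds only) and predicts the held-out
#' fold, so every training sample receives a prediction from a model that
#' never saw it. Predictions are returned on the ppm scale.
#'
#' @param spec a tuned [learner_spec()].
#' @param X feature matrix.
#' @param y response vector (ppm).
#' @param folds integer fold ids, one per row of `X`.
#' @return List with `oof` (length-n prediction vector in row order),
#'   `fold_sets` (per fold: list with `fold`, `y`, `yhat`), `fold_r2`,
#'   `fold_rmse`.
#' @export
oof_predict <- function(spec, X, y, folds) {
  X <- as.matrix(X)
  folds <- as.integer(folds)
  stopifnot(length(folds) == nrow(X), length(y) == nrow(X))
  fold_ids <- sort(unique(folds))
  if (any(table(folds) < 2)) stop("every fold needs at least 2 samples")
  oof <- rep(NA_real_, length(y))
  sets <- vector("list", length(fold_ids))
  for (fi in seq_along(fold_ids)) {
    f <- fold_ids[fi]
    tr <- folds != f
    sc <- minmax_scale(matrix(y[tr], dimnames = list(NULL, ".y")))
    fit <- fit_learner(spec, X[tr, , drop = FALSE], sc$elements[, 1])
    yhat <- minmax_invert(predict(fit, X[!tr, , drop = FALSE]), sc$state, ".y")
    oof[!tr] <- yhat
    sets[[fi]] <- list(fold = f, y = y[!tr], yhat = yhat)
  }
  list(oof = oof, fold_sets = sets,
       fold_r2 = vapply(sets, function(s) r_squared(s$y, s$yhat), numeric(1)),
       fold_rmse = vapply(sets, function(s) rmse(s$y, s$yhat), numeric(1)))
}
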