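test_that("the STR baseline separates spectrally driven targets from noise", {
  ds <- tiny_dataset(n = 40)
  folds <- make_folds(40, 5, seed = 3)
  sp <- ridge_spec()
  s <- fit_str(ds, "Aa", sp, folds)          # Aa is a band rescaled
  expect_gt(s$mean_r2, 0.95)
  expect_length(s$fold_r2, 5)
  expect_length(s$fold_rmse, 5)
  expect_equal(s$mean_r2, mean(s$fold_r2))

  # targets unrelated to the spectra: mean CV R^2 stays near or below zero
  set.seed(20)
  noise_scores <- vapply(1:20, function(i) {
    y <- rnorm(40)
    conc <- ds$elements$values
    conc[, "Cc"] <- y - min(y) + 0.1
    d2 <- ion_dataset(ds$spectra, element_table(conc, ds$elements$sample_ids))
    fit_str(d2, "Cc", sp, folds)$mean_r2
  }, numeric(1))
  expect_lt(mean(noise_scores), 0.05)
})

test_that("candidate filtering keeps the boundary and never touches the target list", {
  scores <- c(A = 0.60, B = 0.54, C = 0.55)
  expect_setequal(filter_candidates(scores, 0.55), c("A", "C"))
  expect_setequal(filter_candidates(scores, 0), c("A", "B", "C"))
  expect_length(filter_candidates(scores, 1.01), 0)
  expect_error(filter_candidates(numeric(0)), "no STR results")
})

test_that("an empty pool reduces chaining to the single-target baseline exactly", {
  ds <- tiny_dataset(n = 40)
  folds <- make_folds(40, 5, seed = 3)
  sp <- ridge_spec()
  m <- fit_mtsc(ds, "Aa", character(0), sp, folds)
  s <- fit_str(ds, "Aa", sp, folds)
  expect_length(m$chain, 0)
  expect_equal(m$fold_r2, s$fold_r2)
  expect_equal(m$fold_rmse, s$fold_rmse)
  expect_equal(m$trajectory, s$mean_r2)
})

test_that("a single-candidate chain matches a hand-run two-stage procedure", {
  pr <- prepped(small_scenario(6, n = 90, bands = 40), k = 4)
  ds <- pr$data; folds <- pr$folds
  sp <- ridge_spec(seed = 6)
  ctrl <- mtsc_control(inner_k = 3, seed = 6)
  m <- fit_mtsc(ds, "C", "A", sp, folds, ctrl)

  # hand-run stages using only exported building blocks
  X <- ds$spectra$values
  E <- ds$elements$values
  str_r2 <- fit_str(ds, "C", sp, folds)$fold_r2
  aug_r2 <- numeric(4)
  for (f in 1:4) {
    tr <- folds != f
    inner <- make_folds(sum(tr), 3, seed = 6 + 1000L * f)
    e <- numeric(nrow(X))
    e[tr] <- oof_predict(sp, X[tr, ], E[tr, "A"], inner)$oof
    scA <- minmax_scale(matrix(E[tr, "A"], dimnames = list(NULL, ".y")))
    mA <- fit_learner(sp, X[tr, ], scA$elements[, 1])
    e[!tr] <- minmax_invert(predict(mA, X[!tr, ]), scA$state, ".y")
    Xa <- cbind(X, Ehat_A = e)
    scC <- minmax_scale(matrix(E[tr, "C"], dimnames = list(NULL, ".y")))
    mC <- fit_learner(sp, Xa[tr, ], scC$elements[, 1])
    yhat <- minmax_invert(predict(mC, Xa[!tr, ]), scC$state, ".y")
    aug_r2[f] <- r_squared(E[!tr, "C"], yhat)
  }
  if (mean(aug_r2) > mean(str_r2)) {
    expect_equal(m$chain, "A")
    expect_equal(m$fold_r2, aug_r2)
  } else {
    expect_length(m$chain, 0)
    expect_equal(m$fold_r2, str_r2)
  }
  expect_equal(m$str$fold_r2, str_r2)
})

test_that("accepted chains never repeat elements, never contain the target, and only climb", {
  pr <- prepped(small_scenario(8, n = 90, bands = 40), k = 4)
  sp <- ridge_spec(seed = 8)
  for (target in c("A", "C", "F")) {
    m <- fit_mtsc(pr$data, target, setdiff(colnames(pr$data$elements$values),
                                           target),
                  sp, pr$folds, mtsc_control(inner_k = 3, seed = 8))
    expect_false(target %in% m$chain)
    expect_equal(anyDuplicated(m$chain), 0)
    expect_length(m$trajectory, length(m$chain) + 1)
    if (length(m$chain) > 0) expect_true(all(diff(m$trajectory) > 0))
    expect_gte(m$mean_r2, m$str$mean_r2)
  }
})

test_that("chaining is reproducible and its held-out predictions are usable", {
  pr <- prepped(small_scenario(4, n = 90, bands = 40), k = 4)
  sp <- ridge_spec(seed = 4)
  ctrl <- mtsc_control(inner_k = 3, seed = 4)
  m1 <- fit_mtsc(pr$data, "C", c("A", "B"), sp, pr$folds, ctrl)
  m2 <- fit_mtsc(pr$data, "C", c("A", "B"), sp, pr$folds, ctrl)
  expect_equal(m1$log, m2$log)
  expect_identical(m1$chain, m2$chain)
  expect_equal(m1$fold_r2, m2$fold_r2)

  pred <- predict(m1, pr$data$spectra)
  expect_length(pred, nrow(pr$data$spectra$values))
  expect_gt(r_squared(pr$data$elements$values[, "C"], pred), 0.5)
})

test_that("the comparison experiment produces a complete, well-formed report", {
  ds <- generate_dataset(small_scenario(3))
  cfg <- experiment_config(
    learners = c("Ridge", "PLS"), k = 5, inner_k = 3, seed = 11,
    grids = list(Ridge = data.frame(lambda = 10^c(-4, -2)),
                 PLS = data.frame(ncomp = c(2, 4))))
  rep <- suppressWarnings(suppressMessages(run_experiment(ds, cfg)))
  expect_s3_class(rep, "comparison_report")
  expect_equal(rep$table$element, c("A", "B", "C", "F"))
  expect_true(all(c("str_model", "str_r2", "chain", "mtsc_r2", "wilcoxon_p",
                    "significance", "test_str_r2", "test_mtsc_r2")
                  %in% names(rep$table)))
  expect_true(all(rep$table$significance %in% c("ns", "*", "**")))
  expect_true(all(grepl("^([A-F]+(-[A-F]+)*)?$", rep$table$chain)))
  expect_equal(nrow(rep$per_fold), 4 * 2 * 5)
  # spectrally active elements are well predicted in CV
  expect_gt(min(rep$table$str_r2[rep$table$element %in% c("A", "B")]), 0.8)

  # an unreachable improvement tolerance freezes every chain at the baseline
  cfg0 <- experiment_config(
    learners = "Ridge", k = 5, inner_k = 3, seed = 11, tolerance = 1e6,
    grids = list(Ridge = data.frame(lambda = 1e-4)))
  rep0 <- suppressWarnings(suppressMessages(run_experiment(ds, cfg0)))
  expect_true(all(rep0$table$chain == ""))
  expect_equal(rep0$table$mtsc_r2, rep0$table$str_r2)
  expect_true(all(rep0$table$delta_r2_pct == 0))
})
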