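test_that("R-squared and RMSE match their definitions and reference formulas", {
  y <- c(1, 2, 3); yhat <- c(1, 2, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, yhat), 0.5)
  expect_error(r_squared(c(2, 2, 2), yhat), "zero variance")

  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y, yhat), sqrt(1 / 3))
  expect_equal(rmse(3 * y, 3 * yhat), 3 * rmse(y, yhat))

  # reference route: moment identities rather than the direct sums
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    a <- rnorm(n); b <- rnorm(n)
    d <- a - b
    rmse_ref <- sqrt(var(d) * (n - 1) / n + mean(d)^2)
    r2_ref <- 1 - (var(d) * (n - 1) + n * mean(d)^2) / (var(a) * (n - 1))
    expect_equal(rmse(a, b), rmse_ref, tolerance = 1e-12)
    expect_equal(r_squared(a, b), r2_ref, tolerance = 1e-12)
  }
})

test_that("percentage differences reproduce the reference fold-mean arithmetic", {
  expect_equal(delta_percent(0.74, 0.67), 100 * 0.07 / 0.67, tolerance = 1e-12)
  expect_equal(round(delta_percent(0.74, 0.67), 2), 10.45)
  expect_equal(round(delta_percent(22.1, 25.0), 1), -11.6)
  expect_equal(delta_percent(0.6, 0.6), 0)
  expect_error(delta_percent(1, 0), "undefined")
})

test_that("exact signed-rank p-values equal full sign enumeration up to n = 12", {
  expect_warning(res <- wilcoxon_paired(1:5, 1:5), "zero")
  expect_equal(res$p.value, 1)

  # all-positive distinct differences at n = 10: the two most extreme of
  # 2^10 assignments
  a <- seq(1, 10) + (1:10) / 100
  res10 <- wilcoxon_paired(a, rep(0, 10))
  expect_equal(res10$p.value, 2 / 1024)
  expect_equal(res10$method, "exact")

  set.seed(17)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    x <- round(rnorm(n), 1)          # rounding forces ties and zeros
    y <- round(rnorm(n), 1)
    if (all(x == y)) x[1] <- x[1] + 0.5
    got <- suppressWarnings(wilcoxon_paired(x, y))
    expect_equal(got$p.value, enumerate_signed_rank_p(x, y),
                 tolerance = 1e-12, label = paste("trial", i))
  }
})

test_that("exact mode agrees with the standard implementation when it is exact", {
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)    # continuous: no ties or zeros
    got <- wilcoxon_paired(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(got$statistic), unname(ref$statistic))
  }
})

test_that("large-sample signed-rank mode uses the tie-corrected normal approximation", {
  set.seed(31)
  x <- rnorm(40); y <- rnorm(40) + 0.4
  got <- wilcoxon_paired(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                      correct = TRUE))
  expect_equal(got$method, "normal approximation")
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("the correlation matrix is symmetric with unit diagonal and honest labels", {
  set.seed(9)
  m <- cbind(a = rnorm(50), b = rnorm(50))
  m <- cbind(m, c = m[, "a"] * 2 + rnorm(50, 0, 0.01), d = -m[, "b"])
  pm <- pearson_matrix(m)
  expect_equal(pm$r, t(pm$r))
  expect_equal(unname(diag(pm$r)), rep(1, 4))
  expect_equal(pm$r["b", "d"], -1)
  expect_equal(pm$label["a", "c"], "***")

  # independent columns rarely show |r| > 0.1 at n = 1000
  set.seed(10)
  small <- vapply(1:100, function(i)
    abs(cor(rnorm(1000), rnorm(1000))) < 0.1, logical(1))
  expect_gte(mean(small), 0.95)
})

test_that("spectral Euclidean distances behave like a metric with group summaries", {
  m <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 1))
  ed <- euclidean_distances(m, grouping = c("g1", "g1", "g2"))
  expect_equal(ed$distances["a", "b"], 5)
  expect_equal(ed$distances, t(ed$distances))
  expect_true(all(diag(ed$distances) == 0))
  expect_equal(ed$group_means$mean_distance[1], 5)   # a's only partner is b
  expect_true(is.na(ed$group_means$mean_distance[3]))
})

test_that("element summaries reproduce the integer CV convention", {
  expect_equal(cv_percent(5.17, 2.79), 54)
  expect_equal(cv_percent(27.7, 18.0), 65)
  set.seed(12)
  m <- cbind(Mg = rlnorm(200, 8, 0.4), K = rep(3, 200))
  s <- element_summary(m)
  expect_equal(s$element, c("Mg", "K"))
  expect_equal(s$cv_percent[1], round(100 * sd(m[, 1]) / mean(m[, 1])))
  expect_equal(s$sd[2], 0)
  expect_equal(s$cv_percent[2], 0)
})
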