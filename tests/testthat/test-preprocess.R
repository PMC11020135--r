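make_spectra <- function(values, wl = NULL) {
  values <- as.matrix(values)
  if (is.null(wl)) wl <- seq(400, 400 + 10 * (ncol(values) - 1), by = 10)
  spectral_table(values, wl, sprintf("s%02d", seq_len(nrow(values))))
}

test_that("band standardization yields mean 0 / sd 1 and reuses train statistics", {
  set.seed(1)
  sp <- make_spectra(matrix(rnorm(60, 5, 2), 12, 5))
  st <- standardize_bands(sp)
  expect_lt(max(abs(colMeans(st$spectra$values))), 1e-12)
  expect_lt(max(abs(apply(st$spectra$values, 2, sd) - 1)), 1e-12)

  # hand arithmetic on a 3-sample toy: train mean 2, sd 1 per band
  tr <- make_spectra(matrix(c(1, 2, 3), 3, 2), wl = c(400, 410))
  fit <- standardize_bands(tr)
  te <- make_spectra(matrix(c(4, 6), 2, 2, byrow = FALSE)[1:2, , drop = FALSE],
                     wl = c(400, 410))
  out <- standardize_bands(te, fit$state)$spectra$values
  expect_equal(unname(out[, 1]), (c(4, 6) - 2) / 1)

  const <- make_spectra(cbind(rnorm(5), rep(3, 5)))
  expect_warning(stc <- standardize_bands(const), "zero-variance")
  expect_equal(unname(stc$spectra$values[, 2]), rep(0, 5))
})

test_that("iterative Grubbs filtering matches a stepwise brute-force run", {
  v <- c(0.0, 0.1, -0.2, 0.05, 0.07, -0.1, 10.0)
  res <- grubbs_outliers(v, alpha = 0.05)
  expect_equal(res$removed, 7L)
  expect_equal(res$kept, 1:6)

  # independent stepwise oracle: recompute G and the critical value from the
  # t quantile at every step
  oracle <- function(values, alpha) {
    idx <- seq_along(values); removed <- integer(0)
    repeat {
      n <- length(idx)
      if (n < 3) break
      x <- values[idx]
      if (sd(x) == 0) break
      g <- max(abs(x - mean(x))) / sd(x)
      tq <- qt(1 - alpha / (2 * n), n - 2)
      gcrit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
      if (g > gcrit) {
        i <- which.max(abs(x - mean(x)))
        removed <- c(removed, idx[i]); idx <- idx[-i]
      } else break
    }
    list(kept = idx, removed = removed)
  }
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(15)
    if (i %% 3 == 0) x[1] <- x[1] + 8        # planted outlier sometimes
    expect_identical(grubbs_outliers(x, 0.05), oracle(x, 0.05))
  }

  expect_equal(grubbs_outliers(rep(2, 6))$removed, integer(0))
  expect_error(grubbs_outliers(c(1, 2)), "at least 3")
  expect_equal(grubbs_critical(10, 0.05), 2.2899540845, tolerance = 1e-9)
})

test_that("Grubbs false-positive rate on clean normal samples stays near alpha", {
  set.seed(2024)
  trials <- 1000
  hits <- sum(vapply(seq_len(trials), function(i)
    length(grubbs_outliers(rnorm(100), alpha = 0.05)$removed) > 0,
    logical(1)))
  expect_lt(hits / trials, 3 * 0.05)
})

test_that("Savitzky-Golay smoothing preserves cubics and shrinks noise", {
  wl <- seq(400, 1000, by = 5)
  cubic <- 0.4 + 1e-4 * (wl - 700) - 2e-7 * (wl - 700)^2 + 1e-9 * (wl - 700)^3
  sp <- make_spectra(rbind(cubic, cubic + 0.01), wl = wl)
  sm <- savgol_smooth(sp, preprocess_config(sg_window_nm = 45, sg_degree = 3))
  expect_equal(sm$values, sp$values, tolerance = 1e-9)

  flat <- make_spectra(matrix(0.5, 2, 40))
  expect_equal(savgol_smooth(flat)$values, flat$values, tolerance = 1e-12)

  set.seed(3)
  shrunk <- vapply(1:100, function(i) {
    noisy <- make_spectra(matrix(rnorm(80), 1, 80))
    var(as.numeric(savgol_smooth(noisy,
      preprocess_config(sg_window_nm = 90))$values)) <
      var(as.numeric(noisy$values))
  }, logical(1))
  expect_true(all(shrunk))
})

test_that("the nm-to-band window rule rounds to odd, ties down, floor at degree+2", {
  wl10 <- seq(400, 1000, by = 10)   # spacing 10 nm
  expect_equal(ionochain:::sg_window_bands(15, wl10, 3), 5)   # 1.5 -> floor 5
  expect_equal(ionochain:::sg_window_bands(52, wl10, 3), 5)   # 5.2 -> 5
  expect_equal(ionochain:::sg_window_bands(60, wl10, 3), 5)   # tie 5/7 -> 5
  expect_equal(ionochain:::sg_window_bands(68, wl10, 3), 7)   # 6.8 -> 7
  expect_equal(ionochain:::sg_window_bands(90, wl10, 3), 9)
})

test_that("the first derivative is the forward difference with left-endpoint labels", {
  sp <- make_spectra(matrix(c(1, 4, 9), 1, 3), wl = c(1, 2, 3))
  d <- first_derivative(sp)
  expect_equal(unname(d$values[1, ]), c(3, 5))
  expect_equal(d$wavelengths_nm, c(1, 2))

  flat <- make_spectra(matrix(2, 3, 10))
  expect_true(all(first_derivative(flat)$values == 0))

  wl <- c(400, 410, 425, 450)
  lin <- make_spectra(matrix(2 * wl, 1), wl = wl)
  expect_equal(unname(first_derivative(lin)$values[1, ]), rep(2, 3))

  # smoothing then differencing an exact cubic equals the analytic forward
  # difference of the cubic
  wlu <- seq(400, 800, by = 5)
  cub <- 1 + 0.01 * wlu - 1e-5 * wlu^2 + 5e-9 * wlu^3
  sp2 <- make_spectra(matrix(cub, 1), wl = wlu)
  got <- first_derivative(savgol_smooth(sp2, preprocess_config(25, 3)))
  expect_equal(unname(got$values[1, ]), diff(cub) / diff(wlu), tolerance = 1e-9)
})

test_that("min-max target scaling is invertible and never clips test values", {
  m <- matrix(c(2, 4, 6), 3, 1, dimnames = list(NULL, "Mg"))
  sc <- minmax_scale(m)
  expect_equal(unname(sc$elements[, 1]), c(0, 0.5, 1))
  expect_equal(minmax_invert(sc$elements, sc$state), m)

  test_val <- matrix(8, 1, 1, dimnames = list(NULL, "Mg"))
  out <- minmax_scale(test_val, sc$state)$elements
  expect_equal(unname(out[1, 1]), (8 - 2) / 4)   # 1.5, outside [0,1]
  expect_gt(out[1, 1], 1)

  const <- matrix(5, 4, 1, dimnames = list(NULL, "K"))
  expect_warning(scc <- minmax_scale(const), "constant")
  expect_true(all(scc$elements == 0))
})

test_that("the preprocessing chain removes flagged samples and applies train state to test", {
  set.seed(11)
  n <- 40; wl <- seq(400, 1400, length.out = 30)
  v <- matrix(rnorm(n * 30, 0.5, 0.02), n, 30)
  v[3, ] <- v[3, ] + 1          # one grossly aberrant sample
  sp <- spectral_table(v, wl, sprintf("s%02d", 1:n))
  pp <- preprocess_spectra(sp)
  expect_true("s03" %in% pp$removed_ids)
  expect_equal(ncol(pp$spectra$values), 29)   # derivative drops one band

  te <- spectral_table(v[1:5, ], wl, paste0("t", 1:5))
  pt <- preprocess_spectra(te, state = pp$state)
  expect_length(pt$removed_ids, 0)            # no filtering outside training
  expect_equal(dim(pt$spectra$values), c(5, 29))
})
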