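#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. May be negative when
#' the predictions are worse than the observed mean.
#'
#' @param y observed values (length >= 2, nonzero variance).
#' @param yhat predicted values, same length.
#' @return The R-squared value.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("observed values have zero variance; R^2 undefined")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Root mean squared error
#'
#' `sqrt(mean((y - yhat)^2))`, in the units of `y`.
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return The RMSE.
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  sqrt(mean((y - yhat)^2))
}

#' Percentage change of a metric from STR to MTSC
#'
#' `100 * (mtsc - str) / str`, applied elementwise; with fold-wise vectors
#' this yields the per-fold percentage differences whose average is the
#' reported mean change.
#'
#' @param metric_mtsc metric value(s) under chaining.
#' @param metric_str metric value(s) under single-target regression (nonzero).
#' @return Percentage difference(s); positive means MTSC larger.
#' @export
delta_percent <- function(metric_mtsc, metric_str) {
  if (any(metric_str == 0)) stop("baseline metric of 0: percentage change undefined")
  100 * (metric_mtsc - metric_str) / metric_str
}

# Exact null distribution of twice the signed-rank statistic (doubled so
# midranks stay integral): counts[w + 1] = number of sign assignments whose
# positive doubled-rank sum equals w.
signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  cnt <- numeric(total + 1)
  cnt[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), cnt[seq_len(total + 1 - r)])
    cnt <- cnt + shifted
  }
  cnt
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Classic zero-handling: differences of zero are dropped before ranking.
#' For an effective sample size `n <= 25` the p-value comes from the exact
#' null distribution of the signed-rank sum, computed by dynamic programming
#' over (mid)ranks so ties are handled exactly; for larger `n` a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param scores_a,scores_b paired numeric vectors (e.g. per-fold R^2 under
#'   two methods), equal length >= 5.
#' @return List with `p.value`, `statistic` (positive-rank sum `V`),
#'   `n_effective` (pairs remaining after zero removal), and `method`.
#' @export
wilcoxon_paired <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 5)
  d <- scores_a - scores_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(p.value = 1, statistic = 0, n_effective = 0L,
                method = "degenerate"))
  }
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * rk))
    cnt <- signed_rank_counts(r2)
    w <- as.integer(round(2 * v))
    tot <- sum(cnt)
    p_le <- sum(cnt[seq_len(w + 1)]) / tot
    p_ge <- sum(cnt[(w + 1):length(cnt)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(p.value = p, statistic = v, n_effective = n, method = method)
}

#' Significance label for a p-value
#'
#' `ns` at p >= 0.05, then `*`, `**`, and (when `three_tiers`) `***` at
#' p < 0.05, 0.01, 0.001.
#'
#' @param p p-value(s).
#' @param three_tiers include the `***` tier (used for correlation matrices);
#'   comparison reports use the two-tier ns/*/** labelling.
#' @return Character label(s).
#' @export
significance_label <- function(p, three_tiers = FALSE) {
  lab <- ifelse(p < 0.05, "*", "ns")
  lab[p < 0.01] <- "**"
  if (three_tiers) lab[p < 0.001] <- "***"
  lab
}

#' Pearson correlation matrix of element concentrations
#'
#' Pairwise Pearson r with two-sided t-based p-values and ns/*/**/***
#' significance labels, the standard display of inter-element dependency
#' structure in an ionome panel.
#'
#' @param elements an `element_table` or numeric matrix (>= 3 rows).
#' @return List with matrices `r`, `p`, and character `label`.
#' @export
pearson_matrix <- function(elements) {
  v <- if (inherits(elements, "element_table")) elements$values else as.matrix(elements)
  n <- nrow(v)
  stopifnot(n >= 3)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance element(s): correlations undefined (NA) for ",
            paste(colnames(v)[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(v))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  diag(r) <- ifelse(sds == 0, NA, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  lab <- matrix(significance_label(p, three_tiers = TRUE), nrow(p),
                dimnames = dimnames(p))
  lab[is.na(p)] <- NA
  list(r = r, p = p, label = lab)
}

#' Pairwise Euclidean distances between sample spectra
#'
#' Spectral similarity index: 0 means identical spectra. With a `grouping`
#' (e.g. plant ids) the per-sample mean distance to all other samples of the
#' same group is also returned, summarizing within-group spectral
#' variability.
#'
#' @param spectra a `spectral_table` or numeric matrix (rows = samples).
#' @param grouping optional vector of group labels, one per sample.
#' @return List with `distances` (symmetric matrix, zero diagonal) and, when
#'   `grouping` is given, `group_means` (data frame: sample, group, mean
#'   within-group distance).
#' @export
euclidean_distances <- function(spectra, grouping = NULL) {
  v <- if (inherits(spectra, "spectral_table")) spectra$values else as.matrix(spectra)
  stopifnot(nrow(v) >= 2)
  dm <- as.matrix(stats::dist(v))
  out <- list(distances = dm)
  if (!is.null(grouping)) {
    stopifnot(length(grouping) == nrow(v))
    gm <- vapply(seq_len(nrow(v)), function(i) {
      same <- which(grouping == grouping[i] & seq_len(nrow(v)) != i)
      if (length(same)) mean(dm[i, same]) else NA_real_
    }, numeric(1))
    out$group_means <- data.frame(sample = rownames(v) %||% seq_len(nrow(v)),
                                  group = grouping, mean_distance = gm,
                                  stringsAsFactors = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coefficient of variation in percent
#'
#' `round(100 * sd / mean)`, the integer CV% convention of element
#' descriptive tables.
#'
#' @param mean mean concentration(s) (nonzero).
#' @param sd standard deviation(s).
#' @return Integer percentage(s).
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean == 0)) stop("mean of 0: CV undefined")
  round(100 * sd / mean)
}

#' Descriptive summary of an element panel
#'
#' Per element: minimum, mean, maximum, sample SD and CV% (rounded to the
#' nearest integer percent).
#'
#' @param elements an `element_table` or numeric matrix (>= 2 rows).
#' @return Data frame with columns `element`, `min`, `mean`, `max`, `sd`,
#'   `cv_percent`.
#' @export
element_summary <- function(elements) {
  v <- if (inherits(elements, "element_table")) elements$values else as.matrix(elements)
  stopifnot(nrow(v) >= 2)
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  cv <- rep(NA_real_, length(mu))
  cv[mu != 0] <- cv_percent(mu[mu != 0], sdv[mu != 0])
  if (any(mu == 0)) warning("zero-mean element(s): CV undefined")
  data.frame(element = colnames(v), min = apply(v, 2, min), mean = mu,
             max = apply(v, 2, max), sd = sdv, cv_percent = cv,
             row.names = NULL, stringsAsFactors = FALSE)
}
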