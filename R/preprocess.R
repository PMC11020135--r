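#' Preprocessing configuration
#'
#' Bundles the parameters of the spectral correction chain: per-band
#' standardization, iterative Grubbs sample filtering, Savitzky-Golay
#' smoothing (window expressed in nm, converted to an odd band count), and
#' the first-derivative transform.
#'
#' @param sg_window_nm Savitzky-Golay window width in nm (default 15).
#' @param sg_degree polynomial degree of the local fit (default 3).
#' @param grubbs_alpha significance level of the iterative Grubbs sample
#'   filter (default 0.05).
#' @param standardize whether to z-score each band over samples first
#'   (default `TRUE`).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window_nm = 15, sg_degree = 3,
                              grubbs_alpha = 0.05, standardize = TRUE) {
  stopifnot(sg_degree >= 1, sg_window_nm > 0,
            grubbs_alpha > 0, grubbs_alpha < 1)
  structure(list(sg_window_nm = sg_window_nm, sg_degree = sg_degree,
                 grubbs_alpha = grubbs_alpha,
                 grubbs_mode = "per_sample_mean",
                 standardize = isTRUE(standardize)),
            class = "preprocess_config")
}

#' Per-band standardization (z-scoring across samples)
#'
#' Without `state`, each band column is centred and scaled to mean 0 / sd 1
#' over the given samples and the fitted scaler is returned; with a
#' train-fitted `state`, the stored parameters are applied (so the test split
#' is transformed with training statistics). A zero-variance band is mapped
#' to 0 with a warning rather than producing NaN.
#'
#' @param spectra a `spectral_table`.
#' @param state optional `band_scaler` fitted on training data.
#' @return List with `spectra` (transformed `spectral_table`) and `state`
#'   (a `band_scaler` with per-band `mean` and `sd`).
#' @export
standardize_bands <- function(spectra, state = NULL) {
  stopifnot(inherits(spectra, "spectral_table"))
  v <- spectra$values
  if (is.null(state)) {
    mu <- colMeans(v)
    sdv <- apply(v, 2, stats::sd)
    if (any(sdv == 0)) {
      warning("zero-variance band(s) mapped to 0: ",
              paste(format(spectra$wavelengths_nm[sdv == 0]), collapse = ", "),
              " nm")
    }
    state <- structure(list(mean = mu, sd = sdv,
                            wavelengths_nm = spectra$wavelengths_nm),
                       class = "band_scaler")
  } else {
    stopifnot(inherits(state, "band_scaler"))
    if (length(state$mean) != ncol(v))
      stop("band count of state (", length(state$mean),
           ") does not match spectra (", ncol(v), ")")
  }
  sdv <- ifelse(state$sd == 0, 1, state$sd)
  out <- sweep(sweep(v, 2, state$mean), 2, sdv, `/`)
  out[, state$sd == 0] <- 0
  list(spectra = spectral_table(out, spectra$wavelengths_nm,
                                spectra$sample_ids, spectra$plant_ids),
       state = state)
}

#' Grubbs critical value
#'
#' Two-sided critical value of the Grubbs single-outlier statistic,
#' `G_crit(n, alpha) = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with `t`
#' the upper `alpha/(2n)` quantile of the t distribution on `n - 2` degrees
#' of freedom.
#'
#' @param n sample size (>= 3).
#' @param alpha significance level.
#' @return The critical value.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3, alpha > 0, alpha < 1)
  t <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative two-sided Grubbs outlier test
#'
#' Repeatedly computes `G = max |v - mean(v)| / sd(v)` and removes the most
#' extreme value while `G` exceeds [grubbs_critical()], stopping when no
#' value is rejected or fewer than 3 values remain. Zero variance means no
#' removal.
#'
#' @param values numeric vector, length >= 3.
#' @param alpha significance level (default 0.05).
#' @return List with integer index vectors `kept` and `removed` (removal
#'   order preserved in `removed`).
#' @export
grubbs_outliers <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("Grubbs test needs at least 3 values")
  keep <- seq_along(values)
  removed <- integer(0)
  repeat {
    n <- length(keep)
    if (n < 3) break
    v <- values[keep]
    s <- stats::sd(v)
    if (s == 0) break
    dev <- abs(v - mean(v))
    i <- which.max(dev)
    if (dev[i] / s > grubbs_critical(n, alpha)) {
      removed <- c(removed, keep[i])
      keep <- keep[-i]
    } else break
  }
  list(kept = keep, removed = removed)
}

# Odd SG window length in bands from a window in nm: nearest odd integer to
# window_nm / median band spacing (ties to the smaller odd), floored at the
# smallest odd integer >= degree + 2.
sg_window_bands <- function(window_nm, wavelengths_nm, degree) {
  spacing <- stats::median(diff(wavelengths_nm))
  r <- window_nm / spacing
  lo <- max(1L, 2L * floor((r - 1) / 2) + 1L)     # largest odd <= r (>=1)
  hi <- lo + 2L
  w <- if (r - lo <= hi - r) lo else hi           # ties go down
  minw <- degree + 2L
  if (minw %% 2L == 0L) minw <- minw + 1L
  max(w, minw)
}

#' Savitzky-Golay smoothing of spectra
#'
#' Local least-squares polynomial smoothing of each spectrum. The window is
#' given in nm and converted to the nearest odd band count using the median
#' band spacing. Edges are handled by a one-sided polynomial fit on the
#' truncated window, so any spectrum that is a polynomial of degree
#' `<= sg_degree` in wavelength (on uniform bands) passes through unchanged,
#' edges included.
#'
#' @param spectra a `spectral_table`.
#' @param config a [preprocess_config()] (fields `sg_window_nm`,
#'   `sg_degree`).
#' @return The smoothed `spectral_table`.
#' @export
savgol_smooth <- function(spectra, config = preprocess_config()) {
  stopifnot(inherits(spectra, "spectral_table"))
  w <- sg_window_bands(config$sg_window_nm, spectra$wavelengths_nm,
                       config$sg_degree)
  if (ncol(spectra$values) < w)
    stop("need at least ", w, " bands for a ", config$sg_window_nm,
         "-nm window, got ", ncol(spectra$values))
  sm <- t(apply(spectra$values, 1, signal::sgolayfilt,
                p = config$sg_degree, n = w))
  spectral_table(sm, spectra$wavelengths_nm, spectra$sample_ids,
                 spectra$plant_ids)
}

#' First-derivative transform
#'
#' Forward finite-difference approximation of the spectral derivative:
#' output band `i` is `(S(l[i+1]) - S(l[i])) / (l[i+1] - l[i])`, labelled by
#' the left endpoint `l[i]`. The output has one band fewer than the input.
#'
#' @param spectra a `spectral_table` with >= 2 bands.
#' @return A `spectral_table` of derivative spectra (units per nm).
#' @export
first_derivative <- function(spectra) {
  stopifnot(inherits(spectra, "spectral_table"))
  wl <- spectra$wavelengths_nm
  if (length(wl) < 2) stop("need at least 2 bands")
  dl <- diff(wl)
  dv <- t(apply(spectra$values, 1, diff)) / rep(dl, each = nrow(spectra$values))
  spectral_table(dv, wl[-length(wl)], spectra$sample_ids, spectra$plant_ids)
}

#' Min-max scaling of element concentrations
#'
#' Maps each element column to `(x - min) / (max - min)` with min/max learned
#' on the supplied (training) data, or applies a previously fitted
#' `minmax_scaler`. Values outside the training range map outside `[0, 1]`
#' and are deliberately not clipped. A constant column maps to 0 with a
#' warning.
#'
#' @param elements an `element_table`, or a numeric matrix with column names.
#' @param state optional fitted `minmax_scaler`.
#' @return List with `elements` (scaled, same type as input) and `state`.
#' @export
minmax_scale <- function(elements, state = NULL) {
  v <- if (inherits(elements, "element_table")) elements$values else as.matrix(elements)
  if (is.null(state)) {
    mn <- apply(v, 2, min); mx <- apply(v, 2, max)
    if (any(mx == mn))
      warning("constant element column(s) mapped to 0: ",
              paste(colnames(v)[mx == mn], collapse = ", "))
    state <- structure(list(min = mn, max = mx, names = colnames(v)),
                       class = "minmax_scaler")
  } else {
    stopifnot(inherits(state, "minmax_scaler"))
    if (!identical(colnames(v), state$names))
      stop("element set does not match the fitted scaler")
  }
  rng <- ifelse(state$max == state$min, 1, state$max - state$min)
  out <- sweep(sweep(v, 2, state$min), 2, rng, `/`)
  out[, state$max == state$min] <- 0
  # returned as a plain matrix: scaled values may leave [0,1] on test data,
  # which the non-negative element_table contract would reject
  list(elements = out, state = state)
}

#' Invert a min-max scaling
#'
#' @param values scaled matrix or vector (if a vector, `element` names the
#'   column of the scaler to invert with).
#' @param state a fitted `minmax_scaler`.
#' @param element column name, required when `values` is a vector.
#' @return Values on the original ppm scale.
#' @export
minmax_invert <- function(values, state, element = NULL) {
  stopifnot(inherits(state, "minmax_scaler"))
  rng <- ifelse(state$max == state$min, 1, state$max - state$min)
  if (is.null(dim(values))) {
    if (is.null(element)) stop("element name required for vector input")
    j <- match(element, state$names)
    if (is.na(j)) stop("unknown element: ", element)
    values * rng[j] + state$min[j]
  } else {
    sweep(sweep(values, 2, rng[state$names], `*`), 2, state$min[state$names], `+`)
  }
}

#' Run the full spectral preprocessing chain
#'
#' Applies, in order: per-band standardization, iterative Grubbs filtering of
#' outlying samples (on each sample's mean standardized reflectance),
#' Savitzky-Golay smoothing, and the first-derivative transform. When a
#' train-fitted `state` is supplied the standardization reuses its
#' parameters and no samples are removed (the filter is a training-time
#' operation).
#'
#' @param spectra a `spectral_table`.
#' @param config a [preprocess_config()].
#' @param state optional state returned by a previous training-split call.
#' @return List with `spectra` (the derivative `spectral_table`), `state`
#'   (the fitted `band_scaler` or `NULL`), and `removed_ids` (sample ids
#'   dropped by the Grubbs filter).
#' @export
preprocess_spectra <- function(spectra, config = preprocess_config(),
                               state = NULL) {
  removed_ids <- character(0)
  fitting <- is.null(state)
  if (config$standardize) {
    st <- standardize_bands(spectra, state)
    spectra <- st$spectra
    state <- st$state
  }
  if (fitting && nrow(spectra$values) >= 3) {
    g <- grubbs_outliers(rowMeans(spectra$values), config$grubbs_alpha)
    if (length(g$removed)) {
      removed_ids <- spectra$sample_ids[g$removed]
      keep <- spectra$sample_ids[g$kept]
      spectra <- spectral_table(
        spectra$values[g$kept, , drop = FALSE], spectra$wavelengths_nm,
        keep, if (!is.null(spectra$plant_ids)) spectra$plant_ids[g$kept])
    }
  }
  spectra <- savgol_smooth(spectra, config)
  spectra <- first_derivative(spectra)
  list(spectra = spectra, state = state, removed_ids = removed_ids)
}
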