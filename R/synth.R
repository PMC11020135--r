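#' Synthetic dataset configuration
#'
#' Describes a simulated hyperspectral/ionome study: each `active` element
#' drives a Gaussian absorption feature in the reflectance spectra, each
#' `dependent` element is a (possibly saturating) function of parent
#' elements plus noise with no direct spectral loading, and `independent`
#' elements relate to nothing. Concentrations are drawn log-normally to hit
#' a configured mean and coefficient of variation, matching the
#' positive-valued, right-skewed ionome panels seen in leaf tissue.
#'
#' @param n_samples number of samples (default 400).
#' @param wavelengths_nm band-centre wavelengths (default 120 uniform bands
#'   on 400-2400 nm).
#' @param elements data frame with one row per element: `name`, `role`
#'   (`active`/`dependent`/`independent`), `mean_ppm`, `cv` (fractional CV
#'   of the log-normal draw; used for active and independent roles),
#'   and for active elements the signature `center_nm`, `width_nm`,
#'   `amplitude`.
#' @param dependencies data frame (possibly empty) with one row per
#'   dependent element: `child`, `parents` (comma-separated names),
#'   `coefficients` (comma-separated), `link` (`linear` or `saturating`),
#'   `noise_frac` (noise SD as a fraction of the child's deterministic SD),
#'   and for the saturating link `v0` (half-saturation value, in the units
#'   of the linear combination).
#' @param spectral_noise_sd additive Gaussian reflectance noise (default
#'   0.005).
#' @param baseline flat reflectance baseline (default 0.5).
#' @param seed integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_samples = 400,
                         wavelengths_nm = seq(400, 2400, length.out = 120),
                         elements, dependencies = NULL,
                         spectral_noise_sd = 0.005, baseline = 0.5,
                         seed = 1L) {
  stopifnot(n_samples >= 2, all(diff(wavelengths_nm) > 0))
  elements <- as.data.frame(elements)
  stopifnot(all(c("name", "role", "mean_ppm", "cv") %in% names(elements)),
            all(elements$role %in% c("active", "dependent", "independent")),
            all(elements$mean_ppm > 0),
            all(elements$cv > 0 & elements$cv < 2))
  act <- elements[elements$role == "active", ]
  if (nrow(act) > 0)
    stopifnot(all(c("center_nm", "width_nm", "amplitude") %in% names(elements)),
              all(act$width_nm > 0), all(act$amplitude >= 0))
  deps <- if (is.null(dependencies)) {
    data.frame(child = character(0), parents = character(0),
               coefficients = character(0), link = character(0),
               noise_frac = numeric(0), v0 = numeric(0))
  } else as.data.frame(dependencies)
  dep_names <- elements$name[elements$role == "dependent"]
  if (!setequal(deps$child, dep_names))
    stop("dependencies must cover exactly the dependent elements")
  # acyclicity: resolve children whose parents are all non-dependent or
  # already resolved
  resolved <- elements$name[elements$role != "dependent"]
  todo <- deps$child
  while (length(todo)) {
    ready <- vapply(todo, function(ch) {
      all(split_names(deps$parents[deps$child == ch]) %in% resolved)
    }, logical(1))
    if (!any(ready)) stop("cyclic element dependencies: ",
                          paste(todo, collapse = ", "))
    resolved <- c(resolved, todo[ready])
    todo <- todo[!ready]
  }
  structure(list(n_samples = n_samples, wavelengths_nm = wavelengths_nm,
                 elements = elements, dependencies = deps,
                 spectral_noise_sd = spectral_noise_sd, baseline = baseline,
                 seed = as.integer(seed),
                 order = resolved),
            class = "synth_config")
}

split_names <- function(s) trimws(strsplit(s, ",")[[1]])

# Log-normal draw with a prescribed arithmetic mean and fractional CV.
rlnorm_mean_cv <- function(n, mean, cv) {
  sigma2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Gaussian absorption signature
#'
#' `g(lambda) = amplitude * exp(-(lambda - center)^2 / (2 width^2))`.
#'
#' @param wavelengths_nm evaluation wavelengths.
#' @param center_nm,width_nm,amplitude feature parameters.
#' @return Numeric vector of feature depths.
#' @export
signature_profile <- function(wavelengths_nm, center_nm, width_nm, amplitude) {
  amplitude * exp(-(wavelengths_nm - center_nm)^2 / (2 * width_nm^2))
}

#' Generate a synthetic hyperspectral/ionome dataset
#'
#' Concentrations are drawn per [synth_config()]; each sample's reflectance
#' is `baseline - sum over active elements of (min-max normalized
#' concentration) * g_e(lambda) + noise`, clipped to the physical range
#' \[0.01, 0.99\]. Deterministic for a fixed seed. The true signatures and
#' dependency structure are attached as attribute `"truth"` so simulation
#' studies can assert recovery.
#'
#' @param config a `synth_config`.
#' @return An `ion_dataset` (raw reflectance spectra + element table).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)

  el <- config$elements
  n <- config$n_samples
  conc <- matrix(NA_real_, n, nrow(el), dimnames = list(NULL, el$name))
  for (nm in config$order) {
    row <- el[el$name == nm, ]
    if (row$role %in% c("active", "independent")) {
      conc[, nm] <- rlnorm_mean_cv(n, row$mean_ppm, row$cv)
    } else {
      d <- config$dependencies[config$dependencies$child == nm, ]
      parents <- split_names(d$parents)
      coefs <- as.numeric(split_names(d$coefficients))
      v <- as.numeric(conc[, parents, drop = FALSE] %*% coefs)
      if (d$link == "saturating") v <- v / (1 + v / d$v0)
      noise_sd <- d$noise_frac * stats::sd(v)
      conc[, nm] <- pmax(0, v + stats::rnorm(n, 0, noise_sd))
    }
  }

  wl <- config$wavelengths_nm
  spec <- matrix(config$baseline, n, length(wl))
  act <- el[el$role == "active", ]
  for (i in seq_len(nrow(act))) {
    g <- signature_profile(wl, act$center_nm[i], act$width_nm[i],
                           act$amplitude[i])
    cvals <- conc[, act$name[i]]
    cnorm <- (cvals - min(cvals)) / (max(cvals) - min(cvals))
    spec <- spec - outer(cnorm, g)
  }
  spec <- spec + matrix(stats::rnorm(n * length(wl), 0, config$spectral_noise_sd),
                        n, length(wl))
  clipped <- mean(spec < 0.01 | spec > 0.99)
  if (clipped > 0.5)
    warning(sprintf("%.0f%% of reflectance values hit the clip bounds; \
signatures likely too strong", 100 * clipped))
  spec <- pmin(pmax(spec, 0.01), 0.99)

  ids <- sprintf("s%04d", seq_len(n))
  ds <- ion_dataset(spectral_table(spec, wl, ids),
                    element_table(conc, ids))
  attr(ds, "truth") <- list(signatures = act,
                            dependencies = config$dependencies,
                            clipped_fraction = clipped)
  ds
}

#' Benchmark scenario with one chained dependency (G1)
#'
#' 400 samples, 120 bands on 400-2400 nm. Elements A, B, C are spectrally
#' active with well-separated Gaussian signatures strong enough for accurate
#' single-target recovery; D = 0.9 A + noise (noise SD 10% of the signal SD)
#' with no spectral loading of its own; E is a saturating function of B; F
#' is independent. The designed outcome is that chaining predicts D better
#' than spectra alone and selects A as its first chain element.
#'
#' @param seed integer seed.
#' @param n_samples sample count (default 400).
#' @return A `synth_config`.
#' @export
scenario_g1 <- function(seed = 1L, n_samples = 400) {
  elements <- data.frame(
    name = c("A", "B", "C", "D", "E", "F"),
    role = c("active", "active", "active", "dependent", "dependent",
             "independent"),
    mean_ppm = c(50, 500, 20, 45, 30, 10),
    cv = c(0.5, 0.4, 0.5, 0.5, 0.4, 0.5),
    center_nm = c(700, 1300, 1900, NA, NA, NA),
    width_nm = c(90, 90, 90, NA, NA, NA),
    amplitude = c(0.18, 0.18, 0.18, 0, 0, 0),
    stringsAsFactors = FALSE)
  dependencies <- data.frame(
    child = c("D", "E"),
    parents = c("A", "B"),
    coefficients = c("0.9", "0.06"),
    link = c("linear", "saturating"),
    noise_frac = c(0.1, 0.1),
    v0 = c(NA, 30),
    stringsAsFactors = FALSE)
  synth_config(n_samples = n_samples, elements = elements,
               dependencies = dependencies, seed = seed)
}

#' Null scenario with independent targets (G0)
#'
#' Same panel size as [scenario_g1()] but no element drives the spectra and
#' no element depends on another: spectra are baseline plus noise, all
#' concentrations are mutually independent log-normals. Single-target
#' accuracy should hover around zero and chains should stay (near) empty.
#'
#' @param seed integer seed.
#' @param n_samples sample count (default 400).
#' @return A `synth_config`.
#' @export
scenario_g0 <- function(seed = 1L, n_samples = 400) {
  elements <- data.frame(
    name = c("A", "B", "C", "D", "E", "F"),
    role = "independent",
    mean_ppm = c(50, 500, 20, 45, 30, 10),
    cv = 0.5,
    center_nm = NA_real_, width_nm = NA_real_, amplitude = NA_real_,
    stringsAsFactors = FALSE)
  synth_config(n_samples = n_samples, elements = elements,
               dependencies = NULL, seed = seed)
}
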