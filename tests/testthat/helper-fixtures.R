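# Fixtures are built in code; nothing is read from disk except the shipped
# reference element-statistics panel.

# Deterministic toy dataset: linear spectra so every learner can recover the
# structure quickly.
tiny_dataset <- function(n = 30, p = 6, seed = 99) {
  set.seed(seed)
  wl <- seq(500, 1000, length.out = p)
  X <- matrix(runif(n * p, 0.2, 0.8), n, p)
  conc <- cbind(Aa = 10 + 50 * X[, 2], Bb = 5 + 20 * X[, 4],
                Cc = runif(n, 1, 2))
  ion_dataset(spectral_table(X, wl, sprintf("t%02d", seq_len(n))),
              element_table(conc, sprintf("t%02d", seq_len(n))))
}

# Small simulated study (two active elements, one linear dependency, one
# independent element) for experiment-level tests.
small_scenario <- function(seed, n = 140, bands = 50) {
  elements <- data.frame(
    name = c("A", "B", "C", "F"),
    role = c("active", "active", "dependent", "independent"),
    mean_ppm = c(50, 500, 45, 10), cv = c(0.5, 0.4, 0.5, 0.5),
    center_nm = c(700, 1500, NA, NA), width_nm = c(120, 120, NA, NA),
    amplitude = c(0.18, 0.18, 0, 0),
    stringsAsFactors = FALSE)
  deps <- data.frame(child = "C", parents = "A", coefficients = "0.9",
                     link = "linear", noise_frac = 0.1, v0 = NA,
                     stringsAsFactors = FALSE)
  synth_config(n_samples = n, wavelengths_nm = seq(400, 2400, length.out = bands),
               elements = elements, dependencies = deps, seed = seed)
}

# Generate a scenario, run the preprocessing chain, and return the aligned
# model-ready dataset plus fold assignment.
prepped <- function(config, k = 5, fold_seed = config$seed) {
  ds <- generate_dataset(config)
  pp <- preprocess_spectra(ds$spectra)
  keep <- pp$spectra$sample_ids
  el <- element_table(
    ds$elements$values[match(keep, ds$elements$sample_ids), , drop = FALSE],
    keep, ds$elements$element_names)
  list(data = ion_dataset(pp$spectra, el),
       folds = make_folds(length(keep), k, seed = fold_seed))
}

# Single-point (pre-tuned) specs used where grid search is not under test.
ridge_spec <- function(seed = 1, lambda = 1e-4) {
  g <- data.frame(lambda = lambda)
  learner_spec("Ridge", g, seed = seed, tuned = as.list(g))
}
rf_spec <- function(seed = 1) {
  g <- data.frame(num_trees = 300, mtry_frac = 0.15, max_depth = 8,
                  min_node = 4, sample_frac = 0.8)
  learner_spec("RF", g, seed = seed, tuned = as.list(g))
}

# Brute-force two-sided signed-rank p-value by enumerating all 2^n sign
# assignments (zeros dropped, midranks), the oracle for the exact mode.
enumerate_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- signs %*% rk
  p_le <- mean(vs <= v_obs + 1e-12)
  p_ge <- mean(vs >= v_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}
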