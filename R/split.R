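new_split_plan <- function(train_ids, test_ids, fold_assignments, k,
                           test_fraction, seed) {
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 fold_assignments = fold_assignments, k = k,
                 test_fraction = test_fraction, seed = seed),
            class = "split_plan")
}

#' Train/test split with k-fold assignment of the training samples
#'
#' Splits the samples of a dataset into a held-out test set and a training
#' set, and partitions the training set into `k` cross-validation folds of
#' near-equal size (sizes differ by at most one). The test-set size is
#' `max(1, round_half_away(test_fraction * n))`, which reproduces the
#' 668-train / 74-test division of 742 samples at a 10% test fraction.
#'
#' @param dataset an `ion_dataset`, or a character vector of sample ids.
#' @param test_fraction fraction of samples held out for testing, in (0, 1).
#' @param k number of cross-validation folds (default 10).
#' @param seed integer seed; the split is deterministic given the seed.
#' @param by_plant if `TRUE` and the spectra carry `plant_ids`, whole plants
#'   are assigned to test/folds so ROIs from one plant never straddle the
#'   split. Default `FALSE`: the ROI is the sampling unit.
#' @return A `split_plan` with `train_ids`, `test_ids`, and
#'   `fold_assignments` (named integer vector over train ids).
#' @export
split_dataset <- function(dataset, test_fraction = 0.1, k = 10, seed = 1,
                          by_plant = FALSE) {
  if (inherits(dataset, "ion_dataset")) {
    ids <- dataset$spectra$sample_ids
    plants <- dataset$spectra$plant_ids
  } else {
    ids <- as.character(dataset)
    plants <- NULL
  }
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must be in (0, 1)")
  if (k < 2) stop("k must be >= 2")
  n <- length(ids)
  if (n < k + 1) stop("need at least k + 1 = ", k + 1, " samples, got ", n)

  round_half_away <- function(x) floor(x + 0.5)  # x >= 0 here
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    list(perm = sample.int(n))
  })
  perm <- rng$perm

  if (by_plant && !is.null(plants)) {
    units <- unique(plants[perm])                  # plants in shuffled order
    n_test_target <- max(1L, round_half_away(test_fraction * n))
    test_units <- character(0); got <- 0L
    for (u in units) {
      if (got >= n_test_target) break
      test_units <- c(test_units, u)
      got <- got + sum(plants == u)
    }
    test_ids <- ids[plants %in% test_units]
    train_ids <- ids[!plants %in% test_units]
    train_units <- setdiff(units, test_units)
    unit_fold <- stats::setNames(rep_len(seq_len(k), length(train_units)),
                                 train_units)
    fa <- unit_fold[plants[match(train_ids, ids)]]
    names(fa) <- train_ids
  } else {
    n_test <- max(1L, round_half_away(test_fraction * n))
    test_ids <- ids[perm[seq_len(n_test)]]
    train_ids <- ids[perm[-seq_len(n_test)]]
    if (length(train_ids) < k) stop("too few training samples for ", k, " folds")
    fa <- stats::setNames(rep_len(seq_len(k), length(train_ids)), train_ids)
  }
  new_split_plan(train_ids = train_ids, test_ids = test_ids,
                 fold_assignments = fa, k = k,
                 test_fraction = test_fraction, seed = seed)
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Split plan: ", length(x$train_ids), " train / ",
      length(x$test_ids), " test; k = ", x$k, " folds (sizes ",
      paste(as.integer(table(x$fold_assignments)), collapse = "/"),
      ")\n", sep = "")
  invisible(x)
}

#' k-fold assignments for a plain sample count
#'
#' Utility used when no held-out test set is wanted: permutes `1..n` under
#' `seed` and deals samples into `k` balanced folds.
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids (1..k), length `n`.
#' @export
make_folds <- function(n, k, seed = 1) {
  stopifnot(k >= 2, n >= k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}
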