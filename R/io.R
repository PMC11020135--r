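#' Read a spectra CSV
#'
#' Expected layout: comma-separated, period decimal, UTF-8. Header
#' `sample_id[,plant_id],<lambda1>,<lambda2>,...` with band wavelengths in nm
#' as plain numbers; one row per ROI sample.
#'
#' @param path file path.
#' @return A [spectral_table()].
#' @export
read_spectra_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA,
                        fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("spectra CSV needs a sample_id column plus bands")
  has_plant <- identical(names(df)[2], "plant_id")
  first_band <- if (has_plant) 3L else 2L
  wl <- suppressWarnings(as.numeric(names(df)[first_band:ncol(df)]))
  if (anyNA(wl))
    stop("non-numeric wavelength header: ",
         paste(names(df)[first_band:ncol(df)][is.na(wl)], collapse = ", "))
  if (length(wl) > 1 && any(diff(wl) <= 0))
    stop("wavelength header must be strictly increasing (nm)")
  vals <- as.matrix(df[, first_band:ncol(df), drop = FALSE])
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("missing cell at row ", bad[1], " (sample '", df[[1]][bad[1]],
         "'), band column ", names(df)[first_band - 1 + bad[2]])
  }
  spectral_table(vals, wl, df[[1]],
                 plant_ids = if (has_plant) df[[2]])
}

#' Write a spectra CSV
#'
#' Inverse of [read_spectra_table()]; full-precision round trip.
#'
#' @param x a `spectral_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(x, path) {
  stopifnot(inherits(x, "spectral_table"))
  df <- data.frame(sample_id = x$sample_ids, stringsAsFactors = FALSE)
  if (!is.null(x$plant_ids)) df$plant_id <- x$plant_ids
  m <- x$values
  colnames(m) <- format(x$wavelengths_nm, trim = TRUE, scientific = FALSE,
                        digits = 15)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an element concentration CSV
#'
#' Layout: header `sample_id,<element>,...`, concentrations in ppm.
#'
#' @param path file path.
#' @return An [element_table()].
#' @export
read_element_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("element CSV needs a sample_id column plus elements")
  vals <- as.matrix(df[, -1, drop = FALSE])
  element_table(vals, df[[1]], names(df)[-1])
}

#' Write an element concentration CSV
#'
#' @param x an `element_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_element_table <- function(x, path) {
  stopifnot(inherits(x, "element_table"))
  df <- data.frame(sample_id = x$sample_ids, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a split plan as a two-column CSV
#'
#' Serializes a [split_dataset()] result as `sample_id,assignment` with
#' assignment `test` or `fold<i>` so a split can be replayed exactly.
#'
#' @param plan a `split_plan`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  stopifnot(inherits(plan, "split_plan"))
  df <- data.frame(
    sample_id = c(plan$train_ids, plan$test_ids),
    assignment = c(paste0("fold", plan$fold_assignments[plan$train_ids]),
                   rep("test", length(plan$test_ids))),
    stringsAsFactors = FALSE)
  df <- df[order(df$sample_id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a split plan CSV written by [write_split_plan()]
#'
#' @param path file path.
#' @return A `split_plan` (with `seed`/`test_fraction` set to `NA`, since the
#'   file records only the realized assignment).
#' @export
read_split_plan <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stopifnot(all(c("sample_id", "assignment") %in% names(df)))
  test_ids <- df$sample_id[df$assignment == "test"]
  tr <- df[df$assignment != "test", ]
  folds <- as.integer(sub("^fold", "", tr$assignment))
  if (anyNA(folds)) stop("assignments must be 'test' or 'fold<i>'")
  fa <- stats::setNames(folds, tr$sample_id)
  new_split_plan(train_ids = tr$sample_id, test_ids = test_ids,
                 fold_assignments = fa, k = max(folds),
                 test_fraction = NA_real_, seed = NA_integer_)
}
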