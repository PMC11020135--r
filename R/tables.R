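#' Spectral table
#'
#' A sample-by-band reflectance (or derivative) matrix with wavelength
#' metadata. Rows are ROI samples (one region-of-interest median spectrum
#' each), columns are wavelength bands in nanometres.
#'
#' @param values numeric matrix, rows = samples, columns = bands.
#' @param wavelengths_nm numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, one per column of `values`.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row of `values`.
#' @param plant_ids optional character vector grouping ROI samples into
#'   plants (used for within/between-plant spectral similarity and for
#'   plant-grouped splitting).
#' @return An object of class `spectral_table`.
#' @export
spectral_table <- function(values, wavelengths_nm, sample_ids,
                           plant_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  wavelengths_nm <- as.numeric(wavelengths_nm)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(sample_ids))
    stop("row count (", nrow(values), ") != number of sample ids (",
         length(sample_ids), ")")
  if (ncol(values) != length(wavelengths_nm))
    stop("column count (", ncol(values), ") != number of wavelengths (",
         length(wavelengths_nm), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing value at sample '", sample_ids[bad[1]], "', band ",
         format(wavelengths_nm[bad[2]]), " nm")
  }
  if (!is.null(plant_ids)) {
    plant_ids <- as.character(plant_ids)
    if (length(plant_ids) != length(sample_ids))
      stop("plant_ids length must match sample_ids")
  }
  dimnames(values) <- list(sample_ids, format_band(wavelengths_nm))
  structure(list(values = values, wavelengths_nm = wavelengths_nm,
                 sample_ids = sample_ids, plant_ids = plant_ids),
            class = "spectral_table")
}

format_band <- function(wl) paste0("b", format(wl, trim = TRUE,
                                               scientific = FALSE))

#' @export
print.spectral_table <- function(x, ...) {
  cat("Spectral table: ", nrow(x$values), " samples x ",
      ncol(x$values), " bands (",
      format(min(x$wavelengths_nm)), "-", format(max(x$wavelengths_nm)),
      " nm)\n", sep = "")
  if (!is.null(x$plant_ids))
    cat("  grouped into", length(unique(x$plant_ids)), "plants\n")
  invisible(x)
}

#' @export
dim.spectral_table <- function(x) dim(x$values)

#' Element concentration table
#'
#' A sample-by-element matrix of concentrations in ppm, the multi-target
#' response of the STR/MTSC methods.
#'
#' @param values numeric matrix of non-negative concentrations (ppm), rows =
#'   samples, columns = elements.
#' @param sample_ids character vector of unique sample identifiers.
#' @param element_names optional character vector of unique element names;
#'   defaults to `colnames(values)`.
#' @return An object of class `element_table`.
#' @export
element_table <- function(values, sample_ids, element_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_ids <- as.character(sample_ids)
  if (is.null(element_names))
    stop("element names are required (as element_names or colnames)")
  element_names <- as.character(element_names)
  if (nrow(values) != length(sample_ids))
    stop("row count != number of sample ids")
  if (ncol(values) != length(element_names))
    stop("column count != number of element names")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(element_names)) stop("duplicate element names")
  if (anyNA(values)) stop("missing concentration values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative concentration for element '", element_names[bad[2]],
         "', sample '", sample_ids[bad[1]], "'")
  }
  dimnames(values) <- list(sample_ids, element_names)
  structure(list(values = values, sample_ids = sample_ids,
                 element_names = element_names),
            class = "element_table")
}

#' @export
print.element_table <- function(x, ...) {
  cat("Element table: ", nrow(x$values), " samples x ",
      ncol(x$values), " elements (",
      paste(utils::head(x$element_names, 8), collapse = ", "),
      if (length(x$element_names) > 8) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' @export
dim.element_table <- function(x) dim(x$values)

#' Paired spectra/element dataset
#'
#' Binds a [spectral_table()] and an [element_table()] over the same samples
#' in the same order.
#'
#' @param spectra a `spectral_table`.
#' @param elements an `element_table`.
#' @return An object of class `ion_dataset`.
#' @export
ion_dataset <- function(spectra, elements) {
  stopifnot(inherits(spectra, "spectral_table"),
            inherits(elements, "element_table"))
  if (!identical(spectra$sample_ids, elements$sample_ids))
    stop("sample ids of spectra and elements differ (or are ordered differently)")
  structure(list(spectra = spectra, elements = elements),
            class = "ion_dataset")
}

#' @export
print.ion_dataset <- function(x, ...) {
  cat("Ionome dataset\n")
  print(x$spectra); print(x$elements)
  invisible(x)
}

#' Subset a dataset by sample ids
#'
#' @param dataset an `ion_dataset`.
#' @param ids sample ids to keep, in the requested order.
#' @return The subset `ion_dataset`.
#' @export
subset_dataset <- function(dataset, ids) {
  stopifnot(inherits(dataset, "ion_dataset"))
  idx <- match(ids, dataset$spectra$sample_ids)
  if (anyNA(idx)) stop("unknown sample ids: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  sp <- dataset$spectra
  ion_dataset(
    spectral_table(sp$values[idx, , drop = FALSE], sp$wavelengths_nm,
                   sp$sample_ids[idx],
                   if (!is.null(sp$plant_ids)) sp$plant_ids[idx]),
    element_table(dataset$elements$values[idx, , drop = FALSE],
                  dataset$elements$sample_ids[idx],
                  dataset$elements$element_names))
}
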