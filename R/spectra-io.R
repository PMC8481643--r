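# Containers and CSV I/O for spectra and reference chemistry.
#
# A `nir_spectra` object is a wide tibble: `sample_id`, `format`, then one
# numeric column per wavenumber (cm^-1), values in absorbance units
# (log 1/R). The canonical in-memory order is ascending wavenumber; files
# may come either way (FT instruments often export descending).

.wn_label <- function(wn) {
  formatC(wn, format = "g", digits = 15, width = 1)
}

#' Construct an NIR spectra table
#'
#' @param absorbance Numeric matrix, samples in rows, wavelengths in columns.
#' @param wavenumbers Numeric vector of wavenumbers (cm^-1), one per column.
#' @param sample_id Character vector of unique sample labels.
#' @param format Optional per-sample presentation format (recycled if
#'   length 1); one of [sorghum_formats] or any label.
#' @return A `nir_spectra` tibble (columns `sample_id`, `format`, then one
#'   column per wavenumber, ascending).
#' @export
#' @examples
#' nir_spectra(matrix(runif(10), 2), seq(4000, 10000, length.out = 5),
#'             c("a", "b"))
nir_spectra <- function(absorbance, wavenumbers, sample_id,
                        format = "whole_grain") {
  absorbance <- as.matrix(absorbance)
  wavenumbers <- as.numeric(wavenumbers)
  sample_id <- as.character(sample_id)
  if (length(wavenumbers) != ncol(absorbance)) {
    abort("`wavenumbers` length must equal ncol(absorbance).")
  }
  if (length(sample_id) != nrow(absorbance)) {
    abort("`sample_id` length must equal nrow(absorbance).")
  }
  format <- rep_len(as.character(format), nrow(absorbance))
  ord <- order(wavenumbers)
  wavenumbers <- wavenumbers[ord]
  absorbance <- absorbance[, ord, drop = FALSE]
  out <- tibble::as_tibble(absorbance, .name_repair = "minimal")
  names(out) <- .wn_label(wavenumbers)
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = sample_id, format = format), out
  )
  out <- tibble::new_tibble(out, wavenumbers = wavenumbers,
                            class = "nir_spectra")
  validate_nir_spectra(out)
}

#' Validate an NIR spectra table
#'
#' Checks the invariants: unique sample ids, strictly increasing finite
#' wavenumbers, and a complete finite absorbance block.
#'
#' @param x A `nir_spectra` tibble (or data frame in the same layout).
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_nir_spectra <- function(x) {
  wn <- wavenumbers(x)
  if (anyNA(wn) || any(!is.finite(wn))) {
    abort("All wavenumber column names must be finite numbers.")
  }
  if (any(diff(wn) <= 0)) {
    abort("Wavenumbers must be strictly increasing.")
  }
  ids <- x$sample_id
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate sample_id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- spectra_matrix(x)
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- ids[rowSums(!is.finite(m)) > 0]
    abort(paste0("Missing or non-finite absorbance values in sample(s): ",
                 paste(bad, collapse = ", ")))
  }
  x
}

#' @export
print.nir_spectra <- function(x, ...) {
  wn <- wavenumbers(x)
  cat(sprintf("<nir_spectra: %d samples x %d wavelengths, %.1f-%.1f cm^-1>\n",
              nrow(x), length(wn), min(wn), max(wn)))
  NextMethod()
}

#' Extract the absorbance matrix of a spectra table
#'
#' @param x A `nir_spectra` tibble (or data frame in the same layout).
#' @return Numeric matrix with `sample_id` row names and one column per
#'   wavenumber.
#' @export
spectra_matrix <- function(x) {
  keep <- !(names(x) %in% c("sample_id", "format"))
  m <- as.matrix(as.data.frame(x)[, keep, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$sample_id
  m
}

#' Wavenumber grid of a spectra table
#'
#' @inheritParams spectra_matrix
#' @return Numeric vector of wavenumbers in cm^-1.
#' @export
wavenumbers <- function(x) {
  wn <- attr(x, "wavenumbers")
  if (!is.null(wn) && length(wn) == sum(!(names(x) %in% c("sample_id", "format")))) {
    return(wn)
  }
  suppressWarnings(
    as.numeric(names(x)[!(names(x) %in% c("sample_id", "format"))])
  )
}

#' Replace the absorbance block of a spectra table
#'
#' Keeps ids, formats and the wavenumber grid; used by the preprocessing
#' steps so treated spectra stay in the same container.
#'
#' @param x A `nir_spectra` tibble.
#' @param m Numeric matrix of the same dimension as `spectra_matrix(x)`.
#' @return A `nir_spectra` tibble.
#' @export
set_spectra_matrix <- function(x, m) {
  nir_spectra(m, wavenumbers(x), x$sample_id,
              format = x$format %||% "whole_grain")
}

#' Read a wide-format spectra CSV
#'
#' Expected header: `sample_id`, optionally `format`, then one numeric
#' wavenumber per remaining column. Columns are reordered to ascending
#' wavenumber on read.
#'
#' @param path Path to a CSV file.
#' @return A validated `nir_spectra` tibble.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L || names(df)[1] != "sample_id") {
    abort("Spectra CSV must start with a `sample_id` column and have rows.")
  }
  has_format <- "format" %in% names(df)
  wn_cols <- setdiff(names(df), c("sample_id", "format"))
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (anyNA(wn)) {
    abort(paste0("Non-numeric wavenumber column(s): ",
                 paste(wn_cols[is.na(wn)], collapse = ", ")))
  }
  m <- as.matrix(df[, wn_cols, drop = FALSE])
  if (!is.numeric(m)) abort("Absorbance cells must all be numeric.")
  nir_spectra(m, wn, df$sample_id,
              format = if (has_format) df$format else "whole_grain")
}

#' Write a spectra table to CSV
#'
#' Numbers are written at full double precision so a read/write round trip
#' is lossless well beyond 12 significant digits.
#'
#' @param x A `nir_spectra` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Read a reference-chemistry CSV
#'
#' Expected header: `sample_id` plus the eight analyte columns of
#' [sorghum_analytes] (g kg^-1); any extra columns (e.g. `format`, `grade`)
#' are kept as metadata and ignored by the analytics.
#'
#' @param path Path to a CSV file.
#' @return A `ref_chemistry` tibble.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_ref_chemistry(df)
}

#' Validate (and class) a reference-chemistry table
#'
#' @param df Data frame with `sample_id` and the eight analyte columns.
#' @return A `ref_chemistry` tibble.
#' @export
as_ref_chemistry <- function(df) {
  if (nrow(df) == 0L) abort("Reference table has no rows.")
  if (!"sample_id" %in% names(df)) abort("Reference table needs `sample_id`.")
  missing <- setdiff(sorghum_analytes, names(df))
  if (length(missing)) {
    abort(paste0("Missing analyte column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) abort("Duplicate sample_id in reference.")
  vals <- as.matrix(df[, sorghum_analytes])
  if (anyNA(vals) || any(!is.finite(vals))) {
    abort("Analyte values must be finite and non-missing.")
  }
  if (any(vals < 0)) abort("Analyte values must be >= 0 (g kg^-1).")
  df <- tibble::as_tibble(df)
  df$sample_id <- as.character(df$sample_id)
  class(df) <- c("ref_chemistry", class(tibble::tibble()))
  df
}

#' Write a reference-chemistry table to CSV
#'
#' @param x A `ref_chemistry` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Align spectra with reference chemistry on sample id
#'
#' Inner-join on `sample_id`, preserving the spectra order. Samples present
#' in only one table are dropped with a warning.
#'
#' @param spectra A `nir_spectra` tibble.
#' @param reference A `ref_chemistry` tibble.
#' @return An `aligned_dataset`: list with `$spectra`, `$chemistry` (same
#'   ordered sample ids) and `$dropped` (ids removed from either side).
#' @export
align_dataset <- function(spectra, reference) {
  shared <- intersect(spectra$sample_id, reference$sample_id)
  if (length(shared) == 0L) {
    abort("No shared sample_id between spectra and reference.")
  }
  dropped <- union(setdiff(spectra$sample_id, shared),
                   setdiff(reference$sample_id, shared))
  if (length(dropped)) {
    warn(paste0("Dropping ", length(dropped),
                " sample(s) without a match: ",
                paste(head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ..." else ""))
  }
  sp <- spectra[spectra$sample_id %in% shared, , drop = FALSE]
  sp <- nir_spectra(spectra_matrix(sp), wavenumbers(sp), sp$sample_id,
                    format = sp$format %||% "whole_grain")
  ref <- reference[match(sp$sample_id, reference$sample_id), , drop = FALSE]
  structure(
    list(spectra = sp, chemistry = as_ref_chemistry(ref), dropped = dropped),
    class = "aligned_dataset"
  )
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf("<aligned_dataset: %d samples, %d wavelengths, %d analytes>\n",
              nrow(x$spectra), length(wavenumbers(x$spectra)),
              length(sorghum_analytes)))
  invisible(x)
}
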