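#' Build a labeled spectra table
#'
#' The package's central container is an ordinary wide tibble: one row per
#' sample, a `sample_id` column, a `label` column, and one numeric column per
#' wavelength (column names are the wavelengths in nm). All modelling
#' functions take this tibble first, so calls chain with the pipe.
#'
#' @section Class encoding:
#' Throughout the package, `label = 0` is a vegetable and `label = 1` a
#' foreign material (FM). Note the confusion-metric convention this implies:
#' vegetables are the *positive* class (a true positive is a correctly
#' recognised vegetable), which inverts the habit of treating the contaminant
#' as positive. See [confusion_counts()].
#'
#' @param absorbance numeric matrix, samples x wavelengths (absorbance units).
#' @param wavelengths strictly increasing numeric vector of wavelengths (nm),
#'   one per matrix column.
#' @param labels integer vector of class labels, 0 = vegetable, 1 = FM.
#' @param sample_ids optional character vector of sample identifiers;
#'   defaults to `"s1", "s2", ...`.
#' @return A tibble with columns `sample_id`, `label`, then one column per
#'   wavelength.
#' @examples
#' s <- new_spectra(matrix(rnorm(6), 2, 3), c(1100, 1200, 1300), c(0L, 1L))
#' spectra_wavelengths(s)
#' @export
new_spectra <- function(absorbance, wavelengths, labels, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  wavelengths <- check_grid(wavelengths, min_len = 1L)
  if (ncol(absorbance) != length(wavelengths)) {
    abort_nirfm("absorbance column count must equal the number of wavelengths",
                "nirfm_spectra_error")
  }
  n <- nrow(absorbance)
  if (length(labels) != n) {
    abort_nirfm("labels length must equal the number of spectra", "nirfm_spectra_error")
  }
  if (n > 0 && !all(labels %in% c(0L, 1L))) {
    abort_nirfm("labels must be 0 (vegetable) or 1 (foreign material)",
                "nirfm_spectra_error")
  }
  if (n > 0 && !all(is.finite(absorbance))) {
    abort_nirfm("absorbance values must all be finite", "nirfm_spectra_error")
  }
  sample_ids <- sample_ids %||% paste0("s", seq_len(n))
  out <- tibble::as_tibble(absorbance, .name_repair = "minimal")
  names(out) <- format_wavelength(wavelengths)
  dplyr::bind_cols(
    tibble::tibble(sample_id = as.character(sample_ids), label = as.integer(labels)),
    out
  )
}

format_wavelength <- function(w) {
  formatC(w, format = "fg", digits = 12, width = 1)
}

spectra_cols <- function(spectra) {
  setdiff(names(spectra), c("sample_id", "label"))
}

#' Wavelength axis of a spectra table
#'
#' @param spectra a spectra tibble from [new_spectra()] or [read_spectra_csv()].
#' @return Numeric vector of wavelengths (nm), in column order.
#' @export
spectra_wavelengths <- function(spectra) {
  w <- suppressWarnings(as.numeric(spectra_cols(spectra)))
  if (anyNA(w)) {
    abort_nirfm("spectra table has non-numeric wavelength column names",
                "nirfm_spectra_error")
  }
  w
}

#' Absorbance matrix of a spectra table
#'
#' @inheritParams spectra_wavelengths
#' @return Numeric matrix, samples x wavelengths, with wavelength column names.
#' @export
spectra_matrix <- function(spectra) {
  cols <- spectra_cols(spectra)
  m <- as.matrix(spectra[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- spectra$sample_id
  m
}

validate_spectra <- function(spectra) {
  if (!all(c("sample_id", "label") %in% names(spectra))) {
    abort_nirfm("spectra table needs sample_id and label columns", "nirfm_spectra_error")
  }
  check_grid(spectra_wavelengths(spectra), min_len = 1L)
  if (nrow(spectra) > 0 && !all(spectra$label %in% c(0L, 1L))) {
    abort_nirfm("labels must be 0 (vegetable) or 1 (foreign material)",
                "nirfm_spectra_error")
  }
  invisible(spectra)
}

#' Read labeled spectra from a wide CSV file
#'
#' Expects the dialect written by [write_spectra_csv()]: comma separated,
#' `.` decimal mark, UTF-8, header `sample_id,label,<wavelength>,...` with
#' strictly increasing numeric wavelengths.
#'
#' @param path path to a CSV file.
#' @return A spectra tibble (see [new_spectra()]).
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) {
    abort_nirfm(sprintf("file not found: %s", path), "nirfm_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!identical(names(raw)[1:2], c("sample_id", "label"))) {
    abort_nirfm("header must start with sample_id,label", "nirfm_format_error")
  }
  w <- suppressWarnings(as.numeric(names(raw)[-(1:2)]))
  if (anyNA(w)) {
    bad <- which(is.na(w))[1] + 2L
    abort_nirfm(sprintf("header column %d is not a numeric wavelength", bad),
                "nirfm_format_error")
  }
  check_grid(w)
  bad_label <- which(!(raw$label %in% c(0, 1)))
  if (length(bad_label) > 0) {
    abort_nirfm(sprintf("label outside {0,1} on data row %d", bad_label[1]),
                "nirfm_format_error")
  }
  m <- as.matrix(raw[, -(1:2), drop = FALSE])
  if (nrow(m) > 0 && !all(is.finite(m))) {
    bad <- which(!apply(is.finite(m), 1, all))[1]
    abort_nirfm(sprintf("non-finite absorbance on data row %d", bad),
                "nirfm_format_error")
  }
  new_spectra(m, w, as.integer(raw$label), raw$sample_id)
}

#' Write labeled spectra to a wide CSV file
#'
#' Round-trips through [read_spectra_csv()] with at least 12 significant
#' digits of fidelity.
#'
#' @inheritParams spectra_wavelengths
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  validate_spectra(spectra)
  w <- spectra_wavelengths(spectra)
  header <- paste(c("sample_id", "label", format_wavelength(w)), collapse = ",")
  m <- spectra_matrix(spectra)
  lines <- header
  if (nrow(spectra) > 0) {
    body <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(spectra$sample_id[i], spectra$label[i],
              formatC(m[i, ], format = "g", digits = 15)), collapse = ",")
    }, character(1))
    lines <- c(header, body)
  }
  con <- tryCatch(file(path, "wb"), error = function(e) {
    abort_nirfm(sprintf("cannot open %s for writing", path), "nirfm_io_error")
  })
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Stratified calibration/validation split
#'
#' Splits a labeled spectra table into calibration and validation subsets,
#' per class: each class contributes `floor(fraction * class size)` samples
#' to calibration and the remainder to validation. With 280 vegetables, 320
#' FMs and `fraction = 0.7` this gives the canonical 196 + 224 = 420
#' calibration and 180 validation samples.
#'
#' @inheritParams spectra_wavelengths
#' @param fraction calibration fraction, strictly between 0 and 1.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return A list with elements `calibration` and `validation`, both spectra
#'   tibbles partitioning the input.
#' @export
stratified_split <- function(spectra, fraction = 0.7, seed = 1L) {
  validate_spectra(spectra)
  if (!(fraction > 0 && fraction < 1)) {
    abort_nirfm("fraction must lie strictly between 0 and 1", "nirfm_split_error")
  }
  labels <- spectra$label
  cal_idx <- integer(0)
  with_rng(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      n_cal <- floor(fraction * length(idx))
      if (n_cal < 1L || n_cal >= length(idx)) {
        abort_nirfm(sprintf(
          "class %d has too few samples (%d) for a non-empty split at fraction %g",
          cl, length(idx), fraction), "nirfm_split_error")
      }
      cal_idx <- c(cal_idx, sort(idx[sample.int(length(idx), n_cal)]))
    }
  })
  cal_idx <- sort(cal_idx)
  list(
    calibration = spectra[cal_idx, , drop = FALSE],
    validation  = spectra[setdiff(seq_len(nrow(spectra)), cal_idx), , drop = FALSE]
  )
}
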