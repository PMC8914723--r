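#' Per-spectrum normalization
#'
#' Rescales each spectrum by its own summary: `mode = "mean"` divides by the
#' row mean, `"max"` by the row maximum, `"range"` maps the row onto
#' \[0, 1\] via `(x - min) / (max - min)`. Grid, labels and sample order are
#' untouched.
#'
#' @inheritParams spectra_wavelengths
#' @param mode one of `"mean"`, `"max"`, `"range"`.
#' @return A spectra tibble of the same shape.
#' @export
normalize <- function(spectra, mode = c("mean", "max", "range")) {
  mode <- match.arg(mode)
  transform_spectra(spectra, function(x) {
    switch(mode,
      mean = {
        m <- mean(x)
        if (m == 0) abort_nirfm("zero-mean spectrum under mean normalization",
                                "nirfm_preprocess_error")
        x / m
      },
      max = {
        m <- max(x)
        if (m == 0) abort_nirfm("zero-max spectrum under max normalization",
                                "nirfm_preprocess_error")
        x / m
      },
      range = {
        r <- max(x) - min(x)
        if (r == 0) abort_nirfm("constant spectrum under range normalization",
                                "nirfm_preprocess_error")
        (x - min(x)) / r
      }
    )
  })
}

#' Standard normal variate (SNV)
#'
#' Centers and scales each spectrum to mean 0 and unit standard deviation
#' (n - 1 denominator, the dominant chemometrics convention). SNV removes
#' per-spectrum offset and multiplicative scatter; it is invariant under
#' positive affine transforms of a spectrum and idempotent.
#'
#' @inheritParams spectra_wavelengths
#' @return A spectra tibble of the same shape.
#' @export
snv <- function(spectra) {
  transform_spectra(spectra, function(x) {
    s <- stats::sd(x)
    if (s == 0) abort_nirfm("constant spectrum under SNV", "nirfm_preprocess_error")
    (x - mean(x)) / s
  })
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a + b * ref`, and
#' returns `(x - a) / b`. The reference defaults to the mean spectrum of the
#' input, so correcting a set against itself is idempotent.
#'
#' @inheritParams spectra_wavelengths
#' @param reference optional numeric reference spectrum (defaults to the
#'   column-wise mean of `spectra`); must not be constant.
#' @param tol smallest admissible |slope| in the per-spectrum fit.
#' @return A spectra tibble of the same shape.
#' @export
msc <- function(spectra, reference = NULL, tol = 1e-10) {
  validate_spectra(spectra)
  m <- spectra_matrix(spectra)
  reference <- reference %||% colMeans(m)
  if (length(reference) != ncol(m)) {
    abort_nirfm("reference length must match the wavelength count",
                "nirfm_preprocess_error")
  }
  if (stats::sd(reference) == 0) {
    abort_nirfm("MSC reference must not be constant", "nirfm_preprocess_error")
  }
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  out <- t(apply(m, 1, function(x) {
    b <- sum((x - mean(x)) * rc) / denom
    if (abs(b) < tol) {
      abort_nirfm("degenerate MSC fit: slope below tolerance", "nirfm_preprocess_error")
    }
    a <- mean(x) - b * mean(reference)
    (x - a) / b
  }))
  replace_matrix(spectra, out)
}

#' Savitzky-Golay derivative
#'
#' Per-spectrum local-polynomial derivative via [signal::sgolayfilt()].
#' The derivative is scaled by the grid spacing, so units are absorbance
#' per nm (first) or per nm squared (second), independent of grid
#' resolution. Edge points are handled by the off-center rows of the
#' Savitzky-Golay projection matrix, i.e. by the polynomial fitted in the
#' terminal window.
#'
#' @inheritParams spectra_wavelengths
#' @param window odd window length (points); default 11.
#' @param polyorder polynomial degree; default 2.
#' @param deriv derivative order, 1 or 2.
#' @return A spectra tibble of the same shape.
#' @export
savitzky_golay <- function(spectra, window = 11L, polyorder = 2L, deriv = 1L) {
  validate_spectra(spectra)
  w <- spectra_wavelengths(spectra)
  if (window %% 2 == 0 || window <= polyorder || polyorder < deriv ||
      !deriv %in% 1:2 || window > length(w)) {
    abort_nirfm(
      "need odd window > polyorder >= deriv (1 or 2) and window <= grid length",
      "nirfm_preprocess_error")
  }
  spacing <- mean(diff(w))
  transform_spectra(spectra, function(x) {
    signal::sgolayfilt(x, p = polyorder, n = window, m = deriv, ts = spacing)
  })
}

transform_spectra <- function(spectra, f) {
  validate_spectra(spectra)
  m <- spectra_matrix(spectra)
  if (nrow(m) > 0) m <- t(apply(m, 1, f))
  replace_matrix(spectra, m)
}

replace_matrix <- function(spectra, m) {
  cols <- spectra_cols(spectra)
  stopifnot(ncol(m) == length(cols))
  spectra[, cols] <- tibble::as_tibble(matrix(m, nrow = nrow(spectra),
                                              dimnames = list(NULL, cols)))
  spectra
}

#' Apply a named preprocessing treatment
#'
#' Dispatch helper used by the pipeline: `"raw"`, `"mean"`, `"max"`,
#' `"range"`, `"snv"`, `"msc"`, `"sg1"` or `"sg2"` (Savitzky-Golay first or
#' second derivative).
#'
#' @inheritParams spectra_wavelengths
#' @param method treatment name.
#' @param ... passed to the underlying treatment (e.g. `window`).
#' @return A spectra tibble of the same shape.
#' @export
preprocess <- function(spectra,
                       method = c("raw", "mean", "max", "range",
                                  "snv", "msc", "sg1", "sg2"),
                       ...) {
  method <- match.arg(method)
  switch(method,
    raw = validate_spectra(spectra),
    mean = normalize(spectra, "mean"),
    max = normalize(spectra, "max"),
    range = normalize(spectra, "range"),
    snv = snv(spectra),
    msc = msc(spectra, ...),
    sg1 = savitzky_golay(spectra, deriv = 1L, ...),
    sg2 = savitzky_golay(spectra, deriv = 2L, ...)
  )
}
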