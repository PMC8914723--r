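#' Construct a multispectral image cube
#'
#' A `hypercube` wraps a `lines x pixels x bands` numeric array (absorbance
#' by default, mirroring the spectral tables) together with its band-center
#' wavelengths and, optionally, a ground-truth object table.
#'
#' @param data numeric 3-D array, lines x pixels x bands.
#' @param band_centers strictly increasing wavelengths (nm), one per band.
#' @param truth optional tibble with columns `object_id` (integer),
#'   `class` (`"vegetable"`, `"fm"` or `"background"`) and `pixels`
#'   (list-column of two-column integer matrices of (line, pixel)
#'   coordinates). Object pixel sets must be disjoint and in bounds.
#' @return A `hypercube` object.
#' @export
new_hypercube <- function(data, band_centers, truth = NULL) {
  if (length(dim(data)) != 3L) {
    abort_nirfm("cube data must be a lines x pixels x bands array", "nirfm_cube_error")
  }
  band_centers <- check_grid(band_centers, "band_centers", min_len = 1L)
  if (dim(data)[3] != length(band_centers)) {
    abort_nirfm("band_centers length must equal the cube's band dimension",
                "nirfm_cube_error")
  }
  if (!is.null(truth)) {
    seen <- matrix(FALSE, dim(data)[1], dim(data)[2])
    for (px in truth$pixels) {
      if (any(px[, 1] < 1 | px[, 1] > dim(data)[1] |
              px[, 2] < 1 | px[, 2] > dim(data)[2])) {
        abort_nirfm("truth mask pixel outside image bounds", "nirfm_cube_error")
      }
      lin <- cbind(px[, 1], px[, 2])
      if (any(seen[lin])) {
        abort_nirfm("truth object pixel sets overlap", "nirfm_cube_error")
      }
      seen[lin] <- TRUE
    }
  }
  structure(
    list(data = data, band_centers = band_centers, truth = truth),
    class = "hypercube"
  )
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d lines x %d pixels x %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$band_centers), max(x$band_centers)))
  if (!is.null(x$truth)) {
    cat(sprintf("  truth: %d objects (%s)\n", nrow(x$truth),
                paste(table(x$truth$class), names(table(x$truth$class)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Write a hypercube as an ENVI header + BSQ binary pair
#'
#' The header is plain text; the binary is band-sequential 32-bit IEEE
#' floats, little endian (ENVI data type 4, byte order 0).
#'
#' @param cube a [new_hypercube()] object.
#' @param path path of the header file (conventionally `.hdr`); the binary
#'   is written next to it with the extension stripped.
#' @return The header path, invisibly.
#' @export
write_envi_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  bin_path <- sub("\\.hdr$", "", path)
  if (identical(bin_path, path)) bin_path <- paste0(path, ".img")
  hdr <- c(
    "ENVI",
    "description = {nirfm simulated cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = nm",
    sprintf("wavelength = {%s}",
            paste(formatC(cube$band_centers, format = "fg", digits = 10, width = 1),
                  collapse = ", "))
  )
  writeLines(hdr, path)
  con <- file(bin_path, "wb")
  on.exit(close(con))
  # BSQ: full spatial plane per band, pixels (samples) fastest, then lines
  for (b in seq_len(d[3])) {
    writeBin(as.numeric(t(cube$data[, , b])), con, size = 4, endian = "little")
  }
  invisible(path)
}

parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  grab <- function(key) {
    m <- regmatches(txt, regexec(sprintf("(?mi)^%s\\s*=\\s*([^\n{]+)$", key), txt,
                                 perl = TRUE))[[1]]
    if (length(m) < 2) NULL else trimws(m[2])
  }
  braces <- function(key) {
    m <- regmatches(txt, regexec(sprintf("(?si)%s\\s*=\\s*\\{([^}]*)\\}", key), txt,
                                 perl = TRUE))[[1]]
    if (length(m) < 2) NULL else as.numeric(strsplit(m[2], ",")[[1]])
  }
  list(
    samples = as.integer(grab("samples")),
    lines = as.integer(grab("lines")),
    bands = as.integer(grab("bands")),
    data_type = as.integer(grab("data type")),
    interleave = tolower(grab("interleave") %||% "bsq"),
    byte_order = as.integer(grab("byte order") %||% "0"),
    wavelength = braces("wavelength")
  )
}

#' Read an ENVI cube written by [write_envi_cube()]
#'
#' Supports BSQ interleave, data type 4 (float32) or 5 (float64),
#' little-endian, with a `wavelength` list in the header.
#'
#' @param path path of the ENVI header file.
#' @return A [new_hypercube()] object (without truth).
#' @export
read_envi_cube <- function(path) {
  if (!file.exists(path)) {
    abort_nirfm(sprintf("header not found: %s", path), "nirfm_io_error")
  }
  h <- parse_envi_header(path)
  if (is.null(h$wavelength)) {
    abort_nirfm("ENVI header has no wavelength field", "nirfm_format_error")
  }
  if (anyNA(c(h$samples, h$lines, h$bands))) {
    abort_nirfm("ENVI header missing samples/lines/bands", "nirfm_format_error")
  }
  if (length(h$wavelength) != h$bands) {
    abort_nirfm("wavelength list length does not match band count",
                "nirfm_format_error")
  }
  if (h$interleave != "bsq") {
    abort_nirfm("only BSQ interleave is supported", "nirfm_format_error")
  }
  size <- switch(as.character(h$data_type), "4" = 4L, "5" = 8L,
                 abort_nirfm("unsupported ENVI data type", "nirfm_format_error"))
  bin_path <- sub("\\.hdr$", "", path)
  if (!file.exists(bin_path)) bin_path <- paste0(path, ".img")
  n <- h$samples * h$lines * h$bands
  vals <- readBin(bin_path, "numeric", n = n, size = size, endian = "little")
  if (length(vals) != n) {
    abort_nirfm("binary length does not match header dimensions",
                "nirfm_format_error")
  }
  data <- array(0, dim = c(h$lines, h$samples, h$bands))
  per_band <- h$samples * h$lines
  for (b in seq_len(h$bands)) {
    plane <- vals[((b - 1) * per_band + 1):(b * per_band)]
    data[, , b] <- t(matrix(plane, nrow = h$samples))
  }
  new_hypercube(data, h$wavelength)
}

#' Write ground-truth masks as a PNG label image plus a CSV class map
#'
#' The PNG is single-channel with background 0 and pixel value = object id;
#' the CSV maps object id to class.
#'
#' @param cube a hypercube with a truth table.
#' @param png_path output PNG path.
#' @param csv_path output CSV path.
#' @return Invisibly, a list of the two paths.
#' @export
write_truth_masks <- function(cube, png_path, csv_path) {
  stopifnot(inherits(cube, "hypercube"))
  if (is.null(cube$truth)) abort_nirfm("cube has no truth table", "nirfm_cube_error")
  if (max(cube$truth$object_id) > 255) {
    abort_nirfm("PNG label image supports at most 255 objects", "nirfm_cube_error")
  }
  lab <- matrix(0L, dim(cube$data)[1], dim(cube$data)[2])
  for (i in seq_len(nrow(cube$truth))) {
    px <- cube$truth$pixels[[i]]
    lab[cbind(px[, 1], px[, 2])] <- cube$truth$object_id[i]
  }
  png::writePNG(lab / 255, png_path)
  readr::write_csv(
    tibble::tibble(object_id = cube$truth$object_id, class = cube$truth$class),
    csv_path, progress = FALSE
  )
  invisible(list(png = png_path, csv = csv_path))
}

#' Read ground-truth masks written by [write_truth_masks()]
#'
#' @param png_path PNG label image path.
#' @param csv_path CSV class-map path.
#' @return A truth tibble suitable for [new_hypercube()].
#' @export
read_truth_masks <- function(png_path, csv_path) {
  lab <- round(png::readPNG(png_path) * 255)
  if (length(dim(lab)) == 3L) lab <- lab[, , 1]
  map <- readr::read_csv(csv_path, col_types = "ic", progress = FALSE)
  tibble::tibble(
    object_id = map$object_id,
    class = map$class,
    pixels = lapply(map$object_id, function(id) {
      which(lab == id, arr.ind = TRUE, useNames = FALSE)
    })
  )
}
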