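#' Extract the bands nearest to requested wavelengths
#'
#' For each requested wavelength the nearest band center is taken; the
#' output cube has exactly one band per request, in request order re-sorted
#' to increasing wavelength. Requests outside the cube's band range are
#' errors.
#'
#' @param cube a [new_hypercube()].
#' @param wavelengths requested wavelengths (nm).
#' @return A hypercube restricted to the chosen bands (truth carried over).
#' @export
extract_bands <- function(cube, wavelengths) {
  stopifnot(inherits(cube, "hypercube"))
  rng <- range(cube$band_centers)
  if (any(wavelengths < rng[1] | wavelengths > rng[2])) {
    abort_nirfm("requested wavelength outside the cube's band range",
                "nirfm_imaging_error")
  }
  idx <- nearest_index(wavelengths, cube$band_centers)
  ord <- order(cube$band_centers[idx])
  idx <- idx[ord]
  new_hypercube(cube$data[, , idx, drop = FALSE], cube$band_centers[idx],
                cube$truth)
}

#' Foreground mask by thresholding one band
#'
#' Separates objects from the conveyor background on a single band's
#' intensity image. `method = "otsu"` picks the threshold maximising
#' between-class variance ([EBImage::otsu()]); `method = "fixed"` uses
#' `level`. Foreground is the brighter (higher-absorbance) side.
#'
#' @param cube a hypercube.
#' @param band wavelength (nm) of the band to threshold (nearest taken).
#' @param method `"otsu"` or `"fixed"`.
#' @param level threshold for `method = "fixed"`.
#' @return A logical lines x pixels matrix, `TRUE` = foreground.
#' @export
remove_background <- function(cube, band, method = c("otsu", "fixed"),
                              level = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  method <- match.arg(method)
  img <- cube$data[, , nearest_index(band, cube$band_centers)]
  if (method == "otsu") {
    if (diff(range(img)) == 0) {
      abort_nirfm("constant band image: Otsu threshold undefined",
                  "nirfm_imaging_error")
    }
    level <- EBImage::otsu(img, range = range(img))
  } else if (is.null(level)) {
    abort_nirfm("fixed thresholding needs a level", "nirfm_imaging_error")
  }
  img > level
}

#' Classify foreground pixels with a band-subset PLS-DA model
#'
#' Each foreground pixel's band spectrum is scored by the model and
#' thresholded at 0.5 into vegetable (score < 0.5) or FM (score >= 0.5);
#' background pixels keep the background label. A 3x3 median filter over
#' the integer label map (background 0, vegetable 1, FM 2) suppresses
#' isolated salt-and-pepper errors; it can be switched off.
#'
#' @param cube a hypercube whose band centers match the model wavelengths.
#' @param model a [fit_plsda()] model fitted on the same band subset.
#' @param mask logical foreground mask from [remove_background()].
#' @param median_filter apply the 3x3 median smoothing (default `TRUE`).
#' @return An integer lines x pixels matrix of class `pixel_class_map`:
#'   0 background, 1 vegetable, 2 FM.
#' @export
classify_pixels <- function(cube, model, mask, median_filter = TRUE) {
  stopifnot(inherits(cube, "hypercube"), inherits(model, "plsda"))
  d <- dim(cube$data)
  if (!all(dim(mask) == d[1:2])) {
    abort_nirfm("mask dimensions do not match the cube", "nirfm_imaging_error")
  }
  if (length(model$wavelengths) != d[3] ||
      max(abs(model$wavelengths - cube$band_centers)) > 1e-6) {
    abort_nirfm("model wavelengths do not match the cube bands",
                "nirfm_imaging_error")
  }
  map <- matrix(0L, d[1], d[2])
  fg <- which(mask)
  if (length(fg) > 0) {
    X <- matrix(0, length(fg), d[3])
    for (b in seq_len(d[3])) {
      plane <- cube$data[, , b]
      X[, b] <- plane[fg]
    }
    score <- as.numeric(model$intercept + X %*% model$beta)
    map[fg] <- ifelse(score >= model$threshold, 2L, 1L)
  }
  if (median_filter) map <- median3x3(map)
  structure(map, class = c("pixel_class_map", "matrix", "array"))
}

# 3x3 running median over an integer label map; edges use the in-image
# part of the window
median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) {
    ri <- max(1, i - 1):min(nr, i + 1)
    for (j in seq_len(nc)) {
      out[i, j] <- stats::median(m[ri, max(1, j - 1):min(nc, j + 1)])
    }
  }
  storage.mode(out) <- "integer"
  out
}

# 8-connected component labeling of a logical matrix (two-pass union-find)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      neigh <- integer(0)
      if (i > 1 && mask[i - 1, j]) neigh <- c(neigh, lab[i - 1, j])
      if (j > 1) {
        if (mask[i, j - 1]) neigh <- c(neigh, lab[i, j - 1])
        if (i > 1 && mask[i - 1, j - 1]) neigh <- c(neigh, lab[i - 1, j - 1])
        if (i < nr && mask[i + 1, j - 1]) neigh <- c(neigh, lab[i + 1, j - 1])
      }
      neigh <- neigh[neigh > 0]
      if (length(neigh) == 0) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else {
        roots <- unique(vapply(neigh, find, integer(1)))
        keep <- min(roots)
        lab[i, j] <- keep
        for (r in roots) parent[r] <- keep
      }
    }
  }
  if (nxt > 0) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    ids <- match(roots, sort(unique(roots)))
    pos <- which(lab > 0)
    lab[pos] <- ids[lab[pos]]
  }
  lab
}

#' Score FM detections against ground truth
#'
#' FM-labeled pixels are grouped into 8-connected blobs; blobs smaller than
#' `min_blob` pixels are discarded as noise. A ground-truth FM object
#' counts as detected iff at least one surviving blob overlaps its mask by
#' at least one pixel; every surviving blob that overlaps no truth FM is
#' one false positive.
#'
#' @param map a [classify_pixels()] label map.
#' @param truth a hypercube truth tibble.
#' @param min_blob smallest blob size kept (pixels), default 5.
#' @param scene_id identifier copied into the report row.
#' @return A one-row tibble: `scene_id`, `total_fms`, `detected_fms`,
#'   `false_positives`.
#' @export
score_detections <- function(map, truth, min_blob = 5L, scene_id = "scene") {
  fm_truth <- truth[truth$class == "fm", , drop = FALSE]
  blobs <- label_components(map == 2L)
  sizes <- tabulate(blobs[blobs > 0])
  keep <- which(sizes >= min_blob)
  detected <- 0L
  used <- logical(length(sizes))
  for (i in seq_len(nrow(fm_truth))) {
    px <- fm_truth$pixels[[i]]
    hit <- blobs[cbind(px[, 1], px[, 2])]
    hit <- unique(hit[hit > 0])
    hit <- hit[hit %in% keep]
    if (length(hit) > 0) {
      detected <- detected + 1L
      used[hit] <- TRUE
    }
  }
  # blobs overlapping any truth FM are accounted for; the rest are FPs
  overlap_any <- logical(length(sizes))
  for (i in seq_len(nrow(fm_truth))) {
    px <- fm_truth$pixels[[i]]
    hit <- blobs[cbind(px[, 1], px[, 2])]
    overlap_any[unique(hit[hit > 0])] <- TRUE
  }
  fp <- sum(!overlap_any[keep])
  tibble::tibble(scene_id = scene_id, total_fms = nrow(fm_truth),
                 detected_fms = detected, false_positives = fp)
}

#' Aggregate per-scene detection rows into an overall report
#'
#' Overall accuracy is `100 * sum(detected) / sum(total)` across scenes —
#' the pooled object-level detection rate.
#'
#' @param rows a tibble of [score_detections()] rows.
#' @return A `detection_report`: the per-scene rows plus attributes; use
#'   [glance.detection_report()] for the pooled summary.
#' @export
aggregate_report <- function(rows) {
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) == 0) {
    abort_nirfm("no detection rows to aggregate", "nirfm_imaging_error")
  }
  total <- sum(rows$total_fms)
  if (total == 0) {
    abort_nirfm("zero total FMs: accuracy undefined", "nirfm_imaging_error")
  }
  if (any(rows$detected_fms > rows$total_fms)) {
    abort_nirfm("detected count exceeds total", "nirfm_imaging_error")
  }
  structure(rows,
            overall_accuracy = 100 * sum(rows$detected_fms) / total,
            class = c("detection_report", class(rows)))
}

#' @rdname aggregate_report
#' @param x a `detection_report`.
#' @param ... unused.
#' @return `glance()`: a one-row tibble with pooled totals and
#'   `overall_accuracy` (percent).
#' @exportS3Method generics::glance
glance.detection_report <- function(x, ...) {
  tibble::tibble(
    n_scenes = nrow(x),
    total_fms = sum(x$total_fms),
    detected_fms = sum(x$detected_fms),
    false_positives = sum(x$false_positives),
    overall_accuracy = attr(x, "overall_accuracy")
  )
}

#' Run the full per-scene detection pipeline for one band subset
#'
#' Convenience wrapper: extract the subset's bands from each cube, build
#' the foreground mask, classify pixels with a model refitted on the
#' band-restricted training spectra, and score against truth.
#'
#' @param cubes list of hypercubes with truth tables.
#' @param training labeled spectra tibble on the cubes' band-center grid.
#' @param bands wavelength subset (nm).
#' @param bg_band band used for background removal (default: the subset
#'   band nearest 1730 nm — the C-H first-overtone region where every
#'   organic material, produce and contaminant alike, absorbs well above
#'   the belt, whereas thresholding inside a water band drops dry
#'   low-absorbance FMs with the background).
#' @param min_blob,median_filter detection-scoring controls.
#' @param n_lv latent variables for the subset model.
#' @return A `detection_report` over the scenes.
#' @export
detect_fms <- function(cubes, training, bands, bg_band = NULL,
                       min_blob = 5L, median_filter = TRUE, n_lv = NULL) {
  w <- spectra_wavelengths(training)
  idx <- sort(unique(nearest_index(bands, w)))
  cols <- c("sample_id", "label", spectra_cols(training)[idx])
  n_lv <- n_lv %||% min(length(idx), 5L)
  model <- fit_plsda(training[, cols, drop = FALSE], n_lv = n_lv)
  bg_band <- bg_band %||% bands[which.min(abs(bands - 1730))]
  rows <- purrr::imap(cubes, function(cube, nm) {
    sub <- extract_bands(cube, w[idx])
    mask <- remove_background(sub, bg_band)
    map <- classify_pixels(sub, model, mask, median_filter = median_filter)
    score_detections(map, cube$truth, min_blob = min_blob,
                     scene_id = if (is.character(nm)) nm else paste0("scene", nm))
  })
  aggregate_report(dplyr::bind_rows(rows))
}

#' Compare waveband combinations on a scene suite
#'
#' Runs [detect_fms()] for each candidate band subset and ranks the
#' results by overall detection accuracy, ties going to fewer bands.
#'
#' @param cubes list of hypercubes with truth.
#' @param training labeled spectra tibble on the cubes' band grid.
#' @param combinations list of wavelength subsets (nm).
#' @param ... passed to [detect_fms()].
#' @return A tibble, one row per combination, sorted best first, with the
#'   per-combination `detection_report` in a list-column.
#' @export
evaluate_band_combinations <- function(cubes, training, combinations, ...) {
  if (length(combinations) == 0) {
    abort_nirfm("no band combinations supplied", "nirfm_imaging_error")
  }
  rows <- purrr::map(combinations, function(bands) {
    rep <- detect_fms(cubes, training, bands, ...)
    nb <- length(bands)
    tibble::tibble(
      bands = paste(round(bands, 1), collapse = ", "),
      n_bands = nb,
      overall_accuracy = attr(rep, "overall_accuracy"),
      false_positives = sum(rep$false_positives),
      report = list(rep)
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$overall_accuracy, out$n_bands), , drop = FALSE]
}

#' Plot a pixel class map
#'
#' @param object a `pixel_class_map`.
#' @param ... unused.
#' @return A ggplot raster of the background/vegetable/FM labels.
#' @exportS3Method ggplot2::autoplot
autoplot.pixel_class_map <- function(object, ...) {
  d <- tibble::tibble(
    line = rep(seq_len(nrow(object)), times = ncol(object)),
    pixel = rep(seq_len(ncol(object)), each = nrow(object)),
    class = factor(c("background", "vegetable", "fm")[as.integer(object) + 1L],
                   levels = c("background", "vegetable", "fm"))
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$pixel, .data$line, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(background = "grey90",
                                          vegetable = "#2e7d32",
                                          fm = "#c62828")) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
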