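#' Material absorbance profile
#'
#' A material is modelled as a smooth absorbance curve — a linear baseline
#' plus a sum of Gaussian absorption bands — degraded per realisation by a
#' log-normal multiplicative scatter factor and additive white noise. This
#' is the minimal model reproducing the artefacts that SNV and MSC are
#' designed to remove, which is exactly what makes preprocessing testable.
#'
#' @param name material label.
#' @param class `"vegetable"` or `"fm"`.
#' @param bands data frame with columns `center` (nm), `width` (Gaussian
#'   sigma, nm) and `amplitude` (absorbance units); may have zero rows.
#' @param baseline_offset baseline absorbance at the low end of the range.
#' @param baseline_slope absorbance change across the normalised 1000-2500 nm
#'   range.
#' @param scatter_sd sd of the log multiplicative scatter factor per spectrum.
#' @param noise_sd sd of additive white noise per wavelength (absorbance).
#' @return A `material_profile` object.
#' @export
material_profile <- function(name, class, bands,
                             baseline_offset = 0, baseline_slope = 0,
                             scatter_sd = 0, noise_sd = 0) {
  class <- match.arg(class, c("vegetable", "fm"))
  bands <- tibble::as_tibble(bands)
  if (nrow(bands) > 0) {
    stopifnot(all(c("center", "width", "amplitude") %in% names(bands)),
              all(bands$width > 0), all(bands$amplitude >= 0))
  }
  stopifnot(scatter_sd >= 0, noise_sd >= 0)
  structure(
    list(name = name, class = class, bands = bands,
         baseline_offset = baseline_offset, baseline_slope = baseline_slope,
         scatter_sd = scatter_sd, noise_sd = noise_sd),
    class = "material_profile"
  )
}

#' Noiseless closed-form absorbance of a material profile
#'
#' @param profile a [material_profile()].
#' @param wavelengths numeric wavelengths (nm).
#' @return Numeric absorbance vector: baseline plus the Gaussian band sum,
#'   with no scatter or noise applied.
#' @export
profile_absorbance <- function(profile, wavelengths) {
  x <- (wavelengths - 1000) / 1500  # normalised position in the NIR range
  a <- profile$baseline_offset + profile$baseline_slope * x
  for (i in seq_len(nrow(profile$bands))) {
    b <- profile$bands[i, ]
    a <- a + b$amplitude * exp(-0.5 * ((wavelengths - b$center) / b$width)^2)
  }
  a
}

band_tbl <- function(...) {
  v <- c(...)
  if (length(v) == 0) {
    return(tibble::tibble(center = numeric(0), width = numeric(0),
                          amplitude = numeric(0)))
  }
  m <- matrix(v, ncol = 3, byrow = TRUE)
  tibble::tibble(center = m[, 1], width = m[, 2], amplitude = m[, 3])
}

#' Built-in material presets
#'
#' Deterministic absorbance profiles for two vegetables and a range of
#' foreign materials. Band *positions* follow well-known NIR assignments:
#' vegetable water bands at 1190, 1450 and 1940 nm (O-H combination/overtone
#' bands, dominating because produce is 70-90% water), the cellulose C-H
#' first overtone near 1730 nm for wood/paper/insects, methyl-group features
#' near 1156 nm and in the 1720-1770 nm window for plastics, and a near-flat
#' reflector for metal. Amplitudes and noise levels are synthetic fixtures:
#' no public spectra exist for these samples, so the numbers encode only the
#' ordinal structure (water bands strongest for vegetables) at magnitudes
#' typical of diffuse NIR absorbance.
#'
#' The `film_mimic` preset is a deliberately adversarial *synthetic*
#' construct: a vegetable-like water profile whose 1450 nm band is replaced
#' by a narrow 1400 nm band of matched height, so it is nearly
#' indistinguishable from produce everywhere except at 1450 nm. It exists to
#' probe what a multispectral system loses by dropping that band.
#'
#' @return A named list of [material_profile()] objects.
#' @export
material_presets <- function() {
  p <- list(
    vegetable_leaf = material_profile(
      "vegetable_leaf", "vegetable",
      band_tbl(1190, 30, 0.18,
               1450, 45, 0.75,
               1730, 20, 0.06,
               1940, 55, 1.10),
      baseline_offset = 0.30, baseline_slope = 0.15,
      scatter_sd = 0.08, noise_sd = 0.010),
    vegetable_root = material_profile(
      "vegetable_root", "vegetable",
      band_tbl(1190, 30, 0.22,
               1450, 45, 0.85,
               1730, 20, 0.08,
               1940, 55, 1.20),
      baseline_offset = 0.35, baseline_slope = 0.18,
      scatter_sd = 0.08, noise_sd = 0.010),
    plastic_pe = material_profile(
      "plastic_pe", "fm",
      band_tbl(1156, 18, 0.28,
               1214, 20, 0.18,
               1740, 18, 0.45,
               2310, 30, 0.30),
      baseline_offset = 0.15, baseline_slope = 0.05,
      scatter_sd = 0.05, noise_sd = 0.008),
    plastic_pet = material_profile(
      "plastic_pet", "fm",
      band_tbl(1094, 20, 0.08,
               1156, 18, 0.22,
               1660, 25, 0.20,
               1760, 20, 0.40,
               2140, 40, 0.25),
      baseline_offset = 0.18, baseline_slope = 0.06,
      scatter_sd = 0.05, noise_sd = 0.008),
    wood = material_profile(
      "wood", "fm",
      band_tbl(1200, 40, 0.15,
               1490, 60, 0.35,
               1730, 25, 0.50,
               2100, 60, 0.35,
               2270, 40, 0.25),
      baseline_offset = 0.25, baseline_slope = 0.12,
      scatter_sd = 0.10, noise_sd = 0.010),
    paper = material_profile(
      "paper", "fm",
      band_tbl(1343, 35, 0.06,
               1490, 55, 0.30,
               1730, 25, 0.40,
               2100, 60, 0.30),
      baseline_offset = 0.20, baseline_slope = 0.08,
      scatter_sd = 0.08, noise_sd = 0.010),
    insect = material_profile(
      "insect", "fm",
      band_tbl(1300, 30, 0.06,
               1510, 40, 0.30,
               1730, 25, 0.35,
               1940, 60, 0.35,
               2050, 50, 0.20),
      baseline_offset = 0.28, baseline_slope = 0.10,
      scatter_sd = 0.08, noise_sd = 0.012),
    metal = material_profile(
      "metal", "fm",
      band_tbl(),
      baseline_offset = 0.08, baseline_slope = 0.02,
      scatter_sd = 0.03, noise_sd = 0.005),
    stone = material_profile(
      "stone", "fm",
      band_tbl(1410, 80, 0.10,
               1915, 90, 0.12),
      baseline_offset = 0.45, baseline_slope = 0.05,
      scatter_sd = 0.06, noise_sd = 0.010),
    rubber = material_profile(
      "rubber", "fm",
      band_tbl(1205, 25, 0.20,
               1730, 30, 0.35,
               2114, 50, 0.20),
      baseline_offset = 0.55, baseline_slope = 0.10,
      scatter_sd = 0.07, noise_sd = 0.010),
    film_mimic = material_profile(
      "film_mimic", "fm",
      # vegetable_leaf with the 1450/sigma-45 water band swapped for a
      # narrow 1400 nm band of equal height at 1400 nm, so only the
      # 1450 nm channel separates it from produce
      band_tbl(1190, 30, 0.18,
               1400, 16, 0.405,
               1730, 20, 0.06,
               1940, 55, 1.10),
      baseline_offset = 0.30, baseline_slope = 0.15,
      scatter_sd = 0.08, noise_sd = 0.010)
  )
  p
}

#' Default FT-NIR wavelength grid
#'
#' 1557 evenly spaced points on 1000-2500 nm, matching the variable count of
#' a benchtop FT-NIR instrument over that range.
#'
#' @param n number of points.
#' @return Numeric wavelength vector (nm).
#' @export
default_grid <- function(n = 1557) {
  seq(1000, 2500, length.out = n)
}

#' Default line-scan imaging band centers
#'
#' 900-2500 nm at the 5.876 nm sampling interval of a SWIR line-scan
#' spectrograph.
#'
#' @param from,to range limits (nm).
#' @param by band spacing (nm).
#' @return Numeric band-center vector (nm).
#' @export
default_imaging_bands <- function(from = 900, to = 2500, by = 5.876) {
  seq(from, to, by = by)
}

#' Simulate labeled FT-NIR-like spectra
#'
#' Each spectrum is `profile_absorbance()` multiplied by a per-spectrum
#' `exp(N(0, scatter_sd))` factor, plus per-wavelength `N(0, noise_sd)`
#' noise. Labels come from the profile class (0 vegetable, 1 FM). All draws
#' flow from a single seeded stream, so results are reproducible.
#'
#' @param profiles a list of entries `list(profile =, n =)` giving each
#'   material and its sample count; a bare list of profiles may be combined
#'   with `n` via [sample_plan()].
#' @param grid wavelength grid (nm); default [default_grid()].
#' @param seed integer seed.
#' @return A spectra tibble; `sample_id` is `<material>_<i>`.
#' @export
simulate_spectra <- function(profiles, grid = default_grid(), seed = 1L) {
  if (length(profiles) == 0) {
    abort_nirfm("at least one material profile is required", "nirfm_sim_error")
  }
  grid <- check_grid(grid)
  rows <- list(); labels <- integer(0); ids <- character(0)
  with_rng(seed, {
    for (entry in profiles) {
      pr <- entry$profile; n <- entry$n
      stopifnot(inherits(pr, "material_profile"), n >= 0)
      if (n == 0) next
      base <- profile_absorbance(pr, grid)
      scatter <- exp(stats::rnorm(n, 0, pr$scatter_sd))
      noise <- matrix(stats::rnorm(n * length(grid), 0, pr$noise_sd), nrow = n)
      m <- outer(scatter, base) + noise
      rows[[length(rows) + 1]] <- m
      labels <- c(labels, rep(if (pr$class == "vegetable") 0L else 1L, n))
      ids <- c(ids, paste0(pr$name, "_", seq_len(n)))
    }
  })
  if (length(rows) == 0) {
    return(new_spectra(matrix(numeric(0), 0, length(grid)), grid, integer(0)))
  }
  new_spectra(do.call(rbind, rows), grid, labels, ids)
}

#' Pair material profiles with sample counts
#'
#' @param ... named integers, e.g. `sample_plan(vegetable_leaf = 50, wood = 20)`;
#'   names must match [material_presets()] entries.
#' @param presets preset list to draw from.
#' @return A list of `list(profile =, n =)` entries for [simulate_spectra()].
#' @export
sample_plan <- function(..., presets = material_presets()) {
  counts <- c(...)
  missing <- setdiff(names(counts), names(presets))
  if (length(missing) > 0) {
    abort_nirfm(paste0("unknown preset(s): ", paste(missing, collapse = ", ")),
                "nirfm_sim_error")
  }
  purrr::map2(names(counts), counts,
              function(nm, n) list(profile = presets[[nm]], n = n))
}

#' Describe a multispectral scene
#'
#' @param lines,pixels image dimensions.
#' @param objects tibble with columns `shape` (`"ellipse"` or `"rectangle"`),
#'   `line`, `pixel` (center coordinates), `height`, `width` (extent in
#'   pixels) and `material` (a [material_profile()] in a list-column).
#' @param background_level constant background absorbance.
#' @param background_noise_sd sd of additive background noise.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(lines, pixels, objects,
                       background_level = 0.05, background_noise_sd = 0.01) {
  objects <- tibble::as_tibble(objects)
  stopifnot(all(c("shape", "line", "pixel", "height", "width", "material")
                %in% names(objects)))
  classes <- vapply(objects$material, function(m) m$class, character(1))
  if (any(classes == "fm") && !any(classes == "vegetable")) {
    abort_nirfm("a scene with FMs must also contain a vegetable object",
                "nirfm_scene_error")
  }
  structure(
    list(lines = lines, pixels = pixels, objects = objects,
         background_level = background_level,
         background_noise_sd = background_noise_sd),
    class = "scene_spec"
  )
}

object_mask_pixels <- function(shape, line, pixel, height, width, lines, pixels) {
  rr <- pmax(1L, floor(line - height / 2)):pmin(lines, ceiling(line + height / 2))
  cc <- pmax(1L, floor(pixel - width / 2)):pmin(pixels, ceiling(pixel + width / 2))
  grid <- expand.grid(line = rr, pixel = cc)
  if (shape == "ellipse") {
    keep <- ((grid$line - line) / (height / 2))^2 +
            ((grid$pixel - pixel) / (width / 2))^2 <= 1
    grid <- grid[keep, , drop = FALSE]
  }
  as.matrix(grid)
}

#' Simulate a line-scan multispectral cube with ground truth
#'
#' Every pixel of an object draws one realisation of the object's material
#' (per-pixel scatter and noise, as in [simulate_spectra()]) evaluated at
#' the band centers; background pixels are a constant level plus noise.
#' Later objects overwrite earlier ones where shapes overlap only if they
#' share a class; overlapping objects of different classes are an error.
#'
#' @param scene a [scene_spec()].
#' @param band_centers band-center wavelengths (nm);
#'   default [default_imaging_bands()].
#' @param seed integer seed.
#' @return A [new_hypercube()] with exact truth masks.
#' @export
simulate_hypercube <- function(scene, band_centers = default_imaging_bands(),
                               seed = 1L) {
  stopifnot(inherits(scene, "scene_spec"))
  band_centers <- check_grid(band_centers, "band_centers")
  nb <- length(band_centers)
  owner <- matrix(0L, scene$lines, scene$pixels)
  masks <- list(); classes <- character(0)
  for (i in seq_len(nrow(scene$objects))) {
    o <- scene$objects[i, ]
    px <- object_mask_pixels(o$shape, o$line, o$pixel, o$height, o$width,
                             scene$lines, scene$pixels)
    if (nrow(px) == 0) abort_nirfm("object lies outside the image", "nirfm_scene_error")
    prev <- owner[px]
    clash <- prev != 0 & classes[pmax(prev, 1)] != o$material[[1]]$class
    if (any(clash, na.rm = TRUE)) {
      abort_nirfm("objects of different classes overlap", "nirfm_scene_error")
    }
    # claimed pixels move to the later object (occlusion)
    owner[px] <- i
    masks[[i]] <- px
    classes[i] <- o$material[[1]]$class
  }
  # rebuild disjoint masks from the ownership map
  masks <- lapply(seq_len(nrow(scene$objects)), function(i) {
    which(owner == i, arr.ind = TRUE, useNames = FALSE)
  })
  data <- array(0, dim = c(scene$lines, scene$pixels, nb))
  with_rng(seed, {
    bg <- matrix(stats::rnorm(scene$lines * scene$pixels * nb,
                              scene$background_level,
                              scene$background_noise_sd),
                 nrow = scene$lines * scene$pixels)
    data[] <- bg
    for (i in seq_len(nrow(scene$objects))) {
      px <- masks[[i]]
      if (nrow(px) == 0) next
      pr <- scene$objects$material[[i]]
      base <- profile_absorbance(pr, band_centers)
      n <- nrow(px)
      scatter <- exp(stats::rnorm(n, 0, pr$scatter_sd))
      noise <- matrix(stats::rnorm(n * nb, 0, pr$noise_sd), nrow = n)
      vals <- outer(scatter, base) + noise
      flat <- px[, 1] + (px[, 2] - 1L) * scene$lines
      for (b in seq_len(nb)) {
        data[flat + (b - 1L) * scene$lines * scene$pixels] <- vals[, b]
      }
    }
  })
  truth <- tibble::tibble(
    object_id = seq_len(nrow(scene$objects)),
    class = classes,
    pixels = masks
  )
  truth <- truth[vapply(masks, nrow, integer(1)) > 0, ]
  new_hypercube(data, band_centers, truth)
}
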