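#' Default pipeline configuration
#'
#' A complete, validated configuration for [run_pipeline()], sized to run
#' end-to-end in well under five minutes on one CPU. Fields mirror the
#' stage functions: `simulate` (per-material sample counts, grid length),
#' `preprocess` (method + parameters), `split` (fraction), `model`
#' (max LVs, folds, autoscale), `selection` (per-method parameters),
#' `imaging` (scene count, band combinations, detection knobs) and `seed`.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(
      grid_points = 311L,
      counts = list(vegetable_leaf = 40L, vegetable_root = 40L,
                    plastic_pe = 15L, plastic_pet = 15L, wood = 15L,
                    paper = 10L, insect = 10L, metal = 10L, stone = 10L,
                    rubber = 10L)
    ),
    preprocess = list(method = "snv"),
    split = list(fraction = 0.7),
    model = list(max_lv = 8L, folds = 5L, autoscale = FALSE),
    selection = list(
      wrc = list(k = 5L, min_separation = 30),
      vip = list(n_lv = 5L, folds = 5L),
      sfs = list(max_features = 5L, folds = 5L, candidate_step = 2L),
      spa = list(min_vars = 2L, max_vars = 6L, folds = 5L, start_step = 8L),
      ipls = list(interval_width = 5L, max_intervals = 4L, folds = 5L)
    ),
    imaging = list(
      enabled = TRUE,
      n_scenes = 2L,
      lines = 48L, pixels = 48L,
      combinations = list(
        c(1150, 1400, 1731, 1880, 1920),
        c(1150, 1400, 1450, 1731, 1880, 1920)
      ),
      min_blob = 5L, median_filter = TRUE
    )
  ), class = "pipeline_config")
}

config_keys <- list(
  top = c("seed", "simulate", "preprocess", "split", "model", "selection",
          "imaging"),
  simulate = c("grid_points", "counts"),
  preprocess = c("method", "window", "polyorder", "reference"),
  split = c("fraction"),
  model = c("max_lv", "folds", "autoscale"),
  selection = c("wrc", "vip", "sfs", "spa", "ipls"),
  imaging = c("enabled", "n_scenes", "lines", "pixels", "combinations",
              "min_blob", "median_filter")
)

#' Validate a pipeline configuration
#'
#' Checks the config against the shipped schema
#' (`inst/schema/pipeline-config.json`): unknown keys anywhere are errors,
#' required sections must be present, and numeric fields must be in range.
#'
#' @param config a named list (e.g. from [jsonlite::read_json()]).
#' @return The config, invisibly, classed `pipeline_config`.
#' @export
validate_config <- function(config) {
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra) > 0) {
      abort_nirfm(sprintf("unknown config key%s in %s: %s",
                          if (length(extra) > 1) "s" else "", where,
                          paste(extra, collapse = ", ")),
                  "nirfm_config_error")
    }
  }
  check_keys(config, config_keys$top, "top level")
  need <- c("seed", "simulate", "split", "model")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) {
    abort_nirfm(paste("missing config section(s):", paste(missing, collapse = ", ")),
                "nirfm_config_error")
  }
  for (sec in intersect(names(config_keys), names(config))) {
    check_keys(config[[sec]], config_keys[[sec]], sec)
  }
  if (!is.numeric(config$seed)) {
    abort_nirfm("seed must be numeric", "nirfm_config_error")
  }
  fr <- config$split$fraction
  if (!is.numeric(fr) || fr <= 0 || fr >= 1) {
    abort_nirfm("split$fraction must lie in (0, 1)", "nirfm_config_error")
  }
  if (!is.null(config$selection)) {
    check_keys(config$selection, config_keys$selection, "selection")
  }
  invisible(structure(config, class = "pipeline_config"))
}

#' Run the full discrimination pipeline
#'
#' Simulate labeled spectra, preprocess, split, fit and evaluate a PLS-DA
#' model, run the configured waveband selectors, refit reduced models on
#' raw spectra, and (optionally) test band combinations on simulated
#' multispectral scenes. All outputs are written under `out_dir` as CSV
#' and JSON, together with a manifest recording the config, seeds and
#' package version; re-running with an identical config reproduces every
#' numeric output.
#'
#' @param config a [default_config()]-style list or a path to a JSON file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results
#'   (`model_report`, `selections`, `refit_reports`, `imaging`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("nirfm_run_")) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(config$imaging$combinations) &&
        !is.list(config$imaging$combinations)) {
      config$imaging$combinations <- list(config$imaging$combinations)
    }
  }
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
  }
  seed <- as.integer(config$seed)
  presets <- material_presets()

  spectra <- stage("simulate", {
    plan <- do.call(sample_plan, as.list(unlist(config$simulate$counts)))
    simulate_spectra(plan, default_grid(config$simulate$grid_points), seed = seed)
  })

  treated <- stage("preprocess", {
    args <- config$preprocess %||% list(method = "raw")
    do.call(preprocess, c(list(spectra), args))
  })

  parts <- stage("split", stratified_split(treated, config$split$fraction,
                                           seed = seed + 1L))
  raw_parts <- stratified_split(spectra, config$split$fraction, seed = seed + 1L)

  model <- stage("fit", {
    n_lv <- choose_n_lv(parts$calibration, max_lv = config$model$max_lv,
                        folds = config$model$folds, seed = seed + 2L,
                        autoscale = isTRUE(config$model$autoscale))
    fit_plsda(parts$calibration, n_lv = as.integer(n_lv),
              autoscale = isTRUE(config$model$autoscale))
  })
  report <- dplyr::bind_rows(
    evaluate_model(model, parts$calibration, "calibration"),
    evaluate_model(model, parts$validation, "validation")
  )
  readr::write_csv(report, file.path(out_dir, "model_report.csv"), progress = FALSE)
  write_plsda_json(model, file.path(out_dir, "model.json"))

  sel_cfg <- config$selection %||% list()
  selections <- list()
  cal_raw <- raw_parts$calibration
  if (!is.null(sel_cfg$wrc)) {
    selections$wrc <- stage("select/wrc", {
      m <- fit_plsda(cal_raw, n_lv = model$n_lv, autoscale = TRUE)
      wrc_select(m, k = sel_cfg$wrc$k %||% 5L,
                 min_separation = sel_cfg$wrc$min_separation %||% 30)
    })
  }
  if (!is.null(sel_cfg$vip)) {
    selections$vip <- stage("select/vip", {
      vip_select(cal_raw, n_lv = sel_cfg$vip$n_lv %||% 5L,
                 folds = sel_cfg$vip$folds %||% 5L, seed = seed + 3L)
    })
  }
  if (!is.null(sel_cfg$sfs)) {
    selections$sfs <- stage("select/sfs", {
      sfs_select(cal_raw, max_features = sel_cfg$sfs$max_features %||% 5L,
                 folds = sel_cfg$sfs$folds %||% 20L, seed = seed + 4L,
                 candidate_step = sel_cfg$sfs$candidate_step %||% 1L)
    })
  }
  if (!is.null(sel_cfg$spa)) {
    selections$spa <- stage("select/spa", {
      step <- sel_cfg$spa$start_step %||% 1L
      spa_select(cal_raw, min_vars = sel_cfg$spa$min_vars %||% 2L,
                 max_vars = sel_cfg$spa$max_vars %||% 10L,
                 folds = sel_cfg$spa$folds %||% 5L, seed = seed + 5L,
                 starts = seq(1L, length(spectra_wavelengths(cal_raw)), by = step))
    })
  }
  if (!is.null(sel_cfg$ipls)) {
    selections$ipls <- stage("select/ipls", {
      ipls_select(cal_raw, interval_width = sel_cfg$ipls$interval_width %||% 1L,
                  max_intervals = sel_cfg$ipls$max_intervals %||% 3L,
                  folds = sel_cfg$ipls$folds %||% 5L, seed = seed + 6L)
    })
  }
  if (length(selections) > 0) {
    summary_tbl <- dplyr::bind_rows(lapply(selections, function(s) {
      tibble::tibble(method = s$method,
                     n_selected = length(s$selected_indices),
                     wavelengths = paste(round(s$selected_wavelengths, 1),
                                         collapse = "; "))
    }))
    readr::write_csv(summary_tbl, file.path(out_dir, "selected_wavebands.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      lapply(selections, function(s) {
        list(method = s$method, parameters = s$parameters,
             selected_indices = s$selected_indices,
             selected_wavelengths = s$selected_wavelengths)
      }),
      file.path(out_dir, "selections.json"), digits = NA, auto_unbox = TRUE)
  }

  refit_reports <- stage("refit", {
    dplyr::bind_rows(lapply(selections, function(s) {
      rep <- refit_with_bands(raw_parts$calibration, s, raw_parts$validation)$report
      dplyr::bind_cols(tibble::tibble(method = s$method,
                                      n_bands = length(s$selected_indices)), rep)
    }))
  })
  if (nrow(refit_reports) > 0) {
    readr::write_csv(refit_reports, file.path(out_dir, "refit_reports.csv"),
                     progress = FALSE)
  }

  imaging <- NULL
  if (isTRUE(config$imaging$enabled)) {
    imaging <- stage("evaluate-image", {
      img <- config$imaging
      bands <- default_imaging_bands()
      cubes <- lapply(seq_len(img$n_scenes %||% 2L), function(i) {
        simulate_hypercube(demo_scene(presets, lines = img$lines %||% 48L,
                                      pixels = img$pixels %||% 48L,
                                      variant = i),
                           bands, seed = seed + 10L + i)
      })
      training <- simulate_spectra(
        sample_plan(vegetable_leaf = 40, vegetable_root = 40, plastic_pe = 20,
                    wood = 20, metal = 15, stone = 15, rubber = 15,
                    film_mimic = 20),
        bands, seed = seed + 20L)
      evaluate_band_combinations(cubes, training,
                                 lapply(img$combinations, as.numeric),
                                 min_blob = img$min_blob %||% 5L,
                                 median_filter = !isFALSE(img$median_filter))
    })
    readr::write_csv(dplyr::select(imaging, -"report"),
                     file.path(out_dir, "band_combination_report.csv"),
                     progress = FALSE)
  }

  manifest <- list(
    package = "nirfm",
    version = as.character(utils::packageVersion("nirfm")),
    seed = seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    stages = c("simulate", "preprocess", "split", "fit",
               names(selections), if (!is.null(imaging)) "evaluate-image")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(out_dir = out_dir, model = model, model_report = report,
                 selections = selections, refit_reports = refit_reports,
                 imaging = imaging))
}

#' Demonstration scene layouts
#'
#' Small mixed scenes: one or two vegetable pieces with assorted FMs on
#' top of or beside them, as on a sorting line.
#'
#' @param presets material presets list.
#' @param lines,pixels image dimensions.
#' @param variant layout variant (1 or 2).
#' @return A [scene_spec()].
#' @export
demo_scene <- function(presets = material_presets(), lines = 48L, pixels = 48L,
                       variant = 1L) {
  sc <- function(l, p) c(round(l * lines), round(p * pixels))
  obj <- function(shape, lp, h, w, material) {
    tibble::tibble(shape = shape, line = lp[1], pixel = lp[2],
                   height = h, width = w, material = list(material))
  }
  # layouts keep FMs clear of the produce pieces: object masks of different
  # classes may not overlap. Metal is deliberately absent — its intensity is
  # so close to the belt that background removal swallows it, which is a
  # documented limitation, not a useful demo.
  objects <- if (variant %% 2L == 1L) {
    dplyr::bind_rows(
      obj("ellipse", sc(0.40, 0.32), round(0.50 * lines), round(0.45 * pixels),
          presets$vegetable_leaf),
      obj("ellipse", sc(0.75, 0.75), round(0.30 * lines), round(0.30 * pixels),
          presets$vegetable_root),
      obj("rectangle", sc(0.18, 0.80), round(0.12 * lines), round(0.14 * pixels),
          presets$plastic_pe),
      obj("rectangle", sc(0.85, 0.22), round(0.10 * lines), round(0.16 * pixels),
          presets$wood),
      obj("ellipse", sc(0.12, 0.55), round(0.10 * lines), round(0.10 * pixels),
          presets$film_mimic)
    )
  } else {
    dplyr::bind_rows(
      obj("ellipse", sc(0.55, 0.42), round(0.50 * lines), round(0.42 * pixels),
          presets$vegetable_root),
      obj("rectangle", sc(0.12, 0.15), round(0.12 * lines), round(0.12 * pixels),
          presets$paper),
      obj("ellipse", sc(0.15, 0.80), round(0.12 * lines), round(0.12 * pixels),
          presets$stone),
      obj("rectangle", sc(0.90, 0.85), round(0.10 * lines), round(0.14 * pixels),
          presets$rubber),
      obj("ellipse", sc(0.45, 0.85), round(0.10 * lines), round(0.10 * pixels),
          presets$film_mimic)
    )
  }
  scene_spec(lines, pixels, objects)
}
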