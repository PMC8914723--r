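new_selection_result <- function(method, indices, wavelengths, trace, parameters,
                                 flags = character(0)) {
  indices <- sort(unique(as.integer(indices)))
  structure(
    list(method = method,
         selected_indices = indices,
         selected_wavelengths = wavelengths[indices],
         criterion_trace = trace,
         parameters = parameters,
         flags = flags),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method=%s, %d wavelengths: %s\n",
              x$method, length(x$selected_indices),
              paste(round(x$selected_wavelengths, 1), collapse = ", ")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy a band-selection result
#'
#' @param x a `selection_result`.
#' @param ... unused.
#' @return A tibble with `method`, `index`, `wavelength`.
#' @exportS3Method generics::tidy
tidy.selection_result <- function(x, ...) {
  tibble::tibble(method = x$method,
                 index = x$selected_indices,
                 wavelength = x$selected_wavelengths)
}

#' Plot a band-selection criterion trace
#'
#' @param object a `selection_result`.
#' @param ... unused.
#' @return A ggplot of the per-step criterion, with selected steps marked.
#' @exportS3Method ggplot2::autoplot
autoplot.selection_result <- function(object, ...) {
  tr <- tibble::as_tibble(object$criterion_trace)
  ggplot2::ggplot(tr, ggplot2::aes(seq_len(nrow(tr)), .data$criterion)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "step", y = "criterion",
                  title = sprintf("%s selection trace", object$method)) +
    ggplot2::theme_minimal()
}

#' Waveband selection from weighted regression coefficients (WRC)
#'
#' Ranks the local extrema of |beta| from an autoscaled PLS-DA fit (the
#' "weighted" coefficients: each variable divided by its standard deviation
#' puts coefficients on a comparable scale) and greedily accepts them in
#' descending magnitude subject to a minimum pairwise wavelength
#' separation. A point is an extremum when its |beta| exceeds both
#' neighbours; the separation constraint (default 30 nm) keeps the picks
#' from piling onto one broad peak while still allowing neighbouring water
#' features ~40 nm apart.
#'
#' @param model a [fit_plsda()] model fitted with `autoscale = TRUE`.
#' @param k number of wavebands to select.
#' @param min_separation minimum pairwise distance between selected
#'   wavelengths, nm.
#' @return A `selection_result`. If fewer than `k` admissible extrema
#'   exist, all found are returned and the result is flagged.
#' @export
wrc_select <- function(model, k = 5L, min_separation = 30) {
  stopifnot(inherits(model, "plsda"), k >= 1)
  if (!isTRUE(model$autoscale)) {
    abort_nirfm("wrc_select needs a model fitted with autoscale = TRUE",
                "nirfm_select_error")
  }
  # the weighted coefficient lives on the standardized variables:
  # beta is stored on the raw scale, so undo the 1/sd mapping
  b <- abs(model$beta * model$x_scale)
  j <- length(b)
  is_ext <- c(FALSE, b[2:(j - 1)] > b[1:(j - 2)] & b[2:(j - 1)] > b[3:j], FALSE)
  cand <- which(is_ext)
  cand <- cand[order(b[cand], decreasing = TRUE)]
  w <- model$wavelengths
  chosen <- integer(0)
  trace <- list()
  for (idx in cand) {
    ok <- all(abs(w[idx] - w[chosen]) >= min_separation)
    trace[[length(trace) + 1]] <- tibble::tibble(
      candidate = idx, wavelength = w[idx], criterion = b[idx], accepted = ok)
    if (ok) chosen <- c(chosen, idx)
    if (length(chosen) == k) break
  }
  flags <- if (length(chosen) < k) {
    sprintf("only %d admissible extrema found (requested %d)", length(chosen), k)
  } else character(0)
  new_selection_result("wrc", chosen, w, dplyr::bind_rows(trace),
                       list(k = k, min_separation = min_separation), flags)
}

#' Variable importance in projection (VIP) scores
#'
#' The Wold VIP of variable `j` over the `I` fitted latent variables:
#' \deqn{VIP_j = \sqrt{J \sum_i (w_{ji}/\|w_i\|)^2 SSY_i / \sum_i SSY_i}}
#' with `SSY_i = q_i^2 t_i^T t_i`, the response sum of squares explained by
#' component `i`. The squared scores average to 1 by construction, which is
#' what makes the conventional "VIP > 1" reading meaningful.
#'
#' @param model a [fit_plsda()] model.
#' @return An object of class `vip_scores`: `scores` (per variable),
#'   `ssy` (per component), `ssy_total`, `wavelengths`.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda"))
  ssy <- model$q^2 * colSums(model$T^2)
  total <- sum(ssy)
  if (total <= 0) {
    abort_nirfm("response unexplained: total SSY is zero", "nirfm_select_error")
  }
  w2 <- sweep(model$W, 2, sqrt(colSums(model$W^2)), "/")^2
  scores <- sqrt(length(model$beta) * as.numeric(w2 %*% ssy) / total)
  structure(
    list(scores = scores, ssy = ssy, ssy_total = total,
         n_lv = model$n_lv, wavelengths = model$wavelengths),
    class = "vip_scores"
  )
}

#' @export
print.vip_scores <- function(x, ...) {
  cat(sprintf("<vip_scores> %d variables over %d components; %d with VIP >= 1\n",
              length(x$scores), x$n_lv, sum(x$scores >= 1)))
  invisible(x)
}

#' @rdname vip_scores
#' @param x a `vip_scores` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.vip_scores <- function(x, ...) {
  tibble::tibble(wavelength = x$wavelengths, vip = x$scores)
}

#' Waveband selection by a VIP cut-off scan
#'
#' Fits a PLS-DA model, computes VIP scores, and scans a grid of cut-offs
#' (default 0.8 to 1.5 in steps of 0.1): for each cut-off the variables
#' with `VIP >= cutoff` are kept, a model is refitted on them and scored by
#' stratified cross-validated accuracy. The winning cut-off maximises CV
#' accuracy, with ties going to the fewest variables. Cut-offs leaving no
#' variables are skipped but recorded in the trace.
#'
#' @inheritParams spectra_wavelengths
#' @param cutoffs numeric cut-off grid.
#' @param n_lv latent variables for the full fit and refits.
#' @param folds,seed cross-validation controls.
#' @return A `selection_result`; the trace has one row per cut-off with
#'   `n_vars` and CV `accuracy`.
#' @export
vip_select <- function(spectra, cutoffs = seq(0.8, 1.5, by = 0.1),
                       n_lv = 5L, folds = 5L, seed = 1L) {
  validate_spectra(spectra)
  model <- fit_plsda(spectra, n_lv = n_lv)
  vip <- vip_scores(model)$scores
  w <- spectra_wavelengths(spectra)
  trace <- list(); best <- NULL
  for (ct in cutoffs) {
    keep <- which(vip >= ct)
    if (length(keep) == 0) {
      trace[[length(trace) + 1]] <- tibble::tibble(
        cutoff = ct, n_vars = 0L, criterion = NA_real_, note = "no variables")
      next
    }
    acc <- 100 * (1 - cv_subset_error(spectra, keep, folds = folds, seed = seed))
    trace[[length(trace) + 1]] <- tibble::tibble(
      cutoff = ct, n_vars = length(keep), criterion = acc, note = "")
    if (is.null(best) || acc > best$acc + 1e-12 ||
        (abs(acc - best$acc) <= 1e-12 && length(keep) < length(best$keep))) {
      best <- list(acc = acc, keep = keep, cutoff = ct)
    }
  }
  if (is.null(best)) {
    abort_nirfm("every cut-off left zero variables", "nirfm_select_error")
  }
  new_selection_result("vip", best$keep, w, dplyr::bind_rows(trace),
                       list(cutoffs = cutoffs, chosen_cutoff = best$cutoff,
                            n_lv = n_lv, folds = folds, seed = seed))
}

# CV performance of a PLS-DA restricted to a variable subset;
# LV count = min(|subset|, 5) for comparability across search methods.
# Returns c(error, mse): misclassification is the criterion, score MSE the
# tie-break — on cleanly separable data many subsets reach error 0 and the
# continuous MSE still ranks them by separation margin.
cv_subset_score <- function(spectra, subset, folds, seed, max_lv = 5L) {
  subset <- sort(unique(as.integer(subset)))
  sub <- spectra[, c("sample_id", "label",
                     spectra_cols(spectra)[subset]), drop = FALSE]
  n_lv <- min(length(subset), max_lv)
  cv <- cv_plsda(sub, n_lv = n_lv, folds = folds, seed = seed)
  c(unname(cv$error), unname(cv$mse))
}

cv_subset_error <- function(spectra, subset, folds, seed, max_lv = 5L) {
  unname(cv_subset_score(spectra, subset, folds, seed, max_lv)[1])
}

# index of the lexicographic minimum over (error, mse) column pairs
best_by_score <- function(scores) {
  ord <- order(scores[1, ], scores[2, ])
  ord[1]
}

#' Sequential forward selection (SFS) of wavebands
#'
#' Greedy wrapper selection: starting from the empty set, at each step the
#' single wavelength whose addition minimises the stratified k-fold
#' cross-validated misclassification rate of a PLS-DA fit (LVs =
#' min(set size, 5)) is added; ties in the error rate are broken by the
#' cross-validated mean squared error of the predicted score, so the most
#' strongly separating wavelength wins even when several reach error 0.
#' Stops when the CV error reaches 0 or `max_features` is hit.
#'
#' @inheritParams spectra_wavelengths
#' @param max_features largest subset size.
#' @param folds number of CV folds (default 20).
#' @param seed integer seed.
#' @param candidate_step evaluate every `candidate_step`-th wavelength as a
#'   candidate (1 = all); a coarse screen for very fine grids.
#' @return A `selection_result`; the trace records the best candidate and
#'   CV error after each addition.
#' @export
sfs_select <- function(spectra, max_features = 10L, folds = 20L, seed = 1L,
                       candidate_step = 1L) {
  validate_spectra(spectra)
  w <- spectra_wavelengths(spectra)
  candidates <- seq(1L, length(w), by = as.integer(candidate_step))
  chosen <- integer(0)
  trace <- list()
  repeat {
    remaining <- setdiff(candidates, chosen)
    scores <- vapply(remaining, function(jx) {
      cv_subset_score(spectra, c(chosen, jx), folds = folds, seed = seed)
    }, numeric(2))
    best <- best_by_score(scores)
    chosen <- c(chosen, remaining[best])
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(chosen), added = remaining[best],
      wavelength = w[remaining[best]], criterion = scores[1, best],
      score_mse = scores[2, best])
    if (scores[1, best] <= 0 || length(chosen) >= max_features) break
  }
  new_selection_result("sfs", chosen, w, dplyr::bind_rows(trace),
                       list(max_features = max_features, folds = folds,
                            seed = seed, candidate_step = candidate_step))
}

# SPA chain from one start column: repeatedly project remaining columns on
# the orthogonal complement of the chosen span and take the max-norm column
spa_chain <- function(Xc, start, max_vars) {
  j <- ncol(Xc)
  chain <- start
  R <- Xc
  # orthogonalise against the chosen column at each step
  for (step in seq_len(max_vars - 1L)) {
    v <- R[, chain[length(chain)]]
    nv2 <- sum(v^2)
    if (nv2 < 1e-12) break
    R <- R - v %*% (crossprod(v, R) / nv2)
    norms <- sqrt(colSums(R^2))
    norms[chain] <- -Inf
    if (max(norms) < 1e-10) break
    chain <- c(chain, which.max(norms))
  }
  chain
}

#' Successive projections algorithm (SPA) waveband selection
#'
#' Builds minimally collinear variable chains on the column-centered
#' calibration matrix: from every start column, variables are added one at
#' a time by maximal residual norm after projection onto the orthogonal
#' complement of the span of the chosen set. Every chain prefix of length
#' `min_vars..max_vars` is then scored by cross-validated misclassification
#' of a PLS-DA on those variables; the winner has minimum error, ties going
#' first to fewer variables, then to the smaller cross-validated score MSE
#' (the margin-sensitive tie-break used by all the search selectors here),
#' then to the lexicographically smallest index set (for determinism).
#'
#' @inheritParams spectra_wavelengths
#' @param min_vars,max_vars subset size bounds (defaults 2 and 10).
#' @param folds,seed cross-validation controls.
#' @param starts optional subset of start columns (default: all).
#' @return A `selection_result`; the trace has one row per scored subset.
#' @export
spa_select <- function(spectra, min_vars = 2L, max_vars = 10L,
                       folds = 5L, seed = 1L, starts = NULL) {
  validate_spectra(spectra)
  w <- spectra_wavelengths(spectra)
  if (min_vars < 2L || max_vars < min_vars || max_vars > length(w)) {
    abort_nirfm("need 2 <= min_vars <= max_vars <= number of wavelengths",
                "nirfm_select_error")
  }
  Xc <- scale(spectra_matrix(spectra), center = TRUE, scale = FALSE)
  starts <- starts %||% seq_len(ncol(Xc))
  subsets <- list()
  for (k0 in starts) {
    chain <- spa_chain(Xc, k0, max_vars)
    if (length(chain) < min_vars) next
    for (m in seq(min_vars, length(chain))) {
      subsets[[length(subsets) + 1]] <- chain[seq_len(m)]
    }
  }
  if (length(subsets) == 0) {
    abort_nirfm("rank deficiency: no chain reached min_vars", "nirfm_select_error")
  }
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = ","), character(1))
  subsets <- subsets[!duplicated(keys)]
  trace <- list(); best <- NULL
  lex_key <- function(s) paste(formatC(sort(s), width = 6, flag = "0"),
                               collapse = ",")
  for (s in subsets) {
    sc <- cv_subset_score(spectra, s, folds = folds, seed = seed)
    trace[[length(trace) + 1]] <- tibble::tibble(
      subset = paste(sort(s), collapse = ","), n_vars = length(s),
      criterion = sc[1], score_mse = sc[2])
    better <- is.null(best) || sc[1] < best$err - 1e-12 ||
      (abs(sc[1] - best$err) <= 1e-12 &&
       (length(s) < length(best$set) ||
        (length(s) == length(best$set) &&
         (sc[2] < best$mse - 1e-12 ||
          (abs(sc[2] - best$mse) <= 1e-12 && lex_key(s) < lex_key(best$set))))))
    if (better) best <- list(err = sc[1], mse = sc[2], set = s)
  }
  new_selection_result("spa", best$set, w, dplyr::bind_rows(trace),
                       list(min_vars = min_vars, max_vars = max_vars,
                            folds = folds, seed = seed))
}

#' Forward interval PLS (iPLS) waveband selection
#'
#' Tiles the wavelength axis into contiguous intervals of
#' `interval_width` variables (the last interval may be short) and runs
#' forward selection over intervals: at each step the interval whose
#' addition minimises the cross-validated misclassification of a PLS-DA
#' (at most `max_lv` latent variables) on the union is added, error ties
#' broken by the cross-validated score MSE. Stops when the error no longer
#' strictly decreases or `max_intervals` are chosen.
#' With `interval_width = 1` the intervals are single wavelengths.
#'
#' @inheritParams spectra_wavelengths
#' @param interval_width variables per interval (>= 1).
#' @param max_intervals maximum intervals to select.
#' @param max_lv LV cap for the interval models (default 5).
#' @param folds,seed cross-validation controls.
#' @return A `selection_result`; selected variables are the union of the
#'   chosen intervals.
#' @export
ipls_select <- function(spectra, interval_width = 1L, max_intervals = 3L,
                        max_lv = 5L, folds = 5L, seed = 1L) {
  validate_spectra(spectra)
  if (interval_width < 1L) {
    abort_nirfm("interval_width must be at least 1", "nirfm_select_error")
  }
  w <- spectra_wavelengths(spectra)
  j <- length(w)
  starts <- seq(1L, j, by = as.integer(interval_width))
  intervals <- lapply(starts, function(s) s:min(s + interval_width - 1L, j))
  chosen <- integer(0); chosen_vars <- integer(0)
  trace <- list(); last_err <- Inf
  repeat {
    remaining <- setdiff(seq_along(intervals), chosen)
    if (length(remaining) == 0 || length(chosen) >= max_intervals) break
    scores <- vapply(remaining, function(ix) {
      cv_subset_score(spectra, c(chosen_vars, intervals[[ix]]),
                      folds = folds, seed = seed, max_lv = max_lv)
    }, numeric(2))
    best <- best_by_score(scores)
    if (scores[1, best] >= last_err) break  # no strict improvement
    chosen <- c(chosen, remaining[best])
    chosen_vars <- c(chosen_vars, intervals[[remaining[best]]])
    last_err <- scores[1, best]
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(chosen), interval = remaining[best],
      first_wavelength = w[intervals[[remaining[best]]][1]],
      criterion = scores[1, best], score_mse = scores[2, best])
    if (last_err <= 0) break
  }
  if (length(chosen_vars) == 0) {
    abort_nirfm("forward iPLS selected no interval", "nirfm_select_error")
  }
  new_selection_result("ipls", chosen_vars, w, dplyr::bind_rows(trace),
                       list(interval_width = interval_width,
                            max_intervals = max_intervals, max_lv = max_lv,
                            folds = folds, seed = seed))
}

#' Refit a PLS-DA model on selected wavebands and evaluate it
#'
#' Restricts the calibration spectra to the selected variables, fits a
#' PLS-DA on the raw (unpreprocessed) values, and evaluates it on a
#' held-out test set, mirroring how reduced multispectral models are
#' validated before committing to an imaging filter set.
#'
#' @param calibration labeled spectra tibble used for fitting.
#' @param selection a `selection_result` (or integer indices).
#' @param test labeled spectra tibble for evaluation.
#' @param n_lv latent variables; default `min(n selected, 5)`.
#' @return A list with the fitted `model` and a one-row `report`
#'   (see [evaluate_model()]).
#' @export
refit_with_bands <- function(calibration, selection, test, n_lv = NULL) {
  idx <- if (inherits(selection, "selection_result")) {
    selection$selected_indices
  } else {
    as.integer(selection)
  }
  if (length(idx) == 0) {
    abort_nirfm("empty waveband selection", "nirfm_select_error")
  }
  cols <- c("sample_id", "label", spectra_cols(calibration)[idx])
  n_lv <- n_lv %||% min(length(idx), 5L)
  n_lv <- min(n_lv, length(idx), nrow(calibration) - 1L)
  model <- fit_plsda(calibration[, cols, drop = FALSE], n_lv = n_lv)
  report <- evaluate_model(model, test[, cols, drop = FALSE], partition = "test")
  list(model = model, report = report)
}
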