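test_that("VIP scores satisfy the Wold normalization identities", {
  s <- recovery_spectra()
  for (a in c(1L, 3L, 5L)) {
    v <- vip_scores(fit_plsda(s, n_lv = a))
    expect_lt(abs(mean(v$scores^2) - 1), 1e-8)
    expect_true(all(v$scores >= 0))
  }
  # one LV with equal |weights| forces every VIP to 1: two variables with
  # identical class contrast and symmetric noise
  withr::with_seed(25, {
    y <- rep(c(0L, 1L), 30)
    base <- y + rnorm(60, sd = 0.1)
  })
  X <- cbind(base, -base)
  s2 <- new_spectra(X, c(1100, 1200), y)
  v2 <- vip_scores(fit_plsda(s2, n_lv = 1L))
  expect_equal(v2$scores, c(1, 1), tolerance = 1e-10)
})

test_that("informative variables earn VIP above the noise median", {
  withr::with_seed(26, {
    y <- rep(c(0L, 1L), 40)
    X <- matrix(rnorm(80 * 20, sd = 0.5), 80, 20)
    X[, 7] <- X[, 7] + 2 * y
    X[, 13] <- X[, 13] - 1.5 * y
  })
  s <- new_spectra(X, seq(1100, by = 50, length.out = 20), y)
  v <- vip_scores(fit_plsda(s, n_lv = 2L))
  expect_gt(min(v$scores[c(7, 13)]), 1)
  expect_gt(min(v$scores[c(7, 13)]), median(v$scores[-c(7, 13)]))
})

test_that("WRC picks the spike and honours the separation constraint", {
  withr::with_seed(27, {
    y <- rep(c(0L, 1L), 30)
    X <- matrix(rnorm(60 * 60, sd = 0.3), 60, 60)
    X[, 42] <- X[, 42] + 3 * y
  })
  s <- new_spectra(X, seq(1000, by = 10, length.out = 60), y)
  m <- fit_plsda(s, n_lv = 2L, autoscale = TRUE)
  sel <- wrc_select(m, k = 1L)
  expect_equal(sel$selected_indices, 42L)

  full <- wrc_select(m, k = 5L, min_separation = 50)
  w <- full$selected_wavelengths
  if (length(w) > 1) {
    expect_gte(min(dist(w)), 50)
  }
  expect_error(wrc_select(fit_plsda(s, n_lv = 2L), k = 1L),
               class = "nirfm_select_error")
})

test_that("WRC recovers two planted bands from an autoscaled fit", {
  # additive noise only: multiplicative scatter interacts with autoscaling
  # and legitimately shifts extrema onto band shoulders (see vignette)
  # one latent variable: the planted contrast is rank one, and CV-based LV
  # choice lands there by parsimony on this data
  s <- planted_two_band_spectra(n = 60, scatter_sd = 0)
  m <- fit_plsda(s, n_lv = 1L, autoscale = TRUE)
  sel <- wrc_select(m, k = 2L, min_separation = 100)
  grid <- spectra_wavelengths(s)
  spacing <- mean(diff(grid))
  for (center in c(1450, 1940)) {
    expect_true(any(abs(sel$selected_wavelengths - center) <= 3 * spacing))
  }
})

test_that("VIP cut-off scan records every cutoff and prefers accuracy then size", {
  s <- recovery_spectra()
  sel <- recovery_selections()$vip
  expect_equal(nrow(sel$criterion_trace), 8L)
  expect_equal(sel$criterion_trace$cutoff, seq(0.8, 1.5, by = 0.1))
  evaluable <- sel$criterion_trace[sel$criterion_trace$n_vars > 0, ]
  best_acc <- max(evaluable$criterion)
  chosen_row <- evaluable[evaluable$cutoff == sel$parameters$chosen_cutoff, ]
  expect_equal(chosen_row$criterion, best_acc)
  expect_equal(chosen_row$n_vars,
               min(evaluable$n_vars[abs(evaluable$criterion - best_acc) <= 1e-12]))
  # cutoff below the minimum VIP keeps everything (degenerate but recorded)
  v <- vip_scores(fit_plsda(s, n_lv = 5L))
  low <- vip_select(s, cutoffs = min(v$scores) * 0.5, folds = 5L, seed = 2L)
  expect_length(low$selected_indices, length(v$scores))
})

test_that("SFS stops immediately on a perfectly separating variable", {
  withr::with_seed(28, {
    y <- rep(c(0L, 1L), 20)
    X <- matrix(rnorm(40 * 6, sd = 0.5), 40, 6)
    X[, 4] <- y * 5 + rnorm(40, sd = 0.05)
  })
  s <- new_spectra(X, seq(1100, by = 50, length.out = 6), y)
  sel <- sfs_select(s, max_features = 3L, folds = 5L, seed = 7L)
  expect_equal(sel$selected_indices, 4L)
  expect_equal(sel$criterion_trace$criterion[1], 0)
})

test_that("SFS greedy steps equal an exhaustive candidate scan", {
  s <- recovery_spectra()[, c("sample_id", "label",
                              nirfm:::spectra_cols(recovery_spectra())[seq(1, 157, by = 16)])]
  sel <- sfs_select(s, max_features = 2L, folds = 5L, seed = 9L)
  # oracle: score every single-variable candidate independently
  scores <- vapply(seq_along(spectra_wavelengths(s)), function(j) {
    oracle_subset_score(s, j, folds = 5, seed = 9)
  }, numeric(2))
  ord <- order(scores[1, ], scores[2, ])
  expect_equal(sel$criterion_trace$added[1], ord[1])
  expect_equal(sel$criterion_trace$criterion[1], min(scores[1, ]))
  # determinism
  again <- sfs_select(s, max_features = 2L, folds = 5L, seed = 9L)
  expect_identical(sel$selected_indices, again$selected_indices)
  expect_identical(sel$criterion_trace, again$criterion_trace)
})

test_that("SPA avoids duplicated columns in favour of orthogonal ones", {
  withr::with_seed(29, {
    u <- rnorm(30)
    v <- rnorm(30)
    u <- u - mean(u); v <- v - mean(v)
    v <- v - u * sum(u * v) / sum(u^2)  # exactly orthogonal
    y <- as.integer(u + v > 0)
  })
  X <- cbind(u, v, u * 1.000001)
  s <- new_spectra(X + 2, c(1100, 1200, 1300), y)
  sel <- spa_select(s, min_vars = 2L, max_vars = 2L, folds = 5L, seed = 3L)
  expect_false(all(c(1L, 3L) %in% sel$selected_indices))
  expect_error(spa_select(s, min_vars = 1L, max_vars = 1L),
               class = "nirfm_select_error")
})

test_that("SPA chains maximise the orthogonal residual norm step by step", {
  s <- recovery_spectra()[, c("sample_id", "label",
                              nirfm:::spectra_cols(recovery_spectra())[seq(1, 157, by = 13)])]
  Xc <- scale(spectra_matrix(s), center = TRUE, scale = FALSE)
  for (start in c(1L, 5L, 9L)) {
    chain <- nirfm:::spa_chain(Xc, start, 4L)
    for (step in 2:length(chain)) {
      sofar <- chain[seq_len(step - 1)]
      Q <- qr.Q(qr(Xc[, sofar, drop = FALSE]))
      R <- Xc - Q %*% crossprod(Q, Xc)
      norms <- sqrt(colSums(R^2))
      norms[sofar] <- -Inf
      expect_equal(chain[step], which.max(norms))
    }
  }
})

test_that("forward iPLS selects single-wavelength intervals greedily", {
  withr::with_seed(30, {
    y <- rep(c(0L, 1L), 25)
    X <- matrix(rnorm(50 * 9, sd = 0.4), 50, 9)
    X[, 6] <- X[, 6] + 3 * y
  })
  s <- new_spectra(X, seq(1100, by = 50, length.out = 9), y)
  sel <- ipls_select(s, interval_width = 1L, max_intervals = 3L,
                     folds = 5L, seed = 8L)
  # the informative interval is chosen first; oracle = exhaustive first step
  scores <- vapply(1:9, function(j) {
    oracle_subset_score(s, j, folds = 5, seed = 8)
  }, numeric(2))
  expect_equal(sel$criterion_trace$interval[1], order(scores[1, ], scores[2, ])[1])
  expect_equal(sel$criterion_trace$interval[1], 6L)
  # trace errors never increase
  expect_true(all(diff(sel$criterion_trace$criterion) <= 0))
  expect_error(ipls_select(s, interval_width = 0L), class = "nirfm_select_error")
})

test_that("iPLS width-1 intervals yield as many variables as intervals", {
  sel <- recovery_selections()$ipls
  expect_equal(length(sel$selected_indices), nrow(sel$criterion_trace))
  expect_lte(length(sel$selected_indices), 3L)
})

test_that("each selection method finds a planted water band", {
  sels <- recovery_selections()
  expect_named(sels, c("wrc", "vip", "sfs", "spa", "ipls"))
  for (nm in names(sels)) {
    hits <- outer(sels[[nm]]$selected_wavelengths, c(1450, 1940), "-")
    expect_true(any(abs(hits) <= 25),
                label = sprintf("%s selects within 25 nm of a water band", nm))
  }
})

test_that("refitting on selected bands matches the full model when trivial", {
  s <- planted_two_band_spectra(n = 40)
  parts <- stratified_split(s, 0.7, seed = 6)
  all_vars <- seq_along(spectra_wavelengths(s))
  full <- fit_plsda(parts$calibration, n_lv = 5L)
  ref <- refit_with_bands(parts$calibration, all_vars, parts$validation)
  direct <- evaluate_model(full, parts$validation, partition = "test")
  expect_equal(ref$report$accuracy, direct$accuracy)
  expect_equal(ref$report$tp, direct$tp)
  # report internally consistent with the metric equations
  r <- ref$report
  expect_equal(r$accuracy, 100 * (r$tp + r$tn) / (r$tp + r$tn + r$fp + r$fn))
  expect_error(refit_with_bands(parts$calibration, integer(0), parts$validation),
               class = "nirfm_select_error")
})

test_that("refits on planted selections separate the classes completely", {
  s <- recovery_spectra()
  parts <- stratified_split(s, 0.7, seed = 12)
  for (sel in recovery_selections()[c("wrc", "sfs", "spa")]) {
    rep <- refit_with_bands(parts$calibration, sel, parts$validation)$report
    expect_equal(rep$accuracy, 100)
  }
})
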