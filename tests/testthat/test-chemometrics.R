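test_that("PCA matches the covariance eigendecomposition", {
  withr::with_seed(14, {
    X <- matrix(rnorm(160), 20, 8)
  })
  s <- new_spectra(X, seq(1100, by = 100, length.out = 8),
                   rep(c(0L, 1L), 10))
  pc <- fit_pca(s, n_components = 7L)
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(pc$explained_variance_ratio, (ev / sum(ev))[1:7], tolerance = 1e-10)
  # loadings orthonormal, ratios non-increasing
  expect_lt(max(abs(crossprod(pc$loadings) - diag(7))), 1e-8)
  expect_true(all(diff(pc$explained_variance_ratio) <= 1e-12))
  # scores are the centered data projected on the loadings, so the rank-7
  # reconstruction leaves a residual orthogonal to every kept direction
  centered <- sweep(X, 2, pc$mean_spectrum)
  expect_equal(unname(pc$scores), unname(centered %*% pc$loadings),
               tolerance = 1e-10)
  resid <- centered - pc$scores %*% t(pc$loadings)
  expect_lt(max(abs(resid %*% pc$loadings)), 1e-8)
})

test_that("collinear data put all variance on the first component", {
  t <- seq(-1, 1, length.out = 12)
  X <- cbind(2 * t, -t, 0.5 * t) + 5
  s <- new_spectra(X, c(1100, 1200, 1300), rep(c(0L, 1L), 6))
  pc <- fit_pca(s, n_components = 2L)
  expect_equal(pc$explained_variance_ratio[1], 1, tolerance = 1e-10)
  expect_error(fit_pca(s, n_components = 5L), class = "nirfm_pca_error")
})

test_that("full-rank PLS-DA reproduces the least-squares solution", {
  withr::with_seed(3, {
    X <- matrix(rnorm(150), 30, 5)
    y <- rep(c(0L, 1L), 15)
  })
  s <- new_spectra(X, seq(1100, by = 100, length.out = 5), y)
  m <- fit_plsda(s, n_lv = 5L)
  ols <- unname(coef(lm(y ~ X)))
  expect_lt(max(abs(m$beta - ols[-1])), 1e-6)
  expect_lt(abs(m$intercept - ols[1]), 1e-6)
})

test_that("NIPALS factorisation satisfies its structural identities", {
  s <- planted_two_band_spectra()
  m <- fit_plsda(s, n_lv = 4L)
  # scores mutually orthogonal
  g <- crossprod(m$T)
  off <- g - diag(diag(g))
  expect_lt(max(abs(off)) / max(diag(g)), 1e-8)
  # X_centered = T P' + Ex reconstruction
  Xc <- sweep(spectra_matrix(s), 2, m$x_mean)
  expect_lt(max(abs(Xc - (m$T %*% t(m$P) + m$Ex))), 1e-8)
  # beta route equals score-chain route on the calibration data
  chain <- as.numeric(m$T %*% m$q) + m$y_mean
  via_beta <- predict(m, s)$score
  expect_lt(max(abs(chain - via_beta)), 1e-8)
  # adding an LV never increases the calibration residual sum of squares
  rss <- vapply(1:4, function(a) {
    fit <- fit_plsda(s, n_lv = a)
    sum((predict(fit, s)$score - s$label)^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("a column carrying y exactly takes all the beta weight", {
  withr::with_seed(8, {
    noise <- matrix(rnorm(40 * 4, sd = 1), 40, 4)
    y <- rep(c(0L, 1L), 20)
  })
  # make the noise columns exactly orthogonal to y in-sample, so the
  # single-predictor limit holds to numerical precision
  noise <- apply(noise, 2, function(col) residuals(lm(col ~ y)))
  X <- cbind(noise[, 1:2], y * 2 - 0.5, noise[, 3:4])
  s <- new_spectra(X, seq(1100, by = 100, length.out = 5), y)
  m <- fit_plsda(s, n_lv = 1L)
  expect_lt(max(abs(m$beta[-3])), 1e-8)
  expect_gt(abs(m$beta[3]), 0.1)
  pred <- predict(m, s)
  expect_equal(pred$predicted, y)
})

test_that("degenerate fits are rejected", {
  one_class <- new_spectra(matrix(rnorm(20), 5, 4),
                           c(1100, 1200, 1300, 1400), rep(0L, 5))
  expect_error(fit_plsda(one_class, 1L), class = "nirfm_plsda_error")
  s <- tiny_spectra()
  expect_error(fit_plsda(s, n_lv = 100L), class = "nirfm_plsda_error")
})

test_that("prediction applies the >= 0.5 FM rule and ignores sample order", {
  s <- planted_two_band_spectra()
  m <- fit_plsda(s, n_lv = 2L)
  # tie at exactly 0.5 goes to the FM side: build a sample scoring 0.5
  x0 <- m$beta / sum(m$beta^2) * (0.5 - m$intercept)
  probe <- new_spectra(matrix(x0, 1), spectra_wavelengths(s), 1L)
  p <- predict(m, probe)
  expect_equal(p$score, 0.5, tolerance = 1e-9)
  expect_equal(p$predicted, 1L)

  # refitting on a permuted calibration set reproduces the scores
  withr::with_seed(6, perm <- sample.int(nrow(s)))
  m2 <- fit_plsda(s[perm, ], n_lv = 2L)
  expect_lt(max(abs(predict(m2, s)$score - predict(m, s)$score)), 1e-10)

  wrong_grid <- new_spectra(matrix(rnorm(10), 1), seq(2, 20, by = 2), 0L)
  expect_error(predict(m, wrong_grid), class = "nirfm_plsda_error")
})

test_that("separable simulations reach full calibration accuracy within 5 LVs", {
  s <- simulate_spectra(sample_plan(vegetable_leaf = 100, plastic_pe = 100),
                        default_grid(157), seed = 19)
  m <- fit_plsda(s, n_lv = 5L)
  rep <- evaluate_model(m, s, partition = "calibration")
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$fn + rep$fp, 0L)
})

test_that("LV choice scans CV error with a parsimony tie-break", {
  s <- planted_two_band_spectra(n = 30)
  chosen <- choose_n_lv(s, max_lv = 4L, folds = 5L, seed = 2L)
  errs <- attr(chosen, "cv_error")
  expect_length(errs, 4L)
  expect_lte(as.integer(chosen), 4L)
  expect_equal(errs[as.integer(chosen)], min(errs))
  expect_false(any(errs[seq_len(as.integer(chosen) - 1)] <= min(errs)))

  # independent oracle: recompute the per-LV CV error by explicit loops
  fold_id <- nirfm:::stratified_folds(s$label, 5L, 2L)
  oracle <- vapply(1:4, function(a) {
    mean(vapply(1:5, function(f) {
      train <- s[fold_id != f, ]
      test <- s[fold_id == f, ]
      pred <- predict(fit_plsda(train, n_lv = a), test)
      mean(pred$predicted != pred$label)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(unname(errs), unname(oracle))
  # a 1-LV-separable problem yields 1 by parsimony
  expect_equal(as.integer(choose_n_lv(planted_two_band_spectra(n = 40),
                                      max_lv = 3L, folds = 5L, seed = 3L)), 1L)
})

test_that("model reports agree with independent metric recomputation", {
  s <- planted_two_band_spectra(n = 40)
  parts <- stratified_split(s, 0.7, seed = 4)
  m <- fit_plsda(parts$calibration, n_lv = 2L)
  rep <- evaluate_model(m, parts$validation, partition = "validation")
  pred <- predict(m, parts$validation)
  counts <- confusion_counts(pred$label, pred$predicted)
  expect_equal(rep$tp, counts$tp)
  expect_equal(rep$accuracy, metrics(counts)$accuracy)
  expect_equal(rep$n, nrow(parts$validation))
  expect_error(evaluate_model(m, parts$validation[0, ]),
               class = "nirfm_plsda_error")
})

test_that("planted discriminative bands surface as the largest beta maxima", {
  s <- planted_two_band_spectra(n = 60)
  grid <- spectra_wavelengths(s)
  m <- fit_plsda(s, n_lv = 2L)
  b <- abs(m$beta)
  j <- length(b)
  ext <- which(c(FALSE, b[2:(j - 1)] > b[1:(j - 2)] & b[2:(j - 1)] > b[3:j], FALSE))
  top2 <- ext[order(b[ext], decreasing = TRUE)][1:2]
  spacing <- mean(diff(grid))
  for (center in c(1450, 1940)) {
    expect_true(any(abs(grid[top2] - center) <= 3 * spacing))
  }
})

test_that("model JSON serialization round trips predictions", {
  s <- planted_two_band_spectra(n = 20)
  m <- fit_plsda(s, n_lv = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_plsda_json(m, path)
  back <- read_plsda_json(path)
  expect_equal(predict(back, s)$score, predict(m, s)$score, tolerance = 1e-12)
})
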