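#' Fit a PLS-DA model by NIPALS
#'
#' Partial least squares discriminant analysis: ordinary PLS1 regression of
#' the 0/1 class code on the absorbance matrix, classified by thresholding
#' the predicted score at 0.5. The factorisation is the classical NIPALS
#' sequence on the centered (optionally autoscaled) data: for each latent
#' variable `a`,
#' \deqn{w_a = X^T y / \|X^T y\|,\; t_a = X w_a,\; p_a = X^T t_a/(t_a^T t_a),
#'       \; q_a = y^T t_a/(t_a^T t_a),}
#' followed by deflation `X <- X - t p^T`, `y <- y - q t`. The regression
#' vector is `beta = W (P^T W)^{-1} q`, mapped back to the raw variable
#' scale, so score-chain and beta predictions agree.
#'
#' @inheritParams spectra_wavelengths
#' @param n_lv number of latent variables.
#' @param autoscale divide each (centered) variable by its standard
#'   deviation before fitting. Off by default; switched on for
#'   weighted-regression-coefficient band selection, where comparable
#'   coefficient magnitudes across wavelengths are the point.
#' @return An object of class `plsda` with the weight/score/loading
#'   matrices `W`, `T`, `P`, `U`, the y-loadings `q`, raw-scale `beta` and
#'   `intercept`, centering/scaling vectors, the residual matrices `Ex`,
#'   `Ey`, the fitted wavelengths and the 0.5 decision threshold.
#' @export
fit_plsda <- function(spectra, n_lv = 2L, autoscale = FALSE) {
  validate_spectra(spectra)
  X0 <- spectra_matrix(spectra)
  y0 <- as.numeric(spectra$label)
  if (length(unique(y0)) < 2L) {
    abort_nirfm("both classes must be present to fit PLS-DA", "nirfm_plsda_error")
  }
  n <- nrow(X0); j <- ncol(X0)
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > min(n - 1L, j)) {
    abort_nirfm(sprintf("n_lv must be in 1..%d", min(n - 1L, j)), "nirfm_plsda_error")
  }
  x_mean <- colMeans(X0)
  x_scale <- if (autoscale) {
    s <- apply(X0, 2, stats::sd)
    if (any(s == 0)) {
      abort_nirfm("autoscaling impossible: constant variable present",
                  "nirfm_plsda_error")
    }
    s
  } else {
    rep(1, j)
  }
  y_mean <- mean(y0)
  X <- sweep(sweep(X0, 2, x_mean), 2, x_scale, "/")
  y <- y0 - y_mean

  W <- matrix(0, j, n_lv); P <- matrix(0, j, n_lv)
  Tm <- matrix(0, n, n_lv); U <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      abort_nirfm(sprintf("degenerate deflation at component %d (zero weight norm)", a),
                  "nirfm_plsda_error")
    }
    w <- w / nw
    t <- X %*% w
    tt <- sum(t^2)
    p <- crossprod(X, t) / tt
    q[a] <- sum(y * t) / tt
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t
    U[, a] <- y / q[a]  # y-scores of the single-response factorisation
    X <- X - t %*% t(p)
    y <- y - q[a] * t
  }
  beta_scaled <- W %*% solve(crossprod(P, W), q)
  beta <- as.numeric(beta_scaled) / x_scale
  intercept <- y_mean - sum(x_mean * beta)
  structure(
    list(
      n_lv = n_lv, W = W, T = Tm, P = P, U = U, q = q,
      beta = beta, intercept = intercept,
      x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
      autoscale = autoscale, threshold = 0.5,
      Ex = X, Ey = y,
      wavelengths = spectra_wavelengths(spectra),
      n_samples = n
    ),
    class = "plsda"
  )
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d latent variables, %d wavelengths, %d calibration samples\n",
              x$n_lv, length(x$wavelengths), x$n_samples))
  cat(sprintf("  decision: FM iff predicted score >= %.2f (0 = vegetable, 1 = FM)\n",
              x$threshold))
  invisible(x)
}

#' Predict classes from a fitted PLS-DA model
#'
#' Scores are `intercept + X beta`; a sample is called a foreign material
#' (class 1) iff its score is `>= 0.5` — the midpoint between the 0 and 1
#' class targets, with ties going to the FM side.
#'
#' @param object a [fit_plsda()] model.
#' @param spectra a spectra tibble on the model's wavelengths.
#' @param ... unused.
#' @return A tibble with `sample_id`, `label`, `score`, `predicted`.
#' @export
predict.plsda <- function(object, spectra, ...) {
  validate_spectra(spectra)
  w <- spectra_wavelengths(spectra)
  if (length(w) != length(object$wavelengths) ||
      max(abs(w - object$wavelengths)) > 1e-6) {
    abort_nirfm("spectra wavelengths do not match the fitted model",
                "nirfm_plsda_error")
  }
  score <- as.numeric(object$intercept + spectra_matrix(spectra) %*% object$beta)
  tibble::tibble(
    sample_id = spectra$sample_id,
    label = spectra$label,
    score = score,
    predicted = as.integer(score >= object$threshold)
  )
}

#' Choose the latent-variable count by cross-validation
#'
#' Stratified k-fold cross-validated misclassification rate for each LV
#' count up to `max_lv`; returns the smallest count attaining the minimum
#' (parsimony tie-break).
#'
#' @inheritParams spectra_wavelengths
#' @param max_lv largest LV count to scan.
#' @param folds number of stratified folds.
#' @param seed integer seed for fold assignment.
#' @param autoscale passed to [fit_plsda()].
#' @return The chosen LV count, with the per-LV CV error attached as
#'   attribute `"cv_error"`.
#' @export
choose_n_lv <- function(spectra, max_lv = 10L, folds = 10L, seed = 1L,
                        autoscale = FALSE) {
  validate_spectra(spectra)
  err <- cv_misclassification(spectra, n_lv = seq_len(max_lv), folds = folds,
                              seed = seed, autoscale = autoscale)
  best <- which(err == min(err))[1]
  structure(as.integer(best), cv_error = err)
}

# stratified k-fold CV of PLS-DA for each LV count in n_lv: per-LV
# misclassification rate and mean squared error of the predicted score.
# LV counts infeasible on a training fold are capped at the fold's rank bound.
cv_plsda <- function(spectra, n_lv, folds, seed, autoscale = FALSE) {
  fold_id <- stratified_folds(spectra$label, folds, seed)
  errs <- matrix(NA_real_, length(n_lv), max(fold_id))
  sqes <- matrix(NA_real_, length(n_lv), max(fold_id))
  for (f in seq_len(max(fold_id))) {
    train <- spectra[fold_id != f, , drop = FALSE]
    test <- spectra[fold_id == f, , drop = FALSE]
    cap <- min(nrow(train) - 1L, length(spectra_wavelengths(spectra)))
    for (i in seq_along(n_lv)) {
      a <- min(n_lv[i], cap)
      pred <- predict(fit_plsda(train, n_lv = a, autoscale = autoscale), test)
      errs[i, f] <- mean(pred$predicted != pred$label)
      sqes[i, f] <- mean((pred$score - pred$label)^2)
    }
  }
  list(error = rowMeans(errs), mse = rowMeans(sqes))
}

cv_misclassification <- function(spectra, n_lv, folds, seed, autoscale = FALSE) {
  cv_plsda(spectra, n_lv, folds, seed, autoscale)$error
}

#' Evaluate a PLS-DA model on a labeled set
#'
#' @param object a [fit_plsda()] model.
#' @param spectra a labeled spectra tibble.
#' @param partition tag naming the data partition
#'   (`"calibration"`, `"validation"`, `"test"`, ...).
#' @return A one-row `model_report` tibble: partition, sample counts,
#'   confusion counts, and unrounded sensitivity/specificity/accuracy (%).
#' @export
evaluate_model <- function(object, spectra, partition = "validation") {
  if (nrow(spectra) == 0) {
    abort_nirfm("cannot evaluate on an empty set", "nirfm_plsda_error")
  }
  pred <- predict(object, spectra)
  counts <- confusion_counts(pred$label, pred$predicted)
  out <- dplyr::bind_cols(
    tibble::tibble(partition = partition, n = nrow(spectra), n_lv = object$n_lv),
    counts, metrics(counts)
  )
  class(out) <- c("model_report", class(out))
  out
}

#' Tidy the regression vector of a PLS-DA model
#'
#' @param x a `plsda` model.
#' @param ... unused.
#' @return A tibble with `wavelength` and `beta` (raw-variable scale).
#' @exportS3Method generics::tidy
tidy.plsda <- function(x, ...) {
  tibble::tibble(wavelength = x$wavelengths, beta = x$beta)
}

#' One-row summary of a PLS-DA model
#'
#' @param x a `plsda` model.
#' @param ... unused.
#' @return A tibble with `n_lv`, `n_samples`, `n_wavelengths`, `autoscale`.
#' @exportS3Method generics::glance
glance.plsda <- function(x, ...) {
  tibble::tibble(
    n_lv = x$n_lv, n_samples = x$n_samples,
    n_wavelengths = length(x$wavelengths), autoscale = x$autoscale
  )
}

#' Plot the regression vector of a PLS-DA model
#'
#' @param object a `plsda` model.
#' @param ... unused.
#' @return A ggplot of beta against wavelength.
#' @exportS3Method ggplot2::autoplot
autoplot.plsda <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$wavelength, .data$beta)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "wavelength (nm)", y = "regression coefficient") +
    ggplot2::theme_minimal()
}

#' Serialize a PLS-DA model to JSON
#'
#' @param object a `plsda` model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plsda_json <- function(object, path) {
  stopifnot(inherits(object, "plsda"))
  x <- unclass(object)
  x$W <- unname(x$W); x$T <- unname(x$T); x$P <- unname(x$P); x$U <- unname(x$U)
  x$x_mean <- unname(x$x_mean); x$x_scale <- unname(x$x_scale)
  x$beta <- unname(x$beta); x$Ex <- unname(x$Ex); x$Ey <- unname(x$Ey)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a PLS-DA model serialized by [write_plsda_json()]
#'
#' @param path JSON path.
#' @return A `plsda` model.
#' @export
read_plsda_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("W", "T", "P", "U", "Ex")) x[[nm]] <- as.matrix(x[[nm]])
  structure(x, class = "plsda")
}
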