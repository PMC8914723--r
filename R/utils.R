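# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_nirfm <- function(msg, class) {
  rlang::abort(msg, class = c(class, "nirfm_error"))
}

# validate a wavelength axis: finite, positive, strictly increasing, length >= 2
check_grid <- function(values, arg = "wavelengths", min_len = 2L) {
  if (length(values) < min_len) {
    abort_nirfm(sprintf("%s must contain at least %d values", arg, min_len),
                "nirfm_grid_error")
  }
  if (!all(is.finite(values)) || any(values <= 0)) {
    abort_nirfm(sprintf("%s must be finite and positive", arg), "nirfm_grid_error")
  }
  if (any(diff(values) <= 0)) {
    abort_nirfm(sprintf("%s must be strictly increasing", arg), "nirfm_grid_error")
  }
  invisible(as.numeric(values))
}

# run expr with a local RNG state seeded from `seed`
with_rng <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# index of the nearest value in `grid` for each element of `x`
nearest_index <- function(x, grid) {
  vapply(x, function(v) which.min(abs(grid - v)), integer(1))
}

# stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into k folds, so fold class counts differ by at most 1
stratified_folds <- function(labels, k, seed) {
  k <- as.integer(k)
  if (k < 2L) abort_nirfm("at least 2 folds are required", "nirfm_cv_error")
  if (min(table(labels)) < k) {
    abort_nirfm("fold count exceeds the size of the smallest class", "nirfm_cv_error")
  }
  folds <- integer(length(labels))
  with_rng(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
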