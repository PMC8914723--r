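#' Principal component analysis of a spectra table
#'
#' Column-mean-centered PCA via the singular value decomposition
#' ([stats::prcomp()]). Used as an exploratory check that vegetables and
#' foreign materials separate before any supervised modelling.
#'
#' @inheritParams spectra_wavelengths
#' @param n_components number of components to keep; at most
#'   `min(n_samples - 1, n_wavelengths)`.
#' @return An object of class `nirfm_pca` with elements `scores`
#'   (samples x components), `loadings` (wavelengths x components,
#'   orthonormal columns), `explained_variance_ratio`, `mean_spectrum`,
#'   `wavelengths` and `labels`.
#' @export
fit_pca <- function(spectra, n_components = 3L) {
  validate_spectra(spectra)
  m <- spectra_matrix(spectra)
  limit <- min(nrow(m) - 1L, ncol(m))
  if (n_components < 1L || n_components > limit) {
    abort_nirfm(sprintf("n_components must be in 1..%d", limit), "nirfm_pca_error")
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = pc$x[, seq_len(n_components), drop = FALSE],
      loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
      explained_variance_ratio = ratio[seq_len(n_components)],
      mean_spectrum = pc$center,
      wavelengths = spectra_wavelengths(spectra),
      labels = spectra$label
    ),
    class = "nirfm_pca"
  )
}

#' @export
print.nirfm_pca <- function(x, ...) {
  cat(sprintf("<nirfm_pca> %d components; variance explained: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy PCA scores
#'
#' @param x an `nirfm_pca` object.
#' @param ... unused.
#' @return A tibble with one row per sample: `sample`, `label`, `class`,
#'   and one `PC<k>` column per component.
#' @exportS3Method generics::tidy
tidy.nirfm_pca <- function(x, ...) {
  out <- tibble::as_tibble(x$scores, .name_repair = "minimal")
  names(out) <- paste0("PC", seq_len(ncol(out)))
  dplyr::bind_cols(
    tibble::tibble(sample = rownames(x$scores) %||% as.character(seq_len(nrow(x$scores))),
                   label = x$labels,
                   class = ifelse(x$labels == 0, "vegetable", "fm")),
    out
  )
}

#' @rdname tidy.nirfm_pca
#' @exportS3Method generics::glance
glance.nirfm_pca <- function(x, ...) {
  tibble::tibble(
    n_components = ncol(x$scores),
    cumulative_variance_pct = 100 * sum(x$explained_variance_ratio)
  )
}

#' PCA score plot
#'
#' @param object an `nirfm_pca` object.
#' @param components which two components to display.
#' @param ... unused.
#' @return A ggplot: score scatter coloured by class.
#' @exportS3Method ggplot2::autoplot
autoplot.nirfm_pca <- function(object, components = c(1L, 2L), ...) {
  d <- tidy(object)
  xs <- paste0("PC", components[1]); ys <- paste0("PC", components[2])
  ggplot2::ggplot(d, ggplot2::aes(.data[[xs]], .data[[ys]], colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xs,
                  100 * object$explained_variance_ratio[components[1]]),
      y = sprintf("%s (%.1f%%)", ys,
                  100 * object$explained_variance_ratio[components[2]]),
      colour = NULL) +
    ggplot2::theme_minimal()
}
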