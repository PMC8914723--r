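#' Confusion counts for the vegetable-positive convention
#'
#' Tallies a two-class confusion table under the encoding used throughout
#' this package: class 0 = vegetable = positive, class 1 = foreign material
#' (FM) = negative. So `tp` counts vegetables recognised as vegetables,
#' `fn` vegetables mistaken for FMs, `tn` FMs recognised as FMs and `fp`
#' FMs mistaken for vegetables. This inverts the common habit of calling
#' the contaminant positive; it is stated here once and used consistently.
#'
#' @param truth integer vector of true labels in \{0, 1\}.
#' @param predicted integer vector of predicted labels, same length.
#' @return A one-row tibble with columns `tp`, `fn`, `tn`, `fp`.
#' @examples
#' confusion_counts(c(0, 0, 1, 1), c(0, 1, 1, 0))
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort_nirfm("truth and predicted must have equal length", "nirfm_metric_error")
  }
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    abort_nirfm("labels must be 0 or 1", "nirfm_metric_error")
  }
  tibble::tibble(
    tp = sum(truth == 0 & predicted == 0),
    fn = sum(truth == 0 & predicted == 1),
    tn = sum(truth == 1 & predicted == 1),
    fp = sum(truth == 1 & predicted == 0)
  )
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Computes, in percent:
#' \deqn{Sensitivity = 100\, Tp/(Tp+Fn), \quad
#'       Specificity = 100\, Tn/(Tn+Fp), \quad
#'       Accuracy = 100\,(Tp+Tn)/(Tp+Tn+Fp+Fn).}
#' A metric with a zero denominator is an error, never a silent 0 or 100 —
#' a sentinel would corrupt model-comparison tables downstream.
#'
#' @param counts a one-row data frame with columns `tp`, `fn`, `tn`, `fp`
#'   (as returned by [confusion_counts()]), or a named list.
#' @return A one-row tibble with columns `sensitivity`, `specificity`,
#'   `accuracy` (percent, unrounded).
#' @examples
#' metrics(data.frame(tp = 200, fn = 0, tn = 93, fp = 7))
#' @export
metrics <- function(counts) {
  counts <- as.list(counts)
  need <- c("tp", "fn", "tn", "fp")
  if (!all(need %in% names(counts))) {
    abort_nirfm("counts must provide tp, fn, tn, fp", "nirfm_metric_error")
  }
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  if (any(c(tp, fn, tn, fp) < 0)) {
    abort_nirfm("confusion counts must be non-negative", "nirfm_metric_error")
  }
  if (tp + fn == 0) {
    abort_nirfm("sensitivity undefined: no vegetable samples (tp + fn = 0)",
                "nirfm_metric_undefined")
  }
  if (tn + fp == 0) {
    abort_nirfm("specificity undefined: no FM samples (tn + fp = 0)",
                "nirfm_metric_undefined")
  }
  tibble::tibble(
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy    = 100 * (tp + tn) / (tp + tn + fp + fn)
  )
}
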