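#' Confusion counts for binary response predictions
#'
#' @param truth factor/character of true labels.
#' @param predicted factor/character of predicted labels.
#' @param positive the positive class (default `"responder"`).
#' @return named list with counts `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted, positive = "responder") {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  list(tp = sum(truth == positive & predicted == positive),
       tn = sum(truth != positive & predicted != positive),
       fp = sum(truth != positive & predicted == positive),
       fn = sum(truth == positive & predicted != positive))
}

#' Matthews correlation coefficient with undefined-value semantics
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any marginal
#' of the confusion matrix is zero — e.g. a classifier predicting the same
#' class for every sample — the denominator is zero and the MCC is undefined;
#' this is reported as `NA`, a typed sentinel that is never conflated with an
#' MCC of 0 (a random-level classifier). No input ever raises.
#'
#' @param cm list with `tp`, `tn`, `fp`, `fn` (see [confusion_counts()]).
#' @return MCC in \[-1, 1\], or `NA_real_` when undefined.
#' @export
mcc <- function(cm) {
  tp <- as.double(cm$tp); tn <- as.double(cm$tn)
  fp <- as.double(cm$fp); fn <- as.double(cm$fn)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) return(NA_real_)
  (tp * tn - fp * fn) / denom
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a uniformly random positive sample receives a higher score
#' than a uniformly random negative sample, with ties counted one half —
#' computed via midranks, which is exactly the Mann-Whitney U identity and is
#' invariant to any monotone transform of the scores.
#'
#' @param scores numeric ranking scores (probabilities or margins).
#' @param labels true labels.
#' @param positive positive class (default `"responder"`).
#' @return AUC in \[0, 1\], or `NA_real_` if only one class is present.
#' @export
roc_auc <- function(scores, labels, positive = "responder") {
  pos <- as.character(labels) == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Median over CV repetitions, excluding undefined values
#'
#' Repetitions with an undefined MCC are excluded from the median and counted;
#' when every repetition is undefined, the summary itself is undefined (a
#' blank grid cell).
#'
#' @param metrics tibble with one row per repetition and columns `seed`,
#'   `mcc`, `auc` (as produced by [run_merged_cv()]).
#' @return one-row tibble: `mmcc`, `median_auc`, `n_undefined`,
#'   `n_repetitions`.
#' @export
summarize_repetitions <- function(metrics) {
  stopifnot(nrow(metrics) >= 1)
  defined <- metrics$mcc[!is.na(metrics$mcc)]
  tibble(
    mmcc = if (length(defined)) median(defined) else NA_real_,
    median_auc = median(metrics$auc, na.rm = TRUE),
    n_undefined = sum(is.na(metrics$mcc)),
    n_repetitions = nrow(metrics))
}
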