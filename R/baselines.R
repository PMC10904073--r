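#' Single-feature baseline model
#'
#' Restricts the feature matrix to one named feature and runs the unchanged
#' merged-CV protocol — the comparison a literature single-gene marker (such
#' as hENT1 expression for gemcitabine) gets against multi-feature models.
#'
#' @param dataset a `matched_dataset`.
#' @param feature_id the single feature to keep.
#' @param algorithms algorithm IDs to evaluate (default `c("rf", "xgboost")`,
#'   matching the customary comparison against the top multi-feature models).
#' @param cv a [cv_config()].
#' @return list with `summary` (one row per algorithm) and `results` (named
#'   list of `merged_cv_result`s).
#' @export
single_gene_model <- function(dataset, feature_id,
                              algorithms = c("rf", "xgboost"),
                              cv = cv_config()) {
  if (!feature_id %in% colnames(dataset$x)) {
    abort(sprintf("feature '%s' not present in the profile", feature_id))
  }
  ds <- dataset
  ds$x <- dataset$x[, feature_id, drop = FALSE]
  results <- lapply(algorithms, function(a) {
    run_merged_cv(ds, model_spec(a, "all_features"), cv = cv)
  })
  names(results) <- algorithms
  summary <- dplyr::bind_rows(lapply(algorithms, function(a) {
    dplyr::bind_cols(tibble(algorithm = a, feature_id = feature_id),
                     results[[a]]$summary)
  }))
  list(summary = summary, results = results)
}

#' Class-permutation null distribution of the merged-CV mMCC
#'
#' Estimates chance-level performance by rerunning the full pipeline —
#' including OMC feature selection, when `spec$mode == "omc"` — on datasets
#' whose labels have been randomly permuted. Selection is repeated inside
#' every permutation so that selection bias is part of the null. The
#' empirical p-value uses the +1 correction
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` and is therefore never 0.
#'
#' @param dataset a `matched_dataset`.
#' @param spec a [model_spec()].
#' @param cv a [cv_config()].
#' @param omc an [omc_control()].
#' @param n_perm number of label permutations (default 50).
#' @param seed integer seed for the permutation draws.
#' @return a `permutation_null` list: `observed` (observed mMCC), `null`
#'   (tibble permutation/mmcc), `p_value`, `observed_result` (the unpermuted
#'   `merged_cv_result`).
#' @export
permutation_null <- function(dataset, spec, cv = cv_config(),
                             omc = omc_control(), n_perm = 50, seed = 0L) {
  assert_count(n_perm, "n_perm", 1)
  observed_result <- run_merged_cv(dataset, spec, cv = cv, omc = omc)
  observed <- observed_result$summary$mmcc
  null_mmcc <- vapply(seq_len(n_perm), function(i) {
    ds <- dataset
    ds$labels <- with_seed(sub_seed(seed, 997, i),
                           sample(as.character(dataset$labels)))
    run_merged_cv(ds, spec, cv = cv, omc = omc)$summary$mmcc
  }, numeric(1))
  n_ge <- sum(!is.na(null_mmcc) & null_mmcc >= observed)
  structure(list(
    observed = observed,
    null = tibble(permutation = seq_len(n_perm), mmcc = null_mmcc),
    p_value = (1 + n_ge) / (1 + n_perm),
    observed_result = observed_result), class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "<permutation_null> observed mMCC = %.3f, null mean = %.3f (%d perms), p = %.4f\n",
    x$observed, mean(x$null$mmcc, na.rm = TRUE), nrow(x$null), x$p_value))
  invisible(x)
}

#' @rdname permutation_null
#' @param x a `permutation_null`.
#' @param ... unused.
#' @method tidy permutation_null
#' @export
tidy.permutation_null <- function(x, ...) x$null

#' @rdname permutation_null
#' @method glance permutation_null
#' @export
glance.permutation_null <- function(x, ...) {
  tibble(observed_mmcc = x$observed,
         null_mean = mean(x$null$mmcc, na.rm = TRUE),
         null_q95 = stats::quantile(x$null$mmcc, 0.95, na.rm = TRUE,
                                    names = FALSE),
         n_perm = nrow(x$null),
         n_undefined = sum(is.na(x$null$mmcc)),
         p_value = x$p_value)
}
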