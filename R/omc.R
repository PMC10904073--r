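#' Rank features by a two-group ANOVA F test
#'
#' Computes, for every feature, the one-way ANOVA F statistic and p-value
#' between the two response classes on the training samples only — a low
#' p-value indicates high discriminative power. Constant features (zero
#' between- and within-class variance) receive p = 1 and rank last; p-value
#' ties are broken by feature ID so the ranking is deterministic.
#'
#' For two groups the ANOVA F equals the square of the pooled-variance t
#' statistic, which the test suite uses as an independent oracle.
#'
#' @param x training samples x features matrix.
#' @param labels training labels (both classes must be present with >= 2
#'   samples each).
#' @return tibble sorted by ascending p-value: `feature_id`, `f_stat`,
#'   `p_value`, `rank`.
#' @export
rank_features_anova <- function(x, labels) {
  y <- as_response_factor(labels)
  counts <- table(y)
  if (any(counts < 2)) {
    abort("ANOVA ranking needs both classes with at least 2 training samples")
  }
  g1 <- y == levels(y)[1]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  x1 <- x[g1, , drop = FALSE]; x2 <- x[!g1, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  ss1 <- colSums(x1^2) - n1 * m1^2
  ss2 <- colSums(x2^2) - n2 * m2^2
  ssw <- ss1 + ss2
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  f <- (ssb / 1) / (ssw / (n - 2))
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  # constant features: 0/0 -> NaN; define F = 0, p = 1 so they rank last
  const <- ssb < .Machine$double.eps^0.75 & ssw < .Machine$double.eps^0.75
  f[const] <- 0
  p[const] <- 1
  # perfect separators with zero within-variance: F infinite, p = 0
  p[is.infinite(f)] <- 0
  out <- tibble(feature_id = colnames(x), f_stat = unname(f), p_value = unname(p))
  out <- out[order(out$p_value, out$feature_id), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Control parameters for OMC nested-CV feature selection
#'
#' @param inner_k folds of the inner merged CV on each outer-training set
#'   (default 10, mirroring the outer protocol).
#' @param k_step step of the candidate top-k grid `seq(2, k_max, by = k_step)`
#'   (default 1; a coarser step trades selection resolution for speed).
#' @param k_max cap on the candidate k; default `NULL` means half the
#'   outer-training sample count, the "top 2 to n/2" rule read per fold.
#'   Supplying a number (e.g. half the full-cohort size) fixes the cap
#'   globally.
#' @return an `omc_control` list.
#' @export
omc_control <- function(inner_k = 10, k_step = 1, k_max = NULL) {
  assert_count(inner_k, "inner_k", 2)
  assert_count(k_step, "k_step", 1)
  if (!is.null(k_max)) assert_count(k_max, "k_max", 2)
  structure(list(inner_k = as.integer(inner_k), k_step = as.integer(k_step),
                 k_max = k_max), class = "omc_control")
}

omc_k_grid <- function(n_train, control) {
  k_max <- min(control$k_max %||% Inf, floor(n_train / 2))
  if (k_max < 2) abort("too few training samples for a top-k grid (need n/2 >= 2)")
  seq(2, k_max, by = control$k_step)
}

#' Inner-CV choice of the number of top-ranked features
#'
#' For each candidate k, restricts training to the top-k ANOVA-ranked features
#' and evaluates the classifier by inner merged CV: the ranking is recomputed
#' inside every inner training split (fully nested, so selection bias cannot
#' leak into the inner estimate), all inner out-of-sample predictions are
#' merged, and one MCC is computed per k. The k with the highest inner MCC
#' wins; ties go to the smallest k (parsimony). If every k has an undefined
#' MCC the smallest k is returned with a warning.
#'
#' @param x outer-training samples x features matrix.
#' @param labels outer-training labels.
#' @param spec a [model_spec()] (its algorithm is what gets fitted; mode is
#'   ignored here).
#' @param control an [omc_control()].
#' @param seed integer seed driving the inner fold assignment and learners.
#' @param threshold probability cutoff for hard classes (default 0.5).
#' @return list with `chosen_k` and `inner` (tibble: `k`, `inner_mcc`).
#' @export
inner_select_k <- function(x, labels, spec, control = omc_control(),
                           seed = 0L, threshold = 0.5) {
  y <- as_response_factor(labels)
  n <- nrow(x)
  k_grid <- omc_k_grid(n, control)
  folds <- stratified_folds(y, min(control$inner_k, n), sub_seed(seed, 101))
  score_mat <- matrix(NA_real_, n, length(k_grid))
  score_type <- if (spec$algorithm %in% c("svc_linear", "svc_rbf"))
    "margin" else "probability"
  for (f in sort(unique(folds))) {
    tr <- folds != f
    ranking <- rank_features_anova(x[tr, , drop = FALSE], y[tr])
    for (j in seq_along(k_grid)) {
      feats <- ranking$feature_id[seq_len(k_grid[j])]
      fitted <- fit_classifier(spec, x[tr, feats, drop = FALSE], y[tr],
                               seed = sub_seed(seed, 101, f))
      score_mat[!tr, j] <- predict_scores(fitted, x[!tr, feats, drop = FALSE])
    }
  }
  inner_mcc <- vapply(seq_along(k_grid), function(j) {
    pred <- classify_scores(score_mat[, j], score_type, threshold)
    mcc(confusion_counts(y, pred))
  }, numeric(1))
  if (all(is.na(inner_mcc))) {
    warn("all candidate k gave undefined inner MCC; falling back to the smallest k")
    chosen <- k_grid[1]
  } else {
    best <- max(inner_mcc, na.rm = TRUE)
    chosen <- min(k_grid[!is.na(inner_mcc) & inner_mcc == best])
  }
  list(chosen_k = chosen, inner = tibble(k = k_grid, inner_mcc = inner_mcc))
}

#' Fit an OMC predictor on one outer-training set
#'
#' The optimal-model-complexity procedure on one outer fold: ANOVA-rank the
#' features on the outer-training samples, choose the number k of top features
#' by inner merged-CV MCC ([inner_select_k()]), refit the classifier on the
#' outer-training set restricted to the chosen top-k, and return a predictor
#' that scores new samples using exactly those k features. Everything is
#' computed from the training samples only; held-out labels can never
#' influence the selection.
#'
#' @inheritParams inner_select_k
#' @return list with `fitted` (a `fitted_classifier` restricted to the
#'   selected features), `features` (selected feature IDs) and `trace`
#'   (ranking head, k grid with inner MCCs, chosen k, selected features).
#' @export
fit_omc <- function(x, labels, spec, control = omc_control(), seed = 0L,
                    threshold = 0.5) {
  y <- as_response_factor(labels)
  ranking <- rank_features_anova(x, y)
  sel <- inner_select_k(x, y, spec, control, seed, threshold)
  feats <- ranking$feature_id[seq_len(sel$chosen_k)]
  fitted <- fit_classifier(spec, x[, feats, drop = FALSE], y,
                           seed = sub_seed(seed, 211))
  list(fitted = fitted, features = feats,
       trace = list(ranking_head = head(ranking, max(sel$chosen_k, 50)),
                    inner = sel$inner, chosen_k = sel$chosen_k,
                    selected_features = feats))
}

#' Cross-fold selection frequency of OMC-selected features
#'
#' Counts how often each feature was selected across outer folds and
#' repetitions — the selection-stability table used to nominate a consensus
#' signature.
#'
#' @param traces list of OMC traces (each with a `selected_features` element),
#'   e.g. flattened from [run_merged_cv()] results.
#' @return tibble `feature_id`, `n_selected`, sorted by descending count (ties
#'   by feature ID).
#' @export
feature_selection_frequency <- function(traces) {
  stopifnot(length(traces) >= 1)
  feats <- unlist(lapply(traces, function(tr) tr$selected_features))
  counts <- sort(table(feats), decreasing = TRUE)
  out <- tibble(feature_id = names(counts), n_selected = as.integer(counts))
  out[order(-out$n_selected, out$feature_id), ]
}
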