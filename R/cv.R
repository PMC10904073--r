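#' Cross-validation configuration
#'
#' @param k number of folds; 5, 10, or the sample count n (leave-one-out).
#' @param seeds integer vector of repetition seeds (default `0:4`, i.e. five
#'   seeded repetitions); one CV repetition is run per seed and the seed
#'   drives both the fold assignment and any stochastic learner.
#' @param threshold probability cutoff for hard classes (default 0.5).
#' @return a `cv_config` list; `n_repetitions` is `length(seeds)`.
#' @export
cv_config <- function(k = 10, seeds = 0:4, threshold = 0.5) {
  assert_count(k, "k", 2)
  if (length(seeds) < 1) abort("need at least one repetition seed")
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  structure(list(k = as.integer(k), seeds = as.integer(seeds),
                 n_repetitions = length(seeds), threshold = threshold),
            class = "cv_config")
}

#' Merged stratified K-fold cross-validation of one model
#'
#' For every repetition seed: assign stratified folds, fit the model on each
#' fold's complement (with OMC feature selection inside the training set when
#' `spec$mode == "omc"`), score the held-out fold, and **merge** all
#' out-of-sample predictions before computing one confusion matrix, one MCC
#' and one ROC-AUC over all n samples. Per-fold metrics are never averaged —
#' with small cohorts per-fold test sets are too small for stable metrics and
#' would not be comparable across values of K. Every sample receives exactly
#' one out-of-sample prediction per repetition, for any K.
#'
#' @param dataset a `matched_dataset` from [join_profile_to_cohort()], or any
#'   list with `x` (samples x features matrix), `labels` and `sample_id`.
#' @param spec a [model_spec()].
#' @param cv a [cv_config()].
#' @param omc an [omc_control()]; used only when `spec$mode == "omc"`.
#' @return a `merged_cv_result`: `metrics` (tibble seed/mcc/auc), `summary`
#'   (from [summarize_repetitions()]), `predictions` (tibble sample_id, seed,
#'   fold, score, class, label), `traces` (per repetition, per outer fold; OMC
#'   mode only), `spec`, `cv`, and `failures` (per-repetition diagnostics).
#' @export
run_merged_cv <- function(dataset, spec, cv = cv_config(),
                          omc = omc_control()) {
  x <- dataset$x
  y <- as_response_factor(dataset$labels)
  sample_id <- dataset$sample_id %||% rownames(x)
  n <- nrow(x)
  if (cv$k > n) abort(sprintf("k = %d exceeds n = %d", cv$k, n))
  score_type <- if (spec$algorithm %in% c("svc_linear", "svc_rbf"))
    "margin" else "probability"

  metrics <- vector("list", length(cv$seeds))
  predictions <- vector("list", length(cv$seeds))
  traces <- list()
  failures <- list()

  for (r in seq_along(cv$seeds)) {
    s <- cv$seeds[r]
    rep_out <- tryCatch({
      folds <- stratified_folds(y, cv$k, s)
      scores <- rep(NA_real_, n)
      rep_traces <- list()
      for (f in sort(unique(folds))) {
        test <- folds == f
        res <- tryCatch({
          if (spec$mode == "omc") {
            om <- fit_omc(x[!test, , drop = FALSE], y[!test], spec,
                          control = omc, seed = sub_seed(s, f),
                          threshold = cv$threshold)
            rep_traces[[length(rep_traces) + 1]] <-
              c(om$trace, list(seed = s, fold = f))
            predict_scores(om$fitted, x[test, om$features, drop = FALSE])
          } else {
            fitted <- fit_classifier(spec, x[!test, , drop = FALSE],
                                     y[!test], seed = sub_seed(s, f))
            predict_scores(fitted, x[test, , drop = FALSE])
          }
        }, error = function(e) {
          abort(sprintf("repetition seed %d: model failed on fold %d: %s",
                        s, f, conditionMessage(e)))
        })
        scores[test] <- res
      }
      stopifnot(!anyNA(scores))  # merged-CV guarantee: one prediction each
      classes <- classify_scores(scores, score_type, cv$threshold)
      list(
        metrics = tibble(seed = s,
                         mcc = mcc(confusion_counts(y, classes)),
                         auc = roc_auc(scores, y)),
        predictions = tibble(sample_id = sample_id, seed = s, fold = folds,
                             score = scores, class = classes,
                             label = as.character(y)),
        traces = rep_traces)
    }, error = function(e) e)
    if (inherits(rep_out, "error")) {
      failures[[as.character(s)]] <- conditionMessage(rep_out)
      metrics[[r]] <- tibble(seed = s, mcc = NA_real_, auc = NA_real_)
    } else {
      metrics[[r]] <- rep_out$metrics
      predictions[[r]] <- rep_out$predictions
      traces <- c(traces, rep_out$traces)
    }
  }

  metrics <- dplyr::bind_rows(metrics)
  structure(list(
    metrics = metrics,
    summary = summarize_repetitions(metrics),
    predictions = dplyr::bind_rows(predictions),
    traces = traces,
    spec = spec, cv = cv,
    failures = failures), class = "merged_cv_result")
}

#' @export
print.merged_cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<merged_cv_result> %s (%s), K=%d, %d repetitions\n",
              x$spec$algorithm, x$spec$mode, x$cv$k, x$cv$n_repetitions))
  cat(sprintf("  mMCC = %s, median AUC = %s, undefined repetitions = %d\n",
              format(round(s$mmcc, 3)), format(round(s$median_auc, 3)),
              s$n_undefined))
  invisible(x)
}

#' @rdname run_merged_cv
#' @param x a `merged_cv_result`.
#' @param ... unused.
#' @method tidy merged_cv_result
#' @export
tidy.merged_cv_result <- function(x, ...) x$metrics

#' @rdname run_merged_cv
#' @method glance merged_cv_result
#' @export
glance.merged_cv_result <- function(x, ...) {
  dplyr::bind_cols(tibble(algorithm = x$spec$algorithm, mode = x$spec$mode,
                          k = x$cv$k), x$summary)
}

#' Evaluate a grid of profiles x algorithms x modes
#'
#' Runs [run_merged_cv()] for every (profile, algorithm, mode) cell, sharing
#' one repetition seed list across all cells so cells are comparable. Cells
#' are independent: a failing cell is recorded and the grid completes, and
#' results are identical regardless of execution order.
#'
#' @param profiles named list of [omics_profile()] objects (names label the
#'   grid rows).
#' @param cohort curated cohort tibble with `patient_id` and `response_label`.
#' @param algorithms character vector of algorithm IDs (default all eight).
#' @param modes subset of `c("all_features", "omc")`.
#' @param cv a [cv_config()].
#' @param omc an [omc_control()].
#' @param id_length barcode prefix length for profile-cohort matching.
#' @return an `evaluation_grid`: `cells` (one summary row per cell),
#'   `metrics` (long per-repetition tibble), `results` (named list of
#'   `merged_cv_result`s).
#' @export
evaluate_grid <- function(profiles, cohort, algorithms = algorithm_ids(),
                          modes = c("all_features", "omc"),
                          cv = cv_config(), omc = omc_control(),
                          id_length = 12) {
  stopifnot(length(profiles) >= 1, !is.null(names(profiles)))
  modes <- match.arg(modes, several.ok = TRUE)
  cells <- tidyr::expand_grid(profile = names(profiles),
                              algorithm = algorithms, mode = modes)
  results <- list()
  rows <- vector("list", nrow(cells))
  metrics <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    key <- paste(cells$profile[i], cells$algorithm[i], cells$mode[i],
                 sep = "|")
    row <- cells[i, ]
    out <- tryCatch({
      ds <- join_profile_to_cohort(profiles[[cells$profile[i]]], cohort,
                                   id_length = id_length)
      run_merged_cv(ds, model_spec(cells$algorithm[i], cells$mode[i]),
                    cv = cv, omc = omc)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      rows[[i]] <- dplyr::bind_cols(row, tibble(
        mmcc = NA_real_, median_auc = NA_real_, n_undefined = NA_integer_,
        n_repetitions = NA_integer_, error = conditionMessage(out)))
    } else {
      results[[key]] <- out
      rows[[i]] <- dplyr::bind_cols(row, out$summary,
                                    tibble(error = NA_character_))
      metrics[[i]] <- dplyr::bind_cols(row, out$metrics)
    }
  }
  structure(list(cells = dplyr::bind_rows(rows),
                 metrics = dplyr::bind_rows(metrics),
                 results = results, cv = cv),
            class = "evaluation_grid")
}

#' @export
print.evaluation_grid <- function(x, ...) {
  cat(sprintf("<evaluation_grid> %d cells\n", nrow(x$cells)))
  print(x$cells, n = 20)
  invisible(x)
}

#' @rdname evaluate_grid
#' @param x an `evaluation_grid`.
#' @param ... unused.
#' @method tidy evaluation_grid
#' @export
tidy.evaluation_grid <- function(x, ...) x$metrics

#' @rdname evaluate_grid
#' @method glance evaluation_grid
#' @export
glance.evaluation_grid <- function(x, ...) x$cells

#' Heatmap of an evaluation grid
#'
#' Profiles as rows, (algorithm, mode) combinations as columns, cell fill =
#' median MCC across repetitions. Cells whose MCC is undefined in every
#' repetition (a constant-prediction model) are rendered blank, never as 0.
#'
#' @param object an `evaluation_grid`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot evaluation_grid
#' @export
autoplot.evaluation_grid <- function(object, ...) {
  df <- object$cells
  df$column <- paste(df$algorithm, ifelse(df$mode == "omc", "OMC", "all"),
                     sep = "-")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$profile,
                                   fill = .data$mmcc)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$mmcc), "", sprintf("%.2f", .data$mmcc))),
      size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-1, 1), na.value = "white",
                                  name = "mMCC") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
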