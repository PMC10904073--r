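#' Welch's two-sample t test
#'
#' Two-tailed unpaired t test with unequal variances (Welch-Satterthwaite
#' degrees of freedom) — the test used for differential expression/methylation
#' of candidate predictor features between responders and nonresponders.
#'
#' @param group_a,group_b numeric vectors (each >= 2 values with nonzero
#'   variance).
#' @return one-row tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2 ||
      stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    abort("welch_t needs two groups of >= 2 values with nonzero variance")
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE,
               alternative = "two.sided")
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value,
         mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Kaplan-Meier median survival
#'
#' Product-limit estimate of the survival curve; the median is the smallest
#' observed time at which the estimated survival drops to 0.5 or below — the
#' time point where 50% of the group has had the event. When the curve never
#' reaches 0.5 (heavy censoring), the median is undefined and `NA` is
#' returned.
#'
#' @param time follow-up times (months).
#' @param event event indicators (1 = event, 0 = censored).
#' @return median survival time, or `NA_real_` when undefined.
#' @export
km_median <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  at_or_below <- fit$time[fit$surv <= 0.5 + 1e-12]
  if (length(at_or_below) == 0) NA_real_ else min(at_or_below)
}

#' Two-group log-rank test
#'
#' Standard observed-vs-expected log-rank statistic over the shared event
#' times, 1 degree of freedom.
#'
#' @param time follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param group two-level grouping vector.
#' @return one-row tibble: `statistic`, `df`, `p_value` (all `NA` when the
#'   data contain no events).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) abort("logrank_test needs exactly 2 groups")
  if (sum(event) == 0) {
    return(tibble(statistic = NA_real_, df = NA_integer_, p_value = NA_real_))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  tibble(statistic = sd$chisq, df = 1L,
         p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Breslow handling of tied event times.
#' Continuous covariates are standardized (mean 0, sd 1) before fitting so
#' hazard ratios of jointly modeled features are on a comparable per-SD scale;
#' binary 0/1 covariates are left as-is. `"univariate"` fits one model per
#' covariate; `"multivariate"` fits one joint model.
#'
#' @param data data frame containing time, event and covariate columns.
#' @param time,event names of the time and event columns.
#' @param covariates character vector of covariate column names.
#' @param type `"univariate"` or `"multivariate"`.
#' @param standardize standardize continuous covariates (default `TRUE`).
#' @return tibble with one row per covariate: `term`, `hr`, `conf_low`,
#'   `conf_high`, `p_value`, `model`.
#' @export
cox_fit <- function(data, time = "os_time", event = "os_event", covariates,
                    type = c("univariate", "multivariate"),
                    standardize = TRUE) {
  type <- match.arg(type)
  stopifnot(all(c(time, event, covariates) %in% names(data)))
  df <- as.data.frame(data[, c(time, event, covariates)])
  for (cv in covariates) {
    v <- df[[cv]]
    if (!is.numeric(v)) abort(sprintf("covariate '%s' must be numeric", cv))
    if (standardize && length(unique(v)) > 2) {
      df[[cv]] <- (v - mean(v)) / stats::sd(v)
    }
  }
  fit_one <- function(covs, model_label) {
    fml <- stats::as.formula(paste0(
      "survival::Surv(", time, ", ", event, ") ~ ",
      paste(sprintf("`%s`", covs), collapse = " + ")))
    fit <- survival::coxph(fml, data = df, ties = "breslow")
    if (anyNA(stats::coef(fit))) {
      abort(paste0("rank-deficient covariate matrix in ", model_label,
                   " Cox model (aliased: ",
                   paste(names(which(is.na(stats::coef(fit)))), collapse = ", "),
                   ")"))
    }
    sm <- summary(fit)
    tibble(term = gsub("`", "", rownames(sm$coefficients)),
           hr = unname(sm$coefficients[, "exp(coef)"]),
           conf_low = unname(sm$conf.int[, "lower .95"]),
           conf_high = unname(sm$conf.int[, "upper .95"]),
           p_value = unname(sm$coefficients[, "Pr(>|z|)"]),
           model = model_label)
  }
  if (type == "multivariate") {
    fit_one(covariates, "multivariate")
  } else {
    dplyr::bind_rows(lapply(covariates, fit_one, model_label = "univariate"))
  }
}

#' Survival comparison of actual versus predicted responder groups
#'
#' Joins one repetition's merged out-of-sample predicted classes to the
#' cohort's survival records and builds the four groups — actual and predicted
#' responders and nonresponders. Reports each group's size and Kaplan-Meier
#' median for both endpoints (OS and PFS), and the four pairwise log-rank
#' comparisons: actual R vs actual NR, predicted R vs predicted NR, actual R
#' vs predicted R, actual NR vs predicted NR. Within the actual view and
#' within the predicted view the two groups partition the evaluable cohort.
#'
#' @param result a `merged_cv_result` whose dataset carried `patient_id`s, or
#'   a predictions tibble with `sample_id`, `seed`, `class`.
#' @param cohort tibble with `patient_id`, `response_label`, `os_time`,
#'   `os_event`, `pfs_time`, `pfs_event`.
#' @param repetition which repetition's predictions to use: a seed value, or
#'   `"first"` (default, the first configured seed), or `"majority"` for a
#'   majority vote over all repetitions (ties go to nonresponder, the larger
#'   class).
#' @param id_length patient barcode prefix length (default 12).
#' @return a `group_comparison` list: `groups` (tibble group/endpoint/n/
#'   median), `tests` (tibble comparison/endpoint/statistic/p_value),
#'   `repetition`.
#' @export
compare_predicted_groups <- function(result, cohort, repetition = "first",
                                     id_length = 12) {
  preds <- if (inherits(result, "merged_cv_result")) result$predictions else result
  stopifnot(all(c("sample_id", "seed", "class") %in% names(preds)))
  if (identical(repetition, "first")) {
    rep_used <- min(preds$seed)
    pred_class <- preds[preds$seed == rep_used, c("sample_id", "class")]
  } else if (identical(repetition, "majority")) {
    rep_used <- "majority"
    pred_class <- preds |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(class = ifelse(
        mean(.data$class == .positive_class) > 0.5,
        .positive_class, "nonresponder"), .groups = "drop")
  } else {
    rep_used <- repetition
    if (!repetition %in% preds$seed) abort("repetition seed not found in predictions")
    pred_class <- preds[preds$seed == repetition, c("sample_id", "class")]
  }
  pred_class$patient_id <- substr(pred_class$sample_id, 1, id_length)
  joined <- dplyr::inner_join(pred_class, cohort, by = "patient_id")
  n_dropped <- nrow(pred_class) - nrow(joined)
  if (n_dropped > 0) {
    warn(sprintf("%d prediction(s) had no survival record and were dropped",
                 n_dropped))
  }

  views <- list(actual = joined$response_label, predicted = joined$class)
  endpoints <- list(OS = c("os_time", "os_event"),
                    PFS = c("pfs_time", "pfs_event"))
  groups <- purrr::map_dfr(names(views), function(v) {
    purrr::map_dfr(names(endpoints), function(ep) {
      cols <- endpoints[[ep]]
      purrr::map_dfr(.response_levels, function(lv) {
        sel <- views[[v]] == lv
        tibble(group = paste(v, lv, sep = "_"), endpoint = ep, n = sum(sel),
               median_survival = if (sum(sel)) {
                 km_median(joined[[cols[1]]][sel], joined[[cols[2]]][sel])
               } else NA_real_)
      })
    })
  })

  comparisons <- list(
    actual_R_vs_actual_NR = list(views$actual == .positive_class,
                                 views$actual != .positive_class),
    predicted_R_vs_predicted_NR = list(views$predicted == .positive_class,
                                       views$predicted != .positive_class),
    actual_R_vs_predicted_R = list(views$actual == .positive_class,
                                   views$predicted == .positive_class),
    actual_NR_vs_predicted_NR = list(views$actual != .positive_class,
                                     views$predicted != .positive_class))
  tests <- purrr::map_dfr(names(comparisons), function(cmp) {
    sel <- comparisons[[cmp]]
    purrr::map_dfr(names(endpoints), function(ep) {
      cols <- endpoints[[ep]]
      time <- c(joined[[cols[1]]][sel[[1]]], joined[[cols[1]]][sel[[2]]])
      event <- c(joined[[cols[2]]][sel[[1]]], joined[[cols[2]]][sel[[2]]])
      grp <- rep(c("g1", "g2"), c(sum(sel[[1]]), sum(sel[[2]])))
      lr <- if (sum(sel[[1]]) == 0 || sum(sel[[2]]) == 0 || sum(event) == 0) {
        tibble(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
      } else {
        logrank_test(time, event, grp)
      }
      dplyr::bind_cols(tibble(comparison = cmp, endpoint = ep), lr)
    })
  })

  structure(list(groups = groups, tests = tests, repetition = rep_used,
                 n_dropped = n_dropped), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> repetition = %s\n", x$repetition))
  print(x$groups)
  print(x$tests)
  invisible(x)
}

#' @rdname compare_predicted_groups
#' @param x a `group_comparison`.
#' @param ... unused.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$groups
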