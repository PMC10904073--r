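test_that("Welch's t test handles identical groups and rejects degenerate input", {
  out <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_error(welch_t(1, c(1, 2)), "nonzero variance")
  expect_error(welch_t(c(2, 2), c(3, 3)), "nonzero variance")
})

test_that("Welch p-values are uniform under the null", {
  set.seed(20)
  p <- replicate(1000, welch_t(rnorm(10), rnorm(12))$p_value)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("KM median matches a hand-worked product-limit table", {
  # 6 records: events at 2, 6, 8, 12; censored at 4 and 10.
  # S(2)=5/6, S(6)=5/6*3/4=0.625, S(8)=0.625*2/3=5/12, S(12)=0
  time <- c(2, 4, 6, 8, 10, 12)
  event <- c(1, 0, 1, 1, 0, 1)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  expect_equal(fit$surv[fit$time == 2], 5 / 6)
  expect_equal(fit$surv[fit$time == 6], 0.625)
  expect_equal(fit$surv[fit$time == 8], 5 / 12)
  # first time the curve reaches 0.5 or below is 8
  expect_equal(km_median(time, event), 8)
})

test_that("KM median follows the 50%-survival rule and undefined cases", {
  expect_equal(km_median(c(1, 2, 3, 4), rep(1, 4)), 2)
  expect_true(is.na(km_median(c(5, 8, 10), c(0, 0, 0))))  # all censored
})

test_that("KM with no censoring reduces to the empirical survival function", {
  set.seed(3)
  time <- rexp(25, 0.1)
  fit <- survival::survfit(survival::Surv(time, rep(1, 25)) ~ 1)
  emp <- vapply(fit$time, function(t) mean(time > t), numeric(1))
  expect_equal(fit$surv, emp)
})

test_that("log-rank matches an independently coded event-table computation", {
  time <- c(2, 5, 8, 12, 16, 20, 4, 6, 9, 11, 15, 30)
  event <- c(1, 0, 1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  group <- rep(c("a", "b"), each = 6)
  out <- logrank_test(time, event, group)
  expect_equal(out$statistic, bf_logrank(time, event, group), tolerance = 1e-8)
  expect_equal(out$p_value,
               pchisq(bf_logrank(time, event, group), 1, lower.tail = FALSE),
               tolerance = 1e-8)
  # invariant to time-unit rescaling
  out_scaled <- logrank_test(time * 12, event, group)
  expect_equal(out$statistic, out_scaled$statistic, tolerance = 1e-10)
  # identical groups give statistic ~ 0, p ~ 1
  same <- logrank_test(rep(time[1:6], 2), rep(event[1:6], 2),
                       rep(c("a", "b"), each = 6))
  expect_lt(same$statistic, 1e-10)
  expect_equal(same$p_value, 1, tolerance = 1e-6)
  # no events -> undefined
  none <- logrank_test(c(1, 2, 3, 4), rep(0, 4), rep(c("a", "b"), 2))
  expect_true(is.na(none$statistic))
})

test_that("two-group log-rank p matches the Cox score-test p at large n", {
  co <- generate_cohort(synth_config(
    n_samples = 200, n_nonresponders = 100, seed = 15,
    survival = list(hr_responder = 0.6, censor_rate = 0.1)))
  lr <- logrank_test(co$os_time, co$os_event, co$response_label)
  fit <- survival::coxph(
    survival::Surv(os_time, os_event) ~ I(response_label == "responder"),
    data = co, ties = "breslow")
  expect_equal(lr$p_value, unname(summary(fit)$sctest["pvalue"]),
               tolerance = 0.02)
})

test_that("Cox fit recovers null and planted hazard ratios and flags aliasing", {
  co <- generate_cohort(synth_config(
    n_samples = 400, n_nonresponders = 200, seed = 21,
    survival = list(hr_responder = 1, censor_rate = 0)))
  co$coin <- withr::with_seed(5, rbinom(nrow(co), 1, 0.5))
  null_fit <- cox_fit(co, covariates = "coin", type = "univariate")
  expect_gt(null_fit$hr, 0.8)
  expect_lt(null_fit$hr, 1.25)
  expect_true(null_fit$conf_low <= null_fit$hr & null_fit$hr <= null_fit$conf_high)

  co2 <- generate_cohort(synth_config(
    n_samples = 400, n_nonresponders = 200, seed = 22,
    survival = list(hr_responder = 0.4, censor_rate = 0)))
  co2$responder <- as.integer(co2$response_label == "responder")
  fit <- cox_fit(co2, covariates = "responder", type = "univariate")
  expect_lt(abs(fit$hr - 0.4), 0.1)  # within 25% of the generating HR

  co2$responder_copy <- co2$responder
  expect_error(cox_fit(co2, covariates = c("responder", "responder_copy"),
                       type = "multivariate"), "rank-deficient")
})

test_that("univariate Cox fits one model per covariate; multivariate one joint model", {
  co <- generate_cohort(synth_config(n_samples = 100, n_nonresponders = 60,
                                     seed = 30))
  co$f1 <- withr::with_seed(1, rnorm(100))
  co$f2 <- withr::with_seed(2, rnorm(100))
  uni <- cox_fit(co, covariates = c("f1", "f2"), type = "univariate")
  multi <- cox_fit(co, covariates = c("f1", "f2"), type = "multivariate")
  expect_equal(nrow(uni), 2)
  expect_equal(nrow(multi), 2)
  expect_true(all(uni$model == "univariate"))
  expect_true(all(multi$model == "multivariate"))
  expect_true(all(multi$hr > 0))
})

test_that("predicted groups equal actual groups when predictions are perfect", {
  co <- generate_cohort(synth_config(seed = 2))
  preds <- tibble::tibble(sample_id = co$patient_id, seed = 0L,
                          class = co$response_label)
  cmp <- compare_predicted_groups(preds, co)
  g <- cmp$groups
  for (ep in c("OS", "PFS")) {
    for (lv in c("responder", "nonresponder")) {
      expect_equal(
        g$median_survival[g$group == paste0("actual_", lv) & g$endpoint == ep],
        g$median_survival[g$group == paste0("predicted_", lv) & g$endpoint == ep])
    }
  }
  expect_equal(sum(g$n[g$endpoint == "OS" & grepl("^actual", g$group)]), 70)
  # actual-vs-predicted comparisons of identical groups: statistic ~ 0
  same <- cmp$tests[cmp$tests$comparison == "actual_R_vs_predicted_R", ]
  expect_true(all(same$statistic < 1e-10))
})

test_that("an accurate classifier propagates the planted survival advantage", {
  cfg <- synth_config(n_features = 50, n_informative = 5, effect_size = 2,
                      seed = 17, survival = list(hr_responder = 0.4))
  co <- generate_cohort(cfg)
  pr <- generate_profile(cfg, co$response_label)
  ds <- join_profile_to_cohort(pr, co)
  res <- run_merged_cv(ds, model_spec("rf"), cv_config(k = 5, seeds = 0))
  expect_gt(res$summary$mmcc, 0.5)  # the classifier is accurate here
  cmp <- compare_predicted_groups(res, co)
  g <- cmp$groups[cmp$groups$endpoint == "OS", ]
  expect_gt(g$median_survival[g$group == "predicted_responder"],
            g$median_survival[g$group == "predicted_nonresponder"])
})
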