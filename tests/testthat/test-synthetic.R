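test_that("cohort generator honors the configured class split and is deterministic", {
  cfg <- synth_config(seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 70)
  expect_equal(sum(co$response_label == "nonresponder"), 41)
  expect_equal(sum(co$best_response %in% c("SD", "PD")), 41)
  expect_equal(sum(co$best_response %in% c("CR", "PR")), 29)
  expect_identical(co, generate_cohort(cfg))
  expect_false(identical(co, generate_cohort(synth_config(seed = 4))))
})

test_that("generated survival respects PFS <= OS and time/event contracts", {
  co <- generate_cohort(synth_config(seed = 7, survival = list(censor_rate = 0.4)))
  expect_true(all(co$pfs_time <= co$os_time + 1e-12))
  expect_true(all(co$os_time >= 0))
  expect_true(all(co$os_event %in% 0:1))
  expect_true(all(co$pfs_event %in% 0:1))
  # a censored OS cut before progression must censor PFS too
  cut_short <- co$os_event == 0 & co$pfs_time == co$os_time
  expect_true(all(co$pfs_event[cut_short] == 0))
})

test_that("degenerate class configurations are rejected", {
  expect_error(synth_config(n_samples = 70, n_nonresponders = 70), "degenerate")
  expect_error(synth_config(n_samples = 70, n_nonresponders = 0), "n_nonresponders")
  expect_error(synth_config(n_informative = 20, n_features = 10), "n_informative")
  expect_error(synth_config(survival = list(censor_rate = 1)), "censor_rate")
})

test_that("with no planted survival effect the log-rank p-value is null-uniform", {
  pvals <- vapply(1:40, function(s) {
    co <- generate_cohort(synth_config(
      seed = s, survival = list(hr_responder = 1, censor_rate = 0)))
    logrank_test(co$os_time, co$os_event, co$response_label)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Cox regression recovers the generating hazard ratio at large n", {
  co <- generate_cohort(synth_config(
    n_samples = 400, n_nonresponders = 200, seed = 11,
    survival = list(hr_responder = 0.4, censor_rate = 0)))
  co$responder <- as.integer(co$response_label == "responder")
  fit <- cox_fit(co, covariates = "responder", type = "univariate")
  expect_gt(fit$hr, 0.3)
  expect_lt(fit$hr, 0.55)
})

test_that("profile values respect each kind's range by construction", {
  co <- generate_cohort(synth_config(seed = 2))
  for (kind in c("beta", "cgi")) {
    pr <- generate_profile(synth_config(seed = 2, profile_kind = kind,
                                        n_features = 50),
                           co$response_label)
    expect_true(all(pr$values >= 0 & pr$values <= 1))
  }
  pr <- generate_profile(synth_config(seed = 2, profile_kind = "fpkm",
                                      n_features = 50), co$response_label)
  expect_true(all(pr$values >= 0))
  pr <- generate_profile(synth_config(seed = 2, profile_kind = "cnv",
                                      n_features = 50), co$response_label)
  expect_equal(mean(pr$values), 2, tolerance = 0.1)
})

test_that("planted features carry the info_ prefix and occupy the first columns", {
  d <- make_signal_dataset(k_info = 3)
  ids <- colnames(d$profile$values)
  expect_identical(ids[1:3], sprintf("info_%04d", 1:3))
  expect_false(any(grepl("^info_", ids[-(1:3)])))
})

test_that("a zero effect size yields null-calibrated feature-level tests", {
  cfg <- synth_config(n_features = 2000, n_informative = 0, effect_size = 0,
                      profile_kind = "log2rpm", seed = 5)
  co <- generate_cohort(cfg)
  pr <- generate_profile(cfg, co$response_label)
  resp <- co$response_label == "responder"
  p <- apply(pr$values, 2, function(v) {
    t.test(v[resp], v[!resp])$p.value
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("ANOVA ranking recovers planted features at the study's effect size", {
  cfg <- synth_config(seed = 1)  # n=70, 41/29, p=1000, 5 planted at delta 1.5
  co <- generate_cohort(cfg)
  pr <- generate_profile(cfg, co$response_label)
  ranking <- rank_features_anova(pr$values, co$response_label)
  top35 <- ranking$feature_id[1:35]
  expect_gte(sum(grepl("^info_", top35)), 4)
})

test_that("cnv segment generator retains exact gene-level ground truth", {
  cfg <- synth_config(n_samples = 8, n_nonresponders = 5, n_features = 50,
                      profile_kind = "cnv_segments", seed = 9)
  gen <- generate_cnv_segments(cfg)
  expect_true(all(table(gen$segments$sample_id) == 20))
  # every gene overlaps >= 1 segment: the truth has no NA
  expect_false(anyNA(gen$truth_mean))
  agg_mean <- aggregate_segments_to_genes(gen$segments, gen$genes, "mean")
  agg_median <- aggregate_segments_to_genes(gen$segments, gen$genes, "median")
  expect_equal(agg_mean$values, gen$truth_mean)
  expect_equal(agg_median$values, gen$truth_median)
})

test_that("generate_profile rejects the segment kind and misaligned labels", {
  cfg <- synth_config(profile_kind = "cnv_segments")
  co <- generate_cohort(cfg)
  expect_error(generate_profile(cfg, co$response_label), "cnv_segments")
  cfg2 <- synth_config()
  expect_error(generate_profile(cfg2, co$response_label[1:10]), "length")
})
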