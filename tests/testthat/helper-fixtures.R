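# Shared fixtures and independent oracles used across test files.

# A small synthetic dataset with planted signal, joined and ready for CV.
make_signal_dataset <- function(n = 40, n_nr = 24, p = 60, k_info = 3,
                                effect = 1.5, seed = 1, kind = "fpkm") {
  cfg <- synth_config(n_samples = n, n_nonresponders = n_nr, n_features = p,
                      n_informative = k_info, effect_size = effect,
                      profile_kind = kind, seed = seed)
  cohort <- generate_cohort(cfg)
  profile <- generate_profile(cfg, cohort$response_label)
  list(cfg = cfg, cohort = cohort, profile = profile,
       dataset = join_profile_to_cohort(profile, cohort))
}

# Brute-force MCC from raw label/prediction vectors: the MCC of a 2x2 table
# is the Pearson correlation of the binary indicators, undefined (NA) when
# either vector is constant.
bf_mcc <- function(truth, predicted, positive = "responder") {
  t01 <- as.integer(as.character(truth) == positive)
  p01 <- as.integer(as.character(predicted) == positive)
  suppressWarnings(stats::cor(t01, p01))
}

# Brute-force O(n^2) pairwise-concordance AUC with half-weight ties.
bf_auc <- function(scores, labels, positive = "responder") {
  pos <- scores[as.character(labels) == positive]
  neg <- scores[as.character(labels) != positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (sp in pos) total <- total + sum(sp > neg) + 0.5 * sum(sp == neg)
  total / (length(pos) * length(neg))
}

# Independent textbook log-rank computation from the per-event-time table.
bf_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))  # 1/2
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n1 <- sum(at_risk & g == 1)
    n2 <- sum(at_risk & g == 2)
    nt <- n1 + n2
    d1 <- sum(time == t & event == 1 & g == 1)
    d <- sum(time == t & event == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / nt)
    if (nt > 1) v <- v + d * (n1 / nt) * (n2 / nt) * (nt - d) / (nt - 1)
  }
  o_minus_e^2 / v
}

# Ten-patient toy clinical table: 2 missing responses, 1 inconsistent
# response, 1 treated before tumor procurement; 6 survive curation.
toy_clinical_records <- function() {
  tibble::tribble(
    ~patient_id, ~drug_name,       ~best_response, ~treatment_start, ~procurement_day,
    "P01",       "gemcitabine",    "PR",           10L,              0L,
    "P01",       "fluorouracil",   "PD",           40L,              0L,
    "P02",       "Gemzar",         "SD",           15L,              0L,
    "P03",       "gemcitabine",    NA,             12L,              0L,
    "P04",       "gemcitabine",    NA,             9L,               0L,
    "P05",       "gemcitabine",    "PR",           11L,              0L,
    "P05",       "gemcitabine",    "PD",           30L,              0L,
    "P06",       "gemcitabine",    "CR",           -5L,              0L,
    "P07",       "gemcitabine",    "PD",           14L,              0L,
    "P08",       "gemcitabine",    "SD",           21L,              0L,
    "P09",       "gemcitabine",    "CR",           13L,              0L,
    "P09",       "gemcitabine",    "PR",           45L,              0L,
    "P10",       "gemcitabine",    "PD",           16L,              0L)
}
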