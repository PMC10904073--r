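#' Configuration for the synthetic cohort and profile generator
#'
#' The generator emulates the study conditions of a small gemcitabine-treated
#' pancreatic-cancer cohort: 70 tumors with a 41/29 nonresponder/responder
#' imbalance, high-dimensional molecular profiles with a small planted subset
#' of informative features, and survival times stochastically longer for
#' responders. All downstream stages (curation, preprocessing, merged CV, OMC
#' selection, survival comparison) are testable against the planted structure.
#'
#' Informative features are generated on a latent Gaussian scale with a
#' class-conditional mean shift of `effect_size` standard deviations, then
#' mapped into the value range of the requested profile kind, so one effect
#' size has a uniform meaning across kinds.
#'
#' @param n_samples total number of patients (default 70).
#' @param n_nonresponders number with SD/PD best response (default 41).
#' @param n_features number of profile features (default 1000).
#' @param n_informative number of planted informative features; these occupy
#'   the first columns and carry an `info_` ID prefix (default 5).
#' @param effect_size standardized latent mean shift between classes
#'   (default 1.5).
#' @param profile_kind one of `"fpkm"`, `"fpkm_uq"`, `"log2rpm"`, `"beta"`,
#'   `"cgi"`, `"cnv"`, `"cnv_segments"`.
#' @param noise_sd latent standard deviation (default 1).
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @param survival list with `baseline_median_nr` (months, median overall
#'   survival of nonresponders; default 20), `hr_responder` (hazard ratio of
#'   responders vs nonresponders; default 0.4) and `censor_rate`
#'   (fraction censored, in \[0,1); default 0.2).
#' @param block_correlation optional equicorrelation within blocks of 10
#'   features (default 0, i.e. independent features).
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_samples = 70, n_nonresponders = 41,
                         n_features = 1000, n_informative = 5,
                         effect_size = 1.5,
                         profile_kind = c("fpkm", "fpkm_uq", "log2rpm",
                                          "beta", "cgi", "cnv",
                                          "cnv_segments"),
                         noise_sd = 1, seed = 0,
                         survival = list(),
                         block_correlation = 0) {
  profile_kind <- match.arg(profile_kind)
  assert_count(n_samples, "n_samples", 2)
  assert_count(n_nonresponders, "n_nonresponders", 1)
  if (n_nonresponders >= n_samples) {
    abort("degenerate config: need at least one responder (n_nonresponders < n_samples)")
  }
  assert_count(n_features, "n_features", 1)
  if (n_informative > n_features) abort("n_informative must be <= n_features")
  if (effect_size < 0) abort("effect_size must be >= 0")
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  surv <- modifyList(
    list(baseline_median_nr = 20, hr_responder = 0.4, censor_rate = 0.2),
    survival)
  if (surv$censor_rate < 0 || surv$censor_rate >= 1) {
    abort("censor_rate must lie in [0, 1)")
  }
  structure(list(
    n_samples = as.integer(n_samples),
    n_nonresponders = as.integer(n_nonresponders),
    n_features = as.integer(n_features),
    n_informative = as.integer(n_informative),
    effect_size = effect_size, profile_kind = profile_kind,
    noise_sd = noise_sd, seed = as.integer(seed), survival = surv,
    block_correlation = block_correlation), class = "synth_config")
}

#' Generate a synthetic clinical cohort
#'
#' Draws per-patient best-response codes (CR/PR for responders, SD/PD for
#' nonresponders), overall survival from exponential models in which the
#' responder hazard is `hr_responder` times the nonresponder hazard, and
#' progression-free survival as OS times a Uniform(0.3, 1) factor so that
#' PFS <= OS always holds. Both endpoints run from diagnosis, OS to death and
#' PFS to progression. Censoring truncates follow-up at a uniform fraction of
#' the true OS time for a `censor_rate` fraction of patients; a censored
#' follow-up also censors PFS when it cuts in before progression.
#'
#' @param config a [synth_config()].
#' @return a tibble with columns `patient_id`, `response_label`,
#'   `best_response`, `os_time`, `os_event`, `pfs_time`, `pfs_event`
#'   (times in months).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_samples
  n_nr <- config$n_nonresponders
  surv <- config$survival
  with_seed(sub_seed(config$seed, 11), {
    label <- sample(rep(.response_levels, c(n_nr, n - n_nr)))
    best_response <- ifelse(label == "responder",
                            sample(c("CR", "PR"), n, replace = TRUE),
                            sample(c("SD", "PD"), n, replace = TRUE))
    rate_nr <- log(2) / surv$baseline_median_nr
    rate <- ifelse(label == "responder", surv$hr_responder * rate_nr, rate_nr)
    os_true <- rexp(n, rate)
    pfs_true <- os_true * runif(n, 0.3, 1)
    censored <- rbinom(n, 1, surv$censor_rate) == 1
    followup <- ifelse(censored, os_true * runif(n), os_true)
    os_time <- followup
    os_event <- as.integer(!censored)
    pfs_event <- as.integer(pfs_true <= followup)
    pfs_time <- pmin(pfs_true, followup)
    tibble(
      patient_id = sprintf("SYN-%04d", seq_len(n)),
      response_label = label,
      best_response = best_response,
      os_time = os_time, os_event = os_event,
      pfs_time = pfs_time, pfs_event = pfs_event)
  })
}

# Map a latent Gaussian matrix into the value range of a profile kind.
latent_to_kind <- function(z, profile_kind) {
  switch(profile_kind,
    fpkm = list(values = exp(z), kind = "fpkm"),
    fpkm_uq = list(values = exp(z), kind = "fpkm_uq"),
    log2rpm = list(values = z, kind = "mirna_log2rpm"),
    beta = list(values = plogis(z), kind = "cpg_beta"),
    cgi = list(values = plogis(z), kind = "cgi_beta"),
    cnv = list(values = 2 + z, kind = "cnv_mean"),
    abort(sprintf("unsupported profile_kind '%s'", profile_kind)))
}

#' Generate a synthetic omics profile with planted informative features
#'
#' The first `n_informative` features carry a class-conditional latent mean
#' shift of `effect_size * noise_sd` (responders higher); the rest are pure
#' noise. Latent values are mapped to the profile kind's range: `exp` for
#' FPKM kinds, a logistic squash into (0, 1) for beta kinds, identity for
#' log2-RPM, and an additive shift around the neutral copy number 2 for CNV.
#'
#' @param config a [synth_config()]; `profile_kind` must not be
#'   `"cnv_segments"` (use [generate_cnv_segments()] for segment tables).
#' @param labels character/factor vector of response labels, one per sample,
#'   aligned with the generated rows.
#' @return an [omics_profile()] with sample IDs `SYN-0001...` and feature IDs
#'   `info_*` (planted) then `feat_*` (noise).
#' @export
generate_profile <- function(config, labels) {
  stopifnot(inherits(config, "synth_config"))
  if (config$profile_kind == "cnv_segments") {
    abort("profile_kind 'cnv_segments' is generated by generate_cnv_segments()")
  }
  labels <- as_response_factor(labels)
  n <- config$n_samples
  if (length(labels) != n) abort("labels length must equal n_samples")
  p <- config$n_features
  k <- config$n_informative
  with_seed(sub_seed(config$seed, 23), {
    z <- matrix(rnorm(n * p, sd = config$noise_sd), n, p)
    if (config$block_correlation > 0) {
      rho <- config$block_correlation
      block <- (seq_len(p) - 1) %/% 10
      f <- matrix(rnorm(n * (max(block) + 1), sd = config$noise_sd),
                  n, max(block) + 1)
      z <- sqrt(1 - rho) * z + sqrt(rho) * f[, block + 1, drop = FALSE]
    }
    if (k > 0 && config$effect_size > 0) {
      shift <- config$effect_size * config$noise_sd
      z[labels == .positive_class, seq_len(k)] <-
        z[labels == .positive_class, seq_len(k)] + shift
    }
    mapped <- latent_to_kind(z, config$profile_kind)
    ids <- c(if (k > 0) sprintf("info_%04d", seq_len(k)),
             if (p > k) sprintf("feat_%04d", seq_len(p - k)))
    dimnames(mapped$values) <- list(sprintf("SYN-%04d", seq_len(n)), ids)
    omics_profile(mapped$values, mapped$kind)
  })
}

#' Generate synthetic copy-number segment tables with known gene-level truth
#'
#' Builds, per sample, a set of segments partitioning one synthetic chromosome
#' (0-based half-open coordinates) with values around the neutral copy number
#' 2, plus a gene interval table in which every gene overlaps at least one
#' segment. The per-gene mean and median over overlapping segments are
#' computed directly by the generator and returned as ground truth, so the
#' interval-overlap aggregation path can be tested for exact equality.
#'
#' @param config a [synth_config()]; `n_features` is the number of genes.
#' @param n_segments segments per sample (default 20).
#' @param chrom_length chromosome length in bp (default 1e6).
#' @return list with `segments` (tibble: sample_id, chrom, start, end, value),
#'   `genes` (tibble: gene_id, chrom, start, end), and ground-truth matrices
#'   `truth_mean`, `truth_median` (samples x genes).
#' @export
generate_cnv_segments <- function(config, n_segments = 20,
                                  chrom_length = 1e6) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_samples
  n_genes <- config$n_features
  with_seed(sub_seed(config$seed, 37), {
    segs <- purrr::map_dfr(seq_len(n), function(i) {
      cuts <- sort(sample.int(chrom_length - 1, n_segments - 1))
      start <- c(0, cuts)
      end <- c(cuts, chrom_length)
      tibble(sample_id = sprintf("SYN-%04d", i), chrom = "chr1",
             start = start, end = end,
             value = 2 + rnorm(n_segments, sd = config$noise_sd))
    })
    gene_start <- sample.int(chrom_length - 2001, n_genes)
    gene_len <- sample(500:2000, n_genes, replace = TRUE)
    genes <- tibble(gene_id = sprintf("gene_%04d", seq_len(n_genes)),
                    chrom = "chr1", start = gene_start,
                    end = gene_start + gene_len)
  })
  # Ground truth by direct interval arithmetic, independent of the
  # GenomicRanges-based aggregation path.
  samples <- sprintf("SYN-%04d", seq_len(n))
  truth_mean <- matrix(NA_real_, n, n_genes, dimnames = list(samples, genes$gene_id))
  truth_median <- truth_mean
  for (i in seq_len(n)) {
    s <- segs[segs$sample_id == samples[i], ]
    for (g in seq_len(n_genes)) {
      ov <- s$value[s$start < genes$end[g] & s$end > genes$start[g]]
      truth_mean[i, g] <- mean(ov)
      truth_median[i, g] <- stats::median(ov)
    }
  }
  list(segments = segs, genes = genes,
       truth_mean = truth_mean, truth_median = truth_median)
}

#' Write the synthetic cohort as CSV / segments as BED-like TSV
#'
#' @param cohort tibble from [generate_cohort()].
#' @param segments tibble from [generate_cnv_segments()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
write_segments_bed <- function(segments, path) {
  readr::write_tsv(segments[, c("chrom", "start", "end", "value", "sample_id")],
                   path, col_names = FALSE)
  invisible(path)
}
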