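#' Default drug synonym map for gemcitabine
#'
#' Lower-cased free-text variants mapped to the canonical drug name, covering
#' the misspellings and trade names commonly found in clinical drug records.
#'
#' @return named character vector (names = lower-cased variants, values =
#'   canonical names).
#' @export
gemcitabine_synonyms <- function() {
  c("gemcitabine" = "gemcitabine",
    "gemzar" = "gemcitabine",
    "gemcitabine hcl" = "gemcitabine",
    "gemcitabine hydrochloride" = "gemcitabine",
    "gemcitibine" = "gemcitabine",
    "gemcitabine injection" = "gemcitabine")
}

#' Standardize free-text drug names against a synonym map
#'
#' Matching is case-insensitive and trims/collapses whitespace. Names without
#' a map entry pass through unchanged, with one warning listing them, so that
#' curation is lenient to drugs outside the study's scope.
#'
#' @param records data frame with a `drug_name` column.
#' @param synonym_map named character vector mapping lower-cased variants to
#'   canonical names; default [gemcitabine_synonyms()].
#' @return `records` with `drug_name` replaced by its canonical form where
#'   mapped.
#' @export
standardize_drug_names <- function(records, synonym_map = gemcitabine_synonyms()) {
  key <- tolower(gsub("\\s+", " ", trimws(records$drug_name)))
  mapped <- unname(synonym_map[key])
  unmapped <- is.na(mapped)
  if (any(unmapped)) {
    warn(paste0("unmapped drug name(s) passed through: ",
                paste(unique(records$drug_name[unmapped]), collapse = ", ")))
  }
  records$drug_name <- ifelse(unmapped, records$drug_name, mapped)
  records
}

#' Binarize best-response codes into responder / nonresponder
#'
#' CR and PR (complete/partial response) become `"responder"`; SD and PD
#' (stable/progressive disease) become `"nonresponder"`. Missing or unknown
#' codes are an error — records must be filtered first.
#'
#' @param best_response character vector of RECIST-style codes.
#' @return character vector of `"responder"` / `"nonresponder"`.
#' @export
binarize_response <- function(best_response) {
  map <- c(CR = "responder", PR = "responder",
           SD = "nonresponder", PD = "nonresponder")
  out <- unname(map[as.character(best_response)])
  if (anyNA(out)) {
    bad <- unique(best_response[is.na(out)])
    abort(paste0("cannot binarize best_response value(s): ",
                 paste(ifelse(is.na(bad), "<missing>", bad), collapse = ", "),
                 " (filter missing responses first)"))
  }
  out
}

#' Curate drug records into a one-row-per-patient cohort
#'
#' Applies the study's exclusion rules, in a fixed order, to standardized
#' drug records:
#' 1. keep only patients with at least one record of the target drug;
#' 2. drop patients with a missing best response on a target-drug record;
#' 3. drop patients whose target-drug records carry contradictory binarized
#'    responses (judged on the responder/nonresponder label, so PR + CR is
#'    consistent);
#' 4. drop patients whose treatment started before tumor procurement.
#'
#' Any record naming the canonical drug counts as a target-drug record,
#' including combination regimens. A per-rule exclusion tally is attached as
#' the `"exclusions"` attribute and also returned by [cohort_exclusions()].
#'
#' @param records data frame with columns `patient_id`, `drug_name`,
#'   `best_response` (CR/PR/SD/PD or NA), and optionally `treatment_start`,
#'   `procurement_day` (day offsets) plus survival columns (`os_time`,
#'   `os_event`, `pfs_time`, `pfs_event`) that are carried through.
#' @param drug canonical target drug name (default `"gemcitabine"`).
#' @return a tibble with one row per surviving patient: `patient_id`,
#'   `response_label`, `best_response`, carried-through columns.
#' @export
filter_cohort <- function(records, drug = "gemcitabine") {
  records <- as_tibble(records)
  patients_in <- unique(records$patient_id)

  rec <- records[records$drug_name == drug, , drop = FALSE]
  kept_drug <- unique(rec$patient_id)
  n_no_drug <- length(setdiff(patients_in, kept_drug))

  missing_pat <- unique(rec$patient_id[is.na(rec$best_response) |
                                         rec$best_response == ""])
  rec <- rec[!rec$patient_id %in% missing_pat, , drop = FALSE]
  n_missing <- length(missing_pat)

  lab <- binarize_response(rec$best_response)
  inconsistent_pat <- names(which(tapply(lab, rec$patient_id,
                                         function(x) length(unique(x)) > 1)))
  rec <- rec[!rec$patient_id %in% inconsistent_pat, , drop = FALSE]
  n_inconsistent <- length(inconsistent_pat)

  n_pre <- 0L
  if (all(c("treatment_start", "procurement_day") %in% names(rec))) {
    pre_pat <- unique(rec$patient_id[!is.na(rec$treatment_start) &
                                       !is.na(rec$procurement_day) &
                                       rec$treatment_start < rec$procurement_day])
    rec <- rec[!rec$patient_id %in% pre_pat, , drop = FALSE]
    n_pre <- length(pre_pat)
  }

  out <- rec |>
    dplyr::arrange(.data$patient_id) |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::mutate(response_label = binarize_response(.data$best_response),
                  .after = "patient_id")
  if (nrow(out) == 0) warn("no patients survive curation")
  attr(out, "exclusions") <- tibble(
    rule = c("no_target_drug", "missing_response", "inconsistent_response",
             "pre_resection_treatment"),
    n_excluded = c(n_no_drug, n_missing, n_inconsistent, n_pre))
  out
}

#' Per-rule exclusion tally of a curated cohort
#'
#' @param cohort result of [filter_cohort()].
#' @return tibble with columns `rule`, `n_excluded`.
#' @export
cohort_exclusions <- function(cohort) {
  attr(cohort, "exclusions") %||%
    abort("no exclusion tally attached; was this produced by filter_cohort()?")
}

#' Match an omics profile to a curated cohort by patient ID
#'
#' Profile sample IDs are truncated to their patient-level prefix (the first
#' `id_length` characters, 12 for TCGA-style barcodes; shorter IDs are used
#' as-is) and inner-joined with the cohort's patient IDs. When several samples
#' map to one patient, the first after sorting sample IDs is kept with a
#' warning. Samples without a label and labels without a sample are dropped
#' and counted.
#'
#' @param profile an [omics_profile()].
#' @param cohort data frame with `patient_id` and `response_label` columns
#'   (and optionally survival columns, carried into the result).
#' @param id_length patient-level barcode prefix length (default 12).
#' @return a `matched_dataset`: list with `x` (samples x features matrix),
#'   `labels` (factor aligned to rows), `sample_id`, `patient_id`, `kind`,
#'   `cohort` (matched rows), and drop counts `n_unmatched_samples`,
#'   `n_unmatched_patients`.
#' @export
join_profile_to_cohort <- function(profile, cohort, id_length = 12) {
  sid <- sort(sample_ids(profile))
  pid <- substr(sid, 1, id_length)
  dup <- duplicated(pid)
  if (any(dup)) {
    warn(sprintf("%d duplicate sample(s) per patient; keeping first by sorted sample ID",
                 sum(dup)))
    sid <- sid[!dup]
    pid <- pid[!dup]
  }
  common <- intersect(pid, cohort$patient_id)
  keep <- pid %in% common
  matched_cohort <- cohort[match(pid[keep], cohort$patient_id), , drop = FALSE]
  x <- profile$values[sid[keep], , drop = FALSE]
  structure(list(
    x = x,
    labels = as_response_factor(matched_cohort$response_label),
    sample_id = sid[keep],
    patient_id = pid[keep],
    kind = profile$kind,
    cohort = as_tibble(matched_cohort),
    n_unmatched_samples = sum(!keep),
    n_unmatched_patients = length(setdiff(cohort$patient_id, pid))),
    class = "matched_dataset")
}

#' @export
print.matched_dataset <- function(x, ...) {
  cat(sprintf("<matched_dataset> %s: %d samples x %d features (%s)\n",
              x$kind, nrow(x$x), ncol(x$x),
              paste(sprintf("%d %s", table(x$labels), levels(x$labels)),
                    collapse = ", ")))
  invisible(x)
}
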