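#' Validate a pipeline run configuration
#'
#' The configuration is a plain named list; unknown keys are rejected before
#' any computation so typos cannot silently change a run.
#'
#' @param config named list with (all optional): `synthetic` (a
#'   [synth_config()] or list of arguments for one), `profile_kinds`
#'   (character vector of kinds to generate), `algorithms`, `modes`, `cv` (a
#'   [cv_config()]), `omc` (an [omc_control()]), `baseline_feature` (feature
#'   ID for the single-gene baseline, or `NULL` to skip), `survival_model`
#'   (cell key whose predictions feed the group comparison; default the first
#'   OMC cell), `out_dir` (directory for CSV/JSON artifacts, or `NULL` to skip
#'   writing).
#' @return the completed config, invisibly.
#' @export
validate_run_config <- function(config) {
  known <- c("synthetic", "profile_kinds", "algorithms", "modes", "cv", "omc",
             "baseline_feature", "survival_model", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults <- list(
    synthetic = synth_config(),
    profile_kinds = "fpkm",
    algorithms = c("rf", "logistic"),
    modes = c("all_features", "omc"),
    cv = cv_config(), omc = omc_control(),
    baseline_feature = NULL, survival_model = NULL, out_dir = NULL)
  config <- modifyList(defaults, config)
  if (is.list(config$synthetic) && !inherits(config$synthetic, "synth_config")) {
    config$synthetic <- do.call(synth_config, config$synthetic)
  }
  bad_alg <- setdiff(config$algorithms, algorithm_ids())
  if (length(bad_alg) > 0) {
    abort(paste0("config field 'algorithms' names unknown algorithm(s): ",
                 paste(bad_alg, collapse = ", ")))
  }
  if (!all(config$modes %in% c("all_features", "omc"))) {
    abort("config field 'modes' must be a subset of all_features, omc")
  }
  invisible(config)
}

#' Run the full synthetic-data screening pipeline
#'
#' End-to-end orchestration: generate a synthetic cohort and profiles,
#' evaluate the profile x algorithm x mode grid by merged CV, run the
#' single-feature baseline, and compare survival of actual versus predicted
#' responder groups using the designated cell's predictions. When `out_dir`
#' is set, writes the grid (long CSV + summary JSON), merged predictions CSV,
#' group comparison CSV, and a run manifest JSON recording seeds, algorithm
#' hyperparameter defaults, and package version.
#'
#' @param config named list, validated by [validate_run_config()].
#' @return a `pipeline_result` list: `cohort`, `profiles`, `grid`, `baseline`,
#'   `survival_comparison`, `config`.
#' @export
run_pipeline <- function(config = list()) {
  config <- validate_run_config(config)
  sc <- config$synthetic
  cohort <- generate_cohort(sc)
  profiles <- lapply(config$profile_kinds, function(kd) {
    sck <- sc
    sck$profile_kind <- kd
    generate_profile(sck, cohort$response_label)
  })
  names(profiles) <- config$profile_kinds

  grid <- evaluate_grid(profiles, cohort, algorithms = config$algorithms,
                        modes = config$modes, cv = config$cv,
                        omc = config$omc)

  baseline <- NULL
  if (!is.null(config$baseline_feature)) {
    ds <- join_profile_to_cohort(profiles[[1]], cohort)
    base_algs <- intersect(c("rf", "xgboost"), config$algorithms)
    if (length(base_algs) == 0) base_algs <- config$algorithms[1]
    baseline <- single_gene_model(ds, config$baseline_feature,
                                  algorithms = base_algs, cv = config$cv)
  }

  surv_key <- config$survival_model %||% {
    omc_keys <- grep("\\|omc$", names(grid$results), value = TRUE)
    if (length(omc_keys)) omc_keys[1] else names(grid$results)[1]
  }
  survival_comparison <- NULL
  if (!is.null(surv_key) && surv_key %in% names(grid$results)) {
    survival_comparison <- compare_predicted_groups(grid$results[[surv_key]],
                                                    cohort)
  }

  out <- structure(list(cohort = cohort, profiles = profiles, grid = grid,
                        baseline = baseline,
                        survival_comparison = survival_comparison,
                        survival_model = surv_key, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- result$grid
  readr::write_csv(grid$metrics, file.path(out_dir, "grid_metrics.csv"))
  readr::write_csv(grid$cells, file.path(out_dir, "grid_summary.csv"))
  preds <- dplyr::bind_rows(lapply(names(grid$results), function(k) {
    dplyr::bind_cols(tibble(cell = k), grid$results[[k]]$predictions)
  }))
  readr::write_csv(preds, file.path(out_dir, "merged_predictions.csv"))
  if (!is.null(result$survival_comparison)) {
    readr::write_csv(result$survival_comparison$groups,
                     file.path(out_dir, "survival_groups.csv"))
    readr::write_csv(result$survival_comparison$tests,
                     file.path(out_dir, "survival_tests.csv"))
  }
  jsonlite::write_json(run_manifest(result),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run manifest: seeds, defaults and versions of a pipeline run
#'
#' @param result a `pipeline_result`.
#' @return a named list suitable for JSON serialization.
#' @export
run_manifest <- function(result) {
  cfg <- result$config
  list(
    package_version = as.character(utils::packageVersion("omcscreen")),
    r_version = as.character(getRversion()),
    cv = list(k = cfg$cv$k, seeds = cfg$cv$seeds,
              threshold = cfg$cv$threshold),
    omc = list(inner_k = cfg$omc$inner_k, k_step = cfg$omc$k_step,
               k_max = cfg$omc$k_max),
    synthetic = unclass(cfg$synthetic),
    algorithms = setNames(
      lapply(cfg$algorithms, default_hyperparameters), cfg$algorithms))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$grid)
  invisible(x)
}
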