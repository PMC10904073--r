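#' Omics profile container
#'
#' A light container for one molecular profile: a samples x features numeric
#' matrix plus a kind tag that governs value-range invariants. Beta-valued
#' kinds (`cpg_beta`, `cgi_beta`) must lie in \[0, 1\]; expression kinds
#' (`fpkm`, `fpkm_uq`) must be non-negative.
#'
#' @param values numeric matrix, samples in rows (rownames = sample IDs),
#'   features in columns (colnames = feature IDs). Feature IDs must be unique.
#' @param kind one of `"fpkm"`, `"fpkm_uq"`, `"mirna_log2rpm"`,
#'   `"isomir_log2rpm"`, `"cpg_beta"`, `"cgi_beta"`, `"cnv_mean"`,
#'   `"cnv_median"`, `"clinical"`, or a composite tag produced by
#'   [concatenate_profiles()].
#' @param validate check range invariants (default `TRUE`).
#' @return an object of class `omics_profile`.
#' @export
omics_profile <- function(values, kind, validate = TRUE) {
  assert_matrix_named(values)
  if (anyDuplicated(colnames(values))) abort("duplicated feature IDs")
  if (anyDuplicated(rownames(values))) abort("duplicated sample IDs")
  out <- structure(list(values = values, kind = kind), class = "omics_profile")
  if (validate) validate_profile(out)
  out
}

validate_profile <- function(profile) {
  v <- profile$values
  finite <- v[!is.na(v)]
  if (profile$kind %in% c("cpg_beta", "cgi_beta") &&
      length(finite) && (min(finite) < 0 || max(finite) > 1)) {
    abort(sprintf("%s values must lie in [0, 1]", profile$kind))
  }
  if (profile$kind %in% c("fpkm", "fpkm_uq") && length(finite) && min(finite) < 0) {
    abort(sprintf("%s values must be non-negative", profile$kind))
  }
  invisible(profile)
}

#' @export
print.omics_profile <- function(x, ...) {
  cat(sprintf("<omics_profile> kind=%s: %d samples x %d features\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_profile <- function(x) dim(x$values)

#' @rdname omics_profile
#' @param x an `omics_profile`.
#' @param ... unused.
#' @method as_tibble omics_profile
#' @export
as_tibble.omics_profile <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "sample_id")
}

sample_ids <- function(profile) rownames(profile$values)
feature_ids <- function(profile) colnames(profile$values)

#' Remove features with any missing value
#'
#' Features (columns) missing a value for at least one sample are dropped
#' entirely; the sample set is unchanged. This is the standard
#' complete-feature filter applied to each profile before modeling.
#'
#' @param profile an [omics_profile()].
#' @return the filtered profile; the number of removed features is attached
#'   as attribute `"n_removed"` and reported via a message.
#' @export
drop_incomplete_features <- function(profile) {
  keep <- !apply(is.na(profile$values), 2, any)
  n_removed <- sum(!keep)
  if (all(!keep)) abort("all features contain missing values; nothing left")
  out <- omics_profile(profile$values[, keep, drop = FALSE], profile$kind)
  if (n_removed > 0) {
    message(sprintf("drop_incomplete_features: removed %d of %d features",
                    n_removed, length(keep)))
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Log2 transform of non-negative read counts per million
#'
#' Applies `log2(x + pseudocount)` elementwise, the usual variance-stabilizing
#' transform for RPM-scale miRNA/isomiR quantifications. The default
#' pseudocount of 1 keeps zero counts at zero.
#'
#' @param profile an [omics_profile()] with non-negative values.
#' @param pseudocount offset added before the log (default 1).
#' @param kind kind tag for the result (default `"mirna_log2rpm"`).
#' @return the transformed profile.
#' @export
log2_rpm <- function(profile, pseudocount = 1, kind = "mirna_log2rpm") {
  v <- profile$values
  if (any(v[!is.na(v)] < 0)) abort("log2_rpm requires non-negative values")
  omics_profile(log2(v + pseudocount), kind, validate = FALSE)
}

#' Average CpG probe beta values over CpG islands
#'
#' Each output feature is one CpG island whose value, per sample, is the
#' arithmetic mean of the beta values of all probes mapped to that island.
#' Probes absent from the map are dropped.
#'
#' @param profile an [omics_profile()] of kind `cpg_beta`.
#' @param map data frame with columns `probe_id`, `island_id` (many probes to
#'   one island; each probe maps to at most one island).
#' @return an `omics_profile` of kind `cgi_beta`, one column per island.
#' @export
aggregate_probes_to_islands <- function(profile, map) {
  if (profile$kind != "cpg_beta") abort("profile kind must be cpg_beta")
  map <- dplyr::distinct(tibble(probe_id = as.character(map$probe_id),
                                island_id = as.character(map$island_id)))
  if (nrow(map) == 0) abort("probe-to-island map is empty")
  if (anyDuplicated(map$probe_id)) abort("a probe maps to more than one island")
  map <- dplyr::filter(map, .data$probe_id %in% feature_ids(profile))
  if (nrow(map) == 0) abort("no mapped probe is present in the profile")
  islands <- split(map$probe_id, map$island_id)
  agg <- vapply(islands, function(probes) {
    rowMeans(profile$values[, probes, drop = FALSE])
  }, numeric(nrow(profile$values)))
  agg <- matrix(agg, nrow = nrow(profile$values),
                dimnames = list(sample_ids(profile), names(islands)))
  omics_profile(agg, "cgi_beta")
}

#' Aggregate copy-number segments to per-gene values
#'
#' For each sample and gene, collects the copy-number values of every segment
#' overlapping the gene interval by at least 1 bp and reduces them with `stat`.
#' Coordinates are 0-based half-open (BED convention). Genes with no
#' overlapping segment in a sample receive `NA` (removed later by
#' [drop_incomplete_features()]).
#'
#' @param segments data frame with columns `sample_id`, `chrom`, `start`,
#'   `end`, `value`.
#' @param gene_intervals data frame with columns `gene_id`, `chrom`, `start`,
#'   `end`.
#' @param stat `"mean"` or `"median"`.
#' @return an `omics_profile` of kind `cnv_mean` or `cnv_median`.
#' @export
aggregate_segments_to_genes <- function(segments, gene_intervals,
                                        stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (any(segments$start >= segments$end) ||
      any(gene_intervals$start >= gene_intervals$end)) {
    abort("malformed interval: start must be < end (0-based half-open)")
  }
  # 0-based half-open -> 1-based closed for IRanges
  seg_gr <- GenomicRanges::GRanges(
    seqnames = segments$chrom,
    ranges = IRanges::IRanges(start = segments$start + 1, end = segments$end))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = gene_intervals$chrom,
    ranges = IRanges::IRanges(start = gene_intervals$start + 1,
                              end = gene_intervals$end))
  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  ov <- tibble(
    gene_id = gene_intervals$gene_id[S4Vectors::queryHits(hits)],
    sample_id = segments$sample_id[S4Vectors::subjectHits(hits)],
    value = segments$value[S4Vectors::subjectHits(hits)])
  reduce_fun <- if (stat == "mean") mean else stats::median
  agg <- ov |>
    dplyr::group_by(.data$sample_id, .data$gene_id) |>
    dplyr::summarise(value = reduce_fun(.data$value), .groups = "drop")
  samples <- sort(unique(segments$sample_id))
  genes <- gene_intervals$gene_id
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(agg$sample_id, samples), match(agg$gene_id, genes))] <- agg$value
  omics_profile(m, paste0("cnv_", stat))
}

#' Concatenate profiles on their common samples
#'
#' Inner-joins a list of profiles on sample IDs and namespaces feature IDs as
#' `"<kind>:<feature_id>"` so identically named features from different
#' profiles cannot collide.
#'
#' @param profiles list of [omics_profile()] objects.
#' @return an `omics_profile` whose kind is the `+`-joined composite of the
#'   input kinds.
#' @export
concatenate_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  common <- Reduce(intersect, lapply(profiles, sample_ids))
  if (length(common) == 0) abort("profiles share no samples")
  blocks <- lapply(profiles, function(p) {
    v <- p$values[common, , drop = FALSE]
    colnames(v) <- paste0(p$kind, ":", colnames(v))
    v
  })
  omics_profile(do.call(cbind, blocks),
                paste(vapply(profiles, function(p) p$kind, ""), collapse = "+"),
                validate = FALSE)
}

#' Read / write a profile as TSV (features x samples)
#'
#' On disk a profile is a TSV with one row per feature, a `feature_id` first
#' column, and one column per sample — the orientation bulk-omics matrices are
#' usually distributed in. In memory the matrix is samples x features.
#'
#' @param profile an [omics_profile()].
#' @param path file path.
#' @param kind kind tag to attach when reading.
#' @return `write_profile_tsv` returns `path` invisibly; `read_profile_tsv`
#'   returns an `omics_profile`.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- tibble::as_tibble(t(profile$values), rownames = "feature_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path, kind) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  omics_profile(t(m), kind)
}
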