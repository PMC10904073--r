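mk_profile <- function(m, kind = "fpkm") {
  if (is.null(dimnames(m))) {
    dimnames(m) <- list(sprintf("S%02d", seq_len(nrow(m))),
                        sprintf("f%03d", seq_len(ncol(m))))
  }
  omics_profile(m, kind, validate = FALSE)
}

test_that("profile construction enforces range and ID invariants", {
  m <- matrix(c(0.2, 0.8, 1.4, 0.1), 2, 2,
              dimnames = list(c("S1", "S2"), c("p1", "p2")))
  expect_error(omics_profile(m, "cpg_beta"), "\\[0, 1\\]")
  expect_error(omics_profile(-m, "fpkm"), "non-negative")
  m2 <- m
  colnames(m2) <- c("p1", "p1")
  expect_error(omics_profile(m2, "clinical"), "duplicated feature")
})

test_that("features with any missing value are removed, samples untouched", {
  m <- matrix(runif(20), 4, 5)
  m[2, 2] <- NA
  m[4, 5] <- NA
  pr <- mk_profile(m)
  out <- suppressMessages(drop_incomplete_features(pr))
  expect_equal(ncol(out$values), 3)
  expect_equal(nrow(out$values), 4)
  expect_equal(attr(out, "n_removed"), 2)
  # fully observed matrix passes through unchanged
  full <- mk_profile(matrix(runif(20), 4, 5))
  expect_equal(drop_incomplete_features(full)$values, full$values)
  # everything missing is an explicit error
  allna <- mk_profile(matrix(NA_real_, 2, 2))
  expect_error(drop_incomplete_features(allna), "all features")
})

test_that("missingness filter count matches an independent mask computation", {
  set.seed(42)
  m <- matrix(rnorm(50 * 1000), 50, 1000)
  mask <- matrix(runif(length(m)) < 0.1, nrow(m))
  m[mask] <- NA
  expected_kept <- sum(colSums(mask) == 0)
  out <- suppressMessages(drop_incomplete_features(mk_profile(m, "clinical")))
  expect_equal(ncol(out$values), expected_kept)
})

test_that("log2 RPM transform matches exact values and round-trips", {
  pr <- mk_profile(matrix(c(8, 0, 3, 15), 2, 2))
  expect_equal(log2_rpm(pr, pseudocount = 0)$values[1, 1], 3)
  expect_equal(log2_rpm(pr, pseudocount = 1)$values[2, 1], 0)
  set.seed(1)
  x <- mk_profile(matrix(rexp(200), 10, 20))
  y <- log2_rpm(x, pseudocount = 1)
  expect_equal(2^y$values - 1, x$values, tolerance = 1e-12)
  expect_identical(y$kind, "mirna_log2rpm")
  neg <- mk_profile(-x$values, "clinical")
  expect_error(log2_rpm(neg), "non-negative")
})

test_that("probe-to-island aggregation averages mapped probes", {
  m <- matrix(c(0.2, 0.4, 0.9, 0.5), 1, 4,
              dimnames = list("S1", c("cg1", "cg2", "cg3", "cg4")))
  map <- tibble::tibble(probe_id = c("cg1", "cg2", "cg3"),
                        island_id = c("isl_A", "isl_A", "isl_B"))
  out <- aggregate_probes_to_islands(omics_profile(m, "cpg_beta"), map)
  expect_equal(out$values["S1", "isl_A"], 0.3)
  expect_equal(out$values["S1", "isl_B"], 0.9)  # singleton passes through
  expect_identical(out$kind, "cgi_beta")
  # cg4 is unmapped and dropped
  expect_equal(ncol(out$values), 2)
  expect_error(aggregate_probes_to_islands(omics_profile(m, "cpg_beta"),
                                           map[0, ]), "empty")
})

test_that("island aggregation equals a brute-force group mean on a random map", {
  set.seed(7)
  m <- matrix(runif(30 * 200), 30, 200,
              dimnames = list(sprintf("S%02d", 1:30), sprintf("cg%03d", 1:200)))
  map <- tibble::tibble(probe_id = sprintf("cg%03d", 1:200),
                        island_id = sprintf("isl%02d", sample(1:40, 200,
                                                              replace = TRUE)))
  out <- aggregate_probes_to_islands(omics_profile(m, "cpg_beta"), map)
  for (isl in unique(map$island_id)) {
    probes <- map$probe_id[map$island_id == isl]
    expect_equal(out$values[, isl],
                 apply(m[, probes, drop = FALSE], 1, mean))
  }
})

test_that("segment-to-gene aggregation follows the any-overlap rule", {
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          start = c(100L, 900L), end = c(200L, 1200L))
  segs <- tibble::tibble(sample_id = "S1", chrom = "chr1",
                         start = c(0L, 800L, 1000L, 1100L),
                         end = c(500L, 1000L, 1100L, 1500L),
                         value = c(0.7, 0.2, 0.8, 0.8))
  mean_out <- aggregate_segments_to_genes(segs, genes, "mean")
  median_out <- aggregate_segments_to_genes(segs, genes, "median")
  expect_equal(mean_out$values["S1", "gA"], 0.7)
  expect_equal(median_out$values["S1", "gA"], 0.7)
  expect_equal(mean_out$values["S1", "gB"], 0.6)
  expect_equal(median_out$values["S1", "gB"], 0.8)
  bad <- segs
  bad$start[1] <- 600L
  expect_error(aggregate_segments_to_genes(bad, genes), "malformed")
})

test_that("half-open boundaries do not count as overlap", {
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1",
                          start = 100L, end = 200L)
  segs <- tibble::tibble(sample_id = "S1", chrom = "chr1",
                         start = c(0L, 200L), end = c(100L, 300L),
                         value = c(5, 9))
  out <- aggregate_segments_to_genes(segs, genes, "mean")
  expect_true(is.na(out$values["S1", "g"]))
})

test_that("profile concatenation joins on common samples and namespaces features", {
  m1 <- matrix(rnorm(70 * 4), 70, 4,
               dimnames = list(sprintf("S%02d", 1:70), paste0("g", 1:4)))
  m2 <- matrix(rnorm(70 * 3), 70, 3,
               dimnames = list(sprintf("S%02d", 1:70), paste0("c", 1:3)))
  both <- concatenate_profiles(list(mk_profile(m1, "fpkm"),
                                    mk_profile(m2, "clinical")))
  expect_equal(ncol(both$values), 7)
  expect_equal(nrow(both$values), 70)
  expect_true(all(grepl("^(fpkm|clinical):", colnames(both$values))))
  # unequal sample sets join on the intersection
  sub <- mk_profile(m2[1:65, , drop = FALSE], "cgi_beta")
  joined <- concatenate_profiles(list(mk_profile(m1, "fpkm"), sub))
  expect_equal(nrow(joined$values), 65)
  # self-concatenation under distinct namespaces doubles columns, keeps values
  twice <- concatenate_profiles(list(mk_profile(m1, "fpkm"),
                                     mk_profile(m1, "fpkm_uq")))
  expect_equal(ncol(twice$values), 8)
  expect_equal(unname(twice$values[, 1:4]), unname(m1))
  # no shared samples is an error
  other <- mk_profile(matrix(rnorm(4), 2, 2,
                             dimnames = list(c("X1", "X2"), c("a", "b"))),
                      "clinical")
  expect_error(concatenate_profiles(list(mk_profile(m1), other)), "share")
})

test_that("profile TSV round-trips through the features-x-samples layout", {
  d <- make_signal_dataset(n = 6, n_nr = 3, p = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(d$profile, path)
  back <- read_profile_tsv(path, d$profile$kind)
  expect_equal(back$values, d$profile$values)
  expect_identical(back$kind, d$profile$kind)
})
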