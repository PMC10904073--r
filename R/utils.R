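# Internal helpers shared across modules.

# Canonical label levels; "responder" is the positive class throughout.
.response_levels <- c("nonresponder", "responder")
.positive_class <- "responder"

#' Coerce response labels to the canonical factor
#'
#' @param x character or factor vector of "responder"/"nonresponder".
#' @return factor with levels nonresponder, responder.
#' @keywords internal
as_response_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), .response_levels)
  if (length(bad) > 0) {
    abort(paste0("Unknown response label(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = .response_levels)
}

# Deterministic sub-seed derivation. Keeps results < 2^31 so R integer
# seeds never overflow regardless of the user-supplied base seed.
sub_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + (as.double(p) %% 1e6) + 1) %% 2147483629
  as.integer(s)
}

# Evaluate `code` under a local RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  invisible(as.integer(x))
}

assert_matrix_named <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) abort("`values` must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("matrix must carry sample IDs as rownames and feature IDs as colnames")
  }
  invisible(x)
}
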