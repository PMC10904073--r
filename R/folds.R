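#' Stratified K-fold assignment
#'
#' Assigns every sample to one of `k` folds so that, within each class, fold
#' sizes differ by at most one — hence per-fold class counts deviate from
#' proportional allocation by at most one sample. Which folds receive the
#' extra samples is randomized by `seed`. `k = n` degenerates to
#' leave-one-out, where stratification is vacuous and each fold is a
#' singleton.
#'
#' @param labels vector of class labels.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed; the same labels and seed always give the same
#'   assignment.
#' @return integer vector of fold indices in `1:k`, aligned with `labels`.
#' @export
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  assert_count(k, "k", 2)
  if (k > n) abort(sprintf("k = %d exceeds the number of samples (%d)", k, n))
  if (k == n) return(seq_len(n))
  cl_sizes <- table(labels)
  if (k > min(cl_sizes)) {
    warn(sprintf("k = %d exceeds the smallest class size (%d); some folds will miss a class",
                 k, min(cl_sizes)))
  }
  folds <- integer(n)
  fold_totals <- integer(k)
  with_seed(seed, {
    # larger classes first; each class's remainder goes to the folds that are
    # currently smallest, so total fold sizes also differ by at most one
    for (cl in names(sort(cl_sizes, decreasing = TRUE))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      m <- length(idx)
      counts <- rep(m %/% k, k)
      r <- m %% k
      if (r > 0) {
        smallest <- order(fold_totals, sample.int(k))[seq_len(r)]
        counts[smallest] <- counts[smallest] + 1
      }
      folds[idx] <- rep(seq_len(k), counts)
      fold_totals <- fold_totals + counts
    }
  })
  folds
}
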