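#' Stratified cross-validation folds
#'
#' Assigns every trial of a contrast to exactly one test fold such that the
#' proportion of each subclass (LSGS, LDGS, LSGD, LDGD) is preserved in every
#' fold to within one trial. Deterministic given `seed`.
#'
#' @param contrast a [make_contrast()] object.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the shuffle.
#' @return A `fold_assignment`: list with `k`, `fold` (per-trial test-fold
#'   index in `1:k`), and `seed`.
#' @export
stratified_folds <- function(contrast, k = 10L, seed = 1L) {
  stopifnot(inherits(contrast, "contrast_spec"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  counts <- table(contrast$subclass)
  small <- names(counts)[counts < k]
  if (length(small))
    stop(sprintf("subclass %s has %d trials, fewer than k = %d folds",
                 small[1L], counts[[small[1L]]], k))
  n <- length(contrast$y)
  fold <- integer(n)
  with_seed(seed, {
    for (s in levels(contrast$subclass)) {
      idx <- which(contrast$subclass == s)
      if (!length(idx)) next
      idx <- idx[sample.int(length(idx))]
      # deal round-robin from a random starting fold so remainders spread out
      start <- sample.int(k, 1L)
      fold[idx] <- ((start - 1L + seq_along(idx) - 1L) %% k) + 1L
    }
  })
  structure(list(k = k, fold = fold, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Subclass sample weights
#'
#' Per-trial weights proportional to the inverse subclass count, scaled so the
#' trials of each present subclass sum to the same total weight (and the
#' overall mean weight is 1). Used in the SVM loss so that the four
#' local-global categories contribute equally to the decision hyperplane;
#' weights are *not* applied when scoring AUC.
#'
#' @param contrast a [make_contrast()] object.
#' @return Numeric vector of per-trial weights.
#' @export
subclass_weights <- function(contrast) {
  stopifnot(inherits(contrast, "contrast_spec"))
  counts <- table(contrast$subclass)
  counts <- counts[counts > 0]
  if (!length(counts)) stop("no trials in any subclass")
  n <- length(contrast$y)
  w <- n / (length(counts) * counts[as.character(contrast$subclass)])
  as.numeric(w)
}
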