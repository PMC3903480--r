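#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a uniformly drawn (deviant, standard)
#' pair of trials is ordered correctly by the scores, with tied scores counted
#' as half. This is the Mann-Whitney convention, so
#' `auc(s, y) * n1 * n2` equals the U statistic of [within_subject_test()].
#'
#' @param scores numeric vector of continuous classifier outputs (higher =
#'   more deviant-like).
#' @param y class labels; positive values (or `TRUE`) mark the deviant class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, y) {
  if (length(scores) != length(y))
    stop("scores and y must have the same length")
  pos <- y > 0
  n1 <- sum(pos)
  n2 <- length(y) - n1
  if (n1 == 0L || n2 == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
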