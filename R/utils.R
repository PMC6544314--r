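#' Area under the ROC curve from scores and binary labels
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counted half.
#' Used to quantify recovery of planted regulators by connectivity ranking.
#'
#' @param scores Numeric vector.
#' @param labels Logical vector (`TRUE` = positive), same length.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.logical(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("need both positives and negatives")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
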