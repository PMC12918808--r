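#' Area under the ROC curve for a score against binary labels
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outranks a random negative, with ties counted one half.
#'
#' @param score Numeric scores (higher = more likely positive).
#' @param positive Logical vector of the same length.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  keep <- is.finite(score) & !is.na(positive)
  score <- score[keep]
  positive <- as.logical(positive[keep])
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L)
    stop("auroc: need both positive and negative labels", call. = FALSE)
  r <- rank(score)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
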