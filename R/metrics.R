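#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney
#' rank-sum: the probability that a random positive outscores a random
#' negative, with tied scores counted 1/2.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in \[0, 1\], or `NA` (with a warning) if only one class
#'   is present.
#' @export
aucRank <- function(labels, scores) {
    stopifnot(length(labels) == length(scores))
    npos <- sum(labels == 1)
    nneg <- sum(labels == 0)
    if (npos == 0 || nneg == 0) {
        warning("AUC undefined with a single class; returning NA")
        return(NA_real_)
    }
    r <- rank(scores)
    (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Classification metrics at a threshold
#'
#' Confusion-matrix metrics at `threshold` (predicted positive iff
#' `score >= threshold`) plus threshold-free AUC: overall accuracy,
#' recall (sensitivity), specificity, PPV (precision),
#' \eqn{F_1}, and \eqn{F_\beta = (1+\beta^2)\,PPV\cdot recall /
#' (\beta^2 PPV + recall)} reported in the `fbeta` slot (default
#' `beta = 0.5`, weighting precision over recall). Undefined ratios
#' (e.g. PPV with no positive predictions) are `NA`, never coerced to
#' 0.
#'
#' @param labels 0/1 vector.
#' @param scores numeric class-1 scores in \[0, 1\].
#' @param threshold decision threshold (default 0.5).
#' @param beta the beta of the `fbeta` slot.
#' @return named numeric vector: `accuracy`, `recall`, `specificity`,
#'   `auc`, `ppv`, `f1`, `fbeta`.
#' @examples
#' computeMetrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
#' @export
computeMetrics <- function(labels, scores, threshold = 0.5, beta = 0.5) {
    stopifnot(length(labels) == length(scores))
    pred <- as.integer(scores >= threshold)
    tp <- sum(pred == 1 & labels == 1)
    tn <- sum(pred == 0 & labels == 0)
    fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1)
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    recall <- ratio(tp, tp + fn)
    ppv <- ratio(tp, tp + fp)
    fscore <- function(b) {
        if (is.na(ppv) || is.na(recall) || (b^2 * ppv + recall) == 0)
            return(NA_real_)
        (1 + b^2) * ppv * recall / (b^2 * ppv + recall)
    }
    auc <- if (all(labels == 1) || all(labels == 0)) NA_real_
           else aucRank(labels, scores)
    c(accuracy = (tp + tn) / length(labels),
      recall = recall,
      specificity = ratio(tn, tn + fp),
      auc = auc,
      ppv = ppv,
      f1 = fscore(1),
      fbeta = fscore(beta))
}
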