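#' Confusion statistics against a gold-standard gene set
#'
#' Precision = overlap / predicted, recall = overlap / truth, false
#' positive rate = (predicted not in truth) / (universe - truth), and
#' fold over chance = precision / baseline, where the default baseline is
#' the truth prevalence in the universe (supply `baseline` to use a
#' screen-specific hit rate instead).
#'
#' @param predicted,truth character vectors (subsets of the universe).
#' @param universe_size total number of genes screened.
#' @param baseline optional chance precision; default `|truth| /
#'   universe_size`.
#' @return One-row tibble with counts, `precision`, `recall`, `fpr`,
#'   `fold_over_chance`; empty predictions give `NA` precision with a
#'   warning.
#' @export
confusion_stats <- function(predicted, truth, universe_size,
                            baseline = NULL) {
  predicted <- unique(predicted)
  truth <- unique(truth)
  if (length(truth) > universe_size || length(predicted) > universe_size) {
    stop("predicted and truth sets must fit inside the universe")
  }
  overlap <- length(intersect(predicted, truth))
  if (is.null(baseline)) baseline <- length(truth) / universe_size
  precision <- if (length(predicted)) overlap / length(predicted) else {
    warning("empty prediction set; precision undefined")
    NA_real_
  }
  tibble::tibble(n_predicted = length(predicted), n_truth = length(truth),
                 n_overlap = overlap, universe_size = universe_size,
                 precision = precision,
                 recall = overlap / length(truth),
                 fpr = (length(predicted) - overlap) /
                   (universe_size - length(truth)),
                 fold_over_chance = precision / baseline)
}

#' ROC and precision-recall analysis of interaction scores
#'
#' Interaction scores are oriented so that *lower* = stronger rescue
#' evidence; the AUC is therefore the probability that a random positive
#' pair scores lower than a random negative one, computed rank-based with
#' tie correction. ROC and PR points are traced in order of increasing
#' score (descending evidence).
#'
#' @param scores numeric interaction scores.
#' @param labels logical vector (TRUE = positive pair).
#' @return List with `auc`, `roc` (tibble fpr/tpr), and `pr` (tibble
#'   recall/precision).
#' @export
score_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  np <- sum(labels); nn <- sum(!labels)
  r <- rank(scores)  # low score = predicted positive
  auc <- (sum(r[!labels]) - nn * (nn + 1) / 2) / (np * nn)

  ord <- order(scores)
  lab <- labels[ord]
  # step through distinct score values so ties move together
  grp <- cumsum(!duplicated(scores[ord]))
  tp <- cumsum(lab); fp <- cumsum(!lab)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  roc <- tibble::tibble(fpr = c(0, fp / nn), tpr = c(0, tp / np))
  pr <- tibble::tibble(recall = tp / np, precision = tp / (tp + fp))
  list(auc = auc, roc = roc, pr = pr)
}

#' Cohen's d effect size
#'
#' Difference of group means divided by the pooled standard deviation
#' `sqrt(((n1-1)*s1^2 + (n2-1)*s2^2) / (n1 + n2 - 2))`.
#'
#' @param x1,x2 numeric vectors, each of length >= 2.
#' @return The effect size (positive when `x1` has the larger mean).
#' @examples
#' cohens_d(c(0, 2), c(-1, 1)) # 1/sqrt(2)
#' @export
cohens_d <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 values")
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled standard deviation")
  (mean(x1) - mean(x2)) / sqrt(sp2)
}
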