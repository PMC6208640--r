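#' ROC curve and AUC for a scalar score threshold classifier
#'
#' Sweeps a classification threshold over a single scalar score (e.g. the
#' Jaccard distance between the pair's trait vectors, or an out-of-bag vote
#' fraction) and traces sensitivity against 1 - specificity. Scores must be
#' oriented so that larger values indicate the positive class. The area under
#' the curve is computed by pROC (trapezoid over the step curve) and equals
#' the concordant-pair (Mann-Whitney) statistic, with ties counted half.
#'
#' @param scores numeric score per sample.
#' @param labels class labels (factor or character/logical).
#' @param positive which label value is the positive class; defaults to the
#'   last factor level.
#' @return list with \code{auc} and \code{curve}, a data.frame of
#'   \code{threshold}, \code{fpr} (1 - specificity) and \code{tpr}
#'   (sensitivity).
#' @examples
#' score_threshold_roc(c(.9, .8, .7, .4, .3, .1),
#'                     c(1, 1, 0, 1, 0, 0), positive = 1)$auc  # 8/9
#' @export
score_threshold_roc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must not contain NA")
  f <- if (is.factor(labels)) labels else factor(labels)
  if (is.null(positive)) positive <- levels(f)[nlevels(f)]
  y <- as.integer(f == positive)
  if (length(unique(y)) < 2L) {
    stop("ROC requires at least one sample of each class")
  }
  if (length(unique(scores)) == 1L) {
    # degenerate sweep: a constant score cannot order the classes
    curve <- data.frame(threshold = c(Inf, -Inf), fpr = c(0, 1), tpr = c(0, 1))
    return(list(auc = 0.5, curve = curve))
  }
  r <- pROC::roc(response = y, predictor = scores, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  curve <- data.frame(threshold = r$thresholds,
                      fpr = 1 - r$specificities,
                      tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  rownames(curve) <- NULL
  list(auc = as.numeric(pROC::auc(r)), curve = curve)
}

#' Jaccard-distance baseline scores for a composite dataset
#'
#' For each ordered pair in the dataset, the Jaccard distance between the
#' responder's and the partner's trait vectors. Organisms with similar trait
#' profiles (small distance) tend to compete for the same nutrients, so the
#' distance itself is oriented towards the nonnegative/positive class.
#'
#' @param traits a [trait_matrix()].
#' @param dataset a [assemble_dataset()] result over the same organisms.
#' @return numeric vector of Jaccard distances, one per dataset row.
#' @export
jaccard_baseline_scores <- function(traits, dataset) {
  stopifnot(inherits(dataset, "composite_dataset"))
  tm <- unclass(traits)
  vapply(seq_len(nrow(dataset$pairs)), function(k) {
    jaccard_distance(tm[dataset$pairs$responder[k], ],
                     tm[dataset$pairs$partner[k], ])
  }, numeric(1))
}
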