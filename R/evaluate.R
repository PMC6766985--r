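## Threshold-free evaluation: ROC by sweeping the score threshold (tied
## scores collapse into one sweep step, so the curve takes the diagonal
## through ties) and AUC by the trapezoidal rule -- equivalent to the
## concordant-pair statistic with ties counted half.

#' ROC curve of a binary scorer
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels (0/1).
#' @return data.frame with columns \code{fpr}, \code{tpr},
#'   \code{threshold}, starting at (0, 0) and ending at (1, 1).
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC requires both classes in the evaluation split")
  o <- order(scores, decreasing = TRUE)
  ys <- labels[o]; ss <- scores[o]
  last <- which(!duplicated(ss, fromLast = TRUE))  # group ends (ties merged)
  tp <- cumsum(ys)[last]
  fp <- cumsum(1L - ys)[last]
  data.frame(fpr = c(0, fp / nNeg), tpr = c(0, tp / nPos),
             threshold = c(Inf, ss[last]))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of \code{\link{rocCurve}}; ties contribute half
#' a concordance. Returns NA with a warning when only one class is present.
#'
#' @inheritParams rocCurve
#' @return AUC in [0, 1], or NA.
#' @export
#' @examples
#' aucFromScores(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
aucFromScores <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) {
    gtWarn("AUC undefined: evaluation split contains a single class")
    return(NA_real_)
  }
  roc <- rocCurve(scores, labels)
  n <- nrow(roc)
  sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-n]) / 2)
}

#' Evaluate a trained model on a labeled split
#'
#' @param model a \code{\link{TrainedCNN}}.
#' @param x array (n, n, channels, samples).
#' @param y binary labels.
#' @param task,split identifiers recorded in the report.
#' @return An \code{\link{EvalReport}}.
#' @export
evaluateModel <- function(model, x, y, task = "task", split = "test") {
  scores <- predictCNN(model, x)
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L) {
    gtWarn("AUC undefined for task '%s' on split '%s': single class", task,
           split)
    return(new("EvalReport", task = task, split = split, auc = NA_real_,
               roc = data.frame(fpr = numeric(), tpr = numeric(),
                                threshold = numeric())))
  }
  roc <- rocCurve(scores, y)
  new("EvalReport", task = task, split = split,
      auc = aucFromScores(scores, y), roc = roc)
}
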