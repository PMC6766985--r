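## Class-imbalance handling: SMOTE over flattened grid vectors, and
## inverse-frequency positive-class weights for the loss. Both mechanisms
## are independently switchable; the training pipeline defaults to SMOTE
## on and weights off to avoid double-correcting.

#' Synthetic minority oversampling (SMOTE)
#'
#' Oversamples the minority class of a binary dataset by linear
#' interpolation: a synthetic sample is \code{x_i + u (x_nn - x_i)} with
#' \code{u ~ Uniform(0, 1)} and \code{x_nn} one of the k nearest minority
#' neighbours of minority point \code{x_i} (Euclidean distance). Generation
#' continues until minority/majority reaches \code{targetRatio}. Original
#' samples are preserved unchanged and come first in the output; majority
#' samples are never modified or duplicated.
#'
#' @param x numeric matrix, one row per sample (flattened grids).
#' @param y binary labels (0/1 or logical), length \code{nrow(x)}.
#' @param k number of minority neighbours considered (default 5); reduced
#'   with a warning when the minority class is smaller than k + 1.
#' @param targetRatio desired minority/majority ratio after resampling,
#'   in (0, 1] (default 1, i.e. fully balanced).
#' @param seed RNG seed for reproducible resampling.
#' @return List with elements \code{x} (matrix of originals then
#'   synthetics), \code{y} (labels) and \code{synthetic} (logical marker).
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20, 2)
#' y <- rep(c(0, 1), c(16, 4))
#' res <- smote(x, y, seed = 7)
#' table(res$y)
smote <- function(x, y, k = 5L, targetRatio = 1, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(as.logical(y))
  stopifnot(nrow(x) == length(y), k >= 1L, targetRatio > 0, targetRatio <= 1)
  tab <- table(factor(y, levels = 0:1))
  if (any(tab == 0L)) stop("smote() requires samples from both classes")
  minLab <- as.integer(names(tab)[which.min(tab)])
  nMin <- min(tab); nMaj <- max(tab)
  nTarget <- floor(targetRatio * nMaj)
  nNew <- nTarget - nMin
  if (nNew <= 0L)
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  if (nMin < 2L) stop("need at least 2 minority samples to interpolate")
  if (nMin <= k) {
    gtWarn("minority class has %d samples <= k = %d; using k = %d",
           nMin, k, nMin - 1L)
    k <- nMin - 1L
  }
  minIdx <- which(y == minLab)
  xm <- x[minIdx, , drop = FALSE]
  ## exact k nearest minority neighbours of each minority point
  D <- as.matrix(dist(xm))
  diag(D) <- Inf
  ord <- apply(D, 1L, function(row) order(row)[seq_len(k)])
  nn <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)

  set.seed(seed)
  base <- sample.int(nMin, nNew, replace = TRUE)
  pick <- sample.int(k, nNew, replace = TRUE)
  u <- runif(nNew)
  nbr <- nn[cbind(base, pick)]
  xNew <- xm[base, , drop = FALSE] +
    u * (xm[nbr, , drop = FALSE] - xm[base, , drop = FALSE])
  gtLog("SMOTE: minority %d -> %d (majority %d, k = %d)", nMin, nTarget,
        nMaj, k)
  list(x = rbind(x, xNew),
       y = c(y, rep(minLab, nNew)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nNew)))
}

#' Inverse-frequency class weights
#'
#' Positive-class weight for the binary cross-entropy loss:
#' \code{w_pos = n_neg / n_pos}, \code{w_neg = 1}. For the most imbalanced
#' endpoints this weight is large (e.g. 7798 negatives against 236
#' positives gives roughly 33).
#'
#' @param y binary labels (0/1 or logical).
#' @return Named numeric vector \code{c(pos = , neg = 1)}.
#' @export
#' @examples
#' classWeights(rep(c(1, 0), c(236, 7798)))
classWeights <- function(y) {
  y <- as.integer(as.logical(y))
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("classWeights() requires samples from both classes")
  c(pos = nNeg / nPos, neg = 1)
}
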