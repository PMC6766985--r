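## A small convolutional classifier for multi-channel grids, implemented
## directly on base-R matrix algebra (im2col + BLAS). The default
## architecture has four hidden layers: three conv blocks (3x3 kernels with
## same padding -> rectifier -> 2x2 max-pool) with 32/64/128 filters, one
## dense rectifier layer, and a single sigmoid output. Training minimizes
## (optionally class-weighted) binary cross-entropy with Adam and L2 weight
## decay; dropout is applied to the input layer only. All randomness
## (initialization, shuffling, dropout) flows from the config seed, so two
## runs with the same data and config produce identical loss histories.

#' Weighted binary cross-entropy
#'
#' Mean over samples of
#' \code{-[w_pos y log(p) + w_neg (1 - y) log(1 - p)]}, with predictions
#' clipped to [1e-7, 1 - 1e-7] so the logs stay finite.
#'
#' @param yHat predicted probabilities.
#' @param y binary labels (0/1).
#' @param weights optional named vector \code{c(pos = , neg = )}; defaults
#'   to unweighted (1, 1).
#' @return Scalar loss.
#' @export
#' @examples
#' bceLoss(c(0.9, 0.2), c(1, 0))
bceLoss <- function(yHat, y, weights = NULL) {
  if (is.null(weights)) weights <- c(pos = 1, neg = 1)
  p <- pmin(pmax(yHat, 1e-7), 1 - 1e-7)
  mean(-(weights[["pos"]] * y * log(p) +
         weights[["neg"]] * (1 - y) * log(1 - p)))
}

## --- architecture ----------------------------------------------------------

## im2col gather indices for a (H, W, C) sample padded by 1, 3x3 kernel.
## Returns a (9C x HW) integer matrix of linear indices into the padded
## (H+2, W+2, C) array; row order is (di, dj, c) fastest-first, column
## order is column-major over output pixels.
.im2colIndex <- function(H, W, C) {
  Hp <- H + 2L; Wp <- W + 2L
  r <- seq_len(9L * C) - 1L
  di <- r %% 3L
  dj <- (r %/% 3L) %% 3L
  cc <- r %/% 9L
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  outer(cc * (Hp * Wp), rep(0L, H * W), "+") +
    outer(dj, j - 1L, "+") * Hp +
    outer(di, i, "+")
}

.initModel <- function(cfg) {
  C <- cfg@inputShape[1L]; H <- cfg@inputShape[2L]; W <- cfg@inputShape[3L]
  blocks <- list()
  idx <- list()
  dims <- list()
  cin <- C; h <- H; w <- W
  for (k in seq_along(cfg@convFilters)) {
    f <- cfg@convFilters[k]
    K <- 9L * cin
    blocks[[k]] <- list(W = matrix(rnorm(f * K, sd = sqrt(2 / K)), f, K),
                        b = numeric(f))
    idx[[k]] <- .im2colIndex(h, w, cin)
    dims[[k]] <- c(h = h, w = w, cin = cin, f = f,
                   h2 = h %/% cfg@pool, w2 = w %/% cfg@pool)
    h <- h %/% cfg@pool; w <- w %/% cfg@pool
    if (h < 1L || w < 1L) stop("grid too small for the pooling stack")
    cin <- f
  }
  D <- h * w * cin
  U <- cfg@denseUnits
  list(blocks = blocks, idx = idx, dims = dims, flatDim = D,
       dense = list(W = matrix(rnorm(U * D, sd = sqrt(2 / D)), U, D),
                    b = numeric(U)),
       out = list(W = matrix(rnorm(U, sd = sqrt(1 / U)), 1L, U),
                  b = 0),
       scaling = NULL)
}

#' Build an untrained grid classifier
#'
#' Instantiates the architecture described by the config with He-scaled
#' random initial weights drawn under the config seed.
#'
#' @param cfg a \code{\link{cnnConfig}}.
#' @return A \code{\link{TrainedCNN}} with empty loss history.
#' @export
buildModel <- function(cfg) {
  stopifnot(is(cfg, "CNNConfig"))
  set.seed(cfg@seed)
  new("TrainedCNN", params = .initModel(cfg), config = cfg,
      lossHistory = numeric(), meta = list())
}

#' Number of trainable parameters
#'
#' @param model a \code{\link{TrainedCNN}}.
#' @return Integer parameter count over all layers.
#' @export
parameterCount <- function(model) {
  p <- model@params
  sum(vapply(p$blocks, function(b) length(b$W) + length(b$b), numeric(1L))) +
    length(p$dense$W) + length(p$dense$b) + length(p$out$W) + length(p$out$b)
}

## --- forward / backward ----------------------------------------------------

## forward pass on X (H, W, C, N); returns prediction and caches
.forward <- function(p, cfg, X, training = FALSE, keepMaps = FALSE) {
  N <- dim(X)[4L]
  if (!is.null(p$scaling))
    X <- (X - rep(p$scaling$mean, each = prod(dim(X)[1:2]))) /
         rep(p$scaling$sd, each = prod(dim(X)[1:2]))
  if (training && cfg@dropoutInput > 0) {
    keepP <- 1 - cfg@dropoutInput
    mask <- array(stats::rbinom(length(X), 1L, keepP) / keepP, dim = dim(X))
    X <- X * mask
  }
  caches <- vector("list", length(p$blocks))
  maps <- if (keepMaps) vector("list", length(p$blocks)) else NULL
  A <- X
  for (k in seq_along(p$blocks)) {
    d <- p$dims[[k]]
    H <- d[["h"]]; W <- d[["w"]]; C <- d[["cin"]]; f <- d[["f"]]
    Hp <- H + 2L; Wp <- W + 2L
    Xp <- array(0, c(Hp, Wp, C, N))
    Xp[2L:(H + 1L), 2L:(W + 1L), , ] <- A
    dim(Xp) <- c(Hp * Wp * C, N)
    cols <- Xp[as.vector(p$idx[[k]]), , drop = FALSE]
    dim(cols) <- c(9L * C, H * W * N)
    Z <- p$blocks[[k]]$W %*% cols + p$blocks[[k]]$b
    Zr <- aperm(array(Z, c(f, H, W, N)), c(2L, 3L, 1L, 4L))
    Ar <- Zr; Ar[Ar < 0] <- 0
    ## 2x2 max pooling (stride 2, floor)
    H2 <- d[["h2"]]; W2 <- d[["w2"]]
    r1 <- seq_len(H2) * 2L - 1L; c1 <- seq_len(W2) * 2L - 1L
    s <- list(Ar[r1, c1, , , drop = FALSE], Ar[r1 + 1L, c1, , , drop = FALSE],
              Ar[r1, c1 + 1L, , , drop = FALSE],
              Ar[r1 + 1L, c1 + 1L, , , drop = FALSE])
    M <- pmax(s[[1L]], s[[2L]], s[[3L]], s[[4L]])
    caches[[k]] <- list(cols = cols, Zr = Zr, slices = s, M = M)
    if (keepMaps) maps[[k]] <- M
    A <- M
  }
  Xf <- matrix(A, p$flatDim, N)
  Zd <- p$dense$W %*% Xf + p$dense$b
  Ad <- Zd; Ad[Ad < 0] <- 0
  z <- p$out$W %*% Ad + p$out$b
  yHat <- as.vector(1 / (1 + exp(-z)))
  list(yHat = yHat, Xf = Xf, Zd = Zd, Ad = Ad, caches = caches, maps = maps)
}

## gradients of the weighted BCE w.r.t. all parameters
.backward <- function(p, cfg, fw, y, weights) {
  N <- length(y)
  yHat <- fw$yHat
  dz <- matrix((weights[["pos"]] * y * (yHat - 1) +
                weights[["neg"]] * (1 - y) * yHat) / N, 1L, N)
  g <- list(out = list(W = dz %*% t(fw$Ad) + cfg@l2 * p$out$W,
                       b = sum(dz)),
            dense = NULL, blocks = vector("list", length(p$blocks)))
  dAd <- t(p$out$W) %*% dz
  dZd <- dAd * (fw$Zd > 0)
  g$dense <- list(W = dZd %*% t(fw$Xf) + cfg@l2 * p$dense$W,
                  b = rowSums(dZd))
  if (length(p$blocks) == 0L) return(g)
  dXf <- t(p$dense$W) %*% dZd
  kLast <- length(p$blocks)
  dM <- array(dXf, c(p$dims[[kLast]][["h2"]], p$dims[[kLast]][["w2"]],
                     p$dims[[kLast]][["f"]], N))
  for (k in rev(seq_along(p$blocks))) {
    d <- p$dims[[k]]
    H <- d[["h"]]; W <- d[["w"]]; C <- d[["cin"]]; f <- d[["f"]]
    H2 <- d[["h2"]]; W2 <- d[["w2"]]
    ca <- fw$caches[[k]]
    ## unpool: route gradient to the argmax (first slice wins ties)
    dA <- array(0, c(H, W, f, N))
    r1 <- seq_len(H2) * 2L - 1L; c1 <- seq_len(W2) * 2L - 1L
    taken <- array(FALSE, dim = dim(ca$M))
    offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
    for (sIdx in 1:4) {
      m <- (ca$slices[[sIdx]] == ca$M) & !taken
      taken <- taken | m
      dA[r1 + offs[[sIdx]][1L], c1 + offs[[sIdx]][2L], , ] <-
        dA[r1 + offs[[sIdx]][1L], c1 + offs[[sIdx]][2L], , , drop = FALSE] +
        m * dM
    }
    dZr <- dA * (ca$Zr > 0)
    dZ <- aperm(dZr, c(3L, 1L, 2L, 4L))
    dim(dZ) <- c(f, H * W * N)
    g$blocks[[k]] <- list(W = dZ %*% t(ca$cols) + cfg@l2 * p$blocks[[k]]$W,
                          b = rowSums(dZ))
    if (k > 1L) {
      dCols <- t(p$blocks[[k]]$W) %*% dZ
      dim(dCols) <- c(9L * C * H * W, N)
      acc <- rowsum(dCols, group = as.vector(p$idx[[k]]))
      Hp <- H + 2L; Wp <- W + 2L
      dXp <- matrix(0, Hp * Wp * C, N)
      dXp[as.integer(rownames(acc)), ] <- acc
      dim(dXp) <- c(Hp, Wp, C, N)
      dM <- dXp[2L:(H + 1L), 2L:(W + 1L), , , drop = FALSE]
    }
  }
  g
}

## flat views of parameters/gradients for the optimizer
.paramList <- function(p) {
  out <- list()
  for (k in seq_along(p$blocks)) {
    out[[paste0("Wc", k)]] <- p$blocks[[k]]$W
    out[[paste0("bc", k)]] <- p$blocks[[k]]$b
  }
  out$Wd <- p$dense$W; out$bd <- p$dense$b
  out$Wo <- p$out$W; out$bo <- p$out$b
  out
}

.setParams <- function(p, lst) {
  for (k in seq_along(p$blocks)) {
    p$blocks[[k]]$W <- lst[[paste0("Wc", k)]]
    p$blocks[[k]]$b <- lst[[paste0("bc", k)]]
  }
  p$dense$W <- lst$Wd; p$dense$b <- lst$bd
  p$out$W <- lst$Wo; p$out$b <- lst$bo
  p
}

#' Train the grid classifier
#'
#' Minimizes (optionally class-weighted) binary cross-entropy with Adam.
#' One model is trained per endpoint. Given the same data, config and seed,
#' two runs produce identical loss histories.
#'
#' @param x numeric array (n, n, channels, samples) -- see
#'   \code{\link{gridArray}} -- or a \code{\link{GridSet}} together with
#'   \code{task}.
#' @param y binary labels (0/1), one per sample.
#' @param cfg a \code{\link{cnnConfig}} whose inputShape matches \code{x}.
#' @param weights optional \code{c(pos=, neg=)} loss weights
#'   (\code{\link{classWeights}}); default unweighted.
#' @param model optional pre-built \code{\link{TrainedCNN}} to continue from.
#' @return A \code{\link{TrainedCNN}} with per-epoch loss history.
#' @export
trainCNN <- function(x, y, cfg, weights = NULL, model = NULL) {
  stopifnot(length(dim(x)) == 4L, dim(x)[4L] == length(y))
  if (is.null(weights)) weights <- c(pos = 1, neg = 1)
  y <- as.numeric(y)
  set.seed(cfg@seed)
  p <- if (is.null(model)) .initModel(cfg) else model@params
  if (cfg@scaleInputs) {
    nc <- dim(x)[3L]
    mu <- sdv <- numeric(nc)
    for (k in seq_len(nc)) {
      v <- x[, , k, ]
      mu[k] <- mean(v)
      sdv[k] <- sd(v)
      if (!is.finite(sdv[k]) || sdv[k] < 1e-12) sdv[k] <- 1
    }
    p$scaling <- list(mean = mu, sd = sdv)
  }
  N <- length(y)
  adam <- lapply(.paramList(p), function(w) list(m = w * 0, v = w * 0))
  t <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lossHist <- numeric(cfg@epochs)
  for (epoch in seq_len(cfg@epochs)) {
    ord <- sample.int(N)
    tot <- 0
    for (start in seq(1L, N, by = cfg@batchSize)) {
      idx <- ord[start:min(start + cfg@batchSize - 1L, N)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx]
      fw <- .forward(p, cfg, xb, training = TRUE)
      loss <- bceLoss(fw$yHat, yb, weights)
      if (!is.finite(loss))
        stop(sprintf("training diverged at epoch %d (loss = %s)", epoch, loss))
      tot <- tot + loss * length(idx)
      g <- .backward(p, cfg, fw, yb, weights)
      t <- t + 1L
      pl <- .paramList(p); gl <- .paramList(g)
      for (nm in names(pl)) {
        adam[[nm]]$m <- beta1 * adam[[nm]]$m + (1 - beta1) * gl[[nm]]
        adam[[nm]]$v <- beta2 * adam[[nm]]$v + (1 - beta2) * gl[[nm]]^2
        mhat <- adam[[nm]]$m / (1 - beta1^t)
        vhat <- adam[[nm]]$v / (1 - beta2^t)
        pl[[nm]] <- pl[[nm]] - cfg@lr * mhat / (sqrt(vhat) + eps)
      }
      p <- .setParams(p, pl)
    }
    lossHist[epoch] <- tot / N
  }
  new("TrainedCNN", params = p, config = cfg, lossHistory = lossHist,
      meta = list(weights = weights,
                  typingRulesVersion = typingRulesVersion()))
}

#' Predict probabilities for new grids
#'
#' @param model a \code{\link{TrainedCNN}}.
#' @param x array (n, n, channels, samples).
#' @return Numeric vector of probabilities.
#' @export
predictCNN <- function(model, x) {
  stopifnot(is(model, "TrainedCNN"), length(dim(x)) == 4L)
  .forward(model@params, model@config, x, training = FALSE)$yHat
}

#' Post-pooling feature maps
#'
#' Runs a single grid through the network and returns the activations after
#' every pooling stage, for rendering per-filter heat maps of what the
#' network attends to.
#'
#' @param model a \code{\link{TrainedCNN}}.
#' @param grid a \code{\link{MolecularGrid}} or (n, n, channels) array.
#' @return List of arrays, one per conv block, each of dimension
#'   (filters, height, width).
#' @export
featureMaps <- function(model, grid) {
  x <- if (is(grid, "MolecularGrid")) gridValues(grid) else grid
  stopifnot(length(dim(x)) == 3L)
  x4 <- array(x, c(dim(x), 1L))
  fw <- .forward(model@params, model@config, x4, training = FALSE,
                 keepMaps = TRUE)
  lapply(fw$maps, function(m) aperm(array(m, dim(m)[1:3]), c(3L, 1L, 2L)))
}
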