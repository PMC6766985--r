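test_that("binary cross-entropy matches closed forms and a scalar loop", {
  expect_equal(bceLoss(1 - 1e-9, 1), 0, tolerance = 1e-6)
  expect_equal(bceLoss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(bceLoss(c(0.9, 0.2), c(1, 0)),
               mean(c(-log(0.9), -log(0.8))), tolerance = 1e-12)
  expect_equal(bceLoss(c(0.9, 0.2), c(1, 0)), 0.164252, tolerance = 1e-6)
  ## epsilon clipping keeps the loss finite at the boundaries
  expect_true(is.finite(bceLoss(c(0, 1), c(1, 0))))
  ## oracle equality on random weighted batches
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    p <- runif(n)
    y <- rbinom(n, 1, 0.5)
    w <- c(pos = runif(1, 0.5, 40), neg = runif(1, 0.5, 2))
    expect_equal(bceLoss(p, y, w), loopBce(p, y, w[["pos"]], w[["neg"]]),
                 tolerance = 1e-9)
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- cnnConfig(inputShape = c(2L, 8L, 8L), convFilters = c(2L, 3L),
                   denseUnits = 4L, dropoutInput = 0, l2 = 0, epochs = 1L,
                   batchSize = 3L, seed = 2L, scaleInputs = FALSE)
  model <- buildModel(cfg)
  p <- model@params
  set.seed(7)
  x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  y <- c(1, 0, 1)
  w <- c(pos = 1.3, neg = 0.8)
  fw <- GridTox:::.forward(p, cfg, x)
  g <- GridTox:::.backward(p, cfg, fw, y, w)
  gl <- GridTox:::.paramList(g)
  pl <- GridTox:::.paramList(p)
  lossAt <- function(lst) {
    p2 <- GridTox:::.setParams(p, lst)
    bceLoss(GridTox:::.forward(p2, cfg, x)$yHat, y, w)
  }
  h <- 1e-5
  for (nm in names(pl)) {
    idx <- sample(length(pl[[nm]]), min(4, length(pl[[nm]])))
    for (i in idx) {
      up <- pl; up[[nm]][i] <- up[[nm]][i] + h
      dn <- pl; dn[[nm]][i] <- dn[[nm]][i] - h
      numeric_grad <- (lossAt(up) - lossAt(dn)) / (2 * h)
      expect_equal(gl[[nm]][i], numeric_grad, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("the architecture halves feature maps at each pooling stage", {
  cfg48 <- cnnConfig(inputShape = c(6L, 48L, 48L))
  m48 <- buildModel(cfg48)
  expect_equal(vapply(m48@params$dims, `[[`, numeric(1), "h2"), c(24, 12, 6))
  cfg12 <- cnnConfig(inputShape = c(6L, 12L, 12L))
  m12 <- buildModel(cfg12)
  expect_equal(vapply(m12@params$dims, `[[`, numeric(1), "h2"), c(6, 3, 1))
  ## grids too small for three poolings are a fatal config error
  expect_error(cnnConfig(inputShape = c(6L, 7L, 7L)), "too small")
})

test_that("depth variants for the layer sweep are constructible", {
  counts <- sapply(1:6, function(d) {
    filters <- if (d == 1) integer() else as.integer(32 * 2^(seq_len(d - 1) - 1))
    m <- buildModel(cnnConfig(inputShape = c(6L, 48L, 48L),
                              convFilters = filters, seed = 1L))
    convPar <- sum(vapply(m@params$blocks,
                          function(b) length(b$W) + length(b$b), numeric(1)))
    c(conv = convPar, total = parameterCount(m))
  })
  ## each added block enlarges the convolutional stack
  expect_true(all(diff(counts["conv", ]) > 0))
  expect_true(all(counts["total", ] > 0))
})

test_that("model building is deterministic under the config seed", {
  cfg <- cnnConfig(inputShape = c(6L, 12L, 12L), seed = 9L)
  m1 <- buildModel(cfg)
  m2 <- buildModel(cfg)
  expect_identical(m1@params$blocks, m2@params$blocks)
  expect_identical(m1@params$dense, m2@params$dense)
})

test_that("feature maps have the architecture's shapes and respect zero input", {
  m <- buildModel(cnnConfig(inputShape = c(6L, 48L, 48L), seed = 3L))
  zero <- array(0, c(48, 48, 6))
  fm <- featureMaps(m, zero)
  expect_equal(lapply(fm, dim),
               list(c(32L, 24L, 24L), c(64L, 12L, 12L), c(128L, 6L, 6L)))
  ## biases initialize at zero, so a zero grid gives zero activations
  expect_true(all(vapply(fm, function(a) all(a == 0), logical(1))))
  set.seed(5)
  fm2 <- featureMaps(m, array(rnorm(48 * 48 * 6), c(48, 48, 6)))
  expect_true(all(vapply(fm2, function(a) all(is.finite(a)), logical(1))))
})

test_that("a small network memorizes a tiny training set", {
  set.seed(21)
  x <- array(rnorm(12 * 12 * 2 * 16), c(12, 12, 2, 16))
  y <- rep(c(0, 1), 8)
  cfg <- cnnConfig(inputShape = c(2L, 12L, 12L), convFilters = c(8L, 16L),
                   denseUnits = 32L, dropoutInput = 0, l2 = 0, lr = 1e-3,
                   epochs = 200L, batchSize = 16L, seed = 4L)
  fit <- trainCNN(x, y, cfg)
  expect_equal(length(lossHistory(fit)), 200L)
  expect_lt(tail(lossHistory(fit), 1), 0.05)
})

test_that("training is reproducible and responds to loss weights", {
  set.seed(22)
  x <- array(rnorm(12 * 12 * 3 * 10), c(12, 12, 3, 10))
  y <- rep(c(0, 1), 5)
  cfg <- cnnConfig(inputShape = c(3L, 12L, 12L), convFilters = c(4L),
                   denseUnits = 8L, epochs = 4L, seed = 11L)
  f1 <- trainCNN(x, y, cfg)
  f2 <- trainCNN(x, y, cfg)
  expect_identical(lossHistory(f1), lossHistory(f2))
  expect_identical(predictCNN(f1, x), predictCNN(f2, x))
  f3 <- trainCNN(x, y, cfg, weights = c(pos = 5, neg = 1))
  expect_false(identical(lossHistory(f1), lossHistory(f3)))
})

test_that("trapezoidal AUC equals exhaustive concordant-pair counting", {
  expect_equal(aucFromScores(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(aucFromScores(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_warning(a <- aucFromScores(c(0.9, 0.8), c(1, 1)), "single class")
  expect_true(is.na(a))
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(4:60, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(aucFromScores(scores, y), pairAuc(scores, y),
                 tolerance = 1e-12)
  }
})

test_that("our AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  for (rep in 1:10) {
    n <- 50
    scores <- round(runif(n), 2)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(aucFromScores(scores, y), ref, tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone from (0,0) to (1,1)", {
  set.seed(43)
  scores <- runif(40)
  y <- c(0, 1, rbinom(38, 1, 0.5))
  roc <- rocCurve(scores, y)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(tail(roc$fpr, 1), 1); expect_equal(tail(roc$tpr, 1), 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("evaluateModel reports NA AUC for single-class splits", {
  cfg <- cnnConfig(inputShape = c(2L, 12L, 12L), convFilters = c(4L),
                   denseUnits = 8L, epochs = 2L, seed = 1L)
  set.seed(44)
  x <- array(rnorm(12 * 12 * 2 * 8), c(12, 12, 2, 8))
  fit <- trainCNN(x, rep(c(0, 1), 4), cfg)
  rep1 <- suppressWarnings(evaluateModel(fit, x, rep(1, 8)))
  expect_true(is.na(aucValue(rep1)))
  rep2 <- evaluateModel(fit, x, rep(c(0, 1), 4), task = "t")
  expect_true(aucValue(rep2) >= 0 && aucValue(rep2) <= 1)
})
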