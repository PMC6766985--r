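## Pipeline runners tying the modules together: featurize-and-archive,
## per-endpoint training with imbalance handling, channel ablations, and
## the hidden-layer depth sweep. Every runner is reproducible from its
## arguments plus a seed; configs are persisted next to outputs.

#' Write a grid archive
#'
#' Serializes a \code{\link{GridSet}} to \code{grids.rds} in \code{dir}
#' with a JSON sidecar recording the grid geometry, channel order, typing
#' rule version and label counts. Reloading is bit-exact.
#'
#' @param gs a \code{\link{GridSet}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the archive directory.
#' @export
writeGridArchive <- function(gs, dir) {
  stopifnot(is(gs, "GridSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(gs, file.path(dir, "grids.rds"))
  spec <- metadata(gs)$gridSpec
  cd <- as.data.frame(colData(gs))
  tasks <- setdiff(colnames(cd), "split")
  sidecar <- list(
    n_molecules = ncol(gs),
    extent = gridExtent(spec), resolution = gridResolution(spec),
    n_pixels = nPixels(spec),
    channel_order = metadata(gs)$channelOrder,
    typing_rules_version = metadata(gs)$typingRulesVersion,
    channel_stats = lapply(stats::setNames(nm = channelNames()), function(ch) {
      a <- assay(gs, ch)
      list(mean = mean(a), max = max(a), min = min(a))
    }),
    tasks = lapply(stats::setNames(nm = tasks), function(tk)
      list(active = sum(cd[[tk]] == 1, na.rm = TRUE),
           inactive = sum(cd[[tk]] == 0, na.rm = TRUE),
           missing = sum(is.na(cd[[tk]])))))
  jsonlite::write_json(sidecar, file.path(dir, "archive.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a grid archive
#'
#' @param dir archive directory written by \code{\link{writeGridArchive}}.
#' @return The \code{\link{GridSet}}.
#' @export
readGridArchive <- function(dir) {
  f <- file.path(dir, "grids.rds")
  if (!file.exists(f)) stop("no grid archive in ", dir)
  gs <- readRDS(f)
  stopifnot(is(gs, "GridSet"))
  gs
}

#' Featurize a molecule table end to end
#'
#' Reads molecules, standardizes (explicit hydrogens, aromatization,
#' InChIKeys), deduplicates, embeds coordinates and computes the
#' six-channel grids, then archives the result. Record-level failures are
#' logged; the run fails only when nothing survives.
#'
#' @param input path to a SMILES table or SDF file, or an existing
#'   \code{\link{MoleculeSet}}.
#' @param outDir output directory for the archive (optional).
#' @param spec a \code{\link{GridSpec}} (default 24 A / 0.5 A).
#' @param format input format, see \code{\link{readMolecules}}.
#' @return The \code{\link{GridSet}}, invisibly when archiving.
#' @export
runFeaturize <- function(input, outDir = NULL, spec = GridSpec(),
                         format = "smiles-table") {
  mset <- if (is(input, "MoleculeSet")) input
          else readMolecules(input, format = format)
  mset <- standardizeMolecules(mset)
  mset <- deduplicateMolecules(mset)
  if (length(mset) == 0L) stop("no molecules left after deduplication")
  gs <- featurizeSet(mset, spec)
  if (!is.null(outDir)) {
    writeGridArchive(gs, outDir)
    jsonlite::write_json(list(extent = gridExtent(spec),
                              resolution = gridResolution(spec),
                              input = if (is.character(input)) input else "in-memory",
                              format = format),
                         file.path(outDir, "featurize_config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(gs))
  }
  gs
}

## pull the (x, y) arrays for one task/split from a GridSet
.taskSplit <- function(gs, task, split, channels) {
  cd <- colData(gs)
  if (!task %in% colnames(cd)) stop("task '", task, "' not in the GridSet")
  sel <- which(cd$split == split & !is.na(cd[[task]]))
  if (length(sel) == 0L) stop("no labeled '", split, "' samples for ", task)
  list(x = gridArray(gs[, sel], channels), y = as.numeric(cd[[task]][sel]))
}

#' Train and evaluate one endpoint model
#'
#' Applies imbalance handling to the training split only (SMOTE over
#' flattened grids and/or positive-class loss weights), trains the
#' convolutional classifier, and evaluates threshold-free on the test
#' split. Test and verification splits are never resampled.
#'
#' @param gs a \code{\link{GridSet}} (or archive directory path).
#' @param task label column to model.
#' @param channels channel subset used as input (default all six).
#' @param smoteEnabled,smoteK,smoteRatio SMOTE switches
#'   (\code{\link{smote}}); default on, k = 5, ratio 1.
#' @param weightsEnabled use \code{\link{classWeights}} in the loss
#'   (default FALSE -- SMOTE already rebalances).
#' @param epochs,lr,l2,denseUnits,convFilters,batchSize,dropoutInput
#'   hyperparameters forwarded to \code{\link{cnnConfig}}.
#' @param seed RNG seed controlling SMOTE and training.
#' @param outDir optional directory for the evaluation CSVs and config.
#' @return List with \code{model} (\code{\link{TrainedCNN}}), \code{report}
#'   (\code{\link{EvalReport}}) and \code{aucTable} (data.frame).
#' @export
runTrain <- function(gs, task, channels = channelNames(),
                     smoteEnabled = TRUE, smoteK = 5L, smoteRatio = 1,
                     weightsEnabled = FALSE, epochs = 60L, lr = 1e-3,
                     l2 = 1e-3, denseUnits = 128L,
                     convFilters = c(32L, 64L, 128L), batchSize = 32L,
                     dropoutInput = 0.2, seed = 1L, outDir = NULL) {
  if (is.character(gs)) gs <- readGridArchive(gs)
  spec <- metadata(gs)$gridSpec
  n <- nPixels(spec)
  tr <- .taskSplit(gs, task, "train", channels)
  te <- .taskSplit(gs, task, "test", channels)
  x <- tr$x; y <- tr$y
  if (smoteEnabled && length(unique(y)) == 2L &&
      min(table(y)) < floor(smoteRatio * max(table(y)))) {
    flat <- t(matrix(x, prod(dim(x)[1:3]), dim(x)[4L]))
    res <- smote(flat, y, k = smoteK, targetRatio = smoteRatio, seed = seed)
    x <- array(t(res$x), c(dim(x)[1:3], nrow(res$x)))
    y <- res$y
  }
  weights <- if (weightsEnabled) classWeights(y) else NULL
  cfg <- cnnConfig(inputShape = c(length(channels), n, n),
                   convFilters = convFilters, denseUnits = denseUnits,
                   dropoutInput = dropoutInput, l2 = l2, lr = lr,
                   epochs = epochs, batchSize = batchSize, seed = seed)
  model <- trainCNN(x, y, cfg, weights = weights)
  model@meta$channels <- channels
  model@meta$gridSpec <- spec
  report <- evaluateModel(model, te$x, te$y, task = task, split = "test")
  aucTable <- data.frame(task = task, split = "test", auc = aucValue(report),
                         stringsAsFactors = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(aucTable, file.path(outDir, "auc.csv"), row.names = FALSE)
    utils::write.csv(rocPoints(report), file.path(outDir, "roc.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(epoch = seq_along(lossHistory(model)),
                                loss = lossHistory(model)),
                     file.path(outDir, "loss.csv"), row.names = FALSE)
    jsonlite::write_json(list(task = task, channels = channels,
                              smote = list(enabled = smoteEnabled, k = smoteK,
                                           ratio = smoteRatio),
                              weights = list(enabled = weightsEnabled),
                              epochs = epochs, lr = lr, l2 = l2,
                              denseUnits = denseUnits, seed = seed),
                         file.path(outDir, "train_config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(model = model, report = report, aucTable = aucTable)
}

#' Leave-one-channel-out ablation
#'
#' Trains the full six-channel model plus one variant per van der Waals
#' channel with that channel removed (the hydrogen-bond channel is always
#' retained) and tabulates the test AUCs.
#'
#' @param gs a \code{\link{GridSet}} (or archive directory path).
#' @param task label column to model.
#' @param ... forwarded to \code{\link{runTrain}} (epochs, seed, ...).
#' @return data.frame with columns variant, removed, auc.
#' @export
runAblate <- function(gs, task, ...) {
  if (is.character(gs)) gs <- readGridArchive(gs)
  variants <- c(list(full = channelNames()),
                lapply(stats::setNames(nm = vdwChannelNames()), function(ch)
                  setdiff(channelNames(), ch)))
  out <- lapply(names(variants), function(v) {
    fit <- runTrain(gs, task, channels = variants[[v]], ...)
    data.frame(variant = if (v == "full") "full" else paste0("minus_", v),
               removed = if (v == "full") "" else v,
               auc = fit$aucTable$auc, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hidden-layer depth sweep
#'
#' Trains variants with 1 to 6 hidden layers -- d - 1 convolutional blocks
#' (filter counts 32, 64, 128, ... doubling) plus one dense hidden layer --
#' and tabulates the test AUC per depth. Depths whose pooling stack
#' collapses the grid below one pixel are rejected by the config check.
#'
#' @param gs a \code{\link{GridSet}} (or archive directory path).
#' @param task label column to model.
#' @param depths hidden-layer counts to train (default 1:4).
#' @param ... forwarded to \code{\link{runTrain}}.
#' @return data.frame with columns depth, auc.
#' @export
depthSweep <- function(gs, task, depths = 1:4, ...) {
  if (is.character(gs)) gs <- readGridArchive(gs)
  out <- lapply(depths, function(d) {
    filters <- if (d == 1L) integer() else as.integer(32 * 2^(seq_len(d - 1L) - 1L))
    fit <- runTrain(gs, task, convFilters = filters, ...)
    data.frame(depth = d, auc = fit$aucTable$auc)
  })
  do.call(rbind, out)
}
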