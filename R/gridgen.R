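## Grid generation: embed a molecule in a planar frame and evaluate the two
## potential equations on a square pixel grid, one layer per descriptor
## channel.
##
## The five non-hydrogen-bond channels use a bounded van der Waals term:
## each atom contributes 1 - exp(-(r_vdw / r)^12) to a pixel at distance r,
## a value in [0, 1) that saturates to 1 as the pixel approaches the atom
## (the r = 0 limit is exactly 1, so no singularity). The hydrogen-bond
## channel uses the 12-10 potential C / r^12 - D / r^10, which is singular
## at r = 0; distances are clamped below at 0.5 A and the summed pixel
## values are clipped to a documented range so the CNN inputs stay bounded.

#' Embed a molecule in the canonical planar frame
#'
#' Takes the 2D depiction coordinates produced during standardization and
#' (1) rescales them so the mean bond length is 1.5 A, (2) translates the
#' atom centroid to the origin, and (3) rotates the first principal axis of
#' the coordinates onto x, with third-moment sign conventions so the
#' orientation is deterministic. Featurization is therefore a pure function
#' of the molecular graph. Set \code{canonical = FALSE} to skip step (3)
#' (useful for rotation-covariance checks).
#'
#' @param mol a \code{GridMolecule} with depiction coordinates.
#' @param canonical apply the principal-axis rotation (default TRUE).
#' @param targetBondLength mean bond length after rescaling, in Angstrom.
#' @return The molecule with \code{coords} replaced by embedded coordinates.
#' @export
embedCoordinates <- function(mol, canonical = TRUE, targetBondLength = 1.5) {
  stopifnot(is(mol, "GridMolecule"))
  xy <- mol@coords
  if (nrow(xy) == 0L)
    stop("molecule '", mol@id, "' has no depiction coordinates to embed")
  bonds <- mol@bonds
  if (nrow(bonds) > 0L) {
    d <- sqrt(rowSums((xy[bonds[, 1L], , drop = FALSE] -
                       xy[bonds[, 2L], , drop = FALSE])^2))
    mbl <- mean(d[d > 1e-12])
    if (is.finite(mbl) && mbl > 1e-12) xy <- xy * (targetBondLength / mbl)
  }
  xy <- sweep(xy, 2L, colMeans(xy))
  if (canonical && nrow(xy) > 1L) {
    cv <- crossprod(xy) / nrow(xy)
    ev <- eigen(cv, symmetric = TRUE)
    proj <- xy %*% ev$vectors
    for (k in 1:2) {
      s3 <- sum(proj[, k]^3)
      if (abs(s3) < 1e-9) s3 <- max(proj[, k]) + min(proj[, k])
      if (s3 < 0) proj[, k] <- -proj[, k]
    }
    xy <- proj
    xy <- sweep(xy, 2L, colMeans(xy))  # numerical re-centering
  }
  dimnames(xy) <- NULL
  mol@coords <- xy
  mol
}

## distances from one atom to every pixel centre; n x n matrix (row = y)
.pixelDistances <- function(spec, x, y) {
  ctr <- pixelCenters(spec)
  sqrt(outer((ctr - y)^2, (ctr - x)^2, "+"))
}

#' van der Waals grid for one channel
#'
#' Evaluates, at every pixel centre, the sum over the channel's member
#' atoms of \code{1 - exp(-(r_vdw / r)^12)} where r is the Euclidean
#' distance from the atom to the pixel centre. Each per-atom term lies in
#' [0, 1), taking the limit value 1 at r = 0, so a pixel value is bounded
#' by the member-atom count. Atoms outside the window still contribute to
#' in-window pixels; their far-field terms underflow to 0 naturally.
#'
#' @param mol a \code{GridMolecule} with embedded coordinates.
#' @param typing the molecule's \code{ChannelTyping}.
#' @param channel one of the five van der Waals channel names (or its
#'   index 2..6 in \code{channelNames()}).
#' @param spec a \code{GridSpec}.
#' @return n x n numeric matrix (row 1 = minimum-y row).
#' @export
vdwGrid <- function(mol, typing, channel, spec = GridSpec()) {
  if (is.numeric(channel)) channel <- channelNames()[channel]
  if (!channel %in% vdwChannelNames())
    stop("'", channel, "' is not a van der Waals channel")
  n <- nPixels(spec)
  G <- matrix(0, n, n)
  member <- which(channelMembership(typing)[, channel])
  xy <- mol@coords
  rv <- vdwRadii(typing)
  for (a in member) {
    r <- .pixelDistances(spec, xy[a, 1L], xy[a, 2L])
    G <- G - expm1(-(rv[a] / r)^12)   # 1 - exp(-x); exact 1 at r = 0
  }
  G
}

#' Hydrogen-bond grid (12-10 potential)
#'
#' Evaluates, at every pixel centre, the sum over donor/acceptor atoms of
#' \code{C / r^12 - D / r^10} with that atom's well coefficients. Distances
#' are clamped below at \code{rMin} before evaluation and the summed pixel
#' values are clipped to \code{clamp}, keeping the channel bounded despite
#' the r -> 0 singularity. Clamping events are logged.
#'
#' @param mol a \code{GridMolecule} with embedded coordinates.
#' @param typing the molecule's \code{ChannelTyping}.
#' @param spec a \code{GridSpec}.
#' @param rMin distance clamp in Angstrom (default 0.5).
#' @param clamp length-2 numeric, final value clip (default c(-50, 50),
#'   i.e. ten times the deepest well).
#' @return n x n numeric matrix.
#' @export
hbondGrid <- function(mol, typing, spec = GridSpec(), rMin = 0.5,
                      clamp = c(-50, 50)) {
  n <- nPixels(spec)
  G <- matrix(0, n, n)
  member <- which(hbondRoles(typing) != "none")
  xy <- mol@coords
  for (a in member) {
    r <- pmax(.pixelDistances(spec, xy[a, 1L], xy[a, 2L]), rMin)
    G <- G + typing@hbondC[a] / r^12 - typing@hbondD[a] / r^10
  }
  nClip <- sum(G < clamp[1L] | G > clamp[2L])
  if (nClip > 0L)
    gtLog("hbond grid of '%s': clipped %d pixel(s) to [%g, %g]", mol@id,
          nClip, clamp[1L], clamp[2L])
  pmin(pmax(G, clamp[1L]), clamp[2L])
}

#' Featurize a molecule as a six-channel grid
#'
#' Runs coordinate embedding (for chemistry-derived molecules), channel
#' typing, the five van der Waals grids and the hydrogen-bond grid, and
#' stacks the channels in canonical order. For \code{ToyMolecule} fixtures
#' the attached typing and stored coordinates are used as-is.
#'
#' @param mol a \code{GridMolecule} or \code{ToyMolecule}.
#' @param spec a \code{GridSpec} (default 24 A / 0.5 A).
#' @param ... passed on (\code{canonical}, \code{rMin}, \code{clamp}).
#' @return A \code{\link{MolecularGrid}}.
#' @export
setGeneric("featurize", function(mol, spec = GridSpec(), ...)
  standardGeneric("featurize"))

.stackChannels <- function(mol, typing, spec, rMin, clamp) {
  n <- nPixels(spec)
  if (any(abs(mol@coords) > gridExtent(spec) / 2))
    gtWarn("molecule '%s' extends beyond the %g A window; kept unscaled",
           mol@id, gridExtent(spec))
  vals <- array(0, dim = c(n, n, 6L), dimnames = list(NULL, NULL, channelNames()))
  vals[, , "hbond"] <- hbondGrid(mol, typing, spec, rMin = rMin, clamp = clamp)
  for (ch in vdwChannelNames()) vals[, , ch] <- vdwGrid(mol, typing, ch, spec)
  new("MolecularGrid", values = vals, spec = spec, id = mol@id)
}

#' @rdname featurize
#' @param canonical canonical orientation for the embedding (default TRUE).
#' @param rMin,clamp hydrogen-bond grid guards, see \code{\link{hbondGrid}}.
#' @export
setMethod("featurize", "GridMolecule",
          function(mol, spec = GridSpec(), canonical = TRUE, rMin = 0.5,
                   clamp = c(-50, 50), ...) {
  mol <- embedCoordinates(mol, canonical = canonical)
  typing <- assignChannels(mol)
  .stackChannels(mol, typing, spec, rMin, clamp)
})

#' @rdname featurize
#' @export
setMethod("featurize", "ToyMolecule",
          function(mol, spec = GridSpec(), rMin = 0.5, clamp = c(-50, 50), ...) {
  .stackChannels(mol, mol@typing, spec, rMin, clamp)
})

#' Featurize a molecule set into a GridSet
#'
#' Applies \code{\link{featurize}} to every molecule and assembles the
#' results as a \code{\link{GridSet}} (a SummarizedExperiment with one
#' flattened-grid assay per channel; labels and split tags in colData).
#' Record-level failures are logged and skipped, never aborting the batch.
#'
#' @param mset a standardized \code{\link{MoleculeSet}} (or a list of
#'   \code{ToyMolecule} with a labels data.frame via \code{labels}/\code{split}).
#' @param spec a \code{GridSpec}.
#' @param labels optional data.frame of task labels (taken from \code{mset}
#'   when it is a MoleculeSet).
#' @param split optional split tags.
#' @param ... passed to \code{\link{featurize}}.
#' @return A \code{\link{GridSet}}.
#' @export
featurizeSet <- function(mset, spec = GridSpec(), labels = NULL, split = NULL,
                         ...) {
  if (is(mset, "MoleculeSet")) {
    mols <- molecules(mset)
    ids <- moleculeIds(mset)
    if (is.null(labels)) labels <- as.data.frame(labelTable(mset))
    if (is.null(split)) split <- splitTags(mset)
  } else {
    mols <- mset
    ids <- vapply(mols, function(m) m@id, character(1L))
  }
  n <- nPixels(spec)
  ok <- logical(length(mols))
  grids <- vector("list", length(mols))
  for (i in seq_along(mols)) {
    g <- tryCatch(featurize(mols[[i]], spec, ...), error = function(e) {
      gtLog("featurization failed for '%s': %s", ids[i], conditionMessage(e),
            level = "WARN")
      NULL
    })
    if (!is.null(g)) { grids[[i]] <- g; ok[i] <- TRUE }
  }
  if (!any(ok)) stop("featurization produced no grids")
  grids <- grids[ok]; ids <- ids[ok]
  asy <- lapply(stats::setNames(nm = channelNames()), function(ch) {
    m <- vapply(grids, function(g) as.vector(g@values[, , ch]), numeric(n * n))
    colnames(m) <- ids
    m
  })
  cd <- DataFrame(row.names = ids)
  if (!is.null(labels) && ncol(as.data.frame(labels)) > 0L) {
    lab <- as.data.frame(labels)[ok, , drop = FALSE]
    for (cc in colnames(lab)) cd[[cc]] <- lab[[cc]]
  }
  cd$split <- if (is.null(split)) rep("train", length(ids)) else split[ok]
  se <- SummarizedExperiment(assays = asy, colData = cd)
  metadata(se)$gridSpec <- spec
  metadata(se)$channelOrder <- channelNames()
  metadata(se)$typingRulesVersion <- typingRulesVersion()
  new("GridSet", se)
}

#' Extract the 4D grid array from a GridSet
#'
#' @param gs a \code{\link{GridSet}}.
#' @param channels channel names to keep (default all six, canonical order).
#' @return Numeric array of dimension (n, n, channels, molecules) -- the
#'   layout consumed by \code{\link{trainCNN}}.
#' @export
gridArray <- function(gs, channels = channelNames()) {
  stopifnot(is(gs, "GridSet"))
  spec <- metadata(gs)$gridSpec
  n <- nPixels(spec)
  N <- ncol(gs)
  out <- array(0, dim = c(n, n, length(channels), N))
  for (k in seq_along(channels))
    out[, , k, ] <- array(assay(gs, channels[k]), dim = c(n, n, N))
  dimnames(out) <- list(NULL, NULL, channels, colnames(gs))
  out
}
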