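#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assays assay colData
NULL

#' Six descriptor channels, in fixed order
#'
#' Channel order used throughout the package: hydrogen bond first, then the
#' five van der Waals channels (hydrophobicity, metallicity, excluded volume,
#' positive ionization, negative ionization). The hydrogen-bond channel is
#' computed with the 12-10 potential; all others with the bounded van der
#' Waals term.
#'
#' @return Character vector of the six channel names.
#' @export
#' @examples
#' channelNames()
channelNames <- function() {
  c("hbond", "hydrophobicity", "metallicity", "excluded_volume",
    "positive_ionization", "negative_ionization")
}

## names of the five channels gridded with the vdW equation
vdwChannelNames <- function() channelNames()[-1L]

#' GridSpec: geometry of the 2D molecular grid
#'
#' A square window of side \code{extent} Angstrom centred on the molecule
#' centroid, discretized at \code{resolution} Angstrom per pixel. Pixel
#' centres lie at \code{-extent/2 + (i - 0.5) * resolution}; row 1 is the
#' minimum-y row. The defaults (24 A window, 0.5 A pixels) give 48 x 48
#' grids; 1.0 A and 2.0 A give 24 x 24 and 12 x 12.
#'
#' @slot extent numeric(1), window side length in Angstrom.
#' @slot resolution numeric(1), pixel edge in Angstrom; must divide extent.
#' @export
setClass("GridSpec", representation(extent = "numeric", resolution = "numeric"),
         prototype(extent = 24, resolution = 0.5))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@extent) != 1L || !is.finite(object@extent) || object@extent <= 0)
    msg <- c(msg, "'extent' must be a single positive number")
  if (length(object@resolution) != 1L || !is.finite(object@resolution) ||
      object@resolution <= 0)
    msg <- c(msg, "'resolution' must be a single positive number")
  if (length(msg) == 0L) {
    n <- object@extent / object@resolution
    if (abs(n - round(n)) > 1e-9)
      msg <- c(msg, "'resolution' must divide 'extent' exactly")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GridSpec-class
#' @param extent window side length in Angstrom (default 24).
#' @param resolution pixel edge length in Angstrom (default 0.5).
#' @return A \code{GridSpec} object.
#' @export
#' @examples
#' GridSpec()                      # 48 x 48
#' nPixels(GridSpec(24, 2))        # 12
GridSpec <- function(extent = 24, resolution = 0.5) {
  new("GridSpec", extent = extent, resolution = resolution)
}

#' @rdname GridSpec-class
#' @param object,x a \code{GridSpec}.
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' @rdname GridSpec-class
#' @export
setMethod("nPixels", "GridSpec", function(x) {
  as.integer(round(x@extent / x@resolution))
})

#' @rdname GridSpec-class
#' @export
setGeneric("pixelCenters", function(x) standardGeneric("pixelCenters"))

#' @rdname GridSpec-class
#' @export
setMethod("pixelCenters", "GridSpec", function(x) {
  n <- nPixels(x)
  -x@extent / 2 + (seq_len(n) - 0.5) * x@resolution
})

#' @rdname GridSpec-class
#' @export
setGeneric("gridExtent", function(x) standardGeneric("gridExtent"))
#' @rdname GridSpec-class
#' @export
setMethod("gridExtent", "GridSpec", function(x) x@extent)

#' @rdname GridSpec-class
#' @export
setGeneric("gridResolution", function(x) standardGeneric("gridResolution"))
#' @rdname GridSpec-class
#' @export
setMethod("gridResolution", "GridSpec", function(x) x@resolution)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %g A x %g A window, %g A pixels (%d x %d)\n",
              object@extent, object@extent, object@resolution,
              nPixels(object), nPixels(object)))
})

#' GridMolecule: a parsed molecule with planar coordinates
#'
#' Light connection-table representation used by the featurizer: element
#' symbols, formal charges, aromatic flags, a bond list and (once embedded)
#' per-atom 2D coordinates in Angstrom. Explicit hydrogens are ordinary
#' atoms. Produced by \code{\link{standardizeMolecules}} or constructed
#' directly for toy fixtures.
#'
#' @slot id character(1) molecule identifier.
#' @slot element character vector of element symbols.
#' @slot charge numeric vector of formal charges.
#' @slot aromatic logical vector, TRUE for atoms in aromatic rings.
#' @slot coords numeric matrix (n x 2) of (x, y) in Angstrom, or 0-row if
#'   not yet embedded.
#' @slot bonds numeric matrix (m x 3): atom index pair and bond order.
#' @export
setClass("GridMolecule",
         representation(id = "character", element = "character",
                        charge = "numeric", aromatic = "logical",
                        coords = "matrix", bonds = "matrix"))

setValidity("GridMolecule", function(object) {
  n <- length(object@element)
  msg <- character()
  if (n < 1L) msg <- c(msg, "molecule must have at least one atom")
  if (length(object@charge) != n || length(object@aromatic) != n)
    msg <- c(msg, "'charge' and 'aromatic' must have one entry per atom")
  if (nrow(object@coords) != 0L &&
      (nrow(object@coords) != n || ncol(object@coords) != 2L))
    msg <- c(msg, "'coords' must be empty or an n x 2 matrix")
  if (nrow(object@coords) > 0L && !all(is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (nrow(object@bonds) > 0L) {
    a <- object@bonds[, 1L]; b <- object@bonds[, 2L]
    if (any(a < 1 | a > n | b < 1 | b > n)) msg <- c(msg, "bond index out of range")
    if (any(a == b)) msg <- c(msg, "bond endpoints must be distinct")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GridMolecule-class
#' @param id molecule identifier.
#' @param element character vector of element symbols.
#' @param charge numeric vector of formal charges (default 0).
#' @param aromatic logical vector of aromatic flags (default FALSE).
#' @param coords n x 2 coordinate matrix in Angstrom, or NULL.
#' @param bonds m x 3 matrix (i, j, order), or NULL for no bonds.
#' @return A \code{GridMolecule}.
#' @export
GridMolecule <- function(id, element, charge = numeric(length(element)),
                         aromatic = logical(length(element)),
                         coords = NULL, bonds = NULL) {
  if (is.null(coords)) coords <- matrix(numeric(), 0L, 2L)
  if (is.null(bonds)) bonds <- matrix(numeric(), 0L, 3L)
  coords <- as.matrix(coords)
  bonds <- as.matrix(bonds)
  if (nrow(bonds) > 0L && ncol(bonds) == 2L) bonds <- cbind(bonds, 1)
  new("GridMolecule", id = as.character(id), element = as.character(element),
      charge = as.numeric(charge), aromatic = as.logical(aromatic),
      coords = coords, bonds = bonds)
}

#' @rdname GridMolecule-class
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))
#' @rdname GridMolecule-class
#' @export
setMethod("atomCount", "GridMolecule", function(x) length(x@element))

#' @rdname GridMolecule-class
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))
#' @rdname GridMolecule-class
#' @export
setMethod("atomCoords", "GridMolecule", function(x) x@coords)

#' @rdname GridMolecule-class
#' @export
setGeneric("atomElements", function(x) standardGeneric("atomElements"))
#' @rdname GridMolecule-class
#' @export
setMethod("atomElements", "GridMolecule", function(x) x@element)

#' @rdname GridMolecule-class
#' @export
setGeneric("molBonds", function(x) standardGeneric("molBonds"))
#' @rdname GridMolecule-class
#' @export
setMethod("molBonds", "GridMolecule", function(x) x@bonds)

setMethod("show", "GridMolecule", function(object) {
  cat(sprintf("GridMolecule '%s': %d atoms, %d bonds%s\n", object@id,
              atomCount(object), nrow(object@bonds),
              if (nrow(object@coords)) ", 2D coordinates set" else ""))
})

#' ChannelTyping: per-atom channel membership and grid parameters
#'
#' For every atom of a molecule: membership in the six descriptor channels,
#' the van der Waals radius used by the bounded vdW grid term, the
#' hydrogen-bond role, and the 12-10 potential coefficients (C, D) for
#' donor/acceptor atoms. Excluded volume is true for every atom by
#' construction; the hydrogen-bond channel is true exactly when the role is
#' not "none".
#'
#' @slot channels logical matrix (n atoms x 6), columns \code{channelNames()}.
#' @slot rVdw numeric vector of van der Waals radii in Angstrom.
#' @slot hbondRole character vector in {donor, acceptor, both, none}.
#' @slot hbondC,hbondD numeric vectors of 12-10 coefficients (0 when role
#'   is none).
#' @export
setClass("ChannelTyping",
         representation(channels = "matrix", rVdw = "numeric",
                        hbondRole = "character", hbondC = "numeric",
                        hbondD = "numeric"))

setValidity("ChannelTyping", function(object) {
  n <- nrow(object@channels)
  msg <- character()
  if (ncol(object@channels) != 6L ||
      !identical(colnames(object@channels), channelNames()))
    msg <- c(msg, "'channels' must have the six canonical channel columns")
  if (length(object@rVdw) != n || length(object@hbondRole) != n ||
      length(object@hbondC) != n || length(object@hbondD) != n)
    msg <- c(msg, "per-atom slots must all have one entry per atom")
  if (any(!object@channels[, "excluded_volume"]))
    msg <- c(msg, "excluded_volume must be TRUE for every atom")
  if (any(object@rVdw <= 0)) msg <- c(msg, "vdW radii must be positive")
  if (!all(object@hbondRole %in% c("donor", "acceptor", "both", "none")))
    msg <- c(msg, "invalid hydrogen-bond role")
  hb <- object@hbondRole != "none"
  if (any(hb != object@channels[, "hbond"]))
    msg <- c(msg, "hbond channel must match hbondRole != 'none'")
  if (any(hb & (object@hbondC <= 0 | object@hbondD <= 0)))
    msg <- c(msg, "C and D must be positive for donor/acceptor atoms")
  if (length(msg)) msg else TRUE
})

#' @rdname ChannelTyping-class
#' @param channels logical n x 6 matrix (columns in \code{channelNames()}
#'   order; names are added if missing).
#' @param rVdw numeric vector of vdW radii.
#' @param hbondRole character vector of roles (default all "none").
#' @param hbondC,hbondD 12-10 coefficients; computed from the role and a
#'   nitrogen/oxygen parameter class when omitted.
#' @return A \code{ChannelTyping}.
#' @export
ChannelTyping <- function(channels, rVdw, hbondRole = NULL,
                          hbondC = NULL, hbondD = NULL) {
  channels <- as.matrix(channels)
  colnames(channels) <- channelNames()
  n <- nrow(channels)
  if (is.null(hbondRole)) hbondRole <- rep("none", n)
  if (is.null(hbondC) || is.null(hbondD)) {
    hbondC <- hbondD <- numeric(n)
    for (i in which(hbondRole != "none")) {
      cd <- hbondParameters(hbondRole[i], "O")
      hbondC[i] <- cd[["C"]]; hbondD[i] <- cd[["D"]]
    }
  }
  channels[, "hbond"] <- hbondRole != "none"
  new("ChannelTyping", channels = channels, rVdw = as.numeric(rVdw),
      hbondRole = hbondRole, hbondC = as.numeric(hbondC),
      hbondD = as.numeric(hbondD))
}

#' @rdname ChannelTyping-class
#' @param x a \code{ChannelTyping}.
#' @export
setGeneric("channelMembership", function(x) standardGeneric("channelMembership"))
#' @rdname ChannelTyping-class
#' @export
setMethod("channelMembership", "ChannelTyping", function(x) x@channels)

#' @rdname ChannelTyping-class
#' @export
setGeneric("vdwRadii", function(x) standardGeneric("vdwRadii"))
#' @rdname ChannelTyping-class
#' @export
setMethod("vdwRadii", "ChannelTyping", function(x) x@rVdw)

#' @rdname ChannelTyping-class
#' @export
setGeneric("hbondRoles", function(x) standardGeneric("hbondRoles"))
#' @rdname ChannelTyping-class
#' @export
setMethod("hbondRoles", "ChannelTyping", function(x) x@hbondRole)

setMethod("show", "ChannelTyping", function(object) {
  cnt <- colSums(object@channels)
  cat("ChannelTyping:", nrow(object@channels), "atoms\n")
  cat(paste(sprintf("  %s: %d", names(cnt), cnt), collapse = "\n"), "\n")
})

#' ToyMolecule: a grid fixture with hand-assigned typing
#'
#' A \code{GridMolecule} whose channel memberships and grid parameters are
#' set directly instead of derived from chemistry, so the grid equations can
#' be tested in isolation. \code{\link{featurize}} uses the attached typing
#' and the stored coordinates as-is (no re-embedding).
#'
#' @slot typing a \code{ChannelTyping} for the atoms.
#' @export
setClass("ToyMolecule", contains = "GridMolecule",
         representation(typing = "ChannelTyping"))

#' @rdname ToyMolecule-class
#' @param mol a \code{GridMolecule} with coordinates.
#' @param typing a matching \code{ChannelTyping}.
#' @return A \code{ToyMolecule}.
#' @export
ToyMolecule <- function(mol, typing) {
  stopifnot(nrow(channelMembership(typing)) == atomCount(mol),
            nrow(atomCoords(mol)) == atomCount(mol))
  new("ToyMolecule", mol, typing = typing)
}

#' MoleculeSet: molecules with labels and splits
#'
#' Container tying parsed molecules to their per-task binary activity labels
#' and train/test/verification split tags. Labels are 0/1/NA; NA means the
#' endpoint was not measured for that compound.
#'
#' @slot mols list of \code{GridMolecule}.
#' @slot meta \code{DataFrame} with columns id, smiles, inchikey, split.
#' @slot labels \code{DataFrame}, one 0/1/NA column per task.
#' @export
setClass("MoleculeSet",
         representation(mols = "list", meta = "DataFrame", labels = "DataFrame"))

setValidity("MoleculeSet", function(object) {
  n <- length(object@mols)
  msg <- character()
  if (nrow(object@meta) != n || nrow(object@labels) != n)
    msg <- c(msg, "meta and labels must have one row per molecule")
  if (!all(c("id", "smiles", "inchikey", "split") %in% colnames(object@meta)))
    msg <- c(msg, "meta must have columns id, smiles, inchikey, split")
  if (anyDuplicated(object@meta$id))
    msg <- c(msg, "molecule ids must be unique")
  if (length(msg)) msg else TRUE
})

#' @rdname MoleculeSet-class
#' @param mols list of \code{GridMolecule}.
#' @param meta data.frame/DataFrame with id, smiles, inchikey, split.
#' @param labels data.frame/DataFrame of 0/1/NA task columns.
#' @return A \code{MoleculeSet}.
#' @export
MoleculeSet <- function(mols, meta, labels) {
  new("MoleculeSet", mols = mols, meta = DataFrame(meta),
      labels = DataFrame(labels, check.names = FALSE))
}

#' @rdname MoleculeSet-class
#' @param x a \code{MoleculeSet}.
#' @export
setMethod("length", "MoleculeSet", function(x) length(x@mols))

#' @rdname MoleculeSet-class
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = FALSE) {
  new("MoleculeSet", mols = x@mols[i], meta = x@meta[i, , drop = FALSE],
      labels = x@labels[i, , drop = FALSE])
})

#' @rdname MoleculeSet-class
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))
#' @rdname MoleculeSet-class
#' @export
setMethod("molecules", "MoleculeSet", function(x) x@mols)

#' @rdname MoleculeSet-class
#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))
#' @rdname MoleculeSet-class
#' @export
setMethod("moleculeIds", "MoleculeSet", function(x) as.character(x@meta$id))

#' @rdname MoleculeSet-class
#' @export
setGeneric("inchiKeys", function(x) standardGeneric("inchiKeys"))
#' @rdname MoleculeSet-class
#' @export
setMethod("inchiKeys", "MoleculeSet", function(x) as.character(x@meta$inchikey))

#' @rdname MoleculeSet-class
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))
#' @rdname MoleculeSet-class
#' @export
setMethod("labelTable", "MoleculeSet", function(x) x@labels)

#' @rdname MoleculeSet-class
#' @export
setGeneric("splitTags", function(x) standardGeneric("splitTags"))
#' @rdname MoleculeSet-class
#' @export
setMethod("splitTags", "MoleculeSet", function(x) as.character(x@meta$split))

setMethod("show", "MoleculeSet", function(object) {
  cat("MoleculeSet:", length(object), "molecules,",
      ncol(object@labels), "tasks\n")
  if (length(object)) {
    sp <- table(object@meta$split)
    cat("  splits:", paste(sprintf("%s=%d", names(sp), sp), collapse = ", "), "\n")
  }
})

#' MolecularGrid: six-channel grid for one molecule
#'
#' The CNN input for a single molecule: a \code{n x n x 6} array of
#' potential values (third dimension in \code{channelNames()} order; rows
#' index y from the minimum-y row, columns index x).
#'
#' @slot values numeric array (n, n, 6).
#' @slot spec the \code{GridSpec} used.
#' @slot id molecule identifier.
#' @export
setClass("MolecularGrid",
         representation(values = "array", spec = "GridSpec", id = "character"))

setValidity("MolecularGrid", function(object) {
  d <- dim(object@values)
  n <- nPixels(object@spec)
  if (length(d) != 3L || d[3L] != 6L) return("'values' must be n x n x 6")
  if (d[1L] != n || d[2L] != n) return("grid dimensions do not match the spec")
  TRUE
})

#' @rdname MolecularGrid-class
#' @param x a \code{MolecularGrid}.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname MolecularGrid-class
#' @export
setMethod("gridValues", "MolecularGrid", function(x) x@values)

#' @rdname MolecularGrid-class
#' @param channel channel name or index.
#' @export
setGeneric("channelGrid", function(x, channel) standardGeneric("channelGrid"))
#' @rdname MolecularGrid-class
#' @export
setMethod("channelGrid", "MolecularGrid", function(x, channel) {
  if (is.character(channel)) channel <- match(channel, channelNames())
  x@values[, , channel]
})

setMethod("show", "MolecularGrid", function(object) {
  n <- nPixels(object@spec)
  cat(sprintf("MolecularGrid '%s': 6 x %d x %d, range [%.4g, %.4g]\n",
              object@id, n, n, min(object@values), max(object@values)))
})

#' GridSet: featurized dataset as a SummarizedExperiment
#'
#' One assay per descriptor channel; each assay is a (pixels x molecules)
#' matrix of flattened grids (column-major over the n x n grid). Labels and
#' split tags live in \code{colData}; the \code{GridSpec} and channel order
#' in \code{metadata}. Use \code{\link{gridArray}} to recover the 4D array
#' consumed by the CNN.
#'
#' @export
setClass("GridSet", contains = "SummarizedExperiment")

setValidity("GridSet", function(object) {
  if (!all(channelNames() %in% names(assays(object))))
    return("GridSet must have one assay per descriptor channel")
  if (is.null(metadata(object)$gridSpec))
    return("GridSet metadata must record the GridSpec")
  TRUE
})

setMethod("show", "GridSet", function(object) {
  spec <- metadata(object)$gridSpec
  cat(sprintf("GridSet: %d molecules, 6 channels, %d x %d pixels (%g A / %g A)\n",
              ncol(object), nPixels(spec), nPixels(spec),
              gridExtent(spec), gridResolution(spec)))
  cn <- setdiff(colnames(colData(object)), "split")
  if (length(cn)) cat("  tasks:", paste(cn, collapse = ", "), "\n")
})

#' CNNConfig: architecture and training hyperparameters
#'
#' The default architecture has four hidden layers: three convolutional
#' blocks (3x3 kernels with same padding, rectifier, 2x2 max-pooling) with
#' 32, 64 and 128 filters, then one dense rectifier layer, then a single
#' sigmoid output. Training minimizes (optionally class-weighted) binary
#' cross-entropy with Adam and L2 weight decay; dropout is applied to the
#' input layer only.
#'
#' @slot inputShape integer(3): channels, height, width.
#' @slot convFilters integer vector of filter counts, one per conv block.
#' @slot denseUnits integer(1), hidden units of the dense layer.
#' @slot kernel,pool integer(1), kernel and pooling size (3 and 2).
#' @slot dropoutInput numeric(1), input dropout rate (default 0.20).
#' @slot l2 numeric(1), L2 weight decay coefficient.
#' @slot lr numeric(1), Adam learning rate.
#' @slot epochs,batchSize integer(1).
#' @slot seed integer(1), RNG seed for init/shuffling/dropout.
#' @slot scaleInputs logical(1), per-channel standardization of inputs.
#' @export
setClass("CNNConfig",
         representation(inputShape = "integer", convFilters = "integer",
                        denseUnits = "integer", kernel = "integer",
                        pool = "integer", dropoutInput = "numeric",
                        l2 = "numeric", lr = "numeric", epochs = "integer",
                        batchSize = "integer", seed = "integer",
                        scaleInputs = "logical"))

setValidity("CNNConfig", function(object) {
  msg <- character()
  if (length(object@inputShape) != 3L || any(object@inputShape < 1L))
    msg <- c(msg, "inputShape must be (channels, height, width), all >= 1")
  if (object@inputShape[2L] != object@inputShape[3L])
    msg <- c(msg, "grids must be square")
  if (any(object@convFilters < 1L)) msg <- c(msg, "filter counts must be >= 1")
  if (object@dropoutInput < 0 || object@dropoutInput >= 1)
    msg <- c(msg, "dropoutInput must be in [0, 1)")
  if (object@lr <= 0 || object@l2 < 0) msg <- c(msg, "lr > 0 and l2 >= 0 required")
  if (object@epochs < 1L || object@batchSize < 1L)
    msg <- c(msg, "epochs and batchSize must be >= 1")
  n <- object@inputShape[2L]
  for (k in seq_along(object@convFilters)) {
    n <- n %/% object@pool
    if (n < 1L)
      msg <- c(msg, sprintf(
        "input %d px is too small for %d pooling stages",
        object@inputShape[2L], length(object@convFilters)))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CNNConfig-class
#' @param inputShape integer(3) (channels, height, width).
#' @param convFilters filter counts per conv block (default c(32, 64, 128)).
#' @param denseUnits dense hidden units (default 128).
#' @param dropoutInput input dropout rate (default 0.2).
#' @param l2 L2 weight decay (default 1e-3).
#' @param lr learning rate (default 1e-3).
#' @param epochs training epochs (default 60).
#' @param batchSize mini-batch size (default 32).
#' @param seed RNG seed (default 1).
#' @param scaleInputs standardize each channel using training-set statistics
#'   (default TRUE).
#' @return A \code{CNNConfig}.
#' @export
#' @examples
#' cnnConfig(inputShape = c(6, 48, 48))
cnnConfig <- function(inputShape, convFilters = c(32L, 64L, 128L),
                      denseUnits = 128L, dropoutInput = 0.2, l2 = 1e-3,
                      lr = 1e-3, epochs = 60L, batchSize = 32L, seed = 1L,
                      scaleInputs = TRUE) {
  new("CNNConfig", inputShape = as.integer(inputShape),
      convFilters = as.integer(convFilters), denseUnits = as.integer(denseUnits),
      kernel = 3L, pool = 2L, dropoutInput = dropoutInput, l2 = l2, lr = lr,
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      seed = as.integer(seed), scaleInputs = scaleInputs)
}

setMethod("show", "CNNConfig", function(object) {
  cat(sprintf(
    "CNNConfig: input (%s), conv blocks [%s], dense %d, %d hidden layers\n",
    paste(object@inputShape, collapse = ", "),
    paste(object@convFilters, collapse = ", "), object@denseUnits,
    length(object@convFilters) + 1L))
  cat(sprintf("  lr=%g, l2=%g, dropout(in)=%g, epochs=%d, batch=%d, seed=%d\n",
              object@lr, object@l2, object@dropoutInput, object@epochs,
              object@batchSize, object@seed))
})

#' TrainedCNN: a fitted grid classifier
#'
#' Holds the fitted parameters, the per-epoch training-loss history, the
#' configuration and provenance metadata (channel subset, input scaling
#' statistics, grid spec).
#'
#' @slot params list of layer parameter matrices.
#' @slot config the \code{CNNConfig} used.
#' @slot lossHistory numeric, one entry per epoch run.
#' @slot meta list of provenance fields.
#' @export
setClass("TrainedCNN",
         representation(params = "list", config = "CNNConfig",
                        lossHistory = "numeric", meta = "list"))

setValidity("TrainedCNN", function(object) {
  if (length(object@lossHistory) &&
      length(object@lossHistory) != object@config@epochs)
    return("loss history length must equal the number of epochs run")
  TRUE
})

#' @rdname TrainedCNN-class
#' @param x a \code{TrainedCNN}.
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))
#' @rdname TrainedCNN-class
#' @export
setMethod("lossHistory", "TrainedCNN", function(x) x@lossHistory)

#' @rdname TrainedCNN-class
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @rdname TrainedCNN-class
#' @export
setMethod("modelConfig", "TrainedCNN", function(x) x@config)

setMethod("show", "TrainedCNN", function(object) {
  cat("TrainedCNN:", length(object@config@convFilters), "conv blocks +",
      "1 dense hidden layer\n")
  if (length(object@lossHistory))
    cat(sprintf("  %d epochs, final loss %.5f\n", length(object@lossHistory),
                tail(object@lossHistory, 1L)))
})

#' EvalReport: threshold-free evaluation of a binary scorer
#'
#' ROC points (by sweeping the score threshold, ties averaged) and the
#' trapezoidal AUC for one task on one split. AUC is NA when the split has
#' a single class.
#'
#' @slot task task name.
#' @slot split split identifier.
#' @slot auc numeric(1), possibly NA.
#' @slot roc data.frame with columns fpr, tpr, threshold.
#' @export
setClass("EvalReport",
         representation(task = "character", split = "character",
                        auc = "numeric", roc = "data.frame"))

#' @rdname EvalReport-class
#' @param x an \code{EvalReport}.
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))
#' @rdname EvalReport-class
#' @export
setMethod("aucValue", "EvalReport", function(x) x@auc)

#' @rdname EvalReport-class
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))
#' @rdname EvalReport-class
#' @export
setMethod("rocPoints", "EvalReport", function(x) x@roc)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: task '%s', split '%s', AUC = %s (%d ROC points)\n",
              object@task, object@split,
              ifelse(is.na(object@auc), "NA", sprintf("%.4f", object@auc)),
              nrow(object@roc)))
})
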