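## Seeded synthetic-data generators. Three kinds of fixture:
##   * random toy molecules with hand-assigned typing, for grid oracles;
##   * a two-population grid dataset whose classes differ only through an
##     acid-like motif planted in the negative-ionization channel, for
##     learnability, imbalance and ablation experiments;
##   * a small hand-curated labeled SMILES table exercising every typing
##     rule and the deduplication logic.
## Every generator is a pure function of its seed.

## random ToyMolecule with hand-assigned channel flags
.randomToy <- function(id, maxAtoms, window = 24) {
  na <- sample.int(maxAtoms, 1L)
  half <- window / 2
  coords <- cbind(runif(na, -half, half), runif(na, -half, half))
  el <- sample(c("C", "N", "O", "S"), na, replace = TRUE)
  ch <- cbind(hbond = FALSE,
              hydrophobicity = runif(na) < 0.5,
              metallicity = runif(na) < 0.2,
              excluded_volume = TRUE,
              positive_ionization = runif(na) < 0.3,
              negative_ionization = runif(na) < 0.3)
  role <- rep("none", na)
  hbCand <- which(el %in% c("N", "O", "S") & runif(na) < 0.5)
  role[hbCand] <- sample(c("donor", "acceptor", "both"), length(hbCand),
                         replace = TRUE)
  ch[, "hbond"] <- role != "none"
  hC <- hD <- numeric(na)
  for (i in which(role != "none")) {
    cd <- hbondParameters(role[i], el[i])
    hC[i] <- cd[["C"]]; hD[i] <- cd[["D"]]
  }
  typ <- new("ChannelTyping", channels = ch, rVdw = runif(na, 1.0, 2.2),
             hbondRole = role, hbondC = hC, hbondD = hD)
  mol <- GridMolecule(id = id, element = el, coords = coords,
                      bonds = NULL)
  ToyMolecule(mol, typ)
}

#' Random toy molecules for grid oracle tests
#'
#' Generates molecules with atoms placed uniformly in the grid window,
#' random channel memberships (excluded volume always on), random vdW radii
#' in [1.0, 2.2] A and random hydrogen-bond roles with the matching 12-10
#' coefficients. Typing bypasses the chemistry rules entirely so the grid
#' equations can be validated in isolation against a brute-force oracle.
#'
#' @param seed RNG seed.
#' @param nMolecules number of fixtures (default 100).
#' @param maxAtoms maximum atoms per molecule (default 20).
#' @param window window side in Angstrom atoms are placed in (default 24).
#' @return List of \code{\link{ToyMolecule}}.
#' @export
makeGridFixtures <- function(seed, nMolecules = 100L, maxAtoms = 20L,
                             window = 24) {
  stopifnot(maxAtoms >= 1L)
  set.seed(seed)
  lapply(seq_len(nMolecules), function(i)
    .randomToy(sprintf("toy%03d", i), maxAtoms, window))
}

## one scaffold + optional acid-like motif; all coordinates jittered
.separableToy <- function(id, active, motif, jitterSd) {
  nsc <- sample(8:14, 1L)
  coords <- cbind(runif(nsc, -7, 7), runif(nsc, -7, 7))
  hydroph <- runif(nsc) < 0.7
  ## the three-atom cluster is placed in both classes with identical
  ## geometry and flags; only its negative-ionization membership differs,
  ## so that channel carries the entire class signal
  ctr <- runif(2L, -5, 5)
  tmpl <- rbind(c(0, 0), c(1.2, 0), c(0.6, 1.0))
  extra <- sweep(tmpl, 2L, ctr, "+")
  extraNeg <- active && motif
  xy <- rbind(coords, extra)
  xy <- xy + matrix(rnorm(length(xy), sd = jitterSd), ncol = 2L)
  na <- nrow(xy)
  ch <- cbind(hbond = rep(FALSE, na),
              hydrophobicity = c(hydroph, rep(FALSE, 3L)),
              metallicity = rep(FALSE, na),
              excluded_volume = rep(TRUE, na),
              positive_ionization = rep(FALSE, na),
              negative_ionization = c(rep(FALSE, nsc), rep(extraNeg, 3L)))
  typ <- new("ChannelTyping", channels = ch,
             rVdw = c(runif(nsc, 1.5, 1.9), rep(1.52, 3L)),
             hbondRole = rep("none", na), hbondC = numeric(na),
             hbondD = numeric(na))
  ToyMolecule(GridMolecule(id = id, element = rep("C", na), coords = xy),
              typ)
}

#' Two-population separable grid dataset
#'
#' Builds a seeded dataset of toy molecules in which the active class
#' carries a three-atom acid-like motif in the negative-ionization channel
#' and the inactive class carries matched decoy atoms instead; both classes
#' share the same random-scaffold distribution and 0.3 A coordinate jitter,
#' so the planted channel is the only systematic difference. The
#' metallicity channel is identically zero (a null channel for ablation
#' controls). Grids are produced by the standard featurizer and returned as
#' a \code{\link{GridSet}} with an \code{activity} label, a stratified
#' train/test split, and the ground truth recorded in metadata.
#'
#' @param seed RNG seed.
#' @param nPerClass majority (inactive) class size (default 60; must be
#'   >= 8).
#' @param imbalanceRatio majority/minority ratio; 1 gives balanced classes,
#'   33 mirrors the most imbalanced endpoint (default 1).
#' @param resolution grid resolution in Angstrom (default 1.0).
#' @param extent grid window in Angstrom (default 24).
#' @param motif plant the motif (default TRUE); FALSE gives a null dataset
#'   with no class signal.
#' @param testFraction held-out fraction per class (default 0.25).
#' @param jitterSd coordinate jitter standard deviation in Angstrom.
#' @return A \code{\link{GridSet}}.
#' @export
makeSeparableDataset <- function(seed, nPerClass = 60L, imbalanceRatio = 1,
                                 resolution = 1.0, extent = 24,
                                 motif = TRUE, testFraction = 0.25,
                                 jitterSd = 0.3) {
  stopifnot(nPerClass >= 8L, imbalanceRatio >= 1)
  set.seed(seed)
  nNeg <- as.integer(nPerClass)
  nPos <- max(2L, as.integer(round(nPerClass / imbalanceRatio)))
  lab <- rep(c(0L, 1L), c(nNeg, nPos))
  mols <- lapply(seq_along(lab), function(i)
    .separableToy(sprintf("syn%04d", i), lab[i] == 1L, motif, jitterSd))
  spec <- GridSpec(extent, resolution)
  split <- character(length(lab))
  for (cls in 0:1) {
    idx <- which(lab == cls)
    nTest <- max(1L, round(testFraction * length(idx)))
    test <- sample(idx, nTest)
    split[idx] <- "train"
    split[test] <- "test"
  }
  gs <- featurizeSet(mols, spec, labels = data.frame(activity = lab),
                     split = split)
  metadata(gs)$groundTruth <- list(signalChannel = "negative_ionization",
                                   nullChannel = "metallicity",
                                   motif = motif, jitterSd = jitterSd,
                                   seed = seed)
  gs
}

#' Hand-curated labeled SMILES fixture table
#'
#' About thirty molecules covering every typing rule (amines, amidines,
#' carboxylic/sulfonic/phosphonic acids, a tetrazole, metal salts, pure
#' hydrocarbons, halogenated compounds, hydrogen-bond donors and
#' acceptors), plus duplicate pairs -- one consistent pair that must merge
#' and one conflicting pair that must be deleted by deduplication. Labels
#' use the twelve endpoint columns with NA for unmeasured cells.
#'
#' @param path optional file path; when given the table is written as TSV
#'   in the format \code{\link{readMolecules}} expects.
#' @return data.frame with columns id, smiles, the twelve tasks, split.
#' @export
makeSmilesFixtures <- function(path = NULL) {
  rows <- list(
    ## id, smiles, then task = value pairs
    list("ethanol",       "CCO",              AhR = 0, ER = 1),
    list("ethanol_dup",   "OCC",              AhR = NA, ER = 1),   # consistent dup
    list("toluene",       "Cc1ccccc1",        AhR = 1),
    list("toluene_confl", "c1ccccc1C",        AhR = 0),            # conflicting dup
    list("benzene",       "c1ccccc1",         AhR = 0),
    list("butane",        "CCCC",             AR = 0),
    list("isobutane",     "CC(C)C"),
    list("cyclohexane",   "C1CCCCC1",         MMP = 0),
    list("ethylamine",    "CCN",              AR = 1),
    list("propylamine",   "CCCN",             AR = 0),
    list("trimethylamine","CN(C)C"),
    list("guanidine",     "NC(N)=N",          p53 = 1),
    list("acetic_acid",   "CC(=O)O",          ARE = 0),
    list("benzoic_acid",  "OC(=O)c1ccccc1",   ARE = 1),
    list("methanesulfonic", "CS(=O)(=O)O",    HSE = 0),
    list("methylphosphonic", "CP(O)(O)=O"),
    list("tetrazole",     "c1nnn[nH]1",       ATAD5 = 1),
    list("sodium_acetate","CC(=O)[O-].[Na+]", ARE = 0),
    list("sodium_chloride", "[Na+].[Cl-]",    MMP = 0),
    list("zinc_chloride", "Cl[Zn]Cl",         MMP = 1),
    list("phenol",        "Oc1ccccc1",        ER = 1),
    list("pyridine",      "c1ccncc1",         AhR = 0),
    list("acetamide",     "CC(N)=O",          p53 = 0),
    list("ethanethiol",   "CCS",              HSE = 1),
    list("thiophene",     "c1ccsc1"),
    list("dichloromethane", "ClCCl",          ATAD5 = 0),
    list("fluoroform",    "FC(F)F"),
    list("bromobenzene",  "Brc1ccccc1",       AhR = 1),
    list("dmso",          "CS(C)=O",          `AR-LBD` = 0),
    list("glycine",       "NCC(=O)O",         `PPAR.g` = 0),
    list("pyrrole",       "c1cc[nH]c1",       Aromatase = 0),
    list("aniline",       "Nc1ccccc1",        `ER-LBD` = 1)
  )
  tasks <- tox21Tasks()
  df <- data.frame(id = vapply(rows, `[[`, character(1L), 1L),
                   smiles = vapply(rows, `[[`, character(1L), 2L),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (tk in tasks) df[[tk]] <- NA_real_
  for (r in seq_along(rows)) {
    extra <- rows[[r]][-(1:2)]
    for (tk in names(extra)) df[r, tk] <- extra[[tk]]
  }
  df$split <- rep(c("train", "test", "verification"),
                  length.out = nrow(df))
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}
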