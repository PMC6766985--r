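## Molecule I/O, standardization and deduplication.
##
## Standardization follows the preprocessing the method requires: every
## molecule gets explicit hydrogens and perceived aromaticity, plus a
## recomputed canonical SMILES and InChIKey. Structure handling goes through
## OpenBabel (ChemmineOB) and ChemmineR; records that fail to parse or
## sanitize are dropped with a logged reason, never aborting a batch.

#' The twelve toxicity endpoints
#'
#' Task identifiers for the twelve binary endpoints (seven nuclear-receptor
#' and five stress-response assays) used for per-endpoint models.
#'
#' @return Character vector of task names.
#' @export
tox21Tasks <- function() {
  c("AhR", "AR", "AR-LBD", "ARE", "Aromatase", "ATAD5",
    "ER", "ER-LBD", "PPAR.g", "HSE", "MMP", "p53")
}

## in-process OpenBabel conversion; returns NA_character_ on failure
.obConvert <- function(from, to, text, options = NULL) {
  out <- tryCatch({
    if (is.null(options))
      ChemmineOB::convertFormat(from, to, text,
                                options = data.frame(names = character(),
                                                     args = character()))
    else ChemmineOB::convertFormat(from, to, text, options = options)
  }, error = function(e) NA_character_)
  if (is.character(out) && length(out) == 1L && nzchar(trimws(out))) out
  else NA_character_
}

.canonicalSmiles <- function(smiles) {
  out <- .obConvert("SMI", "CAN", paste0(smiles, "\n"))
  if (is.na(out)) return(NA_character_)
  strsplit(trimws(out), "[\t ]")[[1L]][1L]
}

.inchikey <- function(smiles) {
  out <- .obConvert("SMI", "inchikey", paste0(smiles, "\n"))
  if (is.na(out)) return(NA_character_)
  key <- trimws(strsplit(out, "\n")[[1L]][1L])
  if (nchar(key) == 27L) key else NA_character_
}

## formal charges from the authoritative "M  CHG" property lines (which
## supersede the old-style atom-block codes and are always emitted by
## OpenBabel for charged molecules)
.chargesFromSdfText <- function(sdfText, nAtoms) {
  charge <- numeric(nAtoms)
  lines <- grep("^M  CHG", strsplit(sdfText, "\n")[[1L]], value = TRUE)
  for (ln in lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1L]])
    nPairs <- f[1L]
    for (p in seq_len(nPairs)) {
      idx <- f[2L * p]; val <- f[2L * p + 1L]
      if (!is.na(idx) && idx >= 1L && idx <= nAtoms) charge[idx] <- val
    }
  }
  charge
}

## parse one ChemmineR SDF instance into a GridMolecule; aromatic flags from
## ChemmineR ring perception
.sdfToGridMolecule <- function(sdf, id, charge = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  el <- gsub("_.*$", "", rownames(ab))
  coords <- cbind(ab[, 1L], ab[, 2L])
  if (is.null(charge)) charge <- numeric(length(el))
  ## bond count from the counts line; the bond block of 0-bond records is junk
  counts <- as.integer(strsplit(trimws(ChemmineR::header(sdf)[["Counts_Line"]]),
                                "[ ]+")[[1L]][1:2])
  nb <- counts[2L]
  bonds <- if (is.na(nb) || nb == 0L) matrix(numeric(), 0L, 3L)
           else {
    bb <- ChemmineR::bondblock(sdf)
    cbind(as.numeric(bb[seq_len(nb), 1L]), as.numeric(bb[seq_len(nb), 2L]),
          as.numeric(bb[seq_len(nb), 3L]))
  }
  arom <- logical(length(el))
  if (nrow(bonds) > 0L) {
    ringInfo <- tryCatch(
      ChemmineR::rings(sdf, type = "all", arom = TRUE, inner = FALSE),
      error = function(e) NULL)
    if (!is.null(ringInfo) && length(ringInfo$RINGS)) {
      aromRings <- ringInfo$RINGS[which(ringInfo$AROMATIC)]
      idx <- unique(as.integer(gsub("^.*_", "", unlist(aromRings))))
      arom[idx] <- TRUE
    }
  }
  GridMolecule(id = id, element = el, charge = charge, aromatic = arom,
               coords = coords, bonds = bonds)
}

## SMILES -> standardized GridMolecule (explicit H + 2D depiction layout),
## or NULL with a logged reason
.standardizeOne <- function(smiles, id) {
  sdfText <- .obConvert("SMI", "SDF", paste0(smiles, "\t", id, "\n"),
                        options = data.frame(names = c("gen2D", "h"),
                                             args = c("", "")))
  if (is.na(sdfText)) {
    gtLog("dropping '%s': OpenBabel could not sanitize SMILES '%s'",
          id, smiles, level = "WARN")
    return(NULL)
  }
  sdfset <- tryCatch(
    suppressWarnings(
      ChemmineR::read.SDFset(strsplit(sdfText, "\n")[[1L]], skipErrors = TRUE)),
    error = function(e) NULL)
  if (is.null(sdfset) || length(sdfset) < 1L) {
    gtLog("dropping '%s': unreadable standardized record", id, level = "WARN")
    return(NULL)
  }
  chg <- .chargesFromSdfText(sdfText,
                             nrow(ChemmineR::atomblock(sdfset[[1L]])))
  tryCatch(.sdfToGridMolecule(sdfset[[1L]], id, charge = chg),
           error = function(e) {
             gtLog("dropping '%s': %s", id, conditionMessage(e), level = "WARN")
             NULL
           })
}

## read a delimited SMILES table (header: id, smiles, optional task columns
## with 0/1/NA, optional split column)
.readSmilesTable <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  if (!all(c("id", "smiles") %in% colnames(df)))
    stop("SMILES table must have 'id' and 'smiles' columns")
  df
}

#' Read molecules and labels
#'
#' Reads a SMILES table (TSV/CSV with header columns \code{id},
#' \code{smiles}, optionally one 0/1/NA column per task and a \code{split}
#' column) or an MDL SDF file. Unparsable records are skipped with a logged
#' reason. The returned molecules are raw (no explicit hydrogens, no
#' InChIKeys yet); run \code{\link{standardizeMolecules}} next.
#'
#' @param path input file path.
#' @param format "smiles-table" or "sdf".
#' @return A \code{\link{MoleculeSet}}.
#' @export
readMolecules <- function(path, format = c("smiles-table", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  taskCols <- character()
  if (format == "smiles-table") {
    df <- .readSmilesTable(path)
    taskCols <- setdiff(colnames(df), c("id", "smiles", "split"))
    ids <- as.character(df$id)
    smiles <- as.character(df$smiles)
    split <- if ("split" %in% colnames(df)) as.character(df$split)
             else rep("train", nrow(df))
    labels <- df[, taskCols, drop = FALSE]
  } else {
    sdfset <- ChemmineR::read.SDFset(path, skipErrors = TRUE)
    ids <- ChemmineR::sdfid(sdfset)
    ids[!nzchar(ids) | is.na(ids)] <-
      paste0("mol", seq_along(ids))[!nzchar(ids) | is.na(ids)]
    smiles <- vapply(seq_along(sdfset), function(i) {
      txt <- paste(ChemmineR::sdf2str(sdfset[[i]]), collapse = "\n")
      out <- .obConvert("SDF", "CAN", paste0(txt, "\n$$$$\n"))
      if (is.na(out)) NA_character_ else strsplit(trimws(out), "[\t ]")[[1L]][1L]
    }, character(1L))
    split <- rep("train", length(ids))
    labels <- data.frame(row.names = seq_along(ids))
  }

  keep <- logical(length(ids))
  mols <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    if (is.na(smiles[i]) || !nzchar(smiles[i])) {
      gtLog("skipping record '%s': empty or unreadable structure", ids[i],
            level = "WARN")
      next
    }
    can <- .canonicalSmiles(smiles[i])
    if (is.na(can)) {
      gtLog("skipping record '%s': unparsable SMILES '%s'", ids[i], smiles[i],
            level = "WARN")
      next
    }
    m <- .standardizeOne(smiles[i], ids[i])  # parse once; re-done on standardize
    if (is.null(m)) next
    mols[[i]] <- m
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("no parsable records in ", path)
  gtLog("read %d/%d molecules from %s", sum(keep), length(ids), path)

  labels <- labels[keep, , drop = FALSE]
  for (cc in colnames(labels)) labels[[cc]] <- suppressWarnings(as.numeric(labels[[cc]]))
  MoleculeSet(mols = mols[keep],
              meta = DataFrame(id = ids[keep], smiles = smiles[keep],
                               inchikey = NA_character_, split = split[keep]),
              labels = labels)
}

#' Standardize molecules
#'
#' Adds explicit hydrogens, perceives aromaticity, generates a 2D depiction
#' layout, and recomputes the canonical SMILES and InChIKey of every
#' molecule. Molecules that fail sanitization are dropped with a logged
#' reason. Standardization is idempotent with respect to the InChIKey.
#'
#' @param mset a \code{\link{MoleculeSet}}.
#' @return The standardized \code{MoleculeSet}.
#' @export
standardizeMolecules <- function(mset) {
  stopifnot(is(mset, "MoleculeSet"))
  n <- length(mset)
  keep <- logical(n)
  mols <- vector("list", n)
  can <- key <- character(n)
  for (i in seq_len(n)) {
    smi <- mset@meta$smiles[i]
    id <- mset@meta$id[i]
    can_i <- .canonicalSmiles(smi)
    key_i <- if (is.na(can_i)) NA_character_ else .inchikey(can_i)
    m <- if (is.na(key_i)) NULL else .standardizeOne(can_i, id)
    if (is.null(m)) {
      gtLog("dropping '%s' during standardization", id, level = "WARN")
      next
    }
    mols[[i]] <- m; can[i] <- can_i; key[i] <- key_i; keep[i] <- TRUE
  }
  if (!any(keep)) stop("standardization left no molecules")
  meta <- mset@meta[keep, , drop = FALSE]
  meta$smiles <- can[keep]
  meta$inchikey <- key[keep]
  MoleculeSet(mols = mols[keep], meta = meta,
              labels = mset@labels[keep, , drop = FALSE])
}

#' Deduplicate molecules by InChIKey
#'
#' Groups records by their full 27-character InChIKey. If any task has
#' conflicting non-missing labels within a group, every record of that
#' group is deleted. Otherwise the group is merged into a single record
#' (the first occurrence) carrying the union of non-missing labels. The
#' operation is idempotent.
#'
#' @param mset a standardized \code{\link{MoleculeSet}} (InChIKeys present).
#' @return The deduplicated \code{MoleculeSet} (possibly empty).
#' @export
deduplicateMolecules <- function(mset) {
  stopifnot(is(mset, "MoleculeSet"))
  keys <- inchiKeys(mset)
  if (anyNA(keys)) stop("deduplication requires InChIKeys; standardize first")
  groups <- split(seq_along(keys), factor(keys, levels = unique(keys)))
  labs <- as.data.frame(mset@labels)
  keepIdx <- integer()
  mergedLabels <- list()
  dropped <- 0L
  for (g in groups) {
    if (length(g) == 1L) {
      keepIdx <- c(keepIdx, g)
      mergedLabels[[length(mergedLabels) + 1L]] <- labs[g, , drop = FALSE]
      next
    }
    sub <- labs[g, , drop = FALSE]
    conflict <- any(vapply(sub, function(v) {
      v <- v[!is.na(v)]
      length(unique(v)) > 1L
    }, logical(1L)))
    if (conflict) {
      dropped <- dropped + length(g)
      gtLog("removing %d records with InChIKey %s: conflicting labels",
            length(g), keys[g[1L]], level = "WARN")
      next
    }
    merged <- lapply(sub, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) v[1L] else NA_real_
    })
    keepIdx <- c(keepIdx, g[1L])
    mergedLabels[[length(mergedLabels) + 1L]] <-
      as.data.frame(merged, check.names = FALSE, optional = TRUE)
  }
  if (length(keepIdx) == 0L) {
    gtLog("deduplication removed every record", level = "WARN")
    return(mset[0L])
  }
  out <- mset[keepIdx]
  if (ncol(labs) > 0L) {
    newLabs <- do.call(rbind, mergedLabels)
    colnames(newLabs) <- colnames(labs)
    out@labels <- DataFrame(newLabs, check.names = FALSE)
  }
  gtLog("deduplication: %d -> %d records (%d removed for label conflicts)",
        length(mset), length(out), dropped)
  out
}

#' Write a cleaned molecule table
#'
#' Writes the dataset back in the SMILES-table format (TSV: id, smiles,
#' task columns, split) together with a JSON manifest recording per-task,
#' per-split label counts.
#'
#' @param mset a \code{\link{MoleculeSet}}.
#' @param path output TSV path; the manifest is written next to it with a
#'   .manifest.json suffix.
#' @return Invisibly, the manifest list.
#' @export
writeMoleculeTable <- function(mset, path) {
  labs <- as.data.frame(mset@labels)
  df <- data.frame(id = moleculeIds(mset), smiles = mset@meta$smiles,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, labs)
  df$split <- splitTags(mset)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(n_molecules = length(mset),
                   typing_rules_version = typingRulesVersion(),
                   tasks = lapply(stats::setNames(nm = colnames(labs)), function(tk) {
                     v <- labs[[tk]]
                     sp <- splitTags(mset)
                     out <- lapply(stats::setNames(nm = unique(sp)), function(s) {
                       vv <- v[sp == s]
                       list(active = sum(vv == 1, na.rm = TRUE),
                            inactive = sum(vv == 0, na.rm = TRUE),
                            missing = sum(is.na(vv)))
                     })
                     out
                   }))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
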