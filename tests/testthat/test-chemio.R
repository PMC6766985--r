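test_that("reading a SMILES table parses records and skips corrupt ones", {
  dir <- tempfile()
  dir.create(dir)
  p <- file.path(dir, "mols.tsv")
  writeLines(c("id\tsmiles\tAhR",
               "eth\tCCO\t0",
               "benz\tc1ccccc1\t1",
               "but\tCCCC\tNA",
               "bad\tC1CC\t1"),   # unclosed ring: unparsable
             p)
  ms <- readMolecules(p)
  expect_s4_class(ms, "MoleculeSet")
  expect_equal(sort(moleculeIds(ms)), c("benz", "but", "eth"))
  expect_equal(ncol(labelTable(ms)), 1L)
})

test_that("missing file and empty input are fatal", {
  expect_error(readMolecules(tempfile()), "not found")
  p <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsmiles", "bad\tC1CC"), p)
  expect_error(readMolecules(p), "no parsable records")
})

test_that("standardization adds explicit hydrogens and aromatizes", {
  ms <- stdFixtures()
  eth <- molecules(ms)[[which(moleculeIds(ms) == "ethanol")]]
  expect_equal(atomCount(eth), 9L)                 # C2H6O
  expect_equal(sum(atomElements(eth) == "H"), 6L)
  benz <- molecules(ms)[[which(moleculeIds(ms) == "benzene")]]
  carbons <- atomElements(benz) == "C"
  expect_equal(sum(carbons), 6L)
  expect_true(all(benz@aromatic[carbons]))         # Kekule input aromatized
  expect_true(all(nchar(inchiKeys(ms)) == 27L))
})

test_that("two encodings of one compound standardize to the same InChIKey", {
  ms <- stdFixtures()
  keys <- inchiKeys(ms)
  ids <- moleculeIds(ms)
  expect_equal(keys[ids == "ethanol"], keys[ids == "ethanol_dup"])
  expect_equal(keys[ids == "toluene"], keys[ids == "toluene_confl"])
})

test_that("standardization is idempotent on the InChIKey", {
  ms <- stdFixtures()
  again <- suppressWarnings(standardizeMolecules(ms))
  expect_equal(inchiKeys(again), inchiKeys(ms))
})

test_that("deduplication removes conflicting groups and merges consistent ones", {
  ms <- stdFixtures()
  dd <- deduplicateMolecules(ms)
  ids <- moleculeIds(dd)
  ## conflicting AhR labels: whole group deleted
  expect_false(any(c("toluene", "toluene_confl") %in% ids))
  ## consistent duplicates: merged into the first record with the union of
  ## non-missing labels (ethanol AhR=0 + dup AhR=NA -> 0; both ER=1)
  expect_true("ethanol" %in% ids)
  expect_false("ethanol_dup" %in% ids)
  lab <- as.data.frame(labelTable(dd))
  expect_equal(lab[ids == "ethanol", "AhR"], 0)
  expect_equal(lab[ids == "ethanol", "ER"], 1)
  expect_false(anyDuplicated(inchiKeys(dd)) > 0)
})

test_that("deduplication is idempotent and never increases label counts", {
  ms <- stdFixtures()
  dd1 <- deduplicateMolecules(ms)
  dd2 <- deduplicateMolecules(dd1)
  expect_equal(moleculeIds(dd2), moleculeIds(dd1))
  expect_equal(as.data.frame(labelTable(dd2)), as.data.frame(labelTable(dd1)))
  lin <- as.data.frame(labelTable(ms))
  lout <- as.data.frame(labelTable(dd1))
  for (tk in colnames(lin))
    expect_lte(sum(!is.na(lout[[tk]])), sum(!is.na(lin[[tk]])))
})

test_that("deduplication leaves all-unique inputs unchanged", {
  ms <- stdFixtures()
  keys <- inchiKeys(ms)
  uni <- ms[!keys %in% keys[duplicated(keys)]]
  dd <- deduplicateMolecules(uni)
  expect_equal(moleculeIds(dd), moleculeIds(uni))
  expect_equal(as.data.frame(labelTable(dd)), as.data.frame(labelTable(uni)))
})

test_that("cleaned tables round-trip through the readers", {
  ms <- deduplicateMolecules(stdFixtures())
  p <- tempfile(fileext = ".tsv")
  manifest <- writeMoleculeTable(ms, p)
  expect_true(file.exists(paste0(p, ".manifest.json")))
  back <- suppressWarnings(readMolecules(p))
  expect_equal(moleculeIds(back), moleculeIds(ms))
  expect_equal(as.data.frame(labelTable(back)), as.data.frame(labelTable(ms)),
               ignore_attr = TRUE)
  expect_equal(splitTags(back), splitTags(ms))
  expect_equal(manifest$n_molecules, length(ms))
})

test_that("SDF input is read through the same pipeline", {
  ms <- stdFixtures()
  idx <- which(moleculeIds(ms) %in% c("ethanol", "benzene"))
  ## write a small SDF through the chemistry layer, then re-read it
  sdfTxt <- ChemmineOB::convertFormat(
    "SMI", "SDF", paste0("CCO\tms1\nc1ccccc1\tms2\n"),
    options = data.frame(names = "gen2D", args = ""))
  p <- tempfile(fileext = ".sdf")
  writeLines(sdfTxt, p)
  sd <- readMolecules(p, format = "sdf")
  expect_equal(length(sd), 2L)
  expect_setequal(moleculeIds(sd), c("ms1", "ms2"))
})
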