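test_that("grid geometry follows the window and resolution", {
  expect_equal(nPixels(GridSpec(24, 0.5)), 48L)
  expect_equal(nPixels(GridSpec(24, 1.0)), 24L)
  expect_equal(nPixels(GridSpec(24, 2.0)), 12L)
  expect_error(GridSpec(24, 0.7), "divide")
  expect_error(GridSpec(-1, 0.5), "positive")
  ## pixel centres: -L/2 + (i - 0.5) * delta, symmetric about 0
  ctr <- pixelCenters(GridSpec(24, 0.5))
  expect_equal(ctr[1], -11.75)
  expect_equal(ctr[48], 11.75)
  expect_equal(ctr, -rev(ctr))
})

test_that("coordinate embedding follows the centroid/principal-axis convention", {
  ## single atom at the origin
  m1 <- embedCoordinates(GridMolecule("a", "C", coords = cbind(5, 3)))
  expect_equal(as.vector(atomCoords(m1)), c(0, 0))
  ## two bonded atoms: rescaled to 1.5 A bond, centred, on the x axis
  m2 <- embedCoordinates(GridMolecule("e", c("C", "C"),
                                      coords = rbind(c(0, 0), c(0.8, 0.6)),
                                      bonds = cbind(1, 2, 1)))
  xy <- atomCoords(m2)
  expect_equal(sort(xy[, 1]), c(-0.75, 0.75))
  expect_equal(xy[, 2], c(0, 0), tolerance = 1e-12)
  ## centroid convention for every standardized fixture molecule
  ms <- stdFixtures()
  for (mol in molecules(ms)[1:8]) {
    em <- embedCoordinates(mol)
    expect_equal(as.vector(colMeans(atomCoords(em))), c(0, 0),
                 tolerance = 1e-9)
  }
})

test_that("the bounded vdW term takes its closed-form values", {
  spec <- GridSpec(24, 0.5)
  ctr <- pixelCenters(spec)
  ## atom on the pixel-(25,25) centre with r_vdw = 1.5 A
  toy <- singleAtomToy(ctr[25], ctr[25], rv = 1.5)
  G <- vdwGrid(toy, toy@typing, "excluded_volume", spec)
  expect_equal(G[25, 25], 1)                       # r = 0 limit
  expect_equal(G[25, 28], 1 - exp(-1))             # r = r_vdw exactly
  expect_equal(G[25, 31], -expm1(-2^-12))          # r = 2 r_vdw
  expect_equal(G[25, 31], 2.44110e-4, tolerance = 1e-5)
  ## additivity: two coincident atoms double every pixel
  ch <- matrix(c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE), 2, 6, byrow = TRUE,
               dimnames = list(NULL, channelNames()))
  typ2 <- new("ChannelTyping", channels = ch, rVdw = c(1.5, 1.5),
              hbondRole = c("none", "none"), hbondC = c(0, 0), hbondD = c(0, 0))
  toy2 <- ToyMolecule(GridMolecule("two", c("C", "C"),
                                   coords = rbind(c(ctr[25], ctr[25]),
                                                  c(ctr[25], ctr[25]))), typ2)
  G2 <- vdwGrid(toy2, toy2@typing, "excluded_volume", spec)
  expect_equal(G2, 2 * G, tolerance = 1e-12)
})

test_that("a single atom's vdW value strictly decreases with distance", {
  spec <- GridSpec(24, 0.5)
  ctr <- pixelCenters(spec)
  toy <- singleAtomToy(ctr[25], ctr[25], rv = 1.7)
  G <- vdwGrid(toy, toy@typing, "excluded_volume", spec)
  along <- G[25, 25:48]    # distances 0, 0.5, 1, ... strictly increasing
  expect_true(all(diff(along) <= 0))
  ## strictly decreasing between the saturated core (exp underflow makes the
  ## term exactly 1 for r << r_vdw) and the underflowed far field
  body <- along > 1e-12 & along < 1
  expect_gte(sum(body), 10)
  expect_true(all(diff(along[body]) < 0))
})

test_that("the hydrogen-bond grid reaches -epsilon at the equilibrium distance", {
  spec <- GridSpec(24, 0.5)
  ctr <- pixelCenters(spec)
  ## N/O class: well depth 5 at 1.9 A
  toy <- singleAtomToy(ctr[25] + 1.9, ctr[25], role = "both", element = "O")
  G <- hbondGrid(toy, toy@typing, spec)
  expect_equal(G[25, 25], -5, tolerance = 1e-9)
  ## S class: depth 1 at 2.5 A
  toyS <- singleAtomToy(ctr[25] + 2.5, ctr[25], role = "donor", element = "S")
  GS <- hbondGrid(toyS, toyS@typing, spec)
  expect_equal(GS[25, 25], -1, tolerance = 1e-9)
  ## clipping keeps the channel bounded
  toy0 <- singleAtomToy(ctr[25], ctr[25], role = "both", element = "O")
  G0 <- hbondGrid(toy0, toy0@typing, spec)
  expect_true(all(G0 >= -50 & G0 <= 50))
  ## no donors/acceptors: identically zero
  none <- singleAtomToy(0, 0)
  expect_true(all(hbondGrid(none, none@typing, spec) == 0))
})

test_that("channels without member atoms are identically zero", {
  toy <- singleAtomToy(0.3, -0.2, channel = "hydrophobicity")
  spec <- GridSpec(24, 1)
  expect_true(all(vdwGrid(toy, toy@typing, "metallicity", spec) == 0))
  expect_gt(max(vdwGrid(toy, toy@typing, "hydrophobicity", spec)), 0)
})

test_that("vectorized grids match the brute-force double loop", {
  toys <- makeGridFixtures(seed = 99, nMolecules = 10, maxAtoms = 12)
  spec <- GridSpec(24, 1)
  for (toy in toys) {
    for (ch in c("hydrophobicity", "excluded_volume", "negative_ionization")) {
      expect_equal(vdwGrid(toy, toy@typing, ch, spec),
                   naiveVdwGrid(toy, ch, spec), tolerance = 1e-9)
    }
    expect_equal(hbondGrid(toy, toy@typing, spec),
                 naiveHbondGrid(toy, spec), tolerance = 1e-9)
  }
})

test_that("vdW pixel values are bounded by the member-atom count", {
  toys <- makeGridFixtures(seed = 5, nMolecules = 10, maxAtoms = 15)
  spec <- GridSpec(24, 1)
  for (toy in toys) {
    for (ch in vdwChannelNames()[c(1, 3)]) {
      nm <- sum(channelMembership(toy@typing)[, ch])
      G <- vdwGrid(toy, toy@typing, ch, spec)
      expect_true(all(G >= 0))
      expect_true(all(G <= nm))
    }
  }
})

test_that("translating a molecule by one pixel shifts the grid by one pixel", {
  set.seed(3)
  spec <- GridSpec(24, 0.5)
  n <- nPixels(spec)
  xy <- cbind(runif(6, -8, 8), runif(6, -8, 8))
  ch <- matrix(FALSE, 6, 6, dimnames = list(NULL, channelNames()))
  ch[, "excluded_volume"] <- TRUE
  typ <- new("ChannelTyping", channels = ch, rVdw = runif(6, 1.2, 2),
             hbondRole = rep("none", 6), hbondC = numeric(6), hbondD = numeric(6))
  t1 <- ToyMolecule(GridMolecule("t", rep("C", 6), coords = xy), typ)
  t2 <- ToyMolecule(GridMolecule("t", rep("C", 6),
                                 coords = cbind(xy[, 1] + 0.5, xy[, 2])), typ)
  G1 <- vdwGrid(t1, typ, "excluded_volume", spec)
  G2 <- vdwGrid(t2, typ, "excluded_volume", spec)
  expect_equal(G2[, 2:n], G1[, 1:(n - 1)], tolerance = 1e-9)
})

test_that("rotating coordinates by 90 degrees permutes the grid accordingly", {
  set.seed(4)
  spec <- GridSpec(24, 0.5)
  n <- nPixels(spec)
  xy <- cbind(runif(5, -8, 8), runif(5, -8, 8))
  ch <- matrix(FALSE, 5, 6, dimnames = list(NULL, channelNames()))
  ch[, "excluded_volume"] <- TRUE
  typ <- new("ChannelTyping", channels = ch, rVdw = runif(5, 1.2, 2),
             hbondRole = rep("none", 5), hbondC = numeric(5), hbondD = numeric(5))
  M <- vdwGrid(ToyMolecule(GridMolecule("t", rep("C", 5), coords = xy), typ),
               typ, "excluded_volume", spec)
  rot <- cbind(-xy[, 2], xy[, 1])   # +90 degrees about the origin
  R <- vdwGrid(ToyMolecule(GridMolecule("t", rep("C", 5), coords = rot), typ),
               typ, "excluded_volume", spec)
  expected <- matrix(0, n, n)
  for (iy in seq_len(n)) for (ix in seq_len(n))
    expected[iy, ix] <- M[n + 1 - ix, iy]
  expect_equal(R, expected, tolerance = 1e-9)
})

test_that("coarse grids are consistent with averaged fine grids", {
  toys <- makeGridFixtures(seed = 21, nMolecules = 5, maxAtoms = 12)
  for (toy in toys) {
    fine <- vdwGrid(toy, toy@typing, "excluded_volume", GridSpec(24, 0.5))
    coarse <- vdwGrid(toy, toy@typing, "excluded_volume", GridSpec(24, 1.0))
    down <- 0.25 * (fine[seq(1, 47, 2), seq(1, 47, 2)] +
                    fine[seq(2, 48, 2), seq(1, 47, 2)] +
                    fine[seq(1, 47, 2), seq(2, 48, 2)] +
                    fine[seq(2, 48, 2), seq(2, 48, 2)])
    expect_gt(cor(as.vector(down), as.vector(coarse)), 0.95)
  }
})

test_that("featurize stacks the six channels in canonical order", {
  toy <- makeGridFixtures(seed = 8, nMolecules = 1, maxAtoms = 10)[[1]]
  spec <- GridSpec(24, 1)
  g <- featurize(toy, spec)
  expect_s4_class(g, "MolecularGrid")
  expect_equal(dim(gridValues(g)), c(24L, 24L, 6L))
  expect_equal(channelGrid(g, "hbond"), hbondGrid(toy, toy@typing, spec),
               ignore_attr = TRUE)
  expect_equal(channelGrid(g, "metallicity"),
               vdwGrid(toy, toy@typing, "metallicity", spec),
               ignore_attr = TRUE)
  ## shape at the three supported resolutions
  expect_equal(dim(gridValues(featurize(toy, GridSpec(24, 0.5))))[1:2], c(48L, 48L))
  expect_equal(dim(gridValues(featurize(toy, GridSpec(24, 2))))[1:2], c(12L, 12L))
})

test_that("molecules wider than the window warn but are never rescaled", {
  far <- singleAtomToy(20, 0)   # outside the 24 A window
  expect_warning(g <- featurize(far, GridSpec(24, 1)), "window")
  ## still contributes its tail to in-window pixels
  expect_gt(max(channelGrid(g, "excluded_volume")), 0)
})

test_that("featurizeSet assembles a GridSet with labels and metadata", {
  toys <- makeGridFixtures(seed = 13, nMolecules = 4, maxAtoms = 8)
  gs <- featurizeSet(toys, GridSpec(24, 2),
                     labels = data.frame(activity = c(0, 1, 0, 1)),
                     split = c("train", "train", "test", "test"))
  expect_s4_class(gs, "GridSet")
  expect_equal(ncol(gs), 4L)
  expect_equal(dim(gridArray(gs)), c(12L, 12L, 6L, 4L))
  expect_equal(S4Vectors::metadata(gs)$channelOrder, channelNames())
  ## flattened assays reconstruct the per-molecule grids
  g1 <- featurize(toys[[1]], GridSpec(24, 2))
  expect_equal(gridArray(gs)[, , "hbond", 1], channelGrid(g1, "hbond"),
               ignore_attr = TRUE)
})
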