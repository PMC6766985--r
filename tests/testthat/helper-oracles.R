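## Independent oracles used across the suite. These deliberately use naive
## scalar loops / exhaustive enumeration and share no code with the package
## implementations they check.

options(GridTox.quiet = TRUE)

## brute-force per-atom / per-pixel double loop over the bounded vdW term
naiveVdwGrid <- function(toy, channel, spec) {
  ctr <- pixelCenters(spec)
  n <- nPixels(spec)
  typ <- toy@typing
  member <- which(channelMembership(typ)[, channel])
  rv <- vdwRadii(typ)
  xy <- atomCoords(toy)
  G <- matrix(0, n, n)
  for (a in member) {
    for (iy in seq_len(n)) {
      for (ix in seq_len(n)) {
        r <- sqrt((ctr[ix] - xy[a, 1])^2 + (ctr[iy] - xy[a, 2])^2)
        G[iy, ix] <- G[iy, ix] +
          (if (r == 0) 1 else 1 - exp(-(rv[a] / r)^12))
      }
    }
  }
  G
}

## brute-force 12-10 hydrogen-bond grid with the same guards as the package
naiveHbondGrid <- function(toy, spec, rMin = 0.5, clamp = c(-50, 50)) {
  ctr <- pixelCenters(spec)
  n <- nPixels(spec)
  typ <- toy@typing
  member <- which(typ@hbondRole != "none")
  xy <- atomCoords(toy)
  G <- matrix(0, n, n)
  for (a in member) {
    for (iy in seq_len(n)) {
      for (ix in seq_len(n)) {
        r <- sqrt((ctr[ix] - xy[a, 1])^2 + (ctr[iy] - xy[a, 2])^2)
        r <- max(r, rMin)
        G[iy, ix] <- G[iy, ix] + typ@hbondC[a] / r^12 - typ@hbondD[a] / r^10
      }
    }
  }
  pmin(pmax(G, clamp[1]), clamp[2])
}

## exhaustive concordant-pair AUC (ties count half)
pairAuc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  mean(outer(sp, sn, ">") + 0.5 * outer(sp, sn, "=="))
}

## scalar-loop weighted binary cross-entropy
loopBce <- function(yHat, y, wPos = 1, wNeg = 1) {
  tot <- 0
  for (i in seq_along(y)) {
    p <- min(max(yHat[i], 1e-7), 1 - 1e-7)
    tot <- tot - (wPos * y[i] * log(p) + wNeg * (1 - y[i]) * log(1 - p))
  }
  tot / length(y)
}

## max distance from points to their nearest segment among the given
## (a, b) index pairs into the matrix `ends`
maxSegmentDistance <- function(points, ends, pairs) {
  apply(points, 1, function(x) {
    d <- apply(pairs, 1, function(pr) {
      a <- ends[pr[1], ]; b <- ends[pr[2], ]
      ab <- b - a
      denom <- sum(ab^2)
      t <- if (denom < 1e-300) 0 else sum((x - a) * ab) / denom
      t <- min(max(t, 0), 1)
      sqrt(sum((x - (a + t * ab))^2))
    })
    min(d)
  })
}

## quick construction of a one-atom toy molecule with a single channel
singleAtomToy <- function(x, y, rv = 1.5, channel = "excluded_volume",
                          role = "none", element = "O") {
  ch <- matrix(FALSE, 1, 6, dimnames = list(NULL, channelNames()))
  ch[, "excluded_volume"] <- TRUE
  ch[, channel] <- TRUE
  hC <- hD <- 0
  if (role != "none") {
    cd <- hbondParameters(role, element)
    hC <- cd[["C"]]; hD <- cd[["D"]]
    ch[, "hbond"] <- TRUE
  }
  typ <- new("ChannelTyping", channels = ch, rVdw = rv,
             hbondRole = role, hbondC = hC, hbondD = hD)
  ToyMolecule(GridMolecule("one", element, coords = cbind(x, y)), typ)
}

## fixture SMILES table on disk; returns the path
fixtureTablePath <- function(dir = tempfile("gt")) {
  dir.create(dir, showWarnings = FALSE)
  p <- file.path(dir, "fixtures.tsv")
  makeSmilesFixtures(p)
  p
}

## standardized fixture MoleculeSet, computed once per test run
stdFixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(
        standardizeMolecules(readMolecules(fixtureTablePath())))
    cache
  }
})
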