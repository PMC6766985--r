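## Atom typing: map each atom of a standardized molecule onto the six
## descriptor channels and attach the physical parameters used by the grid
## equations (vdW radius for the bounded vdW term; 12-10 coefficients for
## the hydrogen-bond term). The rule constants are shipped as versioned
## data files under inst/extdata so they can be inspected and overridden.

typingRules <- function() {
  if (is.null(.gridtox_cache$rules)) {
    rules <- jsonlite::fromJSON(gtExtdata("typing_rules.json"))
    radii <- read.delim(gtExtdata("vdw_radii.tsv"), stringsAsFactors = FALSE)
    rules$radii <- stats::setNames(radii$radius, radii$element)
    .gridtox_cache$rules <- rules
  }
  .gridtox_cache$rules
}

#' Typing rule-set version
#'
#' @return Version string of the packaged channel-typing rule tables.
#' @export
typingRulesVersion <- function() typingRules()$version

#' van der Waals radius of an element
#'
#' Looks up the Bondi-type radius table packaged with the rule set.
#' Unlisted elements fall back to the default radius (1.70 A) with a
#' warning, so exotic species never abort a batch.
#'
#' @param element character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vdwRadius(c("C", "H", "O"))
vdwRadius <- function(element) {
  rules <- typingRules()
  r <- unname(rules$radii[element])
  if (anyNA(r)) {
    unknown <- unique(element[is.na(r)])
    gtWarn("no vdW radius for element(s) %s; using default %.2f A",
           paste(unknown, collapse = ", "), rules$default_radius)
    r[is.na(r)] <- rules$default_radius
  }
  r
}

#' 12-10 hydrogen-bond well coefficients
#'
#' Returns the coefficients of the 12-10 potential
#' \code{V(r) = C / r^12 - D / r^10} for a donor/acceptor atom, using the
#' AutoDock per-class convention \code{C = 5 eps r_eq^12},
#' \code{D = 6 eps r_eq^10}: the well has its unique minimum of depth
#' \code{-eps} at \code{r = r_eq}. Nitrogen and oxygen share one parameter
#' class (eps = 5, r_eq = 1.9 A); sulfur has a shallower, longer well
#' (eps = 1, r_eq = 2.5 A).
#'
#' @param role hydrogen-bond role, one of "donor", "acceptor", "both".
#'   "none" is a contract violation and raises an error.
#' @param element element symbol of the donor/acceptor heavy atom.
#' @return Named numeric vector with components C, D, epsilon, r_eq.
#' @export
#' @examples
#' hbondParameters("both", "O")
hbondParameters <- function(role, element) {
  if (identical(role, "none"))
    stop("hbondParameters() requires a donor/acceptor role, not 'none'")
  if (!role %in% c("donor", "acceptor", "both"))
    stop("unknown hydrogen-bond role: ", role)
  cls <- typingRules()$hbond_classes
  if (element %in% cls$S$elements) p <- cls$S
  else {
    if (!element %in% cls$NO$elements)
      gtWarn("no 12-10 parameter class for element %s; using the N/O class",
             element)
    p <- cls$NO
  }
  eps <- p$epsilon; req <- p$r_eq
  c(C = 5 * eps * req^12, D = 6 * eps * req^10, epsilon = eps, r_eq = req)
}

## --- graph helpers over the connection table -------------------------------

## adjacency list (indices) from a bond matrix
.adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1L]; j <- bonds[b, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

## does atom i have a double (order 2) bond to any neighbor with element in set?
.hasDoubleBondTo <- function(i, set, element, bonds) {
  if (!nrow(bonds)) return(FALSE)
  hit <- (bonds[, 1L] == i & bonds[, 3L] == 2 & element[bonds[, 2L]] %in% set) |
         (bonds[, 2L] == i & bonds[, 3L] == 2 & element[bonds[, 1L]] %in% set)
  any(hit)
}

## orders of bonds incident to atom i
.incidentOrders <- function(i, bonds) {
  if (!nrow(bonds)) return(numeric())
  bonds[bonds[, 1L] == i | bonds[, 2L] == i, 3L]
}

## connected components of the subgraph induced by `keep` (logical)
.components <- function(keep, adj) {
  n <- length(keep)
  comp <- integer(n)
  cur <- 0L
  for (s in which(keep)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- adj[[v]]
      stack <- c(stack, nb[keep[nb] & comp[nb] == 0L])
    }
  }
  comp
}

## --- channel assignment -----------------------------------------------------

#' Assign atoms to the six descriptor channels
#'
#' Applies the packaged typing rule set to a standardized molecule (explicit
#' hydrogens, perceived aromaticity) and returns per-atom channel
#' memberships plus the physical parameters consumed by the grid equations.
#'
#' The rules, chosen as common pharmacophore conventions:
#' \itemize{
#'   \item hydrogen bond: donors are N/O/S bearing at least one explicit
#'     hydrogen; acceptors are oxygens with non-positive charge, nitrogens
#'     with non-positive charge that are not aromatic NH, and divalent
#'     sulfur. The heavy atom carries the channel, not the hydrogen.
#'   \item hydrophobicity: carbons without N/O/S neighbors, plus halogens.
#'   \item metallicity: membership in the packaged metallic-element list.
#'   \item excluded volume: every atom, including explicit hydrogens.
#'   \item positive ionization: basic nitrogens -- positively charged N,
#'     aliphatic amines (all-single-bond N whose heavy neighbors are
#'     non-aromatic carbons without double bonds to O/N/S), and the
#'     nitrogens of amidine/guanidine groups.
#'   \item negative ionization: acidic groups -- negatively charged O/S/N,
#'     carboxylic/sulfonic/phosphonic acid oxygens, and tetrazole ring
#'     nitrogens.
#' }
#' All channels except excluded volume operate on heavy atoms only.
#'
#' @param mol a standardized \code{GridMolecule}.
#' @param verbose log per-channel membership counts (default FALSE).
#' @return A \code{\link{ChannelTyping}}.
#' @export
assignChannels <- function(mol, verbose = FALSE) {
  stopifnot(is(mol, "GridMolecule"))
  rules <- typingRules()
  el <- mol@element
  n <- length(el)
  chg <- mol@charge
  arom <- mol@aromatic
  bonds <- mol@bonds
  adj <- .adjacency(n, bonds)

  isH <- el == "H"
  hasH <- vapply(seq_len(n), function(i) any(isH[adj[[i]]]), logical(1L))
  heavyDeg <- vapply(seq_len(n), function(i) sum(!isH[adj[[i]]]), integer(1L))
  deg <- lengths(adj)

  ## hydrogen-bond roles (heavy atoms only)
  nos <- el %in% c("N", "O", "S")
  donor <- nos & hasH
  acceptor <- logical(n)
  acceptor[el == "O" & chg <= 0] <- TRUE
  acceptor[el == "N" & chg <= 0 & !(arom & hasH)] <- TRUE
  acceptor[el == "S" & chg <= 0 & deg <= 2L] <- TRUE
  role <- rep("none", n)
  role[donor & !acceptor] <- "donor"
  role[acceptor & !donor] <- "acceptor"
  role[donor & acceptor] <- "both"

  ## hydrophobicity
  hydroph <- (el == "C" &
              !vapply(seq_len(n), function(i) any(el[adj[[i]]] %in% c("N", "O", "S")),
                      logical(1L))) |
             el %in% rules$halogens

  ## metallicity
  metal <- el %in% rules$metals

  ## positive ionization: basic nitrogens
  posion <- logical(n)
  posion[el == "N" & chg > 0] <- TRUE
  for (i in which(el == "N" & chg == 0 & !arom)) {
    ord <- .incidentOrders(i, bonds)
    if (length(ord) && all(ord == 1)) {
      heavy <- adj[[i]][!isH[adj[[i]]]]
      ok <- length(heavy) > 0L &&
        all(el[heavy] == "C" & !arom[heavy]) &&
        !any(vapply(heavy, .hasDoubleBondTo, logical(1L),
                    set = c("O", "N", "S"), element = el, bonds = bonds))
      if (ok) posion[i] <- TRUE
    }
  }
  ## amidine / guanidine: C with =N, >=1 single-bonded N, no O/S neighbors
  for (i in which(el == "C" & !arom)) {
    nb <- adj[[i]][!isH[adj[[i]]]]
    if (any(el[nb] %in% c("O", "S"))) next
    nN <- nb[el[nb] == "N"]
    if (length(nN) >= 2L && .hasDoubleBondTo(i, "N", el, bonds))
      posion[nN] <- TRUE
  }

  ## negative ionization: acidic groups
  negion <- logical(n)
  negion[el %in% c("O", "S", "N") & chg < 0] <- TRUE
  acidicO <- function(center, nDoubleO) {
    nb <- adj[[center]][!isH[adj[[center]]]]
    oxy <- nb[el[nb] == "O"]
    dblO <- oxy[vapply(oxy, function(o) {
      any((bonds[, 1L] == center & bonds[, 2L] == o & bonds[, 3L] == 2) |
          (bonds[, 2L] == center & bonds[, 1L] == o & bonds[, 3L] == 2))
    }, logical(1L))]
    hydO <- setdiff(oxy, dblO)
    hydO <- hydO[hasH[hydO] | chg[hydO] < 0]
    if (length(dblO) >= nDoubleO && length(hydO) >= 1L) c(dblO, hydO) else integer()
  }
  if (nrow(bonds)) {
    for (i in which(el == "C" & !arom)) negion[acidicO(i, 1L)] <- TRUE
    for (i in which(el == "S")) negion[acidicO(i, 2L)] <- TRUE
    for (i in which(el == "P")) negion[acidicO(i, 1L)] <- TRUE
  }
  ## tetrazole: aromatic 5-cycle of 4 N + 1 C
  if (any(arom)) {
    comp <- .components(arom, adj)
    for (k in unique(comp[comp > 0L])) {
      memb <- which(comp == k)
      if (length(memb) == 5L && sum(el[memb] == "N") == 4L &&
          sum(el[memb] == "C") == 1L)
        negion[memb[el[memb] == "N"]] <- TRUE
    }
  }

  ## hydrogens carry excluded volume only
  donorlike <- role != "none" & !isH
  channels <- cbind(hbond = donorlike,
                    hydrophobicity = hydroph & !isH,
                    metallicity = metal & !isH,
                    excluded_volume = rep(TRUE, n),
                    positive_ionization = posion & !isH,
                    negative_ionization = negion & !isH)
  role[isH] <- "none"

  rv <- vdwRadius(el)
  hC <- hD <- numeric(n)
  for (i in which(role != "none")) {
    cd <- hbondParameters(role[i], el[i])
    hC[i] <- cd[["C"]]; hD[i] <- cd[["D"]]
  }

  if (verbose) {
    cnt <- colSums(channels)
    gtLog("molecule %s: %s", mol@id,
          paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "))
  }
  new("ChannelTyping", channels = channels, rVdw = rv, hbondRole = role,
      hbondC = hC, hbondD = hD)
}
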