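# Internal molecular-graph layer.
#
# Molecules are parsed from SMILES with ChemmineR/ChemmineOB (OpenBabel) and
# held as light graph records: atoms (element, formal charge, implicit-H
# estimate, ring/aromatic flags, pi-bond count) and bonds (kekulized orders),
# plus an all-pairs topological distance matrix from igraph.  This layer
# feeds the hand-built fingerprint families and Murcko scaffolds; OpenBabel
# re-perceives chemistry itself for the families it computes natively.

.ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si",
               "Se", "As", "H", "Na", "K", "Li", "Mg", "Ca", "Zn", "Fe")

.DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                      Br = 1, I = 1, B = 3, Si = 4, Se = 2, As = 3, H = 1)

# V2000 atom-block charge codes -> formal charge
.CHARGE_CODE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                  `6` = -2, `7` = -3)

.elementIndex <- function(elem) {
  idx <- match(elem, .ELEMENTS)
  idx[is.na(idx)] <- length(.ELEMENTS) + 1L
  idx
}

# Parse a named SMILES vector into SDFset; invalid entries are dropped and
# reported.  Returns list(sdf = SDFset or NULL, failed = character ids).
.parseSmilesBatch <- function(smiles) {
  stopifnot(!is.null(names(smiles)), !anyDuplicated(names(smiles)))
  res <- suppressWarnings(try(ChemmineR::smiles2sdf(smiles), silent = TRUE))
  if (!inherits(res, "try-error")) {
    ChemmineR::cid(res) <- names(smiles)
    return(list(sdf = res, failed = character(0)))
  }
  # fall back to per-molecule parsing so one bad SMILES does not sink the batch
  ok <- list()
  failed <- character(0)
  for (id in names(smiles)) {
    one <- suppressWarnings(try(ChemmineR::smiles2sdf(smiles[id]), silent = TRUE))
    if (inherits(one, "try-error")) failed <- c(failed, id) else ok[[id]] <- one[[1]]
  }
  if (length(ok) == 0) return(list(sdf = NULL, failed = failed))
  sdf <- new("SDFset", SDF = ok, ID = names(ok))
  list(sdf = sdf, failed = failed)
}

.emptyMolgraph <- function() {
  bonds <- matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("from", "to", "order")))
  list(n = 0L, elem = character(0), elemIdx = integer(0), charge = integer(0),
       degree = integer(0), imph = integer(0), npi = integer(0),
       bonds = bonds, bondOrder = numeric(0), inRingAtom = logical(0),
       inRingBond = logical(0), aromatic = logical(0), adj = list(),
       dist = matrix(numeric(0), 0, 0),
       coords = matrix(numeric(0), 0, 3))
}

# Build the graph record for one ChemmineR SDF object.
.molgraphFromSDF <- function(sdfobj) {
  ab <- ChemmineR::atomblock(sdfobj)
  bb <- ChemmineR::bondblock(sdfobj)
  # single-atom molecules come through as degenerate blocks
  if (is.null(ab) || nrow(ab) == 0 || ncol(ab) < 3) return(.emptyMolgraph())
  n <- nrow(ab)
  elem <- sub("_.*$", "", rownames(ab))
  charge <- rep(0L, n)
  if ("C6" %in% colnames(ab)) {
    code <- as.character(ab[, "C6"])
    charge <- as.integer(.CHARGE_CODE[code])
    charge[is.na(charge)] <- 0L
  }
  if (is.null(bb) || length(bb) == 0 || is.null(dim(bb)) || nrow(bb) == 0 ||
      ncol(bb) < 3) {
    bonds <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("from", "to", "order")))
  } else {
    bonds <- cbind(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  }
  # OpenBabel writes kekulized structures; treat a stray aromatic code 4 as 1.5
  ordnum <- ifelse(bonds[, "order"] == 4L, 1.5, as.numeric(bonds[, "order"]))

  deg <- tabulate(c(bonds[, "from"], bonds[, "to"]), nbins = n)
  bondsum <- numeric(n)
  npi <- integer(n)
  for (i in seq_len(nrow(bonds))) {
    f <- bonds[i, "from"]; t <- bonds[i, "to"]; o <- ordnum[i]
    bondsum[f] <- bondsum[f] + o
    bondsum[t] <- bondsum[t] + o
    if (o >= 2) {
      npi[f] <- npi[f] + as.integer(o - 1)
      npi[t] <- npi[t] + as.integer(o - 1)
    }
  }
  defval <- .DEFAULT_VALENCE[elem]
  defval[is.na(defval)] <- 0
  # approximate implicit hydrogens; charge raises capacity on N/P cations and
  # lowers it on anions -- adequate for fingerprint invariants
  imph <- pmax(0, round(defval + charge - bondsum))

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0) {
    g <- igraph::add_edges(g, t(bonds[, c("from", "to"), drop = FALSE]))
  }
  inRingBond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0) {
    br <- igraph::bridges(g)
    inRingBond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  inRingAtom <- rep(FALSE, n)
  if (any(inRingBond)) {
    ra <- unique(c(bonds[inRingBond, "from"], bonds[inRingBond, "to"]))
    inRingAtom[ra] <- TRUE
  }
  hasDouble <- rep(FALSE, n)
  dbl <- which(ordnum >= 2)
  if (length(dbl)) hasDouble[unique(c(bonds[dbl, "from"], bonds[dbl, "to"]))] <- TRUE
  aromatic <- inRingAtom & (hasDouble | elem %in% c("N", "O", "S"))

  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    f <- bonds[i, "from"]; t <- bonds[i, "to"]
    adj[[f]] <- rbind(adj[[f]], c(t, i))
    adj[[t]] <- rbind(adj[[t]], c(f, i))
  }

  list(n = n, elem = elem, elemIdx = .elementIndex(elem), charge = charge,
       degree = deg, imph = as.integer(imph), npi = npi,
       bonds = bonds, bondOrder = ordnum, inRingAtom = inRingAtom,
       inRingBond = inRingBond, aromatic = aromatic, adj = adj,
       dist = igraph::distances(g),
       coords = ab[, 1:3, drop = FALSE])
}

# Parse SMILES into molgraphs. Returns list(graphs = named list, sdf = SDFset,
# failed = character ids).  The SDFset is kept for OpenBabel-backed kinds.
.parseMolecules <- function(smiles) {
  p <- .parseSmilesBatch(smiles)
  graphs <- list()
  if (!is.null(p$sdf)) {
    ids <- ChemmineR::cid(p$sdf)
    for (i in seq_along(ids)) graphs[[ids[i]]] <- .molgraphFromSDF(p$sdf[[i]])
  }
  list(graphs = graphs, sdf = p$sdf, failed = p$failed)
}

# Deterministic tuple hash on non-negative integers (djb2-style, exact in
# double arithmetic below 2^53, reduced mod a Mersenne prime).
.hashInts <- function(v) {
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647
  h
}
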