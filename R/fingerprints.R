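# Fingerprint families and Tanimoto similarity.
#
# Four families are delegated to established toolkits: ECFP4 and MACCS and
# the linear-path family ("Path") to OpenBabel via ChemmineOB, atom pairs to
# ChemmineR.  The remaining families (FCFP4, Torsion, Avalon, Layered) have
# no installed R implementation and are computed here over the internal
# molecular graph as hashed, folded bit vectors of the corresponding feature
# classes: functional-class circular environments, topological torsions,
# path+feature enumeration, and multi-layer path typing.

.FP_KINDS <- c("AtomPair", "Avalon", "ECFP4", "FCFP4", "Layered", "MACCS",
               "Path", "Torsion")
.OB_KINDS <- c(ECFP4 = "ECFP4", MACCS = "MACCS", Path = "FP2")

#' Fingerprint families
#'
#' @return Character vector of the eight supported fingerprint kinds, in
#'   alphabetical order.
#' @examples
#' fingerprintKinds()
#' @export
fingerprintKinds <- function() .FP_KINDS

#' Bit-vector length of a fingerprint kind
#'
#' All families are folded to 1024 bits except MACCS, whose 166 predefined
#' substructure keys fix its length.
#'
#' @param kind One of \code{\link{fingerprintKinds}()}.
#' @return Integer number of bits.
#' @export
fingerprintLength <- function(kind) {
  kind <- match.arg(kind, .FP_KINDS)
  if (kind == "MACCS") 166L else 1024L
}

.setBits <- function(hashes, nbits) {
  v <- logical(nbits)
  if (length(hashes)) v[(hashes %% nbits) + 1L] <- TRUE
  v
}

.lexiMin <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(a)
    if (a[i] > b[i]) return(b)
  }
  a
}

# -- circular (Morgan-style) fingerprint with functional-class invariants ----

.fpFCFP4 <- function(g, nbits = 1024L) {
  n <- g$n
  if (n == 0) return(logical(nbits))
  donor <- as.integer(g$elem %in% c("N", "O") & g$imph > 0)
  acceptor <- as.integer(g$elem %in% c("N", "O"))
  posIon <- as.integer(g$charge > 0 | (g$elem == "N" & !g$aromatic & g$npi == 0))
  negIon <- as.integer(g$charge < 0)
  halogen <- as.integer(g$elem %in% c("F", "Cl", "Br", "I"))
  inv <- vapply(seq_len(n), function(a) {
    .hashInts(c(901L, donor[a], acceptor[a], posIon[a], negIon[a],
                as.integer(g$aromatic[a]), halogen[a]))
  }, numeric(1))
  all_inv <- inv
  for (r in 1:2) {
    newinv <- inv
    for (a in seq_len(n)) {
      nb <- g$adj[[a]]
      if (is.null(nb)) next
      pairs <- cbind(g$bondOrder[nb[, 2]] * 10, inv[nb[, 1]])
      ord <- order(pairs[, 1], pairs[, 2])
      newinv[a] <- .hashInts(c(r, inv[a], as.vector(t(pairs[ord, , drop = FALSE]))))
    }
    inv <- newinv
    all_inv <- c(all_inv, inv)
  }
  .setBits(all_inv, nbits)
}

# -- topological torsions ----------------------------------------------------

.fpTorsion <- function(g, nbits = 1024L) {
  if (g$n == 0 || nrow(g$bonds) == 0) return(logical(nbits))
  at <- vapply(seq_len(g$n), function(a) {
    .hashInts(c(701L, g$elemIdx[a], g$npi[a], g$degree[a]))
  }, numeric(1))
  hashes <- numeric(0)
  for (b in seq_len(nrow(g$bonds))) {
    j <- g$bonds[b, "from"]; k <- g$bonds[b, "to"]
    nbj <- g$adj[[j]]; nbk <- g$adj[[k]]
    is_ <- setdiff(nbj[, 1], k)
    ls_ <- setdiff(nbk[, 1], j)
    for (i in is_) for (l in ls_) {
      if (i == l) next
      tup <- .lexiMin(c(at[i], at[j], at[k], at[l]),
                      c(at[l], at[k], at[j], at[i]))
      hashes <- c(hashes, .hashInts(c(7L, tup)))
    }
  }
  .setBits(hashes, nbits)
}

# -- simple-path enumeration (shared by Avalon and Layered variants) ---------

# All simple paths with 0..maxlen bonds; each returned once (canonical
# direction chosen later per encoding).  Atoms and traversed bond indices.
.enumPaths <- function(g, maxlen) {
  paths <- list()
  emit <- function(atoms, bonds) {
    if (length(atoms) == 1 || atoms[1] < atoms[length(atoms)]) {
      paths[[length(paths) + 1L]] <<- list(atoms = atoms, bonds = bonds)
    }
  }
  walk <- function(atoms, bonds, visited) {
    emit(atoms, bonds)
    if (length(bonds) >= maxlen) return()
    a <- atoms[length(atoms)]
    nb <- g$adj[[a]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1]
      if (visited[nxt]) next
      visited[nxt] <- TRUE
      walk(c(atoms, nxt), c(bonds, nb[r, 2]), visited)
      visited[nxt] <- FALSE
    }
  }
  for (s in seq_len(g$n)) {
    visited <- logical(g$n)
    visited[s] <- TRUE
    walk(s, integer(0), visited)
  }
  paths
}

.pathHash <- function(salt, acodes, bcodes) {
  # interleave a1 b1 a2 ... an, canonical direction = lexicographic minimum
  fwd <- c(acodes[1], as.vector(rbind(bcodes, acodes[-1])))
  rev_ <- c(acodes[length(acodes)],
            as.vector(rbind(rev(bcodes), rev(acodes)[-1])))
  .hashInts(c(salt, .lexiMin(fwd, rev_)))
}

# -- Avalon-style hashed path/feature-class fingerprint ----------------------

.fpAvalon <- function(g, nbits = 1024L, paths = NULL) {
  if (g$n == 0) return(logical(nbits))
  if (is.null(paths)) paths <- .enumPaths(g, 5L)
  acode <- g$elemIdx * 8 + as.integer(g$inRingAtom) * 4 +
    as.integer(g$aromatic) * 2 + as.integer(g$charge != 0)
  hashes <- numeric(0)
  for (p in paths) {
    if (length(p$bonds) > 5L) next
    hashes <- c(hashes,
                .pathHash(11L, acode[p$atoms], g$bondOrder[p$bonds] * 2))
  }
  featu <- vapply(seq_len(g$n), function(a) {
    .hashInts(c(13L, g$elemIdx[a], g$degree[a], g$imph[a],
                as.integer(g$inRingAtom[a])))
  }, numeric(1))
  .setBits(c(hashes, featu), nbits)
}

# -- layered path fingerprint ------------------------------------------------

.fpLayered <- function(g, nbits = 1024L, paths = NULL) {
  if (g$n == 0) return(logical(nbits))
  if (is.null(paths)) paths <- .enumPaths(g, 7L)
  ring <- as.integer(g$inRingAtom)
  hashes <- numeric(0)
  for (p in paths) {
    if (length(p$bonds) == 0) next
    bo <- g$bondOrder[p$bonds] * 2
    hashes <- c(hashes,
                .hashInts(c(21L, bo)),
                .pathHash(22L, g$elemIdx[p$atoms], bo),
                .pathHash(23L, g$elemIdx[p$atoms] * 2 + ring[p$atoms], bo))
  }
  .setBits(hashes, nbits)
}

.fpOwn <- function(g, kind) {
  switch(kind,
         FCFP4 = .fpFCFP4(g),
         Torsion = .fpTorsion(g),
         Avalon = {
           paths <- .enumPaths(g, 5L)
           .fpAvalon(g, paths = paths)
         },
         Layered = .fpLayered(g, paths = .enumPaths(g, 7L)),
         stop("no internal implementation for kind ", kind))
}

.fold4096 <- function(m) {
  m[, 1:1024, drop = FALSE] | m[, 1025:2048, drop = FALSE] |
    m[, 2049:3072, drop = FALSE] | m[, 3073:4096, drop = FALSE]
}

.obFingerprints <- function(sdf, kind) {
  fp <- ChemmineR::fingerprintOB(sdf, .OB_KINDS[[kind]])
  m <- fp@fpma > 0
  rownames(m) <- ChemmineR::cid(sdf)
  if (kind == "ECFP4") m <- .fold4096(m)
  if (kind == "MACCS") m <- m[, 1:166, drop = FALSE]
  if (kind == "Path") m <- m[, 1:1024, drop = FALSE]
  m
}

# the 1024 most frequent atom-pair descriptors (ChemmineR reference set)
.apDescriptors <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env(parent = emptyenv())
      utils::data("apfp", package = "ChemmineR", envir = e)
      cache <<- e$apfp$AP[seq_len(1024)]
    }
    cache
  }
})

.apFingerprints <- function(sdf) {
  ap <- suppressWarnings(ChemmineR::sdf2ap(sdf))
  fp <- ChemmineR::desc2fp(ap, descnames = .apDescriptors(), type = "FPset")
  m <- fp@fpma > 0
  rownames(m) <- ChemmineR::cid(sdf)
  m
}

# SDF-backed kinds choke on degenerate (e.g. single-atom) records; compute
# on the valid subset and leave all-zero rows for the rest.
.sdfKindMatrix <- function(parsed, kind) {
  ids <- ChemmineR::cid(parsed$sdf)
  full <- matrix(FALSE, nrow = length(ids), ncol = fingerprintLength(kind),
                 dimnames = list(ids, NULL))
  valid <- suppressWarnings(ChemmineR::validSDF(parsed$sdf))
  if (any(valid)) {
    sub <- parsed$sdf[valid]
    m <- if (kind == "AtomPair") .apFingerprints(sub) else
      .obFingerprints(sub, kind)
    full[rownames(m), ] <- m
  }
  full
}

# Compute fingerprints from an already-parsed molecule batch.
.fingerprintsFromParsed <- function(parsed, kinds) {
  out <- list()
  for (kind in kinds) {
    if (kind %in% c(names(.OB_KINDS), "AtomPair")) {
      m <- .sdfKindMatrix(parsed, kind)
    } else {
      ids <- names(parsed$graphs)
      m <- matrix(FALSE, nrow = length(ids), ncol = fingerprintLength(kind),
                  dimnames = list(ids, NULL))
      for (id in ids) m[id, ] <- .fpOwn(parsed$graphs[[id]], kind)
    }
    attr(m, "kind") <- kind
    out[[kind]] <- m
  }
  out
}

#' Compute molecular fingerprints
#'
#' Computes one or more 2D fingerprint families for a set of molecules.
#' ECFP4 (folded from OpenBabel's 4096-bit extended-connectivity output),
#' MACCS (166 keys) and Path (linear fragments up to 7 atoms) are computed
#' by OpenBabel; AtomPair by ChemmineR; FCFP4, Torsion, Avalon and Layered
#' by the package's graph-hashing implementations.  All kinds are 1024-bit
#' except MACCS (166).
#'
#' @param smiles Named character vector of SMILES (names are molecule ids).
#' @param kinds Character vector of fingerprint kinds; see
#'   \code{\link{fingerprintKinds}}.
#' @return Named list (one element per kind) of logical matrices with one
#'   row per molecule; each matrix carries a \code{"kind"} attribute.
#' @examples
#' fps <- computeFingerprints(c(tol = "Cc1ccccc1"), kinds = "MACCS")
#' ncol(fps$MACCS)
#' @export
computeFingerprints <- function(smiles, kinds = fingerprintKinds()) {
  kinds <- match.arg(kinds, .FP_KINDS, several.ok = TRUE)
  parsed <- .parseMolecules(smiles)
  if (length(parsed$failed)) {
    stop("unparseable SMILES for: ", paste(parsed$failed, collapse = ", "))
  }
  .fingerprintsFromParsed(parsed, kinds)
}

#' Tanimoto similarity between two fingerprints
#'
#' \eqn{Tc = |A \cap B| / |A \cup B|} on the set bits.  Two all-zero
#' fingerprints have similarity 0 (a featureless fragment carries no
#' evidence of similarity).
#'
#' @param a,b Logical (or 0/1) bit vectors of equal length, from the same
#'   fingerprint kind.
#' @return Numeric scalar in [0, 1].
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))
#' @export
tanimoto <- function(a, b) {
  ka <- attr(a, "kind"); kb <- attr(b, "kind")
  if (!is.null(ka) && !is.null(kb) && !identical(ka, kb)) {
    stop("fingerprint kinds differ: ", ka, " vs ", kb)
  }
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' All-pairs Tanimoto similarity matrix
#'
#' @param A,B Logical fingerprint matrices (rows = molecules) of the same
#'   kind and width.
#' @return Numeric matrix of dimension \code{nrow(A)} x \code{nrow(B)};
#'   pairs of all-zero fingerprints score 0.
#' @export
tanimotoMatrix <- function(A, B) {
  if (ncol(A) != ncol(B)) stop("fingerprint lengths differ")
  ka <- attr(A, "kind"); kb <- attr(B, "kind")
  if (!is.null(ka) && !is.null(kb) && !identical(ka, kb)) {
    stop("fingerprint kinds differ: ", ka, " vs ", kb)
  }
  Am <- matrix(as.numeric(A), nrow = nrow(A))
  Bm <- matrix(as.numeric(B), nrow = nrow(B))
  common <- Am %*% t(Bm)
  union <- outer(rowSums(Am), rowSums(Bm), "+") - common
  sim <- ifelse(union == 0, 0, common / union)
  dimnames(sim) <- list(rownames(A), rownames(B))
  sim
}
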