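# Bemis-Murcko scaffolds.
#
# The molecular framework is the union of ring systems and the linker
# chains connecting them: acyclic side chains are pruned by iteratively
# deleting terminal atoms, after which atoms double-bonded directly to the
# framework (e.g. exocyclic carbonyl oxygens) are restored.  The framework
# is canonicalized through OpenBabel canonical SMILES so that molecules
# differing only in acyclic substituents map to the same scaffold string.

.molblockFromSubgraph <- function(g, keep) {
  idx <- which(keep)
  remap <- match(seq_len(g$n), idx)
  bsel <- which(keep[g$bonds[, "from"]] & keep[g$bonds[, "to"]])
  lines <- c("scaffold", "  tanifish", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     length(idx), length(bsel)))
  for (a in idx) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      g$coords[a, 1], g$coords[a, 2], g$coords[a, 3], g$elem[a]))
  }
  for (b in bsel) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", remap[g$bonds[b, "from"]],
                              remap[g$bonds[b, "to"]], g$bonds[b, "order"]))
  }
  chg <- which(g$charge[idx] != 0)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste(sprintf("%4d%4d", chg, g$charge[idx][chg]),
                                   collapse = "")))
  }
  c(lines, "M  END", "$$$$")
}

.scaffoldAtoms <- function(g) {
  if (g$n == 0 || nrow(g$bonds) == 0 || !any(g$inRingBond)) return(logical(g$n))
  keep <- rep(TRUE, g$n)
  repeat {
    deg <- numeric(g$n)
    bsel <- keep[g$bonds[, "from"]] & keep[g$bonds[, "to"]]
    deg1 <- tabulate(c(g$bonds[bsel, "from"], g$bonds[bsel, "to"]), nbins = g$n)
    drop <- keep & deg1 == 1
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # restore atoms attached to the framework by a multiple bond
  for (b in seq_len(nrow(g$bonds))) {
    if (g$bondOrder[b] < 2) next
    f <- g$bonds[b, "from"]; t <- g$bonds[b, "to"]
    if (keep[f] && !keep[t]) keep[t] <- TRUE
    if (keep[t] && !keep[f]) keep[f] <- TRUE
  }
  keep
}

#' Bemis-Murcko scaffold
#'
#' Computes the canonical molecular framework (ring systems plus linkers,
#' acyclic side chains removed) for each molecule.  Acyclic molecules have
#' an empty scaffold (\code{""}); \code{\link{scaffoldKey}} groups them
#' under a dedicated \code{"acyclic"} key.
#'
#' @param smiles Character vector of SMILES (optionally named).
#' @return Character vector of canonical scaffold SMILES, \code{""} for
#'   acyclic molecules, \code{NA} for unparseable input.
#' @examples
#' murckoScaffold(c("Cc1ccccc1", "CCc1ccccc1"))  # both toluene-like -> benzene
#' @export
murckoScaffold <- function(smiles) {
  if (is.null(names(smiles))) names(smiles) <- sprintf("m%06d", seq_along(smiles))
  parsed <- .parseMolecules(smiles)
  out <- setNames(rep(NA_character_, length(smiles)), names(smiles))
  blocks <- character(0)
  block_ids <- character(0)
  for (id in names(parsed$graphs)) {
    g <- parsed$graphs[[id]]
    keep <- .scaffoldAtoms(g)
    if (!any(keep)) {
      out[id] <- ""
    } else {
      blocks <- c(blocks, .molblockFromSubgraph(g, keep))
      block_ids <- c(block_ids, id)
    }
  }
  if (length(block_ids)) {
    can <- ChemmineOB::convertFormat("SDF", "CAN", paste(blocks, collapse = "\n"))
    can_lines <- strsplit(can, "\n", fixed = TRUE)[[1]]
    can_lines <- can_lines[nzchar(trimws(can_lines))]
    if (length(can_lines) != length(block_ids)) {
      stop("scaffold canonicalization failed (", length(can_lines), " of ",
           length(block_ids), " frameworks converted)")
    }
    out[block_ids] <- vapply(strsplit(can_lines, "[ \t]"), `[`, "", 1)
  }
  out
}

#' Scaffold grouping key
#'
#' Maps scaffold strings to grouping keys: acyclic molecules (empty
#' scaffold) share the single key \code{"acyclic"} so that the scaffold map
#' is a partition of the ligand set.
#'
#' @param scaffold Character vector from \code{\link{murckoScaffold}}.
#' @return Character vector of keys.
#' @export
scaffoldKey <- function(scaffold) {
  ifelse(is.na(scaffold) | scaffold == "", "acyclic", scaffold)
}
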