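#' ReferenceLibrary: curated ligand-target bioactivity store
#'
#' Immutable result of \code{\link{buildLibrary}}: standardized ligand
#' structures, the target table (with optional class annotations and a
#' predictability flag), curated interactions (one row per retained
#' ligand-target pair, median potency in nM), a per-target ligand index,
#' and the curation log of discarded records.
#'
#' @slot ligands data.frame with columns \code{ligand_id}, \code{smiles}
#'   (standardized canonical SMILES).
#' @slot targets data.frame with columns \code{target_id},
#'   \code{target_class} (NA when unannotated), \code{predictable}.
#' @slot interactions data.frame with columns \code{ligand_id},
#'   \code{target_id}, \code{activity_nM}, \code{n_measurements}.
#' @slot ligandIndex named list mapping each predictable target to the
#'   character vector of its ligand ids.
#' @slot curationLog data.frame with columns \code{ligand_id},
#'   \code{target_id}, \code{reason} for every discarded record or pair.
#' @slot standardization list recording the structure-standardization
#'   options used at build time.
#'
#' @exportClass ReferenceLibrary
setClass("ReferenceLibrary",
         representation(ligands = "data.frame",
                        targets = "data.frame",
                        interactions = "data.frame",
                        ligandIndex = "list",
                        curationLog = "data.frame",
                        standardization = "list"))

setValidity("ReferenceLibrary", function(object) {
  msg <- character(0)
  ia <- object@interactions
  if (nrow(ia)) {
    if (!all(ia$ligand_id %in% object@ligands$ligand_id))
      msg <- c(msg, "interaction references unknown ligand")
    if (!all(ia$target_id %in% object@targets$target_id))
      msg <- c(msg, "interaction references unknown target")
    if (anyDuplicated(paste(ia$ligand_id, ia$target_id)))
      msg <- c(msg, "duplicate (ligand, target) interaction")
    if (any(ia$activity_nM >= 1000 | ia$activity_nM <= 0))
      msg <- c(msg, "interaction activity outside (0, 1000) nM")
  }
  idx_pairs <- sum(lengths(object@ligandIndex))
  if (idx_pairs != nrow(ia))
    msg <- c(msg, "ligand index inconsistent with interactions")
  for (t in names(object@ligandIndex)) {
    if (!setequal(object@ligandIndex[[t]], ia$ligand_id[ia$target_id == t])) {
      msg <- c(msg, paste0("ligand index wrong for target ", t))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' TargetRanking: ranked target predictions for one query
#'
#' Ordered prediction list for a single query molecule under one scoring
#' configuration.  \code{entries} keeps the pre-filter ordinal rank even
#' after similarity-threshold filtering (\code{\link{applyThreshold}}), so
#' "top-n" always refers to the unfiltered ranking.
#'
#' @slot query_id character query identifier.
#' @slot kind fingerprint kind (or a "+"-joined set for ensembles).
#' @slot scheme scoring scheme label ("MaxTc", "KNNTc", "MeanTc",
#'   "zscore_sum", "rank_sum").
#' @slot k integer neighbour count (KNNTc only; NA otherwise).
#' @slot entries data.frame with columns \code{rank}, \code{target_id},
#'   \code{score}, \code{best_similarity}, \code{best_ligand_id}.
#'
#' @exportClass TargetRanking
setClass("TargetRanking",
         representation(query_id = "character", kind = "character",
                        scheme = "character", k = "integer",
                        entries = "data.frame"))

setValidity("TargetRanking", function(object) {
  e <- object@entries
  msg <- character(0)
  need <- c("rank", "target_id", "score", "best_similarity", "best_ligand_id")
  if (!all(need %in% names(e))) return("entries missing required columns")
  if (nrow(e)) {
    if (anyDuplicated(e$rank)) msg <- c(msg, "duplicate ranks")
    if (is.unsorted(e$rank, strictly = TRUE)) msg <- c(msg, "ranks not increasing")
    if (any(e$rank < 1)) msg <- c(msg, "ranks must be >= 1")
    if (anyDuplicated(e$target_id)) msg <- c(msg, "duplicate targets")
  }
  if (length(msg)) msg else TRUE
})

#' Accessors for ReferenceLibrary and TargetRanking
#'
#' \code{nLigands}/\code{nTargets} count the library tables;
#' \code{libLigands}, \code{libTargets}, \code{libInteractions},
#' \code{ligandIndex} and \code{curationLog} return the corresponding
#' slots; \code{rankingEntries} returns the entry table of a prediction
#' list.
#'
#' @param x A \code{\linkS4class{ReferenceLibrary}} (or
#'   \code{\linkS4class{TargetRanking}} for \code{rankingEntries}).
#' @return The slot value (data.frame, list, or integer count).
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nLigands", function(x) standardGeneric("nLigands"))
#' @rdname accessors
#' @export
setGeneric("nTargets", function(x) standardGeneric("nTargets"))
#' @rdname accessors
#' @export
setGeneric("libLigands", function(x) standardGeneric("libLigands"))
#' @rdname accessors
#' @export
setGeneric("libTargets", function(x) standardGeneric("libTargets"))
#' @rdname accessors
#' @export
setGeneric("libInteractions", function(x) standardGeneric("libInteractions"))
#' @rdname accessors
#' @export
setGeneric("ligandIndex", function(x) standardGeneric("ligandIndex"))
#' @rdname accessors
#' @export
setGeneric("curationLog", function(x) standardGeneric("curationLog"))
#' @rdname accessors
#' @export
setGeneric("rankingEntries", function(x) standardGeneric("rankingEntries"))

#' @rdname accessors
setMethod("nLigands", "ReferenceLibrary", function(x) nrow(x@ligands))
#' @rdname accessors
setMethod("nTargets", "ReferenceLibrary", function(x) nrow(x@targets))
#' @rdname accessors
setMethod("libLigands", "ReferenceLibrary", function(x) x@ligands)
#' @rdname accessors
setMethod("libTargets", "ReferenceLibrary", function(x) x@targets)
#' @rdname accessors
setMethod("libInteractions", "ReferenceLibrary", function(x) x@interactions)
#' @rdname accessors
setMethod("ligandIndex", "ReferenceLibrary", function(x) x@ligandIndex)
#' @rdname accessors
setMethod("curationLog", "ReferenceLibrary", function(x) x@curationLog)
#' @rdname accessors
setMethod("rankingEntries", "TargetRanking", function(x) x@entries)

#' @describeIn accessors compact display of a library
#' @param object object to display
#' @exportMethod show
setMethod("show", "ReferenceLibrary", function(object) {
  cat("ReferenceLibrary:", nrow(object@ligands), "ligands,",
      nrow(object@targets), "targets (",
      sum(object@targets$predictable), "predictable ),",
      nrow(object@interactions), "curated interactions\n")
  if (nrow(object@curationLog)) {
    tab <- table(object@curationLog$reason)
    cat("  discarded:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "TargetRanking", function(object) {
  cat("TargetRanking for query '", object@query_id, "' [", object@kind, "/",
      object@scheme, if (!is.na(object@k)) paste0("(k=", object@k, ")") else "",
      "]: ", nrow(object@entries), " targets\n", sep = "")
  if (nrow(object@entries)) {
    print(utils::head(object@entries, 5), row.names = FALSE)
    if (nrow(object@entries) > 5) cat("  ...\n")
  }
})
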