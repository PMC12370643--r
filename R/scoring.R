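# Target scoring: MaxTc / KNNTc / MeanTc over per-target similarity lists.

.SCHEMES <- c("MaxTc", "KNNTc", "MeanTc")

#' Library fingerprint cache
#'
#' Computes fingerprints for every library ligand, keyed by kind.  Pass the
#' result to the scoring and evaluation functions to avoid recomputation.
#'
#' @param lib A \code{\linkS4class{ReferenceLibrary}}.
#' @param kinds Fingerprint kinds (default all eight).
#' @return Named list of logical fingerprint matrices (rows = ligand ids).
#' @export
libraryFingerprints <- function(lib, kinds = fingerprintKinds()) {
  smiles <- setNames(lib@ligands$smiles, lib@ligands$ligand_id)
  computeFingerprints(smiles, kinds = kinds)
}

.queryFingerprint <- function(query, kind) {
  if (is.numeric(query) || is.logical(query)) {
    stop("pass query as a (named) SMILES string; precomputed fingerprints ",
         "go through the 'queryFp' argument")
  }
  id <- if (!is.null(names(query))) names(query)[1] else "query"
  fp <- computeFingerprints(setNames(unname(query[1]), id), kinds = kind)
  list(id = id, fp = fp[[kind]][1, ])
}

#' Per-target similarity profile
#'
#' Exact all-pairs Tanimoto similarities between one query molecule and
#' every reference ligand, grouped per target and sorted descending.
#' Targets with no ligands (after exclusions) are omitted.
#'
#' @param query A single SMILES string, optionally named with the query id.
#' @param lib A \code{\linkS4class{ReferenceLibrary}}.
#' @param kind Fingerprint kind.
#' @param fps Optional \code{\link{libraryFingerprints}} cache.
#' @param exclude Character vector of reference ligand ids to leave out
#'   (leave-one-out evaluation).
#' @param queryFp Optional precomputed query fingerprint (logical vector).
#' @return Named list: for each target, a named numeric vector of
#'   similarities to its ligands, sorted descending.
#' @export
similarityProfile <- function(query, lib, kind = "ECFP4", fps = NULL,
                              exclude = character(), queryFp = NULL) {
  kind <- match.arg(kind, .FP_KINDS)
  if (is.null(fps)) fps <- libraryFingerprints(lib, kind)
  if (is.null(queryFp)) queryFp <- .queryFingerprint(query, kind)$fp
  sims <- tanimotoMatrix(matrix(queryFp, nrow = 1), fps[[kind]])[1, ]
  names(sims) <- rownames(fps[[kind]])
  .profileFromSims(sims, lib@ligandIndex, exclude)
}

.profileFromSims <- function(sims, index, exclude = character()) {
  out <- list()
  for (t in names(index)) {
    ligs <- index[[t]]
    if (length(exclude)) ligs <- setdiff(ligs, exclude)
    if (length(ligs) == 0) next
    s <- sims[ligs]
    # deterministic: similarity descending, ligand id ascending on ties
    o <- order(-s, ligs)
    out[[t]] <- setNames(s[o], ligs[o])
  }
  out
}

#' Score one target from its sorted similarity list
#'
#' MaxTc is the top similarity; KNNTc the mean of the top
#' \code{min(k, length)} similarities (a target with fewer than k ligands
#' contributes all of them); MeanTc the mean over all ligands.
#'
#' @param sims Nonempty numeric vector of similarities, sorted descending.
#' @param scheme One of \code{"MaxTc"}, \code{"KNNTc"}, \code{"MeanTc"}.
#' @param k Neighbour count for KNNTc.
#' @return Numeric score.
#' @examples
#' scoreTarget(c(0.9, 0.5, 0.1), "KNNTc", k = 3)  # 0.5
#' @export
scoreTarget <- function(sims, scheme = c("MaxTc", "KNNTc", "MeanTc"), k = 3) {
  scheme <- match.arg(scheme)
  if (length(sims) == 0) stop("empty similarity list; target is unscored")
  switch(scheme,
         MaxTc = sims[[1]],
         KNNTc = mean(utils::head(sims, min(k, length(sims)))),
         MeanTc = mean(sims))
}

#' Rank scored targets into a prediction list
#'
#' Stable total order: score descending (or ascending for rank-sum
#' ensembles), ties broken by target id ascending; ordinal ranks 1..T.
#'
#' @param scores Named numeric vector of per-target scores.
#' @param best Optional data.frame with columns \code{target_id},
#'   \code{best_similarity}, \code{best_ligand_id} carried onto entries
#'   (NA when absent).
#' @param query_id,kind,scheme,k Metadata for the resulting
#'   \code{\linkS4class{TargetRanking}}.
#' @param decreasing Sort direction; TRUE ranks high scores first.
#' @return A \code{\linkS4class{TargetRanking}}.
#' @export
rankTargets <- function(scores, best = NULL, query_id = "query",
                        kind = NA_character_, scheme = "MaxTc",
                        k = NA_integer_, decreasing = TRUE) {
  if (length(scores) == 0) stop("no scored targets")
  ids <- names(scores)
  o <- if (decreasing) order(-scores, ids) else order(scores, ids)
  entries <- data.frame(rank = seq_along(o), target_id = ids[o],
                        score = unname(scores[o]),
                        best_similarity = NA_real_,
                        best_ligand_id = NA_character_,
                        stringsAsFactors = FALSE)
  if (!is.null(best)) {
    m <- match(entries$target_id, best$target_id)
    entries$best_similarity <- best$best_similarity[m]
    entries$best_ligand_id <- best$best_ligand_id[m]
  }
  new("TargetRanking", query_id = query_id, kind = kind, scheme = scheme,
      k = as.integer(k), entries = entries)
}

# Score every target from a precomputed similarity vector (named by ligand).
.rankFromSims <- function(sims, lib, scheme, k, query_id, kind,
                          exclude = character()) {
  prof <- .profileFromSims(sims, lib@ligandIndex, exclude)
  if (length(prof) == 0) return(NULL)
  scores <- vapply(prof, scoreTarget, numeric(1), scheme = scheme, k = k)
  best <- data.frame(
    target_id = names(prof),
    best_similarity = vapply(prof, `[[`, numeric(1), 1),
    best_ligand_id = vapply(prof, function(s) names(s)[1], ""),
    stringsAsFactors = FALSE)
  rankTargets(scores, best = best, query_id = query_id, kind = kind,
              scheme = scheme, k = if (scheme == "KNNTc") k else NA_integer_)
}

#' Predict targets for a query molecule
#'
#' Runs the full similarity search: fingerprints the query, computes its
#' Tanimoto similarity to every reference ligand, scores each target under
#' the chosen scheme and returns the ranked prediction list.  Every entry
#' carries \code{best_similarity} (top-1 Tc to that target) for
#' threshold-based confidence filtering regardless of scheme.
#'
#' @inheritParams similarityProfile
#' @param scheme Scoring scheme.
#' @param k Neighbour count (KNNTc).
#' @param query_id Query identifier (defaults to the name of \code{query}).
#' @return A \code{\linkS4class{TargetRanking}}.
#' @examples
#' rec <- data.frame(ligand_id = c("L1", "L2"),
#'                   smiles = c("Cc1ccccc1", "CCO"),
#'                   target_id = c("T1", "T2"), activity_type = "Ki",
#'                   value = c(10, 20), unit = "nM", source = "x")
#' lib <- buildLibrary(rec)
#' predictTargets("CCc1ccccc1", lib, kind = "MACCS")
#' @export
predictTargets <- function(query, lib, kind = "ECFP4",
                           scheme = c("MaxTc", "KNNTc", "MeanTc"), k = 3,
                           fps = NULL, exclude = character(),
                           queryFp = NULL, query_id = NULL) {
  scheme <- match.arg(scheme)
  kind <- match.arg(kind, .FP_KINDS)
  if (is.null(fps)) fps <- libraryFingerprints(lib, kind)
  if (is.null(queryFp)) {
    q <- .queryFingerprint(query, kind)
    queryFp <- q$fp
    if (is.null(query_id)) query_id <- q$id
  }
  if (is.null(query_id)) query_id <- "query"
  sims <- tanimotoMatrix(matrix(queryFp, nrow = 1), fps[[kind]])[1, ]
  names(sims) <- rownames(fps[[kind]])
  r <- .rankFromSims(sims, lib, scheme, k, query_id, kind, exclude)
  if (is.null(r)) stop("no predictable targets (empty library?)")
  r
}
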