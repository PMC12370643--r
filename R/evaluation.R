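# Scaffold-stratified validation sets, leave-one-out-like CV, and the
# micro-averaged RE_n / PR_n / F1 / enrichment metrics.

# run expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.newEvent <- function(query_id, known_targets, query_smiles = NA_character_) {
  structure(list(query_id = query_id,
                 known_targets = sort(unique(known_targets)),
                 query_smiles = query_smiles, ranking = NULL),
            class = "tfEvent")
}

#' Select a scaffold-stratified validation set
#'
#' Emulates a leave-one-out-like CV design: for every predictable target,
#' its ligands are grouped by Murcko scaffold (acyclic ligands share one
#' group); targets with fewer than 70 distinct scaffolds contribute
#' \code{ceiling(0.30 * n_scaffolds)} sampled scaffolds, targets with 70 or
#' more contribute 20, and one ligand is drawn per sampled scaffold.  A
#' ligand selected for several targets yields a single event carrying all
#' of its known targets.
#'
#' @param lib A \code{\linkS4class{ReferenceLibrary}}.
#' @param seed Integer seed; selection is fully reproducible.
#' @param scaffolds Optional named scaffold vector (by ligand id) to reuse
#'   a precomputed \code{\link{murckoScaffold}} result.
#' @return List of validation events (query id + known targets), ordered by
#'   query id.
#' @export
selectValidationSet <- function(lib, seed, scaffolds = NULL) {
  if (is.null(scaffolds)) {
    smiles <- setNames(lib@ligands$smiles, lib@ligands$ligand_id)
    scaffolds <- murckoScaffold(smiles)
  }
  keys <- scaffoldKey(scaffolds)
  chosen <- .withSeed(seed, {
    picked <- character(0)
    for (t in sort(names(lib@ligandIndex))) {
      ligs <- sort(lib@ligandIndex[[t]])
      groups <- split(ligs, keys[ligs])
      nsc <- length(groups)
      nsel <- if (nsc < 70) ceiling(0.30 * nsc) else 20L
      sel_sc <- sample(sort(names(groups)), nsel)
      for (sc in sel_sc) {
        g <- groups[[sc]]
        picked <- c(picked, if (length(g) == 1) g else sample(g, 1))
      }
    }
    unique(picked)
  })
  chosen <- sort(chosen)
  known <- split(lib@interactions$target_id, lib@interactions$ligand_id)
  lapply(chosen, function(q) .newEvent(q, known[[q]]))
}

#' Turn held-out query molecules into validation events
#'
#' @param queries data.frame with columns \code{query_id}, \code{smiles}
#'   and \code{known_targets} (pipe-joined string or list column), e.g.
#'   from \code{\link{generateQueries}}.
#' @return List of events for \code{\link{runLooCv}}.
#' @export
asEvents <- function(queries) {
  kt <- queries$known_targets
  lapply(seq_len(nrow(queries)), function(i) {
    known <- if (is.list(kt)) kt[[i]] else
      strsplit(as.character(kt[i]), "|", fixed = TRUE)[[1]]
    .newEvent(as.character(queries$query_id[i]), known,
              as.character(queries$smiles[i]))
  })
}

#' Run leave-one-out-like cross-validation
#'
#' For each event whose query is a library ligand, the query is removed
#' from every target's reference-ligand list before scoring (by identifier,
#' or additionally every ligand with an identical standardized structure
#' when \code{excludeBy = "structure"}); external queries (with their own
#' SMILES) are scored against the full library.  Targets left with zero
#' ligands are unpredictable for that event and absent from its prediction
#' list; an event whose every known target is unpredictable is retained and
#' contributes false negatives only.
#'
#' @param lib A \code{\linkS4class{ReferenceLibrary}}.
#' @param events List of events from \code{\link{selectValidationSet}} or
#'   \code{\link{asEvents}}.
#' @param kind Fingerprint kind, or several kinds when fusing.
#' @param scheme Scoring scheme for the members.
#' @param k KNNTc neighbour count.
#' @param fps Optional \code{\link{libraryFingerprints}} cache.
#' @param excludeBy \code{"id"} (default) or \code{"structure"}.
#' @param ensemble \code{"none"}, \code{"zscore"} or \code{"rank"}; with
#'   several kinds, member MaxTc/KNNTc rankings are fused per event.
#' @return The event list with a \code{ranking}
#'   (\code{\linkS4class{TargetRanking}}) attached to each event.
#' @export
runLooCv <- function(lib, events, kind = "ECFP4",
                     scheme = c("MaxTc", "KNNTc", "MeanTc"), k = 3,
                     fps = NULL, excludeBy = c("id", "structure"),
                     ensemble = c("none", "zscore", "rank")) {
  scheme <- match.arg(scheme)
  excludeBy <- match.arg(excludeBy)
  ensemble <- match.arg(ensemble)
  kinds <- match.arg(kind, .FP_KINDS, several.ok = TRUE)
  if (length(kinds) > 1 && ensemble == "none")
    stop("several kinds given; choose ensemble = 'zscore' or 'rank'")
  if (is.null(fps)) fps <- libraryFingerprints(lib, kinds)

  lig_ids <- lib@ligands$ligand_id
  smiles_by_id <- setNames(lib@ligands$smiles, lig_ids)
  ext <- vapply(events, function(e)
    !(e$query_id %in% lig_ids), logical(1))
  qfp <- list()
  for (kd in kinds) qfp[[kd]] <- matrix(FALSE, length(events),
                                        fingerprintLength(kd))
  if (any(!ext)) {
    for (kd in kinds) {
      rows <- match(vapply(events[!ext], `[[`, "", "query_id"), rownames(fps[[kd]]))
      qfp[[kd]][!ext, ] <- fps[[kd]][rows, , drop = FALSE]
    }
  }
  if (any(ext)) {
    ext_smiles <- vapply(events[ext], `[[`, "", "query_smiles")
    if (anyNA(ext_smiles)) stop("external query events need query_smiles")
    names(ext_smiles) <- vapply(events[ext], `[[`, "", "query_id")
    extfp <- computeFingerprints(ext_smiles, kinds = kinds)
    for (kd in kinds) qfp[[kd]][ext, ] <- extfp[[kd]]
  }

  simsAll <- list()
  for (kd in kinds) {
    m <- qfp[[kd]]
    attr(m, "kind") <- kd
    simsAll[[kd]] <- tanimotoMatrix(m, fps[[kd]])
  }

  for (i in seq_along(events)) {
    e <- events[[i]]
    exclude <- character(0)
    if (!ext[i]) {
      exclude <- e$query_id
      if (excludeBy == "structure") {
        qsmi <- smiles_by_id[[e$query_id]]
        exclude <- lig_ids[smiles_by_id == qsmi]
      }
    }
    members <- list()
    for (kd in kinds) {
      sims <- simsAll[[kd]][i, ]
      names(sims) <- lig_ids
      r <- .rankFromSims(sims, lib, scheme, k, e$query_id, kd, exclude)
      if (!is.null(r)) members[[kd]] <- r
    }
    events[[i]]$ranking <- if (length(kinds) == 1) {
      if (length(members)) members[[1]] else NULL
    } else if (length(members) < 2) {
      NULL
    } else if (ensemble == "zscore") fuseZscore(members) else fuseRank(members)
  }
  events
}

# Flatten events into one row per prediction entry; attribute n_known_total
# is the number of known (query, target) pairs across events.
.predictionTable <- function(events) {
  rows <- lapply(seq_along(events), function(i) {
    e <- events[[i]]
    if (is.null(e$ranking) || nrow(e$ranking@entries) == 0) return(NULL)
    en <- e$ranking@entries
    data.frame(event = i, rank = en$rank, target_id = en$target_id,
               best_similarity = en$best_similarity,
               known = en$target_id %in% e$known_targets,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(event = integer(0), rank = integer(0),
                                      target_id = character(0),
                                      best_similarity = numeric(0),
                                      known = logical(0))
  attr(tab, "n_known_total") <-
    sum(vapply(events, function(e) length(e$known_targets), integer(1)))
  tab
}

.metricsFromCounts <- function(TP, FP, FN) {
  recall <- if (TP + FN == 0) 0 else TP / (TP + FN)
  precision <- if (TP + FP == 0) 0 else TP / (TP + FP)
  f1 <- if (recall + precision == 0) 0 else
    2 * recall * precision / (recall + precision)
  list(recall = recall, precision = precision, f1 = f1)
}

#' Micro-averaged top-n metrics over validation events
#'
#' For each event the retained predictions are the top-\code{n} entries of
#' its ranking, optionally further filtered to
#' \code{best_similarity >= tau}.  True/false positives and false
#' negatives are pooled over all events before computing
#' \eqn{RE_n = TP/(TP+FN)}, \eqn{PR_n = TP/(TP+FP)} and
#' \eqn{F1 = 2 \cdot RE \cdot PR / (RE + PR)} (conventions: precision 0
#' with no retained predictions, F1 0 when both are 0).
#'
#' @param events Events with rankings (\code{\link{runLooCv}}).
#' @param n Integer rank cutoff(s), each >= 1.
#' @param tau Similarity threshold in [0, 1] (default 0 = no filter).
#' @return data.frame with one row per \code{n}: columns \code{n},
#'   \code{tau}, \code{TP}, \code{FP}, \code{FN}, \code{recall},
#'   \code{precision}, \code{f1}.
#' @export
computeMetrics <- function(events, n = 10, tau = 0) {
  if (any(n < 1)) stop("rank cutoff n must be >= 1")
  stopifnot(length(tau) == 1, tau >= 0)
  tab <- .predictionTable(events)
  total_known <- attr(tab, "n_known_total")
  out <- lapply(n, function(nn) {
    keep <- tab$rank <= nn & tab$best_similarity >= tau
    TP <- sum(keep & tab$known)
    FP <- sum(keep & !tab$known)
    FN <- total_known - TP
    m <- .metricsFromCounts(TP, FP, FN)
    data.frame(n = nn, tau = tau, TP = TP, FP = FP, FN = FN,
               recall = m$recall, precision = m$precision, f1 = m$f1)
  })
  do.call(rbind, out)
}

#' Enrichment fold over random target picking
#'
#' A recall of \code{re_n} among the top n of T targets corresponds to a
#' \code{re_n / (n / T)} fold enrichment relative to picking n targets at
#' random.
#'
#' @param re_n Recall at rank n, in [0, 1].
#' @param n Rank cutoff.
#' @param n_targets Number of targets T in the library.
#' @return Numeric fold enrichment.
#' @examples
#' enrichmentFold(0.5982, 1, 1460)   # ~873
#' @export
enrichmentFold <- function(re_n, n, n_targets) {
  stopifnot(re_n >= 0, re_n <= 1, n >= 1, n <= n_targets)
  re_n / (n / n_targets)
}

#' Stratified metrics
#'
#' Splits the evaluation by a confidence-relevant factor:
#' \describe{
#'   \item{promiscuity}{events grouped by their number of known targets.}
#'   \item{target_ligands}{cumulative baskets of targets with at least
#'     \code{breaks[i]} reference ligands; metrics are restricted to known
#'     pairs (and retained predictions) whose target falls in the basket.}
#'   \item{target_class}{per-class restriction using the library's target
#'     class annotations.}
#' }
#' Per-target strata restrict TP/FN to known pairs in the stratum, so
#' class-stratum recalls recombine to the global recall as a weighted mean.
#'
#' @param events Events with rankings.
#' @param by Stratification key.
#' @param lib Library (needed for the per-target strata).
#' @param n Rank cutoff.
#' @param tau Similarity threshold.
#' @param breaks Increasing ligand-count thresholds for
#'   \code{"target_ligands"}.
#' @return data.frame with one row per stratum (columns as
#'   \code{\link{computeMetrics}} plus \code{stratum} and \code{n_events}).
#' @export
stratifyMetrics <- function(events, by = c("promiscuity", "target_ligands",
                                           "target_class"),
                            lib = NULL, n = 10, tau = 0,
                            breaks = c(1, 5, 10, 20, 50, 100)) {
  by <- match.arg(by)
  if (by == "promiscuity") {
    sizes <- vapply(events, function(e) length(e$known_targets), integer(1))
    out <- lapply(sort(unique(sizes)), function(s) {
      m <- computeMetrics(events[sizes == s], n = n, tau = tau)
      cbind(stratum = as.character(s), n_events = sum(sizes == s), m)
    })
    return(do.call(rbind, out))
  }
  if (is.null(lib)) stop("per-target strata need the library")
  tab <- .predictionTable(events)
  strata <- if (by == "target_ligands") {
    counts <- lengths(lib@ligandIndex)
    lapply(breaks, function(b) list(
      label = paste0(">=", b), targets = names(counts)[counts >= b]))
  } else {
    tg <- lib@targets
    cls <- sort(unique(tg$target_class[!is.na(tg$target_class)]))
    lapply(cls, function(cl) list(
      label = cl, targets = tg$target_id[!is.na(tg$target_class) &
                                           tg$target_class == cl]))
  }
  out <- lapply(strata, function(s) {
    known_in <- sum(vapply(events, function(e)
      sum(e$known_targets %in% s$targets), integer(1)))
    keep <- tab$rank <= n & tab$best_similarity >= tau &
      tab$target_id %in% s$targets
    TP <- sum(keep & tab$known)
    FP <- sum(keep & !tab$known)
    FN <- known_in - TP
    m <- .metricsFromCounts(TP, FP, FN)
    data.frame(stratum = s$label, n_events = length(events), n = n, tau = tau,
               TP = TP, FP = FP, FN = FN, recall = m$recall,
               precision = m$precision, f1 = m$f1)
  })
  do.call(rbind, out)
}
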