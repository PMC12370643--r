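# Fingerprint ensembles: z-score sum (similarity ensemble) and rank sum
# (rank-order ensemble) over any multi-fingerprint combination.

#' Z-score standardization of per-target scores
#'
#' \eqn{z = (x - \mu) / \sigma} with \eqn{\mu} the mean and \eqn{\sigma}
#' the population standard deviation over all scored targets, so scores
#' from fingerprints with different similarity ranges become commensurate.
#' Constant scores (\eqn{\sigma = 0}) standardize to all zeros.
#'
#' @param x Named numeric vector of scores for at least two targets.
#' @return Numeric vector of z-scores with attributes \code{mu} and
#'   \code{sigma}.
#' @examples
#' zscoreStandardize(c(a = 1, b = 2, c = 3))
#' @export
zscoreStandardize <- function(x) {
  if (length(x) < 2) stop("need at least two scored targets")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  z <- if (sigma == 0) rep(0, length(x)) else (x - mu) / sigma
  names(z) <- names(x)
  attr(z, "mu") <- mu
  attr(z, "sigma") <- sigma
  z
}

.checkMembers <- function(rankings) {
  if (length(rankings) < 2) stop("an ensemble needs at least two members")
  qids <- unique(vapply(rankings, function(r) r@query_id, ""))
  if (length(qids) != 1) stop("members score different queries")
  tsets <- lapply(rankings, function(r) sort(r@entries$target_id))
  for (i in seq_along(tsets)[-1]) {
    if (!identical(tsets[[1]], tsets[[i]]))
      stop("members score different target sets; fusion requires targets ",
           "scored by all members")
  }
  qids
}

.memberBest <- function(rankings, targets) {
  bs <- sapply(rankings, function(r) {
    e <- r@entries
    e$best_similarity[match(targets, e$target_id)]
  })
  bl <- sapply(rankings, function(r) {
    e <- r@entries
    e$best_ligand_id[match(targets, e$target_id)]
  })
  bs <- matrix(bs, nrow = length(targets))
  bl <- matrix(bl, nrow = length(targets))
  pick <- max.col(replace(bs, is.na(bs), -1), ties.method = "first")
  data.frame(target_id = targets,
             best_similarity = bs[cbind(seq_along(targets), pick)],
             best_ligand_id = bl[cbind(seq_along(targets), pick)],
             stringsAsFactors = FALSE)
}

#' Similarity (z-score sum) ensemble
#'
#' Standardizes each member fingerprint's per-target scores to z-scores and
#' sums them; the fused list is ranked by the summed z-score, descending.
#' Invariant to affine rescaling of any member's raw scores.
#'
#' @param rankings List of \code{\linkS4class{TargetRanking}} objects (>= 2
#'   members, same query, same target set).
#' @return A fused \code{\linkS4class{TargetRanking}} with scheme
#'   \code{"zscore_sum"}; \code{best_similarity} is the maximum over
#'   members (per target).
#' @export
fuseZscore <- function(rankings) {
  qid <- .checkMembers(rankings)
  targets <- sort(rankings[[1]]@entries$target_id)
  zsum <- numeric(length(targets))
  for (r in rankings) {
    e <- r@entries
    z <- zscoreStandardize(setNames(e$score, e$target_id))
    zsum <- zsum + unname(z[targets])
  }
  kinds <- paste(sort(vapply(rankings, function(r) r@kind, "")), collapse = "+")
  rankTargets(setNames(zsum, targets), best = .memberBest(rankings, targets),
              query_id = qid, kind = kinds, scheme = "zscore_sum")
}

#' Rank-order (rank sum) ensemble
#'
#' Sums each target's ordinal rank across members; smaller rank sums are
#' better, so the fused list is ranked ascending (ties by target id).
#'
#' @inheritParams fuseZscore
#' @return A fused \code{\linkS4class{TargetRanking}} with scheme
#'   \code{"rank_sum"} (score = rank sum).
#' @export
fuseRank <- function(rankings) {
  qid <- .checkMembers(rankings)
  targets <- sort(rankings[[1]]@entries$target_id)
  rsum <- numeric(length(targets))
  for (r in rankings) {
    e <- r@entries
    rsum <- rsum + e$rank[match(targets, e$target_id)]
  }
  kinds <- paste(sort(vapply(rankings, function(r) r@kind, "")), collapse = "+")
  rankTargets(setNames(rsum, targets), best = .memberBest(rankings, targets),
              query_id = qid, kind = kinds, scheme = "rank_sum",
              decreasing = FALSE)
}

#' Enumerate multi-fingerprint combinations
#'
#' All subsets of size >= 2 of the given fingerprint kinds, in
#' deterministic order (by size, then lexicographic).  Eight kinds yield
#' 2^8 - 8 - 1 = 247 combinations.
#'
#' @param kinds Character vector of distinct fingerprint kinds.
#' @return List of character vectors.
#' @examples
#' length(enumerateCombinations(fingerprintKinds()))  # 247
#' @export
enumerateCombinations <- function(kinds = fingerprintKinds()) {
  if (anyDuplicated(kinds)) stop("kinds must be distinct")
  kinds <- sort(kinds)
  out <- list()
  for (m in 2:length(kinds)) {
    cm <- utils::combn(kinds, m, simplify = FALSE)
    out <- c(out, cm)
  }
  out
}
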