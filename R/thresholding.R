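# Similarity-threshold confidence machinery: filtering, sweeps, binned
# precision profiles, true-positive onset and the improved enrichment rate.
#
# Thresholds always act on best_similarity (the top-1 Tc between the query
# and the target's nearest reference ligand): a target whose nearest ligand
# is below the threshold cannot be considered a potential hit regardless of
# its rank.  Ranks are not renumbered after filtering, so "top-10" always
# means the top 10 of the unfiltered ranking.

#' Filter a prediction list by similarity threshold
#'
#' Removes entries whose \code{best_similarity} is below \code{tau};
#' surviving entries keep their pre-filter ranks.
#'
#' @param ranking A \code{\linkS4class{TargetRanking}}.
#' @param tau Threshold in [0, 1] (values above 1 empty the list).
#' @return The filtered \code{\linkS4class{TargetRanking}}.
#' @export
applyThreshold <- function(ranking, tau) {
  stopifnot(is(ranking, "TargetRanking"), tau >= 0)
  e <- ranking@entries
  keep <- !is.na(e$best_similarity) & e$best_similarity >= tau
  ranking@entries <- e[keep, , drop = FALSE]
  rownames(ranking@entries) <- NULL
  ranking
}

#' Binned precision profile
#'
#' Assigns every retained top-\code{n} prediction to one of ten equal-width
#' Tc bins on [0, 1] by its \code{best_similarity} (half-open bins, the
#' last closed) and reports the per-bin prediction count (background
#' targets) and precision (known-target fraction).  Bin counts sum to the
#' total number of retained predictions.
#'
#' @param events Events with rankings (\code{\link{runLooCv}}).
#' @param n Rank cutoff (default 10).
#' @return data.frame with columns \code{bin_lo}, \code{bin_hi},
#'   \code{count}, \code{n_tp}, \code{precision} (NA for empty bins).
#' @export
binPrecisionProfile <- function(events, n = 10) {
  tab <- .predictionTable(events)
  tab <- tab[tab$rank <= n, , drop = FALSE]
  bin <- pmin(floor(tab$best_similarity * 10) + 1L, 10L)
  count <- tabulate(bin, nbins = 10L)
  n_tp <- tabulate(bin[tab$known], nbins = 10L)
  data.frame(bin_lo = seq(0, 0.9, by = 0.1), bin_hi = seq(0.1, 1, by = 0.1),
             count = count, n_tp = n_tp,
             precision = ifelse(count == 0, NA_real_, n_tp / count))
}

#' True-positive onset threshold
#'
#' Scans the binned precision profile upward and returns the lower edge of
#' the first bin whose precision exceeds \code{floor} (default 0: the
#' first bin containing any true positive).  Below this similarity the
#' probability that a predicted target is real is essentially zero.
#'
#' @param bins data.frame from \code{\link{binPrecisionProfile}}.
#' @param floor Precision floor in [0, 1).
#' @return Numeric threshold (a bin lower edge).
#' @export
detectTpOnset <- function(bins, floor = 0) {
  hit <- which(!is.na(bins$precision) & bins$precision > floor)
  if (length(hit) == 0) stop("no true positives in any similarity bin")
  bins$bin_lo[hit[1]]
}

#' Improved enrichment rate
#'
#' Fold reduction in the number of targets that must be picked to recover
#' the same number of true positives when the threshold \code{tau} is
#' applied, relative to no threshold.  Picks-per-true-positive is the
#' inverse precision, so the rate is \eqn{PR_n(\tau) / PR_n(0)}.
#'
#' @param events Events with rankings.
#' @param n Rank cutoff.
#' @param tau Similarity threshold.
#' @return Numeric rate (1 at \code{tau = 0}).
#' @export
improvedEnrichmentRate <- function(events, n = 10, tau = 0) {
  p0 <- computeMetrics(events, n = n, tau = 0)$precision
  if (p0 == 0) stop("precision without threshold is 0; rate undefined")
  computeMetrics(events, n = n, tau = tau)$precision / p0
}

#' Similarity-threshold sweep
#'
#' Computes the top-\code{n} metrics at every threshold on the grid
#' \code{seq(0, 1, by = step)}, together with the improved enrichment rate,
#' the F1-optimal threshold (smallest grid point attaining the maximum F1),
#' and the true-positive onset threshold from the 10-bin precision
#' profile.  The grid rows double as the precision-recall curve.
#'
#' @param events Events with rankings.
#' @param n Rank cutoff (default 10).
#' @param step Grid step (default 0.01).
#' @return An object of class \code{"tfSweep"}: list with \code{grid}
#'   (data.frame tau/TP/FP/FN/recall/precision/f1/er), \code{tau_f1},
#'   \code{max_f1}, \code{tau_tp} (NA when no bin holds a true positive),
#'   \code{bins}, \code{n}, \code{step}.
#' @export
thresholdSweep <- function(events, n = 10, step = 0.01) {
  stopifnot(step > 0, step <= 1)
  tab <- .predictionTable(events)
  total_known <- attr(tab, "n_known_total")
  tab <- tab[tab$rank <= n, , drop = FALSE]
  taus <- seq(0, 1, by = step)
  grid <- lapply(taus, function(tau) {
    keep <- tab$best_similarity >= tau
    TP <- sum(keep & tab$known)
    FP <- sum(keep & !tab$known)
    FN <- total_known - TP
    m <- .metricsFromCounts(TP, FP, FN)
    data.frame(tau = tau, TP = TP, FP = FP, FN = FN, retained = TP + FP,
               recall = m$recall, precision = m$precision, f1 = m$f1)
  })
  grid <- do.call(rbind, grid)
  p0 <- grid$precision[1]
  grid$er <- if (p0 > 0) grid$precision / p0 else NA_real_
  best <- which(grid$f1 == max(grid$f1))[1]
  bins <- binPrecisionProfile(events, n = n)
  tau_tp <- tryCatch(detectTpOnset(bins), error = function(e) NA_real_)
  structure(list(grid = grid, tau_f1 = grid$tau[best],
                 max_f1 = grid$f1[best], tau_tp = tau_tp, bins = bins,
                 n = n, step = step),
            class = "tfSweep")
}

#' @export
print.tfSweep <- function(x, ...) {
  cat("Similarity-threshold sweep (top-", x$n, ", step ", x$step, ")\n",
      sep = "")
  cat("  max F1 ", round(x$max_f1, 3), " at tau = ", x$tau_f1,
      "; TP-onset tau = ", x$tau_tp, "\n", sep = "")
  invisible(x)
}
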