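# Similarity-threshold machinery: filtering, sweeps, binned precision,
# true-positive onset, improved enrichment rate.

test_that("threshold filtering preserves surviving ranks", {
  r <- rankTargets(c(A = 0.9, B = 0.45, C = 0.2), query_id = "q")
  e <- rankingEntries(r)
  e$best_similarity <- c(0.9, 0.45, 0.2)
  r@entries <- e
  expect_identical(rankingEntries(applyThreshold(r, 0)), rankingEntries(r))
  filtered <- rankingEntries(applyThreshold(r, 0.5))
  expect_equal(filtered$target_id, "A")
  expect_equal(filtered$rank, 1L)      # ranks not renumbered
  expect_equal(nrow(rankingEntries(applyThreshold(r, 1.01))), 0L)
  mid <- rankingEntries(applyThreshold(r, 0.3))
  expect_equal(mid$rank, c(1L, 2L))
})

test_that("the sweep at tau = 0 reproduces computeMetrics exactly", {
  ev <- tf_events()
  sw <- thresholdSweep(ev, n = 10, step = 0.01)
  m <- computeMetrics(ev, n = 10, tau = 0)
  row0 <- sw$grid[sw$grid$tau == 0, ]
  expect_equal(row0$TP, m$TP)
  expect_equal(row0$FP, m$FP)
  expect_equal(row0$recall, m$recall)
  expect_equal(row0$precision, m$precision)
  expect_equal(row0$f1, m$f1)
  expect_equal(row0$er, 1)            # ER(0) = 1 identically
  expect_equal(nrow(sw$grid), 101L)
})

test_that("recall and retained counts are non-increasing across the grid", {
  ev <- tf_events()
  sw <- thresholdSweep(ev, n = 10, step = 0.01)
  expect_true(all(diff(sw$grid$recall) <= 1e-12))
  expect_true(all(diff(sw$grid$retained) <= 0))
  expect_true(all(sw$grid$er >= 0))
  # tau_f1 is the smallest grid point attaining the max F1
  best <- max(sw$grid$f1)
  expect_equal(sw$tau_f1, min(sw$grid$tau[sw$grid$f1 == best]))
})

test_that("events with perfect-similarity hits keep F1 constant to tau = 1", {
  ev <- list(
    tf_fake_event("q1", known = "A", scores = c(A = 1, B = 1),
                  best_sims = c(A = 1, B = 1)),
    tf_fake_event("q2", known = "B", scores = c(A = 1, B = 1),
                  best_sims = c(A = 1, B = 1)))
  sw <- thresholdSweep(ev, n = 2, step = 0.1)
  expect_equal(length(unique(sw$grid$f1)), 1L)
})

test_that("binned precision assigns half-open bins with a closed top bin", {
  ev <- list(
    tf_fake_event("q", known = "TP1",
                  scores = c(TP1 = 0.95, FP1 = 0.05),
                  best_sims = c(TP1 = 0.95, FP1 = 0.05)))
  bins <- binPrecisionProfile(ev, n = 10)
  expect_equal(nrow(bins), 10L)
  expect_equal(bins$count[1], 1L)
  expect_equal(bins$count[10], 1L)
  expect_equal(bins$precision[1], 0)
  expect_equal(bins$precision[10], 1)
  expect_equal(sum(bins$count), 2L)   # counts partition retained predictions
  # boundary values: 1.0 falls in the last (closed) bin, 0.1 in bin 2
  ev2 <- list(tf_fake_event("q", known = "A",
                            scores = c(A = 1, B = 0.1),
                            best_sims = c(A = 1, B = 0.1)))
  b2 <- binPrecisionProfile(ev2, n = 10)
  expect_equal(b2$count[10], 1L)
  expect_equal(b2$count[2], 1L)
})

test_that("bin counts always sum to the retained prediction total", {
  ev <- tf_events()
  bins <- binPrecisionProfile(ev, n = 10)
  tab_retained <- computeMetrics(ev, n = 10)
  expect_equal(sum(bins$count), tab_retained$TP + tab_retained$FP)
})

test_that("the TP onset is the first bin holding a true positive", {
  # true positives only above 0.4
  ev <- list(
    tf_fake_event("q1", known = "A",
                  scores = c(A = 0.45, B = 0.30, C = 0.10),
                  best_sims = c(A = 0.45, B = 0.30, C = 0.10)),
    tf_fake_event("q2", known = "D",
                  scores = c(D = 0.85, E = 0.25, F = 0.05),
                  best_sims = c(D = 0.85, E = 0.25, F = 0.05)))
  bins <- binPrecisionProfile(ev, n = 10)
  expect_equal(detectTpOnset(bins), 0.4)
  # a precision floor skips low-precision bins: dilute the 0.4 bin with
  # three false positives (precision 0.25) and require more than 0.3
  ev3 <- c(ev, list(tf_fake_event(
    "q3", known = "G",
    scores = c(G = 0.95, H = 0.42, I = 0.44, J = 0.47),
    best_sims = c(G = 0.95, H = 0.42, I = 0.44, J = 0.47))))
  bins3 <- binPrecisionProfile(ev3, n = 10)
  expect_equal(bins3$precision[5], 0.25)
  expect_equal(detectTpOnset(bins3, floor = 0.3), 0.8)
  # all-FP profile has no onset
  evfp <- list(tf_fake_event("q", known = "ZZZ",
                             scores = c(A = 0.9, B = 0.1),
                             best_sims = c(A = 0.9, B = 0.1)))
  expect_error(detectTpOnset(binPrecisionProfile(evfp)), "no true positives")
})

test_that("TPs in every bin give onset 0", {
  mk <- function(i, sim) tf_fake_event(
    paste0("q", i), known = "A",
    scores = c(A = sim, B = sim / 2 + 1e-3),
    best_sims = c(A = sim, B = sim / 2 + 1e-3))
  ev <- lapply(1:10, function(i) mk(i, i / 10 - 0.05))
  expect_equal(detectTpOnset(binPrecisionProfile(ev)), 0)
})

test_that("improved enrichment rate is a matched-recall precision ratio", {
  # 2 TPs at high similarity, 2 FPs at low: a threshold in between removes
  # all FPs and no TPs, halving the picks needed per true positive
  ev <- list(
    tf_fake_event("q1", known = "A",
                  scores = c(A = 0.9, B = 0.2),
                  best_sims = c(A = 0.9, B = 0.2)),
    tf_fake_event("q2", known = "C",
                  scores = c(C = 0.85, D = 0.25),
                  best_sims = c(C = 0.85, D = 0.25)))
  expect_equal(improvedEnrichmentRate(ev, n = 2, tau = 0), 1)
  expect_equal(improvedEnrichmentRate(ev, n = 2, tau = 0.5), 2)
  evfp <- list(tf_fake_event("q", known = "ZZZ",
                             scores = c(A = 0.9), best_sims = c(A = 0.9)))
  expect_error(improvedEnrichmentRate(evfp, n = 1, tau = 0.5), "undefined")
})
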