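# Ensemble fusion: z-score standardization, z-score-sum and rank-sum
# fusion, combination enumeration.

test_that("z-score standardization uses the population SD", {
  z <- zscoreStandardize(c(a = 1, b = 2, c = 3))
  expect_equal(as.numeric(z), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(attr(z, "sigma"), sqrt(2 / 3))
  expect_equal(sum(z), 0, tolerance = 1e-9)
  expect_equal(as.numeric(zscoreStandardize(c(a = 2, b = 2, c = 2))),
               c(0, 0, 0))
  set.seed(9)
  x <- runif(17)
  names(x) <- paste0("t", 1:17)
  z2 <- zscoreStandardize(x)
  expect_equal(sum(z2), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z2^2)), 1, tolerance = 1e-9)
  expect_error(zscoreStandardize(c(a = 1)), "two")
})

mk_rank <- function(scores, qid = "Q", kind = "ECFP4") {
  rankTargets(scores, query_id = qid, kind = kind, scheme = "MaxTc")
}

test_that("z-score fusion of identical members preserves the ranking", {
  a <- mk_rank(c(T1 = 0.9, T2 = 0.5, T3 = 0.2), kind = "ECFP4")
  b <- mk_rank(c(T1 = 0.9, T2 = 0.5, T3 = 0.2), kind = "MACCS")
  fused <- fuseZscore(list(a, b))
  expect_equal(rankingEntries(fused)$target_id, c("T1", "T2", "T3"))
  expect_equal(fused@scheme, "zscore_sum")
})

test_that("z-score fusion lets the stronger margin win on opposite rankings", {
  # member 1 separates A from B by a wide margin relative to its spread;
  # member 2 prefers B over A only narrowly (its spread sits in C and D).
  # Hand calculation: summed z-scores are A +1.36, B -1.40, C +1.40, D -1.36,
  # so A stays ahead of B in the fusion.
  a <- mk_rank(c(A = 0.9, B = 0.1, C = 0.50, D = 0.52), kind = "ECFP4")
  b <- mk_rank(c(A = 0.49, B = 0.51, C = 0.9, D = 0.1), kind = "MACCS")
  fused <- fuseZscore(list(a, b))
  e <- rankingEntries(fused)
  expect_lt(which(e$target_id == "A"), which(e$target_id == "B"))
  expect_equal(e$score[e$target_id == "A"], 1.3605, tolerance = 1e-3)
})

test_that("z-score fusion is invariant to affine rescaling of a member", {
  set.seed(31)
  x <- setNames(runif(9), paste0("T", 1:9))
  y <- setNames(runif(9), paste0("T", 1:9))
  f1 <- fuseZscore(list(mk_rank(x, kind = "ECFP4"),
                        mk_rank(y, kind = "MACCS")))
  f2 <- fuseZscore(list(mk_rank(3.7 * x + 0.2, kind = "ECFP4"),
                        mk_rank(y, kind = "MACCS")))
  expect_equal(rankingEntries(f1)$target_id, rankingEntries(f2)$target_id)
  expect_equal(rankingEntries(f1)$score, rankingEntries(f2)$score,
               tolerance = 1e-9)
})

test_that("both fusions are invariant to member order", {
  set.seed(12)
  x <- setNames(runif(7), paste0("T", 1:7))
  y <- setNames(runif(7), paste0("T", 1:7))
  z <- setNames(runif(7), paste0("T", 1:7))
  members <- list(mk_rank(x, kind = "ECFP4"), mk_rank(y, kind = "MACCS"),
                  mk_rank(z, kind = "Torsion"))
  for (fuse in list(fuseZscore, fuseRank)) {
    f1 <- fuse(members)
    f2 <- fuse(rev(members))
    expect_identical(rankingEntries(f1)$target_id,
                     rankingEntries(f2)$target_id)
    # scores agree up to float summation order
    expect_equal(rankingEntries(f1)$score, rankingEntries(f2)$score)
  }
})

test_that("rank-sum fusion ranks ascending with id tie-breaks", {
  a <- mk_rank(c(T1 = 0.9, T2 = 0.8, T3 = 0.7, T4 = 0.6), kind = "ECFP4")
  b <- mk_rank(c(T4 = 0.9, T3 = 0.2, T1 = 0.4, T2 = 0.3), kind = "MACCS")
  # member ranks: a = (T1:1 T2:2 T3:3 T4:4), b = (T4:1 T1:2 T2:3 T3:4)
  fused <- fuseRank(list(a, b))
  e <- rankingEntries(fused)
  expect_equal(e$score[e$target_id == "T1"], 3)
  # T2 and T4 both sum to 5: tie broken by target id
  expect_equal(e$target_id, c("T1", "T2", "T4", "T3"))
  # a target ranked 1 by all members is fused rank 1
  top <- fuseRank(list(mk_rank(c(X = 0.9, Y = 0.1), kind = "ECFP4"),
                       mk_rank(c(X = 0.8, Y = 0.7), kind = "MACCS")))
  expect_equal(rankingEntries(top)$target_id[1], "X")
})

test_that("rank sums total m*T(T+1)/2 and single members are rejected", {
  set.seed(8)
  members <- lapply(c("ECFP4", "MACCS", "Torsion"), function(k)
    mk_rank(setNames(runif(11), paste0("T", 1:11)), kind = k))
  fused <- fuseRank(members)
  expect_equal(sum(rankingEntries(fused)$score), 3 * 11 * 12 / 2)
  expect_error(fuseRank(members[1]), "two members")
  expect_error(fuseZscore(members[1]), "two members")
})

test_that("fusion rejects mismatched target sets", {
  a <- mk_rank(c(T1 = 0.9, T2 = 0.5), kind = "ECFP4")
  b <- mk_rank(c(T1 = 0.8, T3 = 0.4), kind = "MACCS")
  expect_error(fuseZscore(list(a, b)), "target sets")
})

test_that("combination enumeration matches 2^n - n - 1", {
  all8 <- enumerateCombinations(fingerprintKinds())
  expect_length(all8, 247L)
  expect_true(all(lengths(all8) >= 2))
  expect_false(anyDuplicated(vapply(all8, paste, "", collapse = "+")) > 0)
  expect_length(enumerateCombinations(c("A", "B")), 1L)
  expect_length(enumerateCombinations(c("A", "B", "C")), 4L)
  expect_error(enumerateCombinations(c("A", "A", "B")), "distinct")
})
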