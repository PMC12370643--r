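# Evaluation: scaffold-stratified sampling, leave-one-out exclusion
# semantics, micro-averaged metrics, enrichment folds, stratification.

test_that("validation sampling follows the 30% / 20-scaffold rule", {
  # 70-scaffold target -> 20 ligands; 10 -> ceil(3) = 3; 1 -> 1
  lt <- c(setNames(rep(list("Tbig"), 70), sprintf("B%03d", 1:70)),
          setNames(rep(list("Tmid"), 10), sprintf("M%03d", 1:10)),
          list(S001 = "Tsmall"))
  lib <- tf_bare_library(lt)
  ligs <- libLigands(lib)$ligand_id
  scaffolds <- setNames(paste0("scaf_", ligs), ligs)  # all distinct
  ev <- selectValidationSet(lib, seed = 5, scaffolds = scaffolds)
  qids <- vapply(ev, `[[`, "", "query_id")
  expect_equal(sum(startsWith(qids, "B")), 20L)
  expect_equal(sum(startsWith(qids, "M")), 3L)
  expect_equal(sum(startsWith(qids, "S")), 1L)
  # reproducible under the same seed, and one event per ligand
  ev2 <- selectValidationSet(lib, seed = 5, scaffolds = scaffolds)
  expect_identical(ev, ev2)
  expect_false(anyDuplicated(qids) > 0)
})

test_that("ligands sharing a scaffold are sampled once per scaffold", {
  lt <- setNames(rep(list("T1"), 12), sprintf("L%02d", 1:12))
  lib <- tf_bare_library(lt)
  ligs <- libLigands(lib)$ligand_id
  # 4 scaffolds x 3 ligands -> ceil(0.3 * 4) = 2 scaffolds, 1 ligand each
  scaffolds <- setNames(rep(paste0("s", 1:4), each = 3), ligs)
  ev <- selectValidationSet(lib, seed = 2, scaffolds = scaffolds)
  qids <- vapply(ev, `[[`, "", "query_id")
  expect_length(qids, 2L)
  expect_equal(length(unique(scaffolds[qids])), 2L)
})

test_that("a ligand selected for several targets yields one multi-target event", {
  lt <- list(L1 = c("T1", "T2"), L2 = "T1", L3 = "T2")
  lib <- tf_bare_library(lt)
  scaffolds <- setNames(paste0("s", 1:3), c("L1", "L2", "L3"))
  ev <- selectValidationSet(lib, seed = 1, scaffolds = scaffolds)
  qids <- vapply(ev, `[[`, "", "query_id")
  expect_false(anyDuplicated(qids) > 0)
  if ("L1" %in% qids) {
    e <- ev[[which(qids == "L1")]]
    expect_setequal(e$known_targets, c("T1", "T2"))
  }
})

test_that("LOO excludes the query; sole-ligand targets become unpredictable", {
  rec <- data.frame(
    ligand_id = c("L1", "L2", "L3"),
    smiles = c("Cc1ccccc1", "CCc1ccccc1", "CCCO"),
    target_id = c("Tsolo", "Tother", "Tother"),
    activity_type = "Ki", value = 10, unit = "nM", source = "x",
    stringsAsFactors = FALSE)
  lib <- buildLibrary(rec)
  ev <- list(structure(list(query_id = "L1", known_targets = "Tsolo",
                            query_smiles = NA_character_, ranking = NULL),
                       class = "tfEvent"))
  ev <- runLooCv(lib, ev, kind = "MACCS")
  e <- rankingEntries(ev[[1]]$ranking)
  expect_false("Tsolo" %in% e$target_id)   # its only ligand was the query
  expect_true("Tother" %in% e$target_id)
  # the event still counts its known target as a false negative
  m <- computeMetrics(ev, n = 10)
  expect_equal(m$FN, 1L)
  expect_equal(m$TP, 0L)
})

test_that("structural twins are kept under id-exclusion, removed under structure-exclusion", {
  rec <- data.frame(
    ligand_id = c("L1", "Ltwin", "L3"),
    smiles = c("Cc1ccccc1", "Cc1ccccc1", "CCCCO"),
    target_id = c("T1", "T1", "T2"),
    activity_type = "Ki", value = 10, unit = "nM", source = "x",
    stringsAsFactors = FALSE)
  lib <- buildLibrary(rec)
  ev0 <- list(structure(list(query_id = "L1", known_targets = "T1",
                             query_smiles = NA_character_, ranking = NULL),
                        class = "tfEvent"))
  by_id <- runLooCv(lib, ev0, kind = "ECFP4", excludeBy = "id")
  e <- rankingEntries(by_id[[1]]$ranking)
  expect_equal(e$best_similarity[e$target_id == "T1"], 1)  # twin remains
  expect_equal(e$best_ligand_id[e$target_id == "T1"], "Ltwin")
  by_struct <- runLooCv(lib, ev0, kind = "ECFP4", excludeBy = "structure")
  e2 <- rankingEntries(by_struct[[1]]$ranking)
  expect_false("T1" %in% e2$target_id)      # twin removed too
})

test_that("micro-averaged metrics match the worked two-event count", {
  # event A: 1 known target at rank 1 (10 targets ranked)
  # event B: 2 known targets at ranks 3 and 12 (12 targets ranked)
  sA <- setNames(seq(0.95, 0.05, length.out = 10), sprintf("A%02d", 1:10))
  evA <- tf_fake_event("qA", known = "A01", scores = sA)
  sB <- setNames(seq(0.95, 0.05, length.out = 12), sprintf("B%02d", 1:12))
  evB <- tf_fake_event("qB", known = c("B03", "B12"), scores = sB)
  m <- computeMetrics(list(evA, evB), n = 10)
  expect_equal(m$TP, 2L)
  expect_equal(m$FP, 18L)
  expect_equal(m$FN, 1L)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$precision, 0.1)
  m1 <- computeMetrics(list(evA), n = 1)
  expect_equal(unlist(m1[c("recall", "precision", "f1")]),
               c(recall = 1, precision = 1, f1 = 1))
  expect_error(computeMetrics(list(evA), n = 0), ">= 1")
})

test_that("recall is non-decreasing in n and micro totals are conserved", {
  ev <- tf_events()
  total_known <- sum(vapply(ev, function(e) length(e$known_targets),
                            integer(1)))
  for (tau in c(0, 0.3, 0.6)) {
    prev <- -1
    for (n in c(1, 2, 3, 5, 10, 20)) {
      m <- computeMetrics(ev, n = n, tau = tau)
      expect_gte(m$recall, prev)
      prev <- m$recall
      expect_equal(m$TP + m$FN, total_known)
    }
  }
  # with tau = 0 and n = T, every predictable known target is recovered
  mall <- computeMetrics(ev, n = 5)
  expect_equal(mall$recall, 1)
})

test_that("metrics match an independent per-event set-algebra oracle", {
  set.seed(77)
  events <- lapply(seq_len(200), function(i) {
    n_t <- sample(5:15, 1)
    ids <- sprintf("T%02d", seq_len(n_t))
    scores <- setNames(runif(n_t), ids)
    known <- sample(ids, sample(1:3, 1))
    tf_fake_event(sprintf("q%03d", i), known = known, scores = scores,
                  best_sims = setNames(runif(n_t), ids))
  })
  for (n in c(1, 5, 10)) for (tau in c(0, 0.45)) {
    TP <- FP <- FN <- 0L
    for (e in events) {
      en <- rankingEntries(e$ranking)
      retained <- en$target_id[en$rank <= n & en$best_similarity >= tau]
      TP <- TP + length(intersect(retained, e$known_targets))
      FP <- FP + length(setdiff(retained, e$known_targets))
      FN <- FN + length(setdiff(e$known_targets, retained))
    }
    m <- computeMetrics(events, n = n, tau = tau)
    expect_identical(c(m$TP, m$FP, m$FN), c(TP, FP, FN))
    expect_equal(m$recall, TP / (TP + FN))
    expect_equal(m$precision, if (TP + FP == 0) 0 else TP / (TP + FP))
  }
})

test_that("enrichment fold is recall over the random-picking baseline", {
  expect_equal(enrichmentFold(0.5, 10, 100), 5)
  expect_equal(enrichmentFold(10 / 1460, 10, 1460), 1)  # random baseline
  expect_error(enrichmentFold(1.2, 1, 10))
})

test_that("F1 is bounded by the geometric and arithmetic PR means", {
  ev <- tf_events()
  for (n in c(1, 3, 10)) {
    m <- computeMetrics(ev, n = n)
    if (m$precision > 0 && m$recall > 0) {
      expect_lte(m$f1, sqrt(m$precision * m$recall) + 1e-12)
      expect_lte(sqrt(m$precision * m$recall),
                 (m$precision + m$recall) / 2 + 1e-12)
    }
  }
})

test_that("promiscuity strata partition the events", {
  ev <- tf_events()
  s <- stratifyMetrics(ev, by = "promiscuity", n = 3)
  expect_equal(sum(s$n_events), length(ev))
  sizes <- vapply(ev, function(e) length(e$known_targets), integer(1))
  expect_setequal(s$stratum, as.character(sort(unique(sizes))))
  # each stratum equals plain metrics over its events
  for (i in seq_len(nrow(s))) {
    sub <- ev[sizes == as.integer(s$stratum[i])]
    m <- computeMetrics(sub, n = 3)
    expect_equal(s$recall[i], m$recall)
  }
})

test_that("class-stratum recalls recombine to the global recall", {
  f <- tf_fixture()
  ev <- tf_events()
  s <- stratifyMetrics(ev, by = "target_class", lib = f$lib, n = 10)
  known <- s$TP + s$FN
  expect_equal(sum(known),
               sum(vapply(ev, function(e) length(e$known_targets),
                          integer(1))))
  global <- computeMetrics(ev, n = 10)
  expect_equal(sum(s$recall * known) / sum(known), global$recall)
})

test_that("ligand-count baskets are cumulative and need the library", {
  f <- tf_fixture()
  ev <- tf_events()
  s <- stratifyMetrics(ev, by = "target_ligands", lib = f$lib, n = 10,
                       breaks = c(1, 10, 15))
  expect_equal(s$stratum, c(">=1", ">=10", ">=15"))
  # the >=1 basket is the global evaluation
  global <- computeMetrics(ev, n = 10)
  expect_equal(s$recall[1], global$recall)
  expect_true(all(diff(s$TP + s$FN) <= 0))  # known pairs shrink with the basket
  expect_error(stratifyMetrics(ev, by = "target_ligands"), "library")
})
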