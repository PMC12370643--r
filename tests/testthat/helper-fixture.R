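# Shared, memoised fixture objects: the default well-separated library
# (5 targets x 4 scaffolds x 5 ligands, seed 7), its fingerprints, and a
# held-out query event set with MaxTc/ECFP4 rankings.  Built once per run.

.tf_cache <- new.env(parent = emptyenv())

tf_fixture <- function() {
  if (is.null(.tf_cache$fx)) {
    .tf_cache$fx <- generateLibrary(fixtureSpec(seed = 7))
    .tf_cache$lib <- buildLibrary(.tf_cache$fx$records)
  }
  list(fx = .tf_cache$fx, lib = .tf_cache$lib)
}

tf_fps <- function(kinds = "ECFP4") {
  f <- tf_fixture()
  miss <- setdiff(kinds, names(.tf_cache$fps))
  if (length(miss)) {
    .tf_cache$fps <- c(.tf_cache$fps, libraryFingerprints(f$lib, miss))
  }
  .tf_cache$fps[kinds]
}

# external analog queries scored against the full library (ECFP4 / MaxTc)
tf_events <- function() {
  if (is.null(.tf_cache$ev)) {
    f <- tf_fixture()
    q <- generateQueries(f$fx, holdout_fraction = 0.25, seed = 3)
    .tf_cache$ev <- runLooCv(f$lib, asEvents(q), kind = "ECFP4",
                             scheme = "MaxTc", fps = tf_fps("ECFP4"))
  }
  .tf_cache$ev
}

# a small two-target library built directly (no chemistry), for tests that
# only exercise bookkeeping around rankings and sampling
tf_bare_library <- function(ligand_targets, classes = NULL) {
  ligs <- sort(unique(names(ligand_targets)))
  ia <- do.call(rbind, lapply(names(ligand_targets), function(l) {
    data.frame(ligand_id = l, target_id = ligand_targets[[l]],
               activity_nM = 50, n_measurements = 1L,
               stringsAsFactors = FALSE)
  }))
  ia <- ia[order(ia$target_id, ia$ligand_id), ]
  rownames(ia) <- NULL
  tgts <- sort(unique(ia$target_id))
  index <- lapply(split(ia$ligand_id, ia$target_id), sort)
  new("ReferenceLibrary",
      ligands = data.frame(ligand_id = ligs,
                           smiles = paste0("C", seq_along(ligs)),
                           stringsAsFactors = FALSE),
      targets = data.frame(target_id = tgts,
                           target_class = if (is.null(classes))
                             NA_character_ else unname(classes[tgts]),
                           predictable = TRUE, stringsAsFactors = FALSE),
      interactions = ia, ligandIndex = index[sort(names(index))],
      curationLog = data.frame(ligand_id = character(0),
                               target_id = character(0),
                               reason = character(0)),
      standardization = list(standardize = FALSE, neutralize = FALSE))
}

# hand-made event with a synthetic ranking (for metric arithmetic tests)
tf_fake_event <- function(query_id, known, scores, best_sims = NULL) {
  r <- rankTargets(scores, query_id = query_id, kind = "ECFP4",
                   scheme = "MaxTc")
  e <- r@entries
  if (is.null(best_sims)) best_sims <- setNames(unname(scores), names(scores))
  e$best_similarity <- unname(best_sims[e$target_id])
  e$best_ligand_id <- "Lx"
  r@entries <- e
  ev <- structure(list(query_id = query_id, known_targets = sort(known),
                       query_smiles = NA_character_, ranking = r),
                  class = "tfEvent")
  ev
}
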