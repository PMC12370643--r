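# Seeded synthetic fixtures: toy reference libraries with the statistical
# structure the method assumes -- scaffold-clustered target families built
# from distinct parent ring systems, combinatorial substituent decorations,
# promiscuous ligands, replicate measurements with controlled discordant
# and weak fractions -- plus held-out analog queries with an answer key.

# Each family decorates a distinct parent ring system.  ring1 takes two
# substituent slots; scaffold variants >= 1 link a second copy of the
# family ring through an alkyl chain (ring2 takes the second substituent).
.FIXTURE_FAMILIES <- list(
  list(ring1 = "c1cc(%s)ccc1%s",   ring2 = "c2ccc(%s)cc2"),     # benzene
  list(ring1 = "c1cc(%s)cnc1%s",   ring2 = "c2ccc(%s)nc2"),     # pyridine
  list(ring1 = "c1sc(%s)cc1%s",    ring2 = "c2sc(%s)cc2"),      # thiophene
  list(ring1 = "C1CC(%s)CCC1%s",   ring2 = "C2CCC(%s)CC2"),     # cyclohexane
  list(ring1 = "c1oc(%s)cc1%s",    ring2 = "c2oc(%s)cc2"),      # furan
  list(ring1 = "C1CC(%s)CNC1%s",   ring2 = "C2CCC(%s)NC2"),     # piperidine
  list(ring1 = "c1nc(%s)cnc1%s",   ring2 = "c2ncc(%s)nc2"),     # pyrimidine
  list(ring1 = "C1CC(%s)CC1%s",    ring2 = "C2CCC(%s)C2"),      # cyclopentane
  list(ring1 = "C1OC(%s)CC1%s",    ring2 = "C2OCC(%s)C2"),      # oxolane
  list(ring1 = "c1[nH]c(%s)cc1%s", ring2 = "c2[nH]c(%s)cc2"),   # pyrrole
  list(ring1 = "C1OC(%s)CNC1%s",   ring2 = "C2OCC(%s)NC2"),     # morpholine
  list(ring1 = "C1CC(%s)CCCC1%s",  ring2 = "C2CCCC(%s)CC2"))    # cycloheptane

# bounded substituent alphabet: halogens, alkyl, hydroxy, amino, methoxy,
# nitro -- enough to drive fingerprint similarity structure
.FIXTURE_SUBS <- c("F", "Cl", "Br", "C", "CC", "O", "N", "OC", "C(C)C",
                   "[N+](=O)[O-]")

.FIXTURE_CLASSES <- c("Kinase", "GPCR", "Ion channel", "Enzyme",
                      "Transporter")

.fixtureSmiles <- function(family, variant, sub1, sub2) {
  fam <- .FIXTURE_FAMILIES[[family]]
  if (variant == 0) return(sprintf(fam$ring1, sub1, sub2))
  sprintf(fam$ring1, sub1,
          paste0(strrep("C", variant), sprintf(fam$ring2, sub2)))
}

# unordered substituent pairs (with repetition): the decoration pool
.subPairs <- function() {
  n <- length(.FIXTURE_SUBS)
  idx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Specify a synthetic fixture
#'
#' Collects and validates the generator parameters.  Defaults describe a
#' small, well-separated library: five target families of four scaffold
#' variants with five ligands each, a 10\% promiscuous-ligand fraction
#' binding two targets, up to three replicate measurements per pair, and
#' 5\% each of discordant (spread > 10x) and weak (median >= 1 uM) pairs.
#'
#' @param n_targets Number of targets (one ring family each, max 12).
#' @param scaffolds_per_target Scaffold variants per family.
#' @param ligands_per_scaffold Decorated ligands per variant (max 55).
#' @param promiscuous_fraction Fraction of ligands bound to extra targets.
#' @param targets_per_promiscuous Targets per promiscuous ligand (>= 2).
#' @param max_replicates Replicate measurements are drawn uniformly from
#'   1..max_replicates (discordant pairs use at least 2).
#' @param discordant_fraction Fraction of pairs with a forced > 10x spread.
#' @param weak_fraction Fraction of pairs with median >= 1 uM.
#' @param activity_meanlog,activity_sdlog Log-normal location/scale of the
#'   potent-pair activity in nM.
#' @param seed Integer seed; identical spec + seed reproduces the fixture
#'   bit for bit.
#' @return An object of class \code{"tfFixtureSpec"}.
#' @export
fixtureSpec <- function(n_targets = 5, scaffolds_per_target = 4,
                        ligands_per_scaffold = 5, promiscuous_fraction = 0.1,
                        targets_per_promiscuous = 2, max_replicates = 3,
                        discordant_fraction = 0.05, weak_fraction = 0.05,
                        activity_meanlog = log(50), activity_sdlog = 0.8,
                        seed = 1) {
  stopifnot(n_targets >= 1, n_targets <= length(.FIXTURE_FAMILIES),
            scaffolds_per_target >= 1, ligands_per_scaffold >= 1,
            ligands_per_scaffold <= nrow(.subPairs()),
            promiscuous_fraction >= 0, promiscuous_fraction <= 1,
            discordant_fraction >= 0, discordant_fraction <= 1,
            weak_fraction >= 0, weak_fraction <= 1,
            discordant_fraction + weak_fraction <= 1,
            max_replicates >= 1)
  if (promiscuous_fraction > 0 && (targets_per_promiscuous < 2 ||
                                   targets_per_promiscuous > n_targets))
    stop("targets_per_promiscuous must be in [2, n_targets]")
  structure(as.list(environment()), class = "tfFixtureSpec")
}

.drawActivities <- function(outcome, mu, reps) {
  if (outcome == "discard_discordant") {
    reps <- max(2L, reps)
    v <- c(mu, mu * 12, mu * stats::runif(reps - 2, 1, 1.4))
  } else {
    f <- exp(stats::runif(reps, -log(2.5), log(2.5)))
    v <- mu * f
    v <- v * mu / stats::median(v)  # pin the median, spread stays <= 6.25x
  }
  signif(v, 6)
}

#' Generate a synthetic reference library
#'
#' Builds each target family from a distinct parent ring system; ligands
#' are substituent decorations of the family's scaffold variants, so
#' within-family fingerprint similarity is high and cross-family similarity
#' low by construction.  Promiscuous ligands are additionally assigned to
#' other targets, and replicate activity values are drawn log-normally with
#' the discordant and weak pair counts met exactly (one injected > 10x
#' outlier per discordant pair).
#'
#' @param spec A \code{\link{fixtureSpec}}.
#' @return Object of class \code{"tfFixture"}: list with \code{records}
#'   (raw bioactivity records for \code{\link{buildLibrary}}) and
#'   \code{truth} (ground-truth ligand/pair/target tables with per-pair
#'   expected curation outcomes and scaffold family labels).
#' @export
generateLibrary <- function(spec) {
  stopifnot(inherits(spec, "tfFixtureSpec"))
  pairs_pool <- .subPairs()
  .withSeed(spec$seed, {
    ligs <- list()
    li <- 0L
    for (f in seq_len(spec$n_targets)) {
      sel <- sample(nrow(pairs_pool),
                    spec$scaffolds_per_target * spec$ligands_per_scaffold)
      pi_ <- 0L
      for (v in seq_len(spec$scaffolds_per_target) - 1L) {
        for (j in seq_len(spec$ligands_per_scaffold)) {
          pi_ <- pi_ + 1L
          li <- li + 1L
          p <- pairs_pool[sel[pi_], ]
          ligs[[li]] <- data.frame(
            ligand_id = sprintf("L%04d", li),
            smiles = .fixtureSmiles(f, v, .FIXTURE_SUBS[p[1]],
                                    .FIXTURE_SUBS[p[2]]),
            family = f, target_id = sprintf("T%02d", f),
            scaffold_label = sprintf("F%d.V%d", f, v),
            pair_idx = sel[pi_], variant = v,
            stringsAsFactors = FALSE)
        }
      }
    }
    ligands <- do.call(rbind, ligs)

    # promiscuous ligands bind extra targets from other families
    pairs <- data.frame(ligand_id = ligands$ligand_id,
                        target_id = ligands$target_id, primary = TRUE,
                        stringsAsFactors = FALSE)
    n_prom <- round(spec$promiscuous_fraction * nrow(ligands))
    if (n_prom > 0) {
      prom <- sort(sample(ligands$ligand_id, n_prom))
      extra <- list()
      for (lg in prom) {
        own <- ligands$target_id[ligands$ligand_id == lg]
        others <- setdiff(sprintf("T%02d", seq_len(spec$n_targets)), own)
        ex <- sample(others, spec$targets_per_promiscuous - 1L)
        extra[[lg]] <- data.frame(ligand_id = lg, target_id = ex,
                                  primary = FALSE, stringsAsFactors = FALSE)
      }
      pairs <- rbind(pairs, do.call(rbind, extra))
    }
    pairs <- pairs[order(pairs$ligand_id, pairs$target_id), , drop = FALSE]
    rownames(pairs) <- NULL

    np <- nrow(pairs)
    n_disc <- round(spec$discordant_fraction * np)
    n_weak <- round(spec$weak_fraction * np)
    lab <- rep("keep", np)
    special <- sample(np, n_disc + n_weak)
    lab[special[seq_len(n_disc)]] <- "discard_discordant"
    if (n_weak > 0) lab[special[n_disc + seq_len(n_weak)]] <- "discard_weak"
    pairs$outcome <- lab

    rec <- list()
    pairs$n_replicates <- NA_integer_
    for (i in seq_len(np)) {
      mu <- if (lab[i] == "discard_weak") {
        exp(stats::runif(1, log(3000), log(20000)))
      } else {
        min(800, max(1, exp(stats::rnorm(1, spec$activity_meanlog,
                                         spec$activity_sdlog))))
      }
      reps <- sample.int(spec$max_replicates, 1)
      v <- .drawActivities(lab[i], mu, reps)
      pairs$n_replicates[i] <- length(v)
      in_um <- stats::runif(length(v)) < 0.3
      rec[[i]] <- data.frame(
        ligand_id = pairs$ligand_id[i],
        smiles = ligands$smiles[match(pairs$ligand_id[i], ligands$ligand_id)],
        target_id = pairs$target_id[i],
        activity_type = sample(c("IC50", "Ki", "Kd", "EC50"), length(v),
                               replace = TRUE),
        value = ifelse(in_um, v / 1e3, v),
        unit = ifelse(in_um, "uM", "nM"),
        source = sample(c("srcA", "srcB", "srcC"), length(v), replace = TRUE),
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rec)
    rownames(records) <- NULL
    targets <- data.frame(
      target_id = sprintf("T%02d", seq_len(spec$n_targets)),
      target_class = rep_len(.FIXTURE_CLASSES, spec$n_targets),
      family = seq_len(spec$n_targets), stringsAsFactors = FALSE)
    records$target_class <-
      targets$target_class[match(records$target_id, targets$target_id)]
    structure(list(records = records,
                   truth = list(ligands = ligands, pairs = pairs,
                                targets = targets, spec = spec)),
              class = "tfFixture")
  })
}

#' Generate held-out analog queries with an answer key
#'
#' Draws new decorated analogs of each family's scaffolds whose exact
#' structures do not occur in the reference library, together with their
#' true targets and promiscuity counts for stratified evaluation.
#'
#' @param fixture A \code{"tfFixture"} from \code{\link{generateLibrary}}.
#' @param holdout_fraction Number of queries as a fraction of the library
#'   ligand count (0 gives an empty query set).
#' @param seed Integer seed.
#' @return data.frame with columns \code{query_id}, \code{smiles},
#'   \code{known_targets} (pipe-joined), \code{n_known}, \code{family};
#'   convert with \code{\link{asEvents}}.
#' @export
generateQueries <- function(fixture, holdout_fraction = 0.2, seed = 1) {
  stopifnot(inherits(fixture, "tfFixture"),
            holdout_fraction >= 0, holdout_fraction <= 1)
  truth <- fixture$truth
  spec <- truth$spec
  n_q <- round(holdout_fraction * nrow(truth$ligands))
  empty <- data.frame(query_id = character(0), smiles = character(0),
                      known_targets = character(0), n_known = integer(0),
                      family = integer(0), stringsAsFactors = FALSE)
  if (n_q == 0) return(empty)
  pairs_pool <- .subPairs()
  .withSeed(seed, {
    out <- list()
    fam_cycle <- rep_len(seq_len(spec$n_targets), n_q)
    for (qi in seq_len(n_q)) {
      f <- fam_cycle[qi]
      used <- truth$ligands[truth$ligands$family == f, c("variant", "pair_idx")]
      free <- expand.grid(variant = seq_len(spec$scaffolds_per_target) - 1L,
                          pair_idx = seq_len(nrow(pairs_pool)))
      free <- free[!(paste(free$variant, free$pair_idx) %in%
                       paste(used$variant, used$pair_idx)), , drop = FALSE]
      if (nrow(free) == 0) stop("family ", f, " exhausted; nothing to hold out")
      pick <- free[sample.int(nrow(free), 1), ]
      p <- pairs_pool[pick$pair_idx, ]
      known <- sprintf("T%02d", f)
      if (spec$promiscuous_fraction > 0 &&
          stats::runif(1) < spec$promiscuous_fraction) {
        others <- setdiff(sprintf("T%02d", seq_len(spec$n_targets)), known)
        known <- c(known, sample(others, spec$targets_per_promiscuous - 1L))
      }
      out[[qi]] <- data.frame(
        query_id = sprintf("Q%03d", qi),
        smiles = .fixtureSmiles(f, pick$variant, .FIXTURE_SUBS[p[1]],
                                .FIXTURE_SUBS[p[2]]),
        known_targets = paste(sort(known), collapse = "|"),
        n_known = length(known), family = f, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
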