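# Reference-library curation.
#
# Raw bioactivity records (one row per measurement) are harmonised to nM,
# pooled per (ligand, target) pair across activity types and sources, and a
# pair is retained only when its measurements agree within an order of
# magnitude (max/min <= 10); the median of the concordant set is the
# definitive activity and only potent pairs (median < 1 uM) enter the
# library.

.ACTIVITY_TYPES <- c("IC50", "Ki", "Kd", "EC50")
.UNIT_FACTOR <- c(nM = 1, uM = 1e3, M = 1e9)

#' Convert an activity measurement to nM
#'
#' @param value Positive numeric activity value(s).
#' @param unit Unit string(s), one of \code{"nM"}, \code{"uM"}, \code{"M"}.
#' @return Numeric value(s) in nM; \code{NA} for unknown units (callers log
#'   and reject such records).
#' @examples
#' normalizeActivity(1, "uM")    # 1000
#' normalizeActivity(1e-7, "M")  # 100
#' @export
normalizeActivity <- function(value, unit) {
  fac <- .UNIT_FACTOR[unit]
  out <- value * as.numeric(fac)
  out[is.na(fac)] <- NA_real_
  out[!is.na(value) & value <= 0] <- NA_real_
  unname(out)
}

#' Curate one ligand-target measurement set
#'
#' Pools all nM measurements for a single pair and applies the concordance
#' and potency rules: if max/min exceeds 10 the pair is discarded as
#' discordant; otherwise the median (even-sized sets: mean of the two
#' central values) is the definitive activity, and medians of 1000 nM or
#' more are discarded as weak.
#'
#' @param values_nM Nonempty numeric vector of positive activities in nM.
#' @return List with \code{decision} (\code{"keep"},
#'   \code{"discard_discordant"} or \code{"discard_weak"}),
#'   \code{activity_nM} (the median; NA unless kept) and \code{n}.
#' @examples
#' curatePair(c(100, 500))   # keep, 300 nM
#' curatePair(c(50, 600))    # discordant (ratio 12)
#' curatePair(2000)          # weak
#' @export
curatePair <- function(values_nM) {
  if (length(values_nM) == 0) stop("empty measurement set")
  if (any(is.na(values_nM) | values_nM <= 0)) stop("non-positive or missing activity")
  if (max(values_nM) / min(values_nM) > 10) {
    return(list(decision = "discard_discordant", activity_nM = NA_real_,
                n = length(values_nM)))
  }
  med <- stats::median(values_nM)
  if (med >= 1000) {
    return(list(decision = "discard_weak", activity_nM = NA_real_,
                n = length(values_nM)))
  }
  list(decision = "keep", activity_nM = med, n = length(values_nM))
}

#' Read raw bioactivity records from delimited text
#'
#' Expects a header with columns \code{ligand_id}, \code{smiles},
#' \code{target_id}, \code{activity_type}, \code{value}, \code{unit} and
#' optionally \code{source} and \code{target_class}.  Comma-separated for
#' \code{.csv}, otherwise tab-separated.
#'
#' @param file Path to a CSV/TSV file.
#' @return data.frame of records.
#' @export
readBioactivityRecords <- function(file) {
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(file, sep = sep, stringsAsFactors = FALSE)
  need <- c("ligand_id", "smiles", "target_id", "activity_type", "value", "unit")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  if (!"source" %in% names(df)) df$source <- NA_character_
  df$ligand_id <- as.character(df$ligand_id)
  df$target_id <- as.character(df$target_id)
  df$value <- as.numeric(df$value)
  df
}

#' Build the curated reference library
#'
#' Validates and normalises raw records, standardizes ligand structures,
#' applies \code{\link{curatePair}} to every (ligand, target) measurement
#' set, and assembles a \code{\linkS4class{ReferenceLibrary}}.  The result
#' is independent of record order; targets whose every pair was discarded
#' are retained in the target table but flagged unpredictable; ligands with
#' unparseable structures are dropped with a logged reason.
#'
#' @param records data.frame as returned by
#'   \code{\link{readBioactivityRecords}}.
#' @param standardize Logical; standardize structures (largest organic
#'   fragment, canonical SMILES) before identity checks.  Default TRUE.
#' @param neutralize Logical; also neutralize single formal charges.
#' @param target_classes Optional named character vector of class labels by
#'   target id (overrides a \code{target_class} record column).
#' @return A \code{\linkS4class{ReferenceLibrary}}.
#' @examples
#' rec <- data.frame(ligand_id = "L1", smiles = "Cc1ccccc1",
#'                   target_id = "T1", activity_type = "Ki",
#'                   value = 80, unit = "nM", source = "x")
#' buildLibrary(rec)
#' @export
buildLibrary <- function(records, standardize = TRUE, neutralize = FALSE,
                         target_classes = NULL) {
  stopifnot(is.data.frame(records))
  if (!"source" %in% names(records)) records$source <- NA_character_
  log <- list()
  addLog <- function(lig, tgt, reason) {
    log[[length(log) + 1L]] <<- data.frame(ligand_id = lig, target_id = tgt,
                                           reason = reason)
  }

  # record-order invariance: canonical sort before any grouping
  ord <- order(records$ligand_id, records$target_id, records$activity_type,
               records$value, records$unit, records$source)
  records <- records[ord, , drop = FALSE]

  bad_type <- !(records$activity_type %in% .ACTIVITY_TYPES)
  bad_unit <- !(records$unit %in% names(.UNIT_FACTOR))
  bad_value <- is.na(records$value) | records$value <= 0
  bad <- bad_type | bad_unit | bad_value
  if (any(bad)) {
    why <- ifelse(bad_type, "invalid_activity_type",
                  ifelse(bad_unit, "unknown_unit", "non_positive_value"))
    for (i in which(bad)) addLog(records$ligand_id[i], records$target_id[i], why[i])
    records <- records[!bad, , drop = FALSE]
  }
  records$activity_nM <- normalizeActivity(records$value, records$unit)

  # one structure per ligand id (identifier-level identity)
  first <- !duplicated(records$ligand_id)
  lig_smiles <- setNames(records$smiles[first], records$ligand_id[first])
  std <- if (standardize) {
    standardizeSmiles(lig_smiles, neutralize = neutralize)
  } else {
    parsed <- .parseMolecules(lig_smiles)
    s <- lig_smiles
    s[parsed$failed] <- NA_character_
    s
  }
  unparseable <- names(std)[is.na(std)]
  for (id in unparseable) addLog(id, NA_character_, "unparseable_smiles")
  records <- records[!(records$ligand_id %in% unparseable), , drop = FALSE]
  std <- std[!is.na(std)]

  # class annotations
  classes <- character(0)
  if (!is.null(target_classes)) {
    classes <- target_classes
  } else if ("target_class" %in% names(records)) {
    firstt <- !duplicated(records$target_id)
    classes <- setNames(as.character(records$target_class[firstt]),
                        records$target_id[firstt])
  }

  all_targets <- sort(unique(records$target_id))
  key <- paste(records$ligand_id, records$target_id, sep = "\r")
  groups <- split(records$activity_nM, key)
  keep <- list()
  for (k in sort(names(groups))) {
    ids <- strsplit(k, "\r", fixed = TRUE)[[1]]
    res <- curatePair(groups[[k]])
    if (res$decision == "keep") {
      keep[[length(keep) + 1L]] <- data.frame(
        ligand_id = ids[1], target_id = ids[2],
        activity_nM = res$activity_nM, n_measurements = res$n)
    } else {
      addLog(ids[1], ids[2], res$decision)
    }
  }
  interactions <- if (length(keep)) do.call(rbind, keep) else
    data.frame(ligand_id = character(0), target_id = character(0),
               activity_nM = numeric(0), n_measurements = integer(0))
  interactions <- interactions[order(interactions$target_id,
                                     interactions$ligand_id), , drop = FALSE]
  rownames(interactions) <- NULL

  lig_keep <- sort(unique(interactions$ligand_id))
  ligands <- data.frame(ligand_id = lig_keep,
                        smiles = unname(std[lig_keep]),
                        stringsAsFactors = FALSE)
  predictable <- all_targets %in% interactions$target_id
  targets <- data.frame(
    target_id = all_targets,
    target_class = if (length(classes))
      unname(classes[all_targets]) else NA_character_,
    predictable = predictable, stringsAsFactors = FALSE)
  index <- split(interactions$ligand_id, interactions$target_id)
  index <- lapply(index, sort)
  index <- index[sort(names(index))]

  curation_log <- if (length(log)) do.call(rbind, log) else
    data.frame(ligand_id = character(0), target_id = character(0),
               reason = character(0))
  curation_log <- curation_log[order(curation_log$ligand_id,
                                     curation_log$target_id,
                                     curation_log$reason), , drop = FALSE]
  rownames(curation_log) <- NULL

  new("ReferenceLibrary", ligands = ligands, targets = targets,
      interactions = interactions, ligandIndex = index,
      curationLog = curation_log,
      standardization = list(standardize = standardize,
                             neutralize = neutralize))
}

#' Re-export a library as curated records
#'
#' One record per curated interaction (nM, activity type "IC50", source
#' "curated"); feeding the result back through \code{\link{buildLibrary}}
#' reproduces the library (curation is idempotent).
#'
#' @param lib A \code{\linkS4class{ReferenceLibrary}}.
#' @return data.frame of records.
#' @export
libraryRecords <- function(lib) {
  ia <- lib@interactions
  smiles <- setNames(lib@ligands$smiles, lib@ligands$ligand_id)
  cls <- setNames(lib@targets$target_class, lib@targets$target_id)
  data.frame(ligand_id = ia$ligand_id, smiles = unname(smiles[ia$ligand_id]),
             target_id = ia$target_id, activity_type = "IC50",
             value = ia$activity_nM, unit = "nM", source = "curated",
             target_class = unname(cls[ia$target_id]),
             stringsAsFactors = FALSE)
}

#' Serialize a reference library to a directory of TSV tables
#'
#' Writes \code{ligands.tsv}, \code{targets.tsv}, \code{interactions.tsv},
#' \code{curation_log.tsv} and a JSON \code{manifest.json} with curation
#' counts and standardization options.
#'
#' @param lib A \code{\linkS4class{ReferenceLibrary}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeLibrary <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(lib@ligands, "ligands.tsv")
  wt(lib@targets, "targets.tsv")
  wt(lib@interactions, "interactions.tsv")
  wt(lib@curationLog, "curation_log.tsv")
  manifest <- list(
    ligands = nrow(lib@ligands), targets = nrow(lib@targets),
    predictable_targets = sum(lib@targets$predictable),
    interactions = nrow(lib@interactions),
    discarded = as.list(table(lib@curationLog$reason)),
    standardization = lib@standardization,
    tanifish_version = as.character(utils::packageVersion("tanifish")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a serialized reference library
#'
#' @param dir Directory written by \code{\link{writeLibrary}}.
#' @return A \code{\linkS4class{ReferenceLibrary}}.
#' @export
readLibrary <- function(dir) {
  rt <- function(f) utils::read.delim(file.path(dir, f), sep = "\t",
                                      stringsAsFactors = FALSE)
  ligands <- rt("ligands.tsv")
  targets <- rt("targets.tsv")
  targets$target_id <- as.character(targets$target_id)
  targets$target_class <- as.character(targets$target_class)
  ligands$ligand_id <- as.character(ligands$ligand_id)
  interactions <- rt("interactions.tsv")
  interactions$ligand_id <- as.character(interactions$ligand_id)
  interactions$target_id <- as.character(interactions$target_id)
  lg <- if (file.exists(file.path(dir, "curation_log.tsv")))
    rt("curation_log.tsv") else
    data.frame(ligand_id = character(0), target_id = character(0),
               reason = character(0))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  index <- split(interactions$ligand_id, interactions$target_id)
  index <- lapply(index, sort)
  index <- index[sort(names(index))]
  new("ReferenceLibrary", ligands = ligands, targets = targets,
      interactions = interactions, ligandIndex = index, curationLog = lg,
      standardization = list(
        standardize = isTRUE(manifest$standardization$standardize),
        neutralize = isTRUE(manifest$standardization$neutralize)))
}
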