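# Structure standardization: largest organic fragment, optional charge
# neutralization (OpenBabel's neutralize operation), canonical SMILES.

.largestFragment <- function(smi) {
  frags <- strsplit(smi, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1) return(smi)
  # heavy-atom proxy from the SMILES text; prefer carbon-containing fragments
  size <- vapply(frags, function(f) {
    letters_only <- gsub("[^A-Za-z]", "", f)
    nchar(letters_only) - lengths(regmatches(f, gregexpr("H", f)))
  }, numeric(1))
  organic <- grepl("c", frags) | grepl("C(?![laodurse])", frags, perl = TRUE)
  if (any(organic)) size[!organic] <- -Inf
  frags[which.max(size)]
}

#' Standardize SMILES
#'
#' Reduces each input to its largest organic fragment, optionally
#' neutralizes +1/-1 formal charges where valence-legal (OpenBabel
#' \code{neutralize}), and returns OpenBabel canonical SMILES.  Identity
#' checks in the library are made on the standardized form.
#'
#' @param smiles Character vector of SMILES.
#' @param neutralize Logical; neutralize single charges (default FALSE).
#' @return Character vector of canonical SMILES; \code{NA} where the input
#'   could not be parsed.
#' @examples
#' standardizeSmiles("C(C)c1ccccc1")
#' @export
standardizeSmiles <- function(smiles, neutralize = FALSE) {
  out <- rep(NA_character_, length(smiles))
  frags <- vapply(smiles, .largestFragment, "", USE.NAMES = FALSE)
  opts <- if (neutralize) {
    data.frame(names = "neutralize", args = "", stringsAsFactors = FALSE)
  } else NULL
  canOne <- function(s) {
    r <- suppressWarnings(try(
      if (is.null(opts)) ChemmineOB::convertFormat("SMI", "CAN", s)
      else ChemmineOB::convertFormat("SMI", "CAN", s, options = opts),
      silent = TRUE))
    if (inherits(r, "try-error")) return(NA_character_)
    line <- strsplit(r, "\n", fixed = TRUE)[[1]][1]
    if (is.na(line) || !nzchar(trimws(line))) return(NA_character_)
    strsplit(trimws(line), "[ \t]")[[1]][1]
  }
  src <- paste(frags, collapse = "\n")
  r <- suppressWarnings(try(
    if (is.null(opts)) ChemmineOB::convertFormat("SMI", "CAN", src)
    else ChemmineOB::convertFormat("SMI", "CAN", src, options = opts),
    silent = TRUE))
  lines <- if (inherits(r, "try-error")) character(0) else {
    l <- strsplit(r, "\n", fixed = TRUE)[[1]]
    l[nzchar(trimws(l))]
  }
  if (length(lines) == length(smiles)) {
    out <- vapply(strsplit(trimws(lines), "[ \t]"), `[`, "", 1)
  } else {
    # at least one entry failed to convert: redo one-by-one to keep alignment
    out <- vapply(frags, canOne, "", USE.NAMES = FALSE)
  }
  names(out) <- names(smiles)
  out
}
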