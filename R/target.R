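#' Target sequence
#'
#' The target amino-acid sequence is the frame of reference for the whole
#' quality-estimation pipeline: every model residue is mapped to a 1-based
#' position along it, and every per-residue score track has one entry per
#' target position. Residues use 1-letter codes from the 20 standard amino
#' acids plus `X` for unknowns.
#'
#' @param residues Character vector of 1-letter residue codes (or a single
#'   string, which is split).
#' @param id Short text label for the target.
#' @return An object of class `target_seq` with fields `id`, `residues`
#'   (character vector) and `length`.
#' @export
target_sequence <- function(residues, id = "target") {
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(residues)
  residues <- residues[!residues %in% c(" ", "\t", "\n", "")]
  if (length(residues) < 1L) {
    abort_format("target sequence is empty")
  }
  bad <- which(!residues %in% AA_CODES)
  if (length(bad) > 0L) {
    abort_format(sprintf(
      "invalid residue code '%s' at position %d (expected 1-letter amino-acid codes)",
      residues[bad[1L]], bad[1L]
    ))
  }
  structure(
    list(id = as.character(id), residues = residues, length = length(residues)),
    class = "target_seq"
  )
}

#' Read a target sequence from a FASTA file
#'
#' The first record of the file is used. Whitespace is stripped and codes are
#' uppercased; anything outside the 20 standard codes plus `X` is an error.
#'
#' @param path Path to a FASTA file.
#' @return A [target_sequence()] object.
#' @export
read_target_fasta <- function(path) {
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort_format("could not parse FASTA file '", path, "': ", conditionMessage(e))
  )
  if (length(seqs) < 1L) {
    abort_format("FASTA file '", path, "' contains no sequences")
  }
  id <- strsplit(names(seqs)[1L], "\\s+")[[1]][1]
  if (is.na(id) || id == "") id <- "target"
  target_sequence(gsub("\\s", "", as.character(seqs[[1L]])), id = id)
}

#' @export
print.target_seq <- function(x, ...) {
  cat(sprintf("<target_seq> %s (%d residues)\n", x$id, x$length))
  cat(paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

target_string <- function(target) paste(target$residues, collapse = "")
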