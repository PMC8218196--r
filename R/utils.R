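# Internal helpers shared across the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 3-letter -> 1-letter residue codes (20 standard + selenomethionine).
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"
)

AA_CODES <- c(sort(unique(unname(AA_3TO1))), "X")

aa3to1 <- function(res3) {
  out <- unname(AA_3TO1[toupper(res3)])
  out[is.na(out)] <- "X"
  out
}

abort_format <- function(msg, ...) {
  rlang::abort(paste0(msg, ...), class = "modfold_format_error")
}

abort_domain <- function(msg, ...) {
  rlang::abort(paste0(msg, ...), class = "modfold_domain_error")
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_domain(sprintf("`%s` must be a single finite number", name))
  }
}
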