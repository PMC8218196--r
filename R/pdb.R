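#' @title Structure models
#' @description
#' A `structure_model` holds one parsed 3D model: an atom table and a residue
#' table, with every residue mapped (where possible) to a 1-based position on
#' the target sequence. PDB author numbering is discarded after mapping; all
#' scoring uses target positions, so partial models and models with shifted
#' numbering are compared on the same frame.
#' @name structure_model
NULL

new_structure_model <- function(model_id, chain, atoms, residues, target_length) {
  structure(
    list(
      model_id = model_id, chain = chain,
      atoms = atoms, residues = residues,
      target_length = as.integer(target_length)
    ),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "<structure_model> %s: %d residues (%d mapped to target of %d), %d atoms, chain %s\n",
    x$model_id, nrow(x$residues), sum(!is.na(x$residues$target_index)),
    x$target_length, nrow(x$atoms), x$chain
  ))
  invisible(x)
}

#' Read a 3D model from a PDB file
#'
#' Parses fixed-column `ATOM` records. Only the first chain containing ATOM
#' records is used (others are dropped with a warning), only the first MODEL
#' of a multi-model file is read, HETATM records (waters, ligands) are
#' ignored, and alternate locations other than blank/`A` are dropped.
#' Residues lacking a C-alpha atom are dropped with a warning. The model
#' sequence is then mapped onto the target with [map_model_to_target()].
#'
#' @param path Path to a PDB file.
#' @param target The [target_sequence()] the model claims to represent.
#' @param model_id Label for the model; defaults to the file name.
#' @return A `structure_model`.
#' @export
read_model_pdb <- function(path, target, model_id = NULL) {
  model_id <- model_id %||% sub("\\.(pdb|ent)$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1L] - 1L)]
  atom_lines <- lines[startsWith(lines, "ATOM  ")]
  if (length(atom_lines) == 0L) {
    abort_format("no ATOM records found in '", path, "'")
  }
  atom_lines <- sprintf("%-80s", atom_lines)  # pad short records to full width
  fx <- function(l, a, b) substr(l, a, b)
  alt <- fx(atom_lines, 17, 17)
  keep <- alt %in% c(" ", "", "A")
  atom_lines <- atom_lines[keep]
  chains <- fx(atom_lines, 22, 22)
  chain <- chains[1L]
  if (any(chains != chain)) {
    rlang::warn(sprintf("model '%s' has multiple chains; using first chain '%s'", model_id, chain))
    atom_lines <- atom_lines[chains == chain]
  }
  num <- function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v)) abort_format("malformed numeric field in ATOM record of '", path, "'")
    v
  }
  atoms <- tibble::tibble(
    name = trimws(fx(atom_lines, 13, 16)),
    resname = trimws(fx(atom_lines, 18, 20)),
    resno = as.integer(num(fx(atom_lines, 23, 26))),
    icode = fx(atom_lines, 27, 27),
    x = num(fx(atom_lines, 31, 38)),
    y = num(fx(atom_lines, 39, 46)),
    z = num(fx(atom_lines, 47, 54)),
    b = suppressWarnings(as.numeric(fx(atom_lines, 61, 66))),
    element = trimws(fx(atom_lines, 77, 78)),
    line = atom_lines
  )
  atoms$b[is.na(atoms$b)] <- 0
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort_format("non-finite coordinates in '", path, "'")
  }
  # group into residues by (resno, icode) in order of residue number
  key <- paste(atoms$resno, atoms$icode)
  first_seen <- !duplicated(key)
  res <- tibble::tibble(
    key = key[first_seen],
    resno = atoms$resno[first_seen],
    icode = atoms$icode[first_seen],
    resname = atoms$resname[first_seen]
  )
  res <- res[order(res$resno, res$icode), , drop = FALSE]
  res$res_key <- seq_len(nrow(res))
  atoms$res_key <- res$res_key[match(key, res$key)]
  # drop residues without a C-alpha
  has_ca <- vapply(split(atoms$name, atoms$res_key), function(n) "CA" %in% n, logical(1))
  ca_keys <- as.integer(names(has_ca))[has_ca]
  if (length(ca_keys) < nrow(res)) {
    rlang::warn(sprintf(
      "model '%s': dropping %d residue(s) lacking a CA atom",
      model_id, nrow(res) - length(ca_keys)
    ))
  }
  res <- res[res$res_key %in% ca_keys, , drop = FALSE]
  atoms <- atoms[atoms$res_key %in% ca_keys, , drop = FALSE]
  # renumber residue keys 1..n in order
  remap <- stats::setNames(seq_len(nrow(res)), res$res_key)
  res$res_key <- unname(remap[as.character(res$res_key)])
  atoms$res_key <- unname(remap[as.character(atoms$res_key)])
  atoms <- atoms[order(atoms$res_key), , drop = FALSE]

  residues <- tibble::tibble(
    res_key = res$res_key,
    resno = res$resno,
    code = aa3to1(res$resname),
    resname = res$resname,
    target_index = NA_integer_
  )
  residues$target_index <- map_model_to_target(residues$code, target)
  new_structure_model(
    model_id, chain,
    atoms[, c("res_key", "name", "element", "x", "y", "z", "b", "line")],
    residues, target$length
  )
}

#' Map model residues onto the target sequence
#'
#' If the model sequence is an exact contiguous substring of the target, the
#' mapping is the substring offset. Otherwise a global alignment (match +1,
#' mismatch -1, linear gap -2) is performed and non-gap aligned columns are
#' mapped; model residues aligned to gaps are left unmapped (`NA`) and take
#' no part in scoring. An alignment identity below 50% over aligned columns
#' is treated as a wrong-target error.
#'
#' @param model_seq Character vector of the model's 1-letter residue codes.
#' @param target A [target_sequence()].
#' @return Integer vector of target positions (`NA` = unmapped), one per
#'   model residue, strictly increasing over mapped residues.
#' @export
map_model_to_target <- function(model_seq, target) {
  if (length(model_seq) == 0L) abort_domain("model sequence is empty")
  mstr <- paste(model_seq, collapse = "")
  tstr <- target_string(target)
  hit <- regexpr(mstr, tstr, fixed = TRUE)
  if (hit[1L] > 0L) {
    return(seq.int(hit[1L], length.out = length(model_seq)))
  }
  alphabet <- sort(unique(c(model_seq, target$residues)))
  smat <- matrix(-1, length(alphabet), length(alphabet),
                 dimnames = list(alphabet, alphabet))
  diag(smat) <- 1
  al <- Biostrings::pairwiseAlignment(
    Biostrings::BString(mstr), Biostrings::BString(tstr),
    substitutionMatrix = smat, gapOpening = 0, gapExtension = 2,
    type = "global"
  )
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  idx <- rep(NA_integer_, length(model_seq))
  mi <- 0L; ti <- 0L; n_aln <- 0L; n_match <- 0L
  for (k in seq_along(pat)) {
    pm <- pat[k] != "-"; tm <- sub[k] != "-"
    if (pm) mi <- mi + 1L
    if (tm) ti <- ti + 1L
    if (pm && tm) {
      idx[mi] <- ti
      n_aln <- n_aln + 1L
      if (pat[k] == sub[k]) n_match <- n_match + 1L
    }
  }
  if (n_aln == 0L || n_match / n_aln < 0.5) {
    abort_domain(sprintf(
      "model sequence does not correspond to target '%s' (alignment identity %.0f%% < 50%%)",
      target$id, if (n_aln == 0L) 0 else 100 * n_match / n_aln
    ))
  }
  idx
}

# --- coordinate accessors ----------------------------------------------------

# Matrix of coordinates for one atom name (default CA) indexed by target
# position; rownames are target positions as character.
atom_coords <- function(model, atom = "CA") {
  a <- model$atoms[model$atoms$name == atom, , drop = FALSE]
  ti <- model$residues$target_index[match(a$res_key, model$residues$res_key)]
  keep <- !is.na(ti)
  m <- as.matrix(a[keep, c("x", "y", "z")])
  rownames(m) <- ti[keep]
  m
}

model_mapped_positions <- function(model) {
  sort(model$residues$target_index[!is.na(model$residues$target_index)])
}

# All atoms of mapped residues keyed by "target_index:atom_name".
mapped_atom_table <- function(model, calpha_only = FALSE) {
  a <- model$atoms
  if (calpha_only) a <- a[a$name == "CA", , drop = FALSE]
  ti <- model$residues$target_index[match(a$res_key, model$residues$res_key)]
  keep <- !is.na(ti) & a$element != "H" & !grepl("^H", a$name)
  tibble::tibble(
    key = paste0(ti[keep], ":", a$name[keep]),
    target_index = ti[keep],
    x = a$x[keep], y = a$y[keep], z = a$z[keep]
  )
}

# --- writers -----------------------------------------------------------------

format_atom_line <- function(serial, name, resname, chain, resno, x, y, z, b,
                             element = "") {
  name_fmt <- if (nchar(name) >= 4L) sprintf("%-4s", name) else sprintf(" %-3s", name)
  sprintf(
    "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial %% 100000L, name_fmt, resname, chain, resno, x, y, z, 1.0, b, element
  )
}

#' Write a structure model as a PDB file
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @param b Optional per-atom b-factor override (numeric, one per atom).
#' @export
write_model_pdb <- function(model, path, b = NULL) {
  at <- model$atoms
  bvals <- b %||% at$b
  res <- model$residues
  lines <- character(nrow(at))
  for (i in seq_len(nrow(at))) {
    if (!is.na(at$line[i]) && is.null(b)) {
      lines[i] <- at$line[i]
    } else if (!is.na(at$line[i])) {
      l <- at$line[i]
      substr(l, 61, 66) <- sprintf("%6.2f", clamp(bvals[i], 0, 99.99))
      lines[i] <- l
    } else {
      r <- res[res$res_key == at$res_key[i], ]
      lines[i] <- format_atom_line(
        i, at$name[i], r$resname, model$chain %||% "A", r$resno,
        at$x[i], at$y[i], at$z[i], clamp(bvals[i], 0, 99.99), at$element[i]
      )
    }
  }
  writeLines(c(sub("\\s+$", "", lines), "END"), path)
  invisible(path)
}

#' Write a model with predicted residue errors in the b-factor column
#'
#' Echoes the model's ATOM records with the b-factor column replaced by the
#' residue's predicted C-alpha error in Angstroms (clamped to 99.99, 2
#' decimals); every atom of a residue carries the same value and unmapped
#' residues are written with 99.99. Coordinates are echoed byte-for-byte, so
#' re-reading the written file reproduces them exactly.
#'
#' @param model A `structure_model`.
#' @param residue_errors Numeric vector of predicted errors in Angstroms,
#'   either of length `target_length` (indexed by target position) or named
#'   by target position. `NA` means unmapped/unknown.
#' @param out_path Output path.
#' @export
write_annotated_pdb <- function(model, residue_errors, out_path) {
  L <- model$target_length
  err <- rep(NA_real_, L)
  if (!is.null(names(residue_errors))) {
    err[as.integer(names(residue_errors))] <- unname(residue_errors)
  } else if (length(residue_errors) == L) {
    err <- as.numeric(residue_errors)
  } else {
    abort_domain("residue_errors must be named by target position or have length target_length")
  }
  if (any(err < 0, na.rm = TRUE)) abort_domain("residue errors must be non-negative")
  res <- model$residues
  per_res <- vapply(seq_len(nrow(res)), function(i) {
    ti <- res$target_index[i]
    if (is.na(ti) || is.na(err[ti])) 99.99 else clamp(err[ti], 0, 99.99)
  }, numeric(1))
  b_atom <- per_res[match(model$atoms$res_key, res$res_key)]
  at <- model$atoms
  lines <- character(nrow(at))
  for (i in seq_len(nrow(at))) {
    if (!is.na(at$line[i])) {
      l <- at$line[i]
      substr(l, 61, 66) <- sprintf("%6.2f", b_atom[i])
      lines[i] <- l
    } else {
      r <- res[res$res_key == at$res_key[i], ]
      lines[i] <- format_atom_line(
        i, at$name[i], r$resname, model$chain %||% "A", r$resno,
        at$x[i], at$y[i], at$z[i], b_atom[i], at$element[i]
      )
    }
  }
  writeLines(c(sub("\\s+$", "", lines), "END"), out_path)
  invisible(out_path)
}
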