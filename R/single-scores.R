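#' Contact-distance agreement (CDA) parameters
#'
#' CDA measures how well the distances realised in a model agree with
#' sequence-predicted residue-residue contacts. A predicted contact is
#' considered when its probability reaches `min_probability` and the pair is
#' at least `min_sequence_separation` apart in sequence; it is satisfied
#' when the model's C-beta--C-beta distance (C-alpha for glycine) is within
#' `contact_distance_threshold`.
#'
#' @param contact_distance_threshold Satisfaction distance in Angstroms
#'   (default 8, the standard contact definition).
#' @param min_sequence_separation Minimum `|i - j|` (default 5).
#' @param min_probability Probability floor for considering a predicted
#'   contact (default 0.5).
#' @param neutral_score Score given to residues touching no considered
#'   contact (default 0.5).
#' @return A list of class `cda_params`.
#' @export
cda_params <- function(contact_distance_threshold = 8,
                       min_sequence_separation = 5,
                       min_probability = 0.5,
                       neutral_score = 0.5) {
  if (contact_distance_threshold <= 0) abort_domain("contact distance threshold must be positive")
  if (min_sequence_separation < 1) abort_domain("minimum sequence separation must be >= 1")
  if (min_probability < 0 || min_probability > 1) abort_domain("min_probability must lie in [0, 1]")
  structure(
    list(contact_distance_threshold = contact_distance_threshold,
         min_sequence_separation = min_sequence_separation,
         min_probability = min_probability,
         neutral_score = neutral_score),
    class = "cda_params"
  )
}

# C-beta coordinates per mapped residue (C-alpha for glycine; ideal
# reconstruction from N/CA/C when C-beta is absent), rownames = target pos.
cbeta_coords <- function(model) {
  res <- model$residues[!is.na(model$residues$target_index), , drop = FALSE]
  at <- model$atoms
  out <- matrix(NA_real_, nrow(res), 3, dimnames = list(res$target_index, NULL))
  for (k in seq_len(nrow(res))) {
    ra <- at[at$res_key == res$res_key[k], , drop = FALSE]
    get <- function(nm) {
      i <- match(nm, ra$name)
      if (is.na(i)) NULL else c(ra$x[i], ra$y[i], ra$z[i])
    }
    cb <- get("CB")
    if (is.null(cb)) {
      if (res$code[k] != "G") {
        n <- get("N"); ca <- get("CA"); cc <- get("C")
        cb <- if (!is.null(n) && !is.null(ca) && !is.null(cc)) {
          reconstruct_cbeta(n, ca, cc)
        } else {
          get("CA")
        }
      } else {
        cb <- get("CA")
      }
    }
    out[k, ] <- cb
  }
  out
}

#' Per-residue contact-distance agreement
#'
#' Each residue's score is the probability-weighted fraction of considered
#' predicted contacts touching it that the model satisfies:
#' `sum(p, satisfied) / sum(p, considered)`. Mapped residues touching no
#' considered contact take the neutral score; unmapped target positions are
#' missing. Instantiated three ways (CDA, CDA_DMP, CDA_SC) by swapping the
#' contact input.
#'
#' @param model A mapped `structure_model`.
#' @param contacts A [contact_prediction()].
#' @param params [cda_params()].
#' @return A [score_track()] over the target.
#' @export
cda_per_residue <- function(model, contacts, params = cda_params()) {
  L <- model$target_length
  cb <- cbeta_coords(model)
  mapped <- as.integer(rownames(cb))
  vals <- rep(NA_real_, L)
  vals[mapped] <- params$neutral_score
  cts <- tibble::as_tibble(contacts)
  cts <- cts[cts$p >= params$min_probability &
               abs(cts$i - cts$j) >= params$min_sequence_separation &
               cts$i %in% mapped & cts$j %in% mapped, , drop = FALSE]
  if (nrow(cts) == 0L) {
    rlang::warn("no considered contacts; CDA track is neutral for mapped residues")
    return(score_track(vals, method = attr(contacts, "source") %||% "cda"))
  }
  ci <- cb[as.character(cts$i), , drop = FALSE]
  cj <- cb[as.character(cts$j), , drop = FALSE]
  d <- sqrt(rowSums((ci - cj)^2))
  sat <- d <= params$contact_distance_threshold
  num <- den <- rep(0, L)
  for (k in seq_len(nrow(cts))) {
    for (r in c(cts$i[k], cts$j[k])) {
      den[r] <- den[r] + cts$p[k]
      if (sat[k]) num[r] <- num[r] + cts$p[k]
    }
  }
  touched <- which(den > 0)
  vals[touched] <- clamp(num[touched] / den[touched], 0, 1)
  score_track(vals, method = attr(contacts, "source") %||% "cda")
}

#' Secondary-structure assignment parameters
#'
#' Torsion-box 3-state assignment: residues whose phi/psi fall in the helix
#' box in runs of at least `min_run_helix` become H; residues in the strand
#' box in runs of at least `min_run_strand` become E; all else C.
#'
#' @param helix_phi,helix_psi,strand_phi Degree ranges `c(lo, hi)`.
#' @param strand_psi List of degree ranges (the strand psi region wraps
#'   around 180).
#' @param min_run_helix,min_run_strand Minimum run lengths (4 and 3).
#' @return A list of class `ssa_params`.
#' @export
ssa_params <- function(helix_phi = c(-120, -30), helix_psi = c(-80, -5),
                       strand_phi = c(-180, -45),
                       strand_psi = list(c(45, 180), c(-180, -170)),
                       min_run_helix = 4L, min_run_strand = 3L) {
  structure(
    list(helix_phi = helix_phi, helix_psi = helix_psi,
         strand_phi = strand_phi, strand_psi = strand_psi,
         min_run_helix = min_run_helix, min_run_strand = min_run_strand),
    class = "ssa_params"
  )
}

in_range <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]

#' Assign 3-state secondary structure from backbone torsions
#'
#' Computes phi/psi from backbone N, C-alpha, C atoms (torsions are only
#' defined across consecutively mapped residues) and applies the torsion
#' boxes of [ssa_params()]. At chain termini, where one of the two angles is
#' undefined, the defined angle alone must fall inside the box. Residues
#' lacking backbone atoms are coil.
#'
#' @param model A mapped `structure_model`.
#' @param params [ssa_params()].
#' @return A tibble with columns `pos`, `phi`, `psi`, `state` for every
#'   mapped residue.
#' @export
assign_secondary_structure <- function(model, params = ssa_params()) {
  res <- model$residues[!is.na(model$residues$target_index), , drop = FALSE]
  res <- res[order(res$target_index), , drop = FALSE]
  nres <- nrow(res)
  at <- model$atoms
  bb <- function(k, nm) {
    ra <- at[at$res_key == res$res_key[k], ]
    i <- match(nm, ra$name)
    if (is.na(i)) NULL else c(ra$x[i], ra$y[i], ra$z[i])
  }
  phi <- psi <- rep(NA_real_, nres)
  consec_prev <- c(FALSE, diff(res$target_index) == 1L)
  consec_next <- c(diff(res$target_index) == 1L, FALSE)
  for (k in seq_len(nres)) {
    n <- bb(k, "N"); ca <- bb(k, "CA"); cc <- bb(k, "C")
    if (is.null(n) || is.null(ca) || is.null(cc)) next
    if (consec_prev[k]) {
      cprev <- bb(k - 1L, "C")
      if (!is.null(cprev)) phi[k] <- dihedral(cprev, n, ca, cc)
    }
    if (consec_next[k]) {
      nnext <- bb(k + 1L, "N")
      if (!is.null(nnext)) psi[k] <- dihedral(n, ca, cc, nnext)
    }
  }
  box <- function(phi_ok, psi_ok) {
    # terminus rule: an undefined angle defers to the defined one
    both_na <- is.na(phi) & is.na(psi)
    ok <- ifelse(is.na(phi), psi_ok, ifelse(is.na(psi), phi_ok, phi_ok & psi_ok))
    ok & !both_na
  }
  phi_h <- in_range(phi, params$helix_phi); psi_h <- in_range(psi, params$helix_psi)
  phi_e <- in_range(phi, params$strand_phi)
  psi_e <- Reduce(`|`, lapply(params$strand_psi, function(r) in_range(psi, r)))
  cand_h <- box(phi_h, psi_h)
  cand_e <- box(phi_e, psi_e) & !cand_h
  state <- rep("C", nres)
  keep_runs <- function(cand, min_run) {
    r <- rle(cand)
    r$values <- r$values & r$lengths >= min_run
    inverse.rle(r)
  }
  state[keep_runs(cand_h, params$min_run_helix)] <- "H"
  state[keep_runs(cand_e, params$min_run_strand) & state == "C"] <- "E"
  tibble::tibble(pos = res$target_index, phi = phi, psi = psi, state = state)
}

#' Per-residue secondary-structure agreement (SSA)
#'
#' Scores each mapped residue with the predictor's probability of the state
#' the model actually realises (from [assign_secondary_structure()]): a pure
#' lookup, no further arithmetic. Unmapped positions are missing.
#'
#' @param model A mapped `structure_model`.
#' @param ss_pred An `ss_prediction` from [read_ss2()].
#' @param params [ssa_params()].
#' @return A [score_track()] over the target.
#' @export
ssa_per_residue <- function(model, ss_pred, params = ssa_params()) {
  obs <- assign_secondary_structure(model, params)
  L <- model$target_length
  vals <- rep(NA_real_, L)
  for (k in seq_len(nrow(obs))) {
    p <- obs$pos[k]
    row <- ss_pred[ss_pred$pos == p, , drop = FALSE]
    if (nrow(row) == 0L) next
    vals[p] <- switch(obs$state[k], H = row$p_h, E = row$p_e, C = row$p_c)
  }
  score_track(vals, method = "ssa")
}
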