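#' S-score parameters
#'
#' The S-score maps a per-residue C-alpha deviation `d` (Angstroms) to a
#' similarity `s = 1 / (1 + (d / d0)^2)` in (0, 1]; the inverse function
#' `d = d0 * sqrt(1/s - 1)` converts predicted similarities back to
#' Angstrom error estimates. The distance constant `d0` defaults to 3.5 A,
#' so `d = d0` maps to the midpoint `s = 0.5`.
#'
#' @param d0 Distance constant in Angstroms (> 0).
#' @return A list of class `sscore_params`.
#' @export
sscore_params <- function(d0 = 3.5) {
  stopifnot_scalar_number(d0, "d0")
  if (d0 <= 0) abort_domain("d0 must be positive")
  structure(list(d0 = d0), class = "sscore_params")
}

#' S-score similarity from distance, and back
#'
#' @param d Distance(s) in Angstroms, `d >= 0`.
#' @param s Similarity value(s) in (0, 1]; `s = 0` maps to `Inf`.
#' @param params [sscore_params()].
#' @return `s_from_d()`: similarities in (0, 1]. `d_from_s()`: distances in
#'   Angstroms.
#' @export
s_from_d <- function(d, params = sscore_params()) {
  if (any(d < 0, na.rm = TRUE)) abort_domain("distances must be non-negative")
  1 / (1 + (d / params$d0)^2)
}

#' @rdname s_from_d
#' @export
d_from_s <- function(s, params = sscore_params()) {
  if (any(s < 0 | s > 1, na.rm = TRUE)) abort_domain("similarities must lie in [0, 1]")
  out <- ifelse(s == 0, Inf, params$d0 * sqrt(1 / s - 1))
  out
}

#' lDDT parameters
#'
#' @param inclusion_radius Reference inter-atomic distances below this
#'   radius (Angstroms) define the eligible pairs (default 15).
#' @param thresholds Preservation tolerances in Angstroms (default
#'   0.5, 1, 2, 4), strictly positive and sorted.
#' @param atom_mode `"all"` (every non-hydrogen atom) or `"calpha"`.
#' @return A list of class `lddt_params`.
#' @export
lddt_params <- function(inclusion_radius = 15, thresholds = c(0.5, 1, 2, 4),
                        atom_mode = c("all", "calpha")) {
  atom_mode <- match.arg(atom_mode)
  thresholds <- sort(as.numeric(thresholds))
  if (any(thresholds <= 0)) abort_domain("lDDT thresholds must be strictly positive")
  if (inclusion_radius <= max(thresholds)) {
    abort_domain("inclusion radius must exceed the largest threshold")
  }
  structure(
    list(inclusion_radius = inclusion_radius, thresholds = thresholds,
         atom_mode = atom_mode),
    class = "lddt_params"
  )
}

# Shared mapped C-alpha coordinates of two models, ordered by target position.
shared_ca_coords <- function(modelA, modelB) {
  a <- atom_coords(modelA, "CA"); b <- atom_coords(modelB, "CA")
  pos <- intersect(rownames(a), rownames(b))
  pos <- pos[order(as.integer(pos))]
  list(pos = as.integer(pos), A = a[pos, , drop = FALSE], B = b[pos, , drop = FALSE])
}

#' Iterative superposition with per-residue S-scores
#'
#' Superposes `modelB` onto `modelA` over their shared target positions,
#' then iteratively refits on the well-modelled core (residues with
#' C-alpha deviation below `d0`), up to `max_iter` rounds or until the core
#' stabilises or would shrink below 3 residues. Among the iterates visited,
#' the fit maximising the mean per-residue S-score is kept.
#'
#' @param modelA,modelB `structure_model`s mapped to the same target.
#' @param params [sscore_params()]; `d0` doubles as the core cutoff.
#' @param max_iter Iteration cap (default 10).
#' @return A list with `superposition`, `scores` (named numeric of
#'   per-residue similarities over shared positions), `distances` (named
#'   deviations in Angstroms) and `positions`.
#' @export
iterative_superpose_sscore <- function(modelA, modelB, params = sscore_params(),
                                       max_iter = 10L) {
  sh <- shared_ca_coords(modelA, modelB)
  n <- length(sh$pos)
  if (n < 3L) abort_domain("fewer than 3 shared mapped residues; cannot superpose")
  core <- rep(TRUE, n)
  best <- NULL
  for (iter in seq_len(max_iter)) {
    fit <- kabsch_superpose(sh$A[core, , drop = FALSE], sh$B[core, , drop = FALSE])
    Bt <- apply_superposition(fit, sh$B)
    d <- sqrt(rowSums((sh$A - Bt)^2))
    s <- s_from_d(d, params)
    if (is.null(best) || mean(s) > best$mean_s) {
      fit$core_set <- sh$pos[core]
      best <- list(superposition = fit, scores = s, distances = d, mean_s = mean(s))
    }
    new_core <- d < params$d0
    if (sum(new_core) < 3L || identical(new_core, core)) break
    core <- new_core
  }
  names(best$scores) <- sh$pos
  names(best$distances) <- sh$pos
  list(
    superposition = best$superposition,
    scores = best$scores,
    distances = best$distances,
    positions = sh$pos
  )
}

#' Observed per-residue S-score track against a native structure
#'
#' @param model,native `structure_model`s mapped to the same target.
#' @param params [sscore_params()].
#' @return A [score_track()] over the target; positions absent from either
#'   structure are missing.
#' @export
observed_sscore_track <- function(model, native, params = sscore_params()) {
  res <- iterative_superpose_sscore(model, native, params)
  track_from_named(res$scores, model$target_length, method = "observed_sscore")
}

#' Per-residue lDDT of a model against a reference structure
#'
#' Superposition-free local score: reference atom pairs in different
#' residues with inter-atomic distance below the inclusion radius, both
#' atoms present in the model, are checked for preservation of their
#' distance within each tolerance threshold. A residue's score is the mean
#' over thresholds of the preserved fraction of eligible pairs touching it;
#' residues touching no eligible pair are missing.
#'
#' @param model,reference `structure_model`s mapped to the same target.
#' @param params [lddt_params()].
#' @return A [score_track()] over the target.
#' @export
lddt_per_residue <- function(model, reference, params = lddt_params()) {
  calpha <- params$atom_mode == "calpha"
  ra <- mapped_atom_table(reference, calpha_only = calpha)
  ma <- mapped_atom_table(model, calpha_only = calpha)
  common <- intersect(ra$key, ma$key)
  if (length(intersect(unique(ra$target_index), unique(ma$target_index))) == 0L) {
    abort_domain("model and reference share no mapped residues")
  }
  ra <- ra[match(common, ra$key), , drop = FALSE]
  ma <- ma[match(common, ma$key), , drop = FALSE]
  L <- reference$target_length
  if (length(common) < 2L) {
    return(score_track(rep(NA_real_, L), method = "lddt"))
  }
  rxyz <- as.matrix(ra[, c("x", "y", "z")])
  mxyz <- as.matrix(ma[, c("x", "y", "z")])
  dref <- as.matrix(stats::dist(rxyz))
  dmod <- as.matrix(stats::dist(mxyz))
  resi <- ra$target_index
  elig <- upper.tri(dref) & dref < params$inclusion_radius &
    outer(resi, resi, `!=`)
  pairs <- which(elig, arr.ind = TRUE)
  vals <- rep(NA_real_, L)
  if (nrow(pairs) > 0L) {
    delta <- abs(dmod[pairs] - dref[pairs])
    pres <- vapply(params$thresholds, function(t) delta < t, logical(nrow(pairs)))
    pres <- matrix(pres, nrow = nrow(pairs))
    ri <- resi[pairs[, 1]]; rj <- resi[pairs[, 2]]
    touched <- sort(unique(c(ri, rj)))
    for (r in touched) {
      touch <- ri == r | rj == r
      frac <- colSums(pres[touch, , drop = FALSE]) / sum(touch)
      vals[r] <- mean(frac)
    }
  }
  score_track(vals, method = "lddt")
}
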