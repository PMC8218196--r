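#' Reference model set
#'
#' Quasi-single scores compare the model under assessment against an
#' ensemble of alternative models built for the same target (in production
#' use, a tertiary-structure prediction pipeline generates on the order of
#' 135 such reference models; any user-supplied directory of PDB models
#' works).
#'
#' @param models List of `structure_model`s mapped to the same target.
#' @param nominal_size Expected production ensemble size (default 135);
#'   informational only.
#' @return A list of class `reference_set`.
#' @export
reference_set <- function(models, nominal_size = 135L) {
  if (length(models) < 1L) abort_domain("reference set needs at least one model")
  L <- unique(vapply(models, `[[`, integer(1), "target_length"))
  if (length(L) != 1L) abort_domain("reference models are mapped to different targets")
  structure(
    list(models = models, target_length = L, nominal_size = nominal_size),
    class = "reference_set"
  )
}

#' Read a directory of reference models
#'
#' @param dir Directory containing `.pdb` files.
#' @param target The [target_sequence()].
#' @return A [reference_set()].
#' @export
read_reference_set <- function(dir, target) {
  paths <- sort(list.files(dir, pattern = "\\.(pdb|ent)$", full.names = TRUE))
  if (length(paths) == 0L) abort_format("no PDB files found in '", dir, "'")
  reference_set(lapply(paths, read_model_pdb, target = target))
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d models, target length %d\n",
              length(x$models), x$target_length))
  invisible(x)
}

#' Superposition-free Q-score parameters
#'
#' @param sigma_exponent Exponent of the separation-dependent tolerance
#'   `sigma_ij = |i - j|^sigma_exponent` Angstroms (default 0.15, the
#'   Levitt-Gerstein Q convention).
#' @param min_separation Minimum sequence separation of compared pairs.
#' @return A list of class `q_params`.
#' @export
q_params <- function(sigma_exponent = 0.15, min_separation = 1L) {
  if (sigma_exponent <= 0) abort_domain("sigma_exponent must be positive")
  structure(list(sigma_exponent = sigma_exponent,
                 min_separation = as.integer(min_separation)),
            class = "q_params")
}

#' Disorder/B-factor agreement parameters
#'
#' @param fluct_midpoint RMSF (Angstroms) mapping to a disorder-likeness of
#'   0.5 (default 3.5).
#' @param fluct_steepness Logistic steepness (default 1).
#' @return A list of class `dba_params`.
#' @export
dba_params <- function(fluct_midpoint = 3.5, fluct_steepness = 1.0) {
  if (fluct_midpoint <= 0) abort_domain("fluct_midpoint must be positive")
  structure(list(fluct_midpoint = fluct_midpoint,
                 fluct_steepness = fluct_steepness),
            class = "dba_params")
}

# Apply f over usable reference models, averaging named per-position values.
average_over_refs <- function(model, refset, per_ref, min_shared, method) {
  L <- model$target_length
  ssum <- cnt <- rep(0, L)
  used <- 0L
  for (ref in refset$models) {
    sh <- shared_ca_coords(model, ref)
    if (length(sh$pos) < min_shared) {
      rlang::warn(sprintf(
        "reference model '%s' shares only %d residue(s) with '%s'; skipped",
        ref$model_id, length(sh$pos), model$model_id
      ))
      next
    }
    sc <- per_ref(ref, sh)
    idx <- as.integer(names(sc))
    keep <- !is.na(sc)
    ssum[idx[keep]] <- ssum[idx[keep]] + sc[keep]
    cnt[idx[keep]] <- cnt[idx[keep]] + 1L
    used <- used + 1L
  }
  if (used == 0L) abort_domain("no usable reference models (all skipped)")
  vals <- ifelse(cnt > 0, ssum / cnt, NA_real_)
  score_track(clamp(vals, 0, 1) * ifelse(cnt > 0, 1, NA_real_), method = method)
}

#' Per-residue MF5s score (superposition-based reference agreement)
#'
#' For each reference model, the input model is iteratively superposed and
#' per-residue S-scores computed; MF5s is the mean similarity over the
#' reference models sharing each residue. References sharing fewer than 3
#' residues are skipped with a warning.
#'
#' @param model A mapped `structure_model`.
#' @param refset A [reference_set()].
#' @param params [sscore_params()].
#' @return A [score_track()] over the target.
#' @export
mf5s_per_residue <- function(model, refset, params = sscore_params()) {
  average_over_refs(
    model, refset, min_shared = 3L, method = "mf5s",
    per_ref = function(ref, sh) {
      iterative_superpose_sscore(model, ref, params)$scores
    }
  )
}

#' Per-residue MFcQs score (superposition-free reference agreement)
#'
#' For each reference model, each residue's Q-score is the mean over shared
#' partner residues `j` (at least `min_separation` apart in sequence) of
#' `exp(-(d_ij^model - d_ij^ref)^2 / (2 sigma_ij^2))` with C-alpha distances
#' and `sigma_ij = |i - j|^sigma_exponent`; MFcQs is the mean over the
#' reference set.
#'
#' @param model A mapped `structure_model`.
#' @param refset A [reference_set()].
#' @param qparams [q_params()].
#' @return A [score_track()] over the target.
#' @export
mfcqs_per_residue <- function(model, refset, qparams = q_params()) {
  average_over_refs(
    model, refset, min_shared = 2L, method = "mfcqs",
    per_ref = function(ref, sh) {
      dm <- as.matrix(stats::dist(sh$A))
      dr <- as.matrix(stats::dist(sh$B))
      sep <- abs(outer(sh$pos, sh$pos, `-`))
      valid <- sep >= qparams$min_separation
      sig <- sep^qparams$sigma_exponent
      sig[!valid] <- 1  # avoid 0^x; masked below
      w <- exp(-(dm - dr)^2 / (2 * sig^2))
      w[!valid] <- NA
      q <- rowMeans(w, na.rm = TRUE)
      q[rowSums(valid) == 0] <- NA
      names(q) <- sh$pos
      q
    }
  )
}

#' Per-residue positional fluctuation (RMSF) of a reference set
#'
#' Every reference model is superposed onto the first via the iterative
#' S-score fit; the RMSF of each target position is the root-mean-square
#' deviation of its C-alpha position about the ensemble mean, over the
#' models covering it. Positions covered by fewer than 2 models are missing.
#'
#' @param refset A [reference_set()] with at least 2 models.
#' @param params [sscore_params()] controlling the superposition.
#' @return A tibble with columns `pos`, `rmsf`, `n_models`.
#' @export
rmsf_from_reference_set <- function(refset, params = sscore_params()) {
  if (length(refset$models) < 2L) abort_domain("RMSF requires at least 2 reference models")
  L <- refset$target_length
  frame <- refset$models[[1L]]
  coords <- vector("list", length(refset$models))
  coords[[1L]] <- atom_coords(frame, "CA")
  for (k in seq_along(refset$models)[-1L]) {
    ref <- refset$models[[k]]
    fit <- iterative_superpose_sscore(frame, ref, params)$superposition
    ck <- atom_coords(ref, "CA")
    coords[[k]] <- apply_superposition(fit, ck)
    rownames(coords[[k]]) <- rownames(ck)
  }
  rmsf <- rep(NA_real_, L)
  nmod <- integer(L)
  for (p in seq_len(L)) {
    pts <- do.call(rbind, lapply(coords, function(m) {
      i <- match(as.character(p), rownames(m))
      if (is.na(i)) NULL else m[i, , drop = FALSE]
    }))
    if (is.null(pts) || nrow(pts) < 2L) next
    mu <- colMeans(pts)
    rmsf[p] <- sqrt(mean(rowSums(sweep(pts, 2, mu)^2)))
    nmod[p] <- nrow(pts)
  }
  tibble::tibble(pos = seq_len(L), rmsf = rmsf, n_models = nmod)
}

#' Per-residue disorder/B-factor agreement (DBA)
#'
#' The reference ensemble's RMSF is squashed to a disorder-likeness
#' `f = logistic(steepness * (RMSF - midpoint))` (high fluctuation looks
#' disordered) and compared to the sequence-predicted disorder probability:
#' `DBA = 1 - |disorder - f|`. Note DBA depends only on the disorder
#' prediction and the reference ensemble, not on the model under assessment.
#'
#' @param disorder A `disorder_prediction`.
#' @param refset A [reference_set()].
#' @param params [dba_params()].
#' @param rmsf Optional precomputed [rmsf_from_reference_set()] result.
#' @return A [score_track()] over the target.
#' @export
dba_per_residue <- function(disorder, refset, params = dba_params(), rmsf = NULL) {
  rmsf <- rmsf %||% rmsf_from_reference_set(refset)
  f <- stats::plogis(params$fluct_steepness * (rmsf$rmsf - params$fluct_midpoint))
  vals <- 1 - abs(disorder$prob[rmsf$pos] - f)
  vals[is.na(rmsf$rmsf)] <- NA_real_
  score_track(vals, method = "dba")
}
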