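#' Synthetic benchmark specification
#'
#' The synthetic generator builds self-contained study material for the
#' whole pipeline: an ideal-geometry native structure, Gaussian-noise decoy
#' ladders, a perturbed reference model ensemble, and sequence-based
#' predictions (contacts, secondary structure, disorder) whose fidelity to
#' the native truth is controlled.
#'
#' @param L Target length (>= 8).
#' @param fold `"helix"`, `"extended"` or `"mixed"` (alternating runs).
#' @param noise_levels Coordinate noise standard deviations in Angstroms.
#' @param n_decoys Decoys per noise level.
#' @param seed Master seed; every derived artefact is deterministic in it.
#' @param contact_fidelity,ss_fidelity Probability mass a generated
#'   prediction places on the native truth, in \[0, 1\].
#' @param refset_size Number of reference models (production default 135;
#'   tests and examples use 5-10).
#' @param refset_noise Noise levels (Angstroms) cycled over the reference
#'   models, emulating an imperfect but usable reference ensemble.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(L = 40L, fold = c("mixed", "helix", "extended"),
                         noise_levels = c(0, 0.5, 1, 2, 4), n_decoys = 3L,
                         seed = 1L, contact_fidelity = 0.9, ss_fidelity = 0.9,
                         refset_size = 135L, refset_noise = c(0.5, 1, 2)) {
  fold <- match.arg(fold)
  if (L < 8L) abort_domain("synthetic targets need L >= 8")
  if (any(noise_levels < 0)) abort_domain("noise levels must be non-negative")
  if (contact_fidelity < 0 || contact_fidelity > 1 || ss_fidelity < 0 || ss_fidelity > 1) {
    abort_domain("fidelities must lie in [0, 1]")
  }
  structure(
    list(L = as.integer(L), fold = fold, noise_levels = noise_levels,
         n_decoys = as.integer(n_decoys), seed = as.integer(seed),
         contact_fidelity = contact_fidelity, ss_fidelity = ss_fidelity,
         refset_size = as.integer(refset_size), refset_noise = refset_noise),
    class = "fixture_spec"
  )
}

# Ideal backbone internal coordinates (Angstroms / degrees).
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  omega = 180
)

fold_torsions <- function(fold, L) {
  switch(
    fold,
    helix = list(phi = rep(-57, L), psi = rep(-47, L)),
    extended = list(phi = rep(-120, L), psi = rep(130, L)),
    mixed = {
      # alternating helix (8) and strand (7) runs joined by 2-residue type-I'
      # turns, so the chain folds back on itself and long-range contacts exist
      phi <- numeric(0); psi <- numeric(0)
      helix_next <- TRUE
      while (length(phi) < L) {
        if (length(phi) > 0L) {
          phi <- c(phi, 60, 90); psi <- c(psi, 30, 0)
        }
        n <- max(min(if (helix_next) 8L else 7L, L - length(phi)), 0L)
        if (helix_next) {
          phi <- c(phi, rep(-57, n)); psi <- c(psi, rep(-47, n))
        } else {
          phi <- c(phi, rep(-120, n)); psi <- c(psi, rep(130, n))
        }
        helix_next <- !helix_next
      }
      list(phi = phi[seq_len(L)], psi = psi[seq_len(L)])
    }
  )
}

#' Build an ideal-geometry native structure
#'
#' Constructs a backbone (N, C-alpha, C, C-beta) from ideal bond lengths and
#' angles with fold-specific phi/psi torsions (helix -57/-47, extended
#' -120/130, mixed alternating helix/strand runs joined by tight turns so
#' the chain packs against itself); consecutive C-alpha atoms sit about
#' 3.8 A apart. The sequence is sampled deterministically from the
#' seed (glycine and proline excluded so every residue carries a real
#' C-beta and the torsion boxes apply uniformly).
#'
#' @param spec A [fixture_spec()].
#' @return A list with `target` ([target_sequence()]) and `native`
#'   (`structure_model`).
#' @export
make_native <- function(spec) {
  L <- spec$L
  set.seed(spec$seed)
  seq_pool <- strsplit("ACDEFHIKLMNQRSTVWY", "")[[1]]
  residues <- sample(seq_pool, L, replace = TRUE)
  target <- target_sequence(residues, id = sprintf("synth_%s_L%d_s%d", spec$fold, L, spec$seed))
  tors <- fold_torsions(spec$fold, L)
  g <- BB_GEOM
  N <- CA <- C <- CB <- matrix(NA_real_, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(L)[-1L]) {
    N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                         g$c_n, g$ang_ca_c_n, tors$psi[i - 1L])
    CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                          g$n_ca, g$ang_c_n_ca, g$omega)
    C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                         g$ca_c, g$ang_n_ca_c, tors$phi[i])
  }
  for (i in seq_len(L)) CB[i, ] <- reconstruct_cbeta(N[i, ], CA[i, ], C[i, ])
  atoms <- tibble::tibble(
    res_key = rep(seq_len(L), each = 4L),
    name = rep(c("N", "CA", "C", "CB"), L),
    element = rep(c("N", "C", "C", "C"), L),
    x = as.vector(rbind(N[, 1], CA[, 1], C[, 1], CB[, 1])),
    y = as.vector(rbind(N[, 2], CA[, 2], C[, 2], CB[, 2])),
    z = as.vector(rbind(N[, 3], CA[, 3], C[, 3], CB[, 3])),
    b = 0, line = NA_character_
  )
  res3 <- names(AA_3TO1)[match(residues, AA_3TO1)]
  residues_tbl <- tibble::tibble(
    res_key = seq_len(L), resno = seq_len(L), code = residues,
    resname = res3, target_index = seq_len(L)
  )
  native <- new_structure_model("native", "A", atoms, residues_tbl, L)
  list(target = target, native = native)
}

#' Perturb a structure with isotropic Gaussian coordinate noise
#'
#' Adds independent zero-mean Gaussian noise (sd `sigma` Angstroms) to every
#' atom coordinate; `sigma = 0` returns an exact copy. Optionally truncates
#' `truncate` residues from the C-terminus to fabricate a partial model.
#'
#' @param native A `structure_model`.
#' @param sigma Noise standard deviation in Angstroms.
#' @param seed Integer seed.
#' @param truncate Number of C-terminal residues to drop (default 0).
#' @param model_id Identifier for the decoy.
#' @return A `structure_model`.
#' @export
perturb_model <- function(native, sigma, seed, truncate = 0L,
                          model_id = sprintf("decoy_s%g_r%d", sigma, seed)) {
  m <- native
  m$model_id <- model_id
  if (truncate > 0L) {
    keep_keys <- utils::head(m$residues$res_key, nrow(m$residues) - truncate)
    m$residues <- m$residues[m$residues$res_key %in% keep_keys, , drop = FALSE]
    m$atoms <- m$atoms[m$atoms$res_key %in% keep_keys, , drop = FALSE]
  }
  if (sigma > 0) {
    set.seed(seed)
    n <- nrow(m$atoms)
    m$atoms$x <- m$atoms$x + stats::rnorm(n, 0, sigma)
    m$atoms$y <- m$atoms$y + stats::rnorm(n, 0, sigma)
    m$atoms$z <- m$atoms$z + stats::rnorm(n, 0, sigma)
  }
  m$atoms$line <- NA_character_
  m
}

# Native C-beta contact pairs (|i-j| >= min_sep, d <= threshold).
native_contact_pairs <- function(native, threshold = 8, min_sep = 5L) {
  cb <- cbeta_coords(native)
  pos <- as.integer(rownames(cb))
  d <- as.matrix(stats::dist(cb))
  sep <- abs(outer(pos, pos, `-`))
  hit <- which(upper.tri(d) & d <= threshold & sep >= min_sep, arr.ind = TRUE)
  tibble::tibble(i = pos[hit[, 1]], j = pos[hit[, 2]])
}

#' Generate sequence-based predictions consistent with a native structure
#'
#' Contacts: each true native C-beta contact (<= 8 A, separation >= 5) is
#' emitted with probability `contact_fidelity` at p ~ U(0.7, 1.0); false
#' pairs are added at rate `1 - contact_fidelity` with p ~ U(0.5, 0.8).
#' Secondary structure: the native torsion-box assignment receives
#' probability mass `ss_fidelity`, the remainder split equally; the stated
#' state is the argmax. Disorder: one minus the logistic-normalised native
#' per-residue contact count, clipped to \[0, 1\].
#'
#' @param native A `structure_model` (the synthetic native).
#' @param spec A [fixture_spec()].
#' @param seed Seed (defaults to `spec$seed + 1`).
#' @param contact_fidelity Override of `spec$contact_fidelity`.
#' @return A list with `contacts` ([contact_prediction()]), `ss`
#'   (`ss_prediction`) and `disorder` (`disorder_prediction`).
#' @export
synth_predictions <- function(native, spec, seed = spec$seed + 1L,
                              contact_fidelity = spec$contact_fidelity) {
  set.seed(seed)
  L <- native$target_length
  true_pairs <- native_contact_pairs(native)
  n_true <- nrow(true_pairs)
  keep <- stats::runif(n_true) < contact_fidelity
  kept <- true_pairs[keep, , drop = FALSE]
  kept$p <- stats::runif(nrow(kept), 0.7, 1.0)
  n_false <- round((1 - contact_fidelity) * n_true)
  false_pairs <- tibble::tibble(i = integer(), j = integer(), p = numeric())
  if (n_false > 0L) {
    all_ij <- which(upper.tri(matrix(TRUE, L, L)), arr.ind = TRUE)
    cand <- tibble::tibble(i = all_ij[, 1], j = all_ij[, 2])
    cand <- cand[abs(cand$i - cand$j) >= 5L, , drop = FALSE]
    cand <- dplyr::anti_join(cand, true_pairs, by = c("i", "j"))
    pick <- cand[sample.int(nrow(cand), min(n_false, nrow(cand))), , drop = FALSE]
    pick$p <- stats::runif(nrow(pick), 0.5, 0.8)
    false_pairs <- pick
  }
  contacts <- contact_prediction(dplyr::bind_rows(kept, false_pairs), source = "cda")

  obs_ss <- assign_secondary_structure(native)
  state <- rep("C", L)
  state[obs_ss$pos] <- obs_ss$state
  fid <- spec$ss_fidelity
  rest <- (1 - fid) / 2
  pr <- matrix(rest, L, 3, dimnames = list(NULL, c("C", "H", "E")))
  for (i in seq_len(L)) pr[i, state[i]] <- fid
  stated <- colnames(pr)[max.col(pr, ties.method = "first")]
  ss <- tibble::tibble(
    pos = seq_len(L), aa = native$residues$code[seq_len(L)],
    state = stated, p_c = pr[, "C"], p_h = pr[, "H"], p_e = pr[, "E"]
  )
  class(ss) <- c("ss_prediction", class(ss))

  counts <- integer(L)
  for (k in seq_len(nrow(true_pairs))) {
    counts[true_pairs$i[k]] <- counts[true_pairs$i[k]] + 1L
    counts[true_pairs$j[k]] <- counts[true_pairs$j[k]] + 1L
  }
  sdc <- stats::sd(counts)
  z <- if (is.na(sdc) || sdc == 0) rep(0, L) else (counts - mean(counts)) / sdc
  disorder <- disorder_prediction(clamp(1 - stats::plogis(z), 0, 1))

  list(contacts = contacts, ss = ss, disorder = disorder)
}

# In-memory benchmark bundle: everything the pipeline consumes for one
# synthetic target, deterministic in spec$seed.
#' Generate a complete in-memory synthetic benchmark
#'
#' Builds the native, the decoy ladder (every noise level times
#' `n_decoys`, seeded), the perturbed reference ensemble, three contact
#' predictions of decreasing fidelity (standing in for distinct contact
#' predictors), secondary-structure and disorder predictions, observed
#' S-score and lDDT tracks for every decoy against the native, and
#' synthetic stand-ins for the six external single-model score tracks
#' (noise-corrupted copies of the observed S-score).
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `synthetic_benchmark`.
#' @export
generate_benchmark <- function(spec) {
  nat <- make_native(spec)
  target <- nat$target; native <- nat$native
  base <- spec$seed * 1000L

  decoys <- list()
  meta <- list()
  k <- 0L
  for (sig in spec$noise_levels) {
    for (r in seq_len(spec$n_decoys)) {
      k <- k + 1L
      id <- sprintf("decoy_%02d_s%s_r%d", k, format(sig), r)
      decoys[[id]] <- perturb_model(native, sig, seed = base + k, model_id = id)
      meta[[id]] <- list(sigma = sig, rep = r, seed = base + k)
    }
  }

  refs <- list()
  for (j in seq_len(spec$refset_size)) {
    sig <- spec$refset_noise[((j - 1L) %% length(spec$refset_noise)) + 1L]
    refs[[j]] <- perturb_model(native, sig, seed = base + 500L + j,
                               model_id = sprintf("ref_%03d", j))
  }
  refset <- reference_set(refs)

  preds <- synth_predictions(native, spec, seed = base + 900L)
  contacts <- list(cda = preds$contacts)
  for (nm in c("cda_dmp", "cda_sc")) {
    drop <- if (nm == "cda_dmp") 0.05 else 0.1
    p2 <- synth_predictions(native, spec, seed = base + 901L + (nm == "cda_sc"),
                            contact_fidelity = max(spec$contact_fidelity - drop, 0))
    ct <- p2$contacts
    attr(ct, "source") <- nm
    contacts[[nm]] <- ct
  }

  observed_s <- observed_l <- list()
  external <- list()
  ext_methods <- c(proq2 = 0.08, proq2d = 0.08, proq3d = 0.06, proq4 = 0.1,
                   voromqa = 0.12, resq = 0.1)
  e <- 0L
  for (id in names(decoys)) {
    observed_s[[id]] <- observed_sscore_track(decoys[[id]], native)
    observed_l[[id]] <- lddt_per_residue(decoys[[id]], native)
    obs <- track_values(observed_s[[id]])
    external[[id]] <- list()
    for (m in names(ext_methods)) {
      e <- e + 1L
      set.seed(base + 2000L + e)
      v <- clamp(obs + stats::rnorm(length(obs), 0, ext_methods[[m]]), 0.001, 1)
      external[[id]][[m]] <- score_track(v, method = m, provenance = "ingested")
    }
  }

  structure(
    list(spec = spec, target = target, native = native,
         decoys = decoys, decoy_meta = meta, refset = refset,
         contacts = contacts, ss = preds$ss, disorder = preds$disorder,
         observed_sscore = observed_s, observed_lddt = observed_l,
         external = external),
    class = "synthetic_benchmark"
  )
}

#' Write a synthetic benchmark bundle to disk
#'
#' Writes everything the command-line interface consumes: target FASTA,
#' native and decoy PDBs, reference-set PDBs, three RR contact files, an
#' ss2-style secondary-structure table, a disorder table, observed S-score
#' and lDDT tracks per decoy, synthetic external score tracks per decoy
#' (the template-based error stand-in, `resq`, is written in Angstroms to
#' exercise distance ingestion), and a JSON manifest recording seeds and
#' parameters.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return The in-memory [generate_benchmark()] bundle, invisibly.
#' @export
make_benchmark <- function(spec, dir) {
  bundle <- generate_benchmark(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("decoys", "refset", "observed", "external")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }
  writeLines(c(paste0(">", bundle$target$id),
               paste(bundle$target$residues, collapse = "")),
             file.path(dir, "target.fasta"))
  write_model_pdb(bundle$native, file.path(dir, "native.pdb"))
  for (id in names(bundle$decoys)) {
    write_model_pdb(bundle$decoys[[id]], file.path(dir, "decoys", paste0(id, ".pdb")))
  }
  for (ref in bundle$refset$models) {
    write_model_pdb(ref, file.path(dir, "refset", paste0(ref$model_id, ".pdb")))
  }
  for (src in names(bundle$contacts)) {
    ct <- bundle$contacts[[src]]
    writeLines(
      c("PFRMAT RR", paste("TARGET", bundle$target$id),
        sprintf("%d %d 0 8 %.4f", ct$i, ct$j, ct$p), "END"),
      file.path(dir, paste0(src, ".rr"))
    )
  }
  ss <- bundle$ss
  writeLines(sprintf("%d %s %s %.3f %.3f %.3f", ss$pos, ss$aa, ss$state,
                     ss$p_c, ss$p_h, ss$p_e),
             file.path(dir, "target.ss2"))
  writeLines(sprintf("%d %.4f", bundle$disorder$pos, bundle$disorder$prob),
             file.path(dir, "target.diso"))
  write_track_tsv <- function(track, path, as_distance = FALSE) {
    v <- track_values(track)
    keep <- !is.na(v)
    vals <- if (as_distance) pmin(d_from_s(v[keep]), 99.99) else v[keep]
    writeLines(sprintf("%d %.6f", which(keep), vals), path)
  }
  for (id in names(bundle$decoys)) {
    write_track_tsv(bundle$observed_sscore[[id]],
                    file.path(dir, "observed", paste0(id, ".sscore.tsv")))
    write_track_tsv(bundle$observed_lddt[[id]],
                    file.path(dir, "observed", paste0(id, ".lddt.tsv")))
    for (m in names(bundle$external[[id]])) {
      write_track_tsv(bundle$external[[id]][[m]],
                      file.path(dir, "external", paste0(id, ".", m, ".tsv")),
                      as_distance = (m == "resq"))
    }
  }
  manifest <- list(
    format = "modfoldkit_benchmark_v1",
    spec = unclass(bundle$spec),
    target_id = bundle$target$id,
    decoys = lapply(bundle$decoy_meta, function(m) m[c("sigma", "rep", "seed")])
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(bundle)
}

#' Assemble combiner training data from synthetic benchmarks
#'
#' Computes the 13 per-residue score tracks for every decoy of every bundle
#' and pairs the windowed features with the observed per-residue targets
#' (S-score or lDDT versus the native); positions with missing targets are
#' dropped.
#'
#' @param bundles A `synthetic_benchmark` or list of them.
#' @param target_metric `"sscore"` or `"lddt"`.
#' @param config A [combiner_config()].
#' @return A list with `features` (matrix) and `targets` (vector).
#' @export
collect_training_data <- function(bundles, target_metric = c("sscore", "lddt"),
                                  config = combiner_config()) {
  target_metric <- match.arg(target_metric)
  if (inherits(bundles, "synthetic_benchmark")) bundles <- list(bundles)
  feats <- list(); targs <- list()
  for (b in bundles) {
    rmsf <- rmsf_from_reference_set(b$refset)
    dba_track <- dba_per_residue(b$disorder, b$refset, rmsf = rmsf)
    for (id in names(b$decoys)) {
      tracks <- compute_model_tracks(
        b$decoys[[id]], b$contacts, b$ss, dba_track, b$refset,
        config = config, external_tracks = b$external[[id]]
      )
      X <- build_window_features(tracks, config)
      y <- track_values(
        if (target_metric == "sscore") b$observed_sscore[[id]] else b$observed_lddt[[id]]
      )
      keep <- !is.na(y)
      feats[[length(feats) + 1L]] <- X[keep, , drop = FALSE]
      targs[[length(targs) + 1L]] <- y[keep]
    }
  }
  list(features = do.call(rbind, feats), targets = unlist(targs))
}
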