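# Shared fixtures, built in code and cached per test session.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

# Minimal C-alpha-only model with given x coordinates on a line (y = z = 0)
# or an explicit n x 3 coordinate matrix; target positions 1..n.
toy_ca_model <- function(coords, model_id = "toy", target_index = NULL) {
  if (is.null(dim(coords))) coords <- cbind(coords, 0, 0)
  n <- nrow(coords)
  target_index <- target_index %||% seq_len(n)
  atoms <- tibble::tibble(
    res_key = seq_len(n), name = "CA", element = "C",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    b = 0, line = NA_character_
  )
  res <- tibble::tibble(
    res_key = seq_len(n), resno = seq_len(n), code = "A", resname = "ALA",
    target_index = as.integer(target_index)
  )
  modfoldkit:::new_structure_model(model_id, "A", atoms, res, max(target_index))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Text of a minimal PDB file for a sequence of residues with given CA coords.
toy_pdb_text <- function(codes, coords, chain = "A", resno = seq_along(codes)) {
  aa3 <- names(modfoldkit:::AA_3TO1)[match(codes, modfoldkit:::AA_3TO1)]
  vapply(seq_along(codes), function(i) {
    sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, aa3[i], chain, resno[i],
            coords[i, 1], coords[i, 2], coords[i, 3], 1.0, 0.0)
  }, character(1))
}

# Displace all atoms of one target position of a synthetic model by dx.
displace_residue <- function(model, target_pos, dx = c(0, 0, 0)) {
  rk <- model$residues$res_key[match(target_pos, model$residues$target_index)]
  i <- model$atoms$res_key == rk
  model$atoms$x[i] <- model$atoms$x[i] + dx[1]
  model$atoms$y[i] <- model$atoms$y[i] + dx[2]
  model$atoms$z[i] <- model$atoms$z[i] + dx[3]
  model$atoms$line <- NA_character_
  model
}

# Study-condition benchmark shared across test files (L = 40 mixed fold,
# noise ladder 0/0.5/1/2/4 A x 3 decoys, reference set of 8).
study_benchmark <- function(seed = 11) {
  cached(paste0("bench", seed),
         generate_benchmark(fixture_spec(L = 40, seed = seed, refset_size = 8)))
}

# Combiner pair trained on four synthetic targets (study conditions).
trained_combiners <- function() {
  cached("combiners", {
    bundles <- lapply(21:24, function(s) {
      generate_benchmark(fixture_spec(L = 40, seed = s, refset_size = 8))
    })
    cfg_s <- combiner_config(target_metric = "sscore", seed = 7)
    cfg_l <- combiner_config(target_metric = "lddt", seed = 7)
    td_s <- collect_training_data(bundles, "sscore", cfg_s)
    td_l <- collect_training_data(bundles, "lddt", cfg_l)
    list(
      sscore = mlp_train(td_s$features, td_s$targets, cfg_s),
      lddt = mlp_train(td_l$features, td_l$targets, cfg_l)
    )
  })
}

# Held-out benchmark never used in training.
heldout_benchmark <- function() {
  cached("heldout",
         generate_benchmark(fixture_spec(L = 40, seed = 25, refset_size = 8)))
}

# Full pipeline result on the held-out benchmark.
heldout_result <- function() {
  cached("heldout_result", {
    hb <- heldout_benchmark()
    cb <- trained_combiners()
    suppressWarnings(score_models(
      hb$target, hb$decoys, hb$contacts, hb$ss, hb$disorder, hb$refset,
      cb$sscore, cb$lddt, external_tracks = hb$external
    ))
  })
}

decoy_sigmas <- function(bundle) {
  vapply(names(bundle$decoys), function(id) bundle$decoy_meta[[id]]$sigma,
         numeric(1))
}

# A simple constant-value set of 13 tracks for combiner plumbing tests.
constant_tracks <- function(L, value = 1, config = combiner_config()) {
  tr <- lapply(config$methods, function(m) score_track(rep(value, L), method = m))
  stats::setNames(tr, config$methods)
}
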