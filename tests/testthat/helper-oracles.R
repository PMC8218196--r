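# Independent brute-force oracles, deliberately written as plain double loops
# so they share no code with the package implementations they check.

# Per-residue lDDT by direct enumeration over atom pairs and thresholds.
# atoms: data frame with columns res (residue id), name, x, y, z for the
# reference; model_atoms likewise for the model.
oracle_lddt <- function(ref_atoms, model_atoms, L,
                        r0 = 15, thresholds = c(0.5, 1, 2, 4)) {
  key <- function(df) paste(df$res, df$name)
  mk <- key(model_atoms)
  scores <- rep(NA_real_, L)
  for (r in seq_len(L)) {
    per_thr <- numeric(0)
    for (t in thresholds) {
      n_elig <- 0L; n_pres <- 0L
      for (a in seq_len(nrow(ref_atoms))) {
        for (b in seq_len(nrow(ref_atoms))) {
          if (b <= a) next
          if (ref_atoms$res[a] == ref_atoms$res[b]) next
          if (ref_atoms$res[a] != r && ref_atoms$res[b] != r) next
          ka <- paste(ref_atoms$res[a], ref_atoms$name[a])
          kb <- paste(ref_atoms$res[b], ref_atoms$name[b])
          ia <- match(ka, mk); ib <- match(kb, mk)
          if (is.na(ia) || is.na(ib)) next
          dref <- sqrt(sum((ref_atoms[a, c("x", "y", "z")] -
                              ref_atoms[b, c("x", "y", "z")])^2))
          if (dref >= r0) next
          n_elig <- n_elig + 1L
          dmod <- sqrt(sum((model_atoms[ia, c("x", "y", "z")] -
                              model_atoms[ib, c("x", "y", "z")])^2))
          if (abs(dmod - dref) < t) n_pres <- n_pres + 1L
        }
      }
      if (n_elig > 0L) per_thr <- c(per_thr, n_pres / n_elig)
    }
    if (length(per_thr) == length(thresholds)) scores[r] <- mean(per_thr)
  }
  scores
}

atoms_of <- function(model) {
  res <- model$residues
  ti <- res$target_index[match(model$atoms$res_key, res$res_key)]
  data.frame(res = ti, name = model$atoms$name,
             x = model$atoms$x, y = model$atoms$y, z = model$atoms$z)[!is.na(ti), ]
}

# Superposition-free Q-score (one reference) by direct double loop.
oracle_q <- function(ca_model, ca_ref, pos, sigma_exponent = 0.15, min_sep = 1) {
  n <- length(pos)
  q <- rep(NA_real_, n)
  for (a in seq_len(n)) {
    acc <- numeric(0)
    for (b in seq_len(n)) {
      if (abs(pos[a] - pos[b]) < min_sep) next
      dm <- sqrt(sum((ca_model[a, ] - ca_model[b, ])^2))
      dr <- sqrt(sum((ca_ref[a, ] - ca_ref[b, ])^2))
      sig <- abs(pos[a] - pos[b])^sigma_exponent
      acc <- c(acc, exp(-(dm - dr)^2 / (2 * sig^2)))
    }
    if (length(acc) > 0L) q[a] <- mean(acc)
  }
  q
}

# Random compact-ish C-alpha cloud for toy comparisons.
random_toy_coords <- function(n, spread = 6) {
  matrix(stats::runif(n * 3, -spread, spread), n, 3)
}
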