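test_that("S-score and its inverse agree with the defining formula", {
  p <- sscore_params()
  expect_equal(s_from_d(0, p), 1)
  expect_equal(d_from_s(1, p), 0)
  expect_equal(s_from_d(3.5, p), 0.5)   # d = d0 forces the midpoint
  expect_equal(d_from_s(0.2, p), 7.0)   # 3.5 * sqrt(1/0.2 - 1) = 3.5 * 2
  expect_equal(d_from_s(0, p), Inf)
  expect_error(d_from_s(1.5, p), class = "modfold_domain_error")
  expect_error(s_from_d(-1, p), class = "modfold_domain_error")
  # round trip to 1e-10 across the working range
  d <- seq(0, 50, by = 0.25)
  expect_lt(max(abs(d_from_s(s_from_d(d, p), p) - d)), 1e-10)
})

test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(42)
  A <- random_toy_coords(12)
  # pure translation: translation recovered in B -> A convention
  B <- sweep(A, 2, c(5, 0, 0), `+`)
  sp <- kabsch_superpose(A, B)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$translation, c(-5, 0, 0), tolerance = 1e-8)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)
  # 90 degree rotation about z
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ac <- sweep(A, 2, colMeans(A))
  B2 <- Ac %*% t(Rz)
  sp2 <- kabsch_superpose(Ac, B2)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-6)
  expect_equal(B2 %*% sp2$rotation, Ac, tolerance = 1e-6)
  # identity
  sp3 <- kabsch_superpose(A, A)
  expect_equal(sp3$rotation, diag(3), tolerance = 1e-8)
  expect_equal(sp3$translation, c(0, 0, 0), tolerance = 1e-8)
  # rotation is orthonormal with det +1
  expect_equal(crossprod(sp2$rotation), diag(3), tolerance = 1e-8)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-8)
  # degenerate inputs
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "3 paired points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch fit matches bio3d and beats random rigid transforms", {
  skip_if_not_installed("bio3d")
  set.seed(7)
  A <- random_toy_coords(15)
  B <- A + matrix(rnorm(45, 0, 0.8), 15, 3)
  sp <- kabsch_superpose(A, B)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(A)), mobile = as.vector(t(B)))
  )
  rmsd_bio3d <- sqrt(mean(rowSums((A - matrix(fitted, ncol = 3, byrow = TRUE))^2)))
  expect_equal(sp$rmsd, rmsd_bio3d, tolerance = 1e-6)
  # optimality spot-check against 100 random rigid placements
  for (k in 1:100) {
    Q <- modfoldkit:::random_rotation()
    t0 <- rnorm(3, 0, 3)
    rmsd_k <- sqrt(mean(rowSums((A - sweep(B %*% Q, 2, t0, `+`))^2)))
    expect_gte(rmsd_k, sp$rmsd - 1e-9)
  }
})

test_that("iterative superposition scores outliers without disturbing the core", {
  nat <- make_native(fixture_spec(L = 12, fold = "helix", seed = 2))$native
  # self comparison: all similarities 1
  r0 <- iterative_superpose_sscore(nat, nat)
  expect_equal(unname(r0$scores), rep(1, 12), tolerance = 1e-12)
  # one residue displaced 7 A: that residue scores 0.2, the rest 1
  m <- displace_residue(nat, 6, c(7, 0, 0))
  r <- iterative_superpose_sscore(nat, m)
  expect_equal(unname(r$scores["6"]), 0.2, tolerance = 1e-9)
  expect_equal(unname(r$scores[setdiff(names(r$scores), "6")]), rep(1, 11),
               tolerance = 1e-9)
  # scores are the S-score of the post-fit deviations, exactly
  m2 <- displace_residue(nat, 6, c(3.5, 0, 0))
  r2 <- iterative_superpose_sscore(nat, m2)
  expect_equal(unname(r2$scores), unname(s_from_d(r2$distances)), tolerance = 1e-12)
  # a residue left 3.5 A from its reference position after the fit scores 0.5
  expect_equal(unname(s_from_d(3.5)), 0.5)
  # unrelated folds score below self-comparison
  set.seed(5)
  other <- toy_ca_model(random_toy_coords(12))
  helix_ca <- toy_ca_model(atom_coords(nat, "CA"))
  r3 <- iterative_superpose_sscore(helix_ca, other)
  expect_lt(mean(r3$scores), 1)
  expect_error(iterative_superpose_sscore(toy_ca_model(random_toy_coords(2)),
                                          toy_ca_model(random_toy_coords(2))),
               "fewer than 3")
})

test_that("observed S-score track is 1 for rigid copies and penalises displacement", {
  nat <- make_native(fixture_spec(L = 15, fold = "mixed", seed = 3))$native
  tr <- observed_sscore_track(nat, nat)
  expect_equal(track_values(tr), rep(1, 15), tolerance = 1e-12)
  set.seed(9)
  moved <- modfoldkit:::transform_model(nat, modfoldkit:::random_rotation(), c(4, -7, 2))
  tr2 <- observed_sscore_track(moved, nat)
  expect_equal(track_values(tr2), rep(1, 15), tolerance = 1e-8)
})

test_that("lDDT matches the hand-enumerated collinear toy", {
  ref <- toy_ca_model(c(0, 4, 8))
  mod <- toy_ca_model(c(0, 4, 9.5))
  v <- track_values(lddt_per_residue(mod, ref))
  expect_equal(v, c(0.75, 0.75, 0.5))
  # self comparison: all 1
  expect_equal(track_values(lddt_per_residue(ref, ref)), rep(1, 3))
  # model missing residue 3: residues 1,2 scored on their remaining pair
  mod2 <- toy_ca_model(c(0, 4), target_index = 1:2)
  mod2$target_length <- 3L
  v2 <- track_values(lddt_per_residue(mod2, ref))
  expect_equal(v2, c(1, 1, NA_real_))
})

test_that("lDDT equals an independent brute-force oracle on random toys", {
  set.seed(101)
  for (k in 1:200) {
    n <- sample(3:10, 1)
    ref <- toy_ca_model(random_toy_coords(n))
    mod <- toy_ca_model(random_toy_coords(n) * 0.2 + atom_coords(ref, "CA") * 0.8)
    got <- track_values(lddt_per_residue(mod, ref))
    want <- oracle_lddt(atoms_of(ref), atoms_of(mod), n)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("lDDT with all backbone atoms equals the oracle on structured toys", {
  nat <- make_native(fixture_spec(L = 10, fold = "mixed", seed = 4))$native
  dec <- perturb_model(nat, 1.0, seed = 5)
  got <- track_values(lddt_per_residue(dec, nat))
  want <- oracle_lddt(atoms_of(nat), atoms_of(dec), 10)
  expect_equal(got, want, tolerance = 1e-12)
  # calpha mode also agrees with a CA-only oracle
  got_ca <- track_values(lddt_per_residue(dec, nat, lddt_params(atom_mode = "calpha")))
  ref_ca <- atoms_of(nat); ref_ca <- ref_ca[ref_ca$name == "CA", ]
  mod_ca <- atoms_of(dec); mod_ca <- mod_ca[mod_ca$name == "CA", ]
  expect_equal(got_ca, oracle_lddt(ref_ca, mod_ca, 10), tolerance = 1e-12)
})

test_that("lDDT and post-superposition S-scores are rigid-motion invariant", {
  nat <- make_native(fixture_spec(L = 12, fold = "mixed", seed = 6))$native
  dec <- perturb_model(nat, 1.5, seed = 7)
  base_l <- track_values(lddt_per_residue(dec, nat))
  base_s <- track_values(observed_sscore_track(dec, nat))
  set.seed(8)
  for (k in 1:20) {
    moved <- modfoldkit:::transform_model(dec, modfoldkit:::random_rotation(),
                                          rnorm(3, 0, 10))
    expect_equal(track_values(lddt_per_residue(moved, nat)), base_l,
                 tolerance = 1e-8)
    expect_equal(track_values(observed_sscore_track(moved, nat)), base_s,
                 tolerance = 1e-6)
  }
})

test_that("lDDT parameter validation enforces radius and threshold invariants", {
  expect_error(lddt_params(inclusion_radius = 3), "exceed")
  expect_error(lddt_params(thresholds = c(-1, 2)), "positive")
})
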