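test_that("MF5s averages per-reference S-scores, with self and rigid copies at 1", {
  nat <- make_native(fixture_spec(L = 12, fold = "helix", seed = 2))$native
  # refset = the model itself
  expect_equal(track_values(mf5s_per_residue(nat, reference_set(list(nat)))),
               rep(1, 12), tolerance = 1e-12)
  # refset = two rigid-transformed copies
  set.seed(12)
  refs <- lapply(1:2, function(k) {
    modfoldkit:::transform_model(nat, modfoldkit:::random_rotation(), rnorm(3, 0, 8))
  })
  expect_equal(track_values(mf5s_per_residue(nat, reference_set(refs))),
               rep(1, 12), tolerance = 1e-8)
  # identical copy + copy with residue 6 displaced 7 A -> residue 6 = 0.6
  moved <- displace_residue(nat, 6, c(7, 0, 0))
  v <- track_values(mf5s_per_residue(nat, reference_set(list(nat, moved))))
  expect_equal(v[6], (1 + 0.2) / 2, tolerance = 1e-8)
  expect_equal(v[-6], rep(1, 11), tolerance = 1e-8)
})

test_that("MFcQs matches the hand toy and a brute-force oracle", {
  # 3-residue toy: pair (1,3) differs by exactly sigma_13 = 2^0.15
  sig13 <- 2^0.15
  ref <- toy_ca_model(c(0, 4, 8))
  mod <- toy_ca_model(rbind(c(0, 0, 0), c(4, 0, 0), c(8 + sig13, 0, 0)))
  v <- track_values(mfcqs_per_residue(mod, reference_set(list(ref))))
  # residue 1 partners: j=2 (|d|=0 -> 1), j=3 (exp(-1/2))
  expect_equal(v[1], (1 + exp(-0.5)) / 2, tolerance = 1e-10)
  expect_equal(v[3], (exp(-0.5) + exp(-(sig13^2) / 2)) / 2, tolerance = 1e-10)
  # oracle agreement on random toys up to 10 residues
  set.seed(55)
  for (k in 1:50) {
    n <- sample(3:10, 1)
    refk <- toy_ca_model(random_toy_coords(n))
    modk <- toy_ca_model(atom_coords(refk, "CA") + matrix(rnorm(n * 3, 0, 1), n, 3))
    got <- track_values(mfcqs_per_residue(modk, reference_set(list(refk))))
    want <- oracle_q(atom_coords(modk, "CA"), atom_coords(refk, "CA"), seq_len(n))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("MFcQs is invariant under rigid transforms of model or reference", {
  b <- study_benchmark()
  dec <- b$decoys[[5]]
  base <- track_values(mfcqs_per_residue(dec, b$refset))
  set.seed(77)
  moved <- modfoldkit:::transform_model(dec, modfoldkit:::random_rotation(), rnorm(3, 0, 15))
  expect_equal(track_values(mfcqs_per_residue(moved, b$refset)), base,
               tolerance = 1e-10)
})

test_that("reference-set RMSF captures per-residue spread after superposition", {
  nat <- make_native(fixture_spec(L = 12, fold = "helix", seed = 4))$native
  # identical copies -> RMSF 0
  r0 <- rmsf_from_reference_set(reference_set(list(nat, nat)))
  expect_equal(r0$rmsf, rep(0, 12), tolerance = 1e-10)
  # rigid-transformed copies -> RMSF 0 (superposition removes the motion)
  set.seed(21)
  moved <- modfoldkit:::transform_model(nat, modfoldkit:::random_rotation(), rnorm(3, 0, 6))
  r1 <- rmsf_from_reference_set(reference_set(list(nat, moved)))
  expect_equal(r1$rmsf, rep(0, 12), tolerance = 1e-7)
  # residue 6 differing by 7 A post-fit (outside the fitting core, so the
  # superposition is untouched): deviations +-3.5 A about the two-point mean
  shifted <- displace_residue(nat, 6, c(7, 0, 0))
  r2 <- rmsf_from_reference_set(reference_set(list(nat, shifted)))
  expect_equal(r2$rmsf[6], 3.5, tolerance = 1e-6)
  expect_equal(r2$rmsf[-6], rep(0, 11), tolerance = 1e-6)
  expect_error(rmsf_from_reference_set(reference_set(list(nat))), "at least 2")
})

test_that("DBA rewards agreement between predicted disorder and fluctuation", {
  nat <- make_native(fixture_spec(L = 12, fold = "helix", seed = 5))$native
  shifted <- displace_residue(nat, 6, c(7, 0, 0))
  refset <- reference_set(list(nat, shifted))
  rmsf <- rmsf_from_reference_set(refset)
  # agreement at the logistic midpoint: rmsf = midpoint, disorder = 0.5 -> DBA 1
  pars <- dba_params(fluct_midpoint = rmsf$rmsf[6])
  diso <- disorder_prediction(rep(0.5, 12))
  v <- track_values(dba_per_residue(diso, refset, pars, rmsf = rmsf))
  expect_equal(v[6], 1.0, tolerance = 1e-9)
  # same midpoint but disorder 0.9 -> 1 - |0.9 - 0.5| = 0.6
  diso9 <- disorder_prediction(rep(0.9, 12))
  v9 <- track_values(dba_per_residue(diso9, refset, pars, rmsf = rmsf))
  expect_equal(v9[6], 0.6, tolerance = 1e-9)
  # rigid region with zero predicted disorder scores near 1
  pars2 <- dba_params()
  diso0 <- disorder_prediction(rep(0, 12))
  v0 <- track_values(dba_per_residue(diso0, refset, pars2, rmsf = rmsf))
  expect_gt(min(v0[-6]), 0.95)
  # DBA in [0,1] wherever defined; equality with 1 iff disorder == f
  expect_true(all(v0 >= 0 & v0 <= 1, na.rm = TRUE))
})

test_that("external score tracks ingest with range checks and distance conversion", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1 0.9", "2 0.4"), f)
  tr <- ingest_external_track(f, "proq2", L = 3)
  expect_equal(track_values(tr), c(0.9, 0.4, NA))
  expect_equal(attr(tr, "provenance"), "ingested")

  writeLines("1 3.5", f)
  expect_error(ingest_external_track(f, "resq", L = 3), "as_distance")
  tr2 <- ingest_external_track(f, "resq", L = 3, as_distance = TRUE)
  expect_equal(track_values(tr2)[1], 0.5)  # s_from_d(3.5) at d0 = 3.5

  writeLines("5 0.9", f)
  expect_error(ingest_external_track(f, "x", L = 3), "outside")
})

test_that("quasi-single scores of rigid-copy reference sets are identically 1", {
  nat <- make_native(fixture_spec(L = 10, fold = "mixed", seed = 6))$native
  set.seed(99)
  refs <- lapply(1:3, function(k) {
    modfoldkit:::transform_model(nat, modfoldkit:::random_rotation(), rnorm(3, 0, 10))
  })
  rs <- reference_set(refs)
  expect_equal(track_values(mf5s_per_residue(nat, rs)), rep(1, 10), tolerance = 1e-8)
  expect_equal(track_values(mfcqs_per_residue(nat, rs)), rep(1, 10), tolerance = 1e-8)
})
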