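test_that("FASTA targets are read, normalised, and validated", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t some description", "mkV"), f)
  t <- read_target_fasta(f)
  expect_equal(t$residues, c("M", "K", "V"))
  expect_equal(t$length, 3L)
  expect_equal(t$id, "t")

  writeLines(character(0), f)
  expect_error(read_target_fasta(f), class = "modfold_format_error")

  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad", "MK9"), f2)
  expect_error(read_target_fasta(f2), "9")
})

test_that("model residues map onto the target by substring offset or alignment", {
  t <- target_sequence("MKV")
  expect_equal(map_model_to_target(c("K", "V"), t), c(2L, 3L))
  expect_equal(map_model_to_target(c("M", "K", "V"), t), 1:3)
  # one mismatch, identity 2/3 >= 50%: alignment maps all columns
  expect_equal(map_model_to_target(c("M", "A", "V"), t), 1:3)
  # wrong target: identity below half
  t2 <- target_sequence("MKVLYQRE")
  expect_error(map_model_to_target(strsplit("WWWWWWWW", "")[[1]], t2),
               "does not correspond")
})

test_that("mapping is idempotent, injective and strictly increasing", {
  t <- target_sequence("MKVLYQREAGHT")
  for (ms in list(c("K", "V", "L"), c("M", "K", "L", "Y"), strsplit("MKVLYQREAGHT", "")[[1]])) {
    idx <- map_model_to_target(ms, t)
    idx2 <- map_model_to_target(ms, t)
    expect_identical(idx, idx2)
    mapped <- idx[!is.na(idx)]
    expect_false(any(duplicated(mapped)))
    expect_true(all(diff(mapped) > 0))
  }
})

test_that("PDB reader keeps the first chain, drops waters and CA-less residues", {
  t <- target_sequence("MKV")
  coords <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  lines <- toy_pdb_text(c("M", "K", "V"), coords)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines,
               "HETATM  900  O   HOH A 101      1.000   1.000   1.000  1.00  0.00           O"),
             f)
  m <- read_model_pdb(f, t)
  expect_equal(nrow(m$residues), 3L)
  expect_equal(m$residues$target_index, 1:3)
  expect_false(any(m$atoms$name == "O"))

  # residue lacking CA is dropped with a warning
  f2 <- withr::local_tempfile(fileext = ".pdb")
  noca <- sub(" CA ", " CB ", lines[3], fixed = TRUE)
  writeLines(c(lines[1:2], noca), f2)
  expect_warning(m2 <- read_model_pdb(f2, t), "lacking a CA")
  expect_equal(nrow(m2$residues), 2L)

  # no ATOM records at all
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f3)
  expect_error(read_model_pdb(f3, t), class = "modfold_format_error")
})

test_that("PDB read -> write -> read preserves atoms and coordinates exactly", {
  b <- study_benchmark()
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(b$native, f1)
  m1 <- read_model_pdb(f1, b$target)
  expect_equal(nrow(m1$atoms), nrow(b$native$atoms))
  expect_equal(m1$atoms$name, b$native$atoms$name)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(m1, f2)
  m2 <- read_model_pdb(f2, b$target)
  expect_identical(m1$atoms[, c("x", "y", "z")], m2$atoms[, c("x", "y", "z")])
  expect_identical(readLines(f1), readLines(f2))
})

test_that("RR contact files parse with dedup, normalisation and line errors", {
  f <- withr::local_tempfile(fileext = ".rr")
  writeLines(c("PFRMAT RR", "TARGET t", "MKVLYQREA",
               "1 9 0 8 0.92", "2 7 0 8 0.4", "7 2 0 8 0.6"), f)
  ct <- read_contacts_rr(f, source = "cda")
  expect_equal(nrow(ct), 2L)
  expect_equal(ct$p[ct$i == 1 & ct$j == 9], 0.92)
  expect_equal(ct$p[ct$i == 2 & ct$j == 7], 0.6)  # duplicate keeps max
  expect_true(all(ct$i < ct$j))

  writeLines(c("1 9 0 8 notanumber"), f)
  expect_error(read_contacts_rr(f), "line 1")

  writeLines(character(0), f)
  expect_equal(nrow(read_contacts_rr(f)), 0L)
})

test_that("ss2 and disorder tables parse with invariant checks and filling", {
  f <- withr::local_tempfile(fileext = ".ss2")
  writeLines(c("# comment", "1 M C 0.9 0.05 0.05", "2 K H 0.1 0.8 0.1"), f)
  ss <- read_ss2(f, L = 2)
  expect_equal(ss$state, c("C", "H"))
  expect_equal(ss$p_c[1], 0.9)

  writeLines("1 M C 0.2 0.2 0.1", f)
  expect_error(read_ss2(f), "sum")

  d <- withr::local_tempfile(fileext = ".diso")
  writeLines(c("1 0.1", "3 0.8"), d)
  expect_warning(diso <- read_disorder(d, L = 3), "filled")
  expect_equal(diso$prob, c(0.1, 0.5, 0.8))
  expect_equal(diso$filled, c(FALSE, TRUE, FALSE))

  writeLines("4 0.5", d)
  expect_error(read_disorder(d, L = 3), "outside")
})

test_that("CASP QA writer emits QMODE 2 records that round-trip", {
  est1 <- quality_estimate(
    "model_a",
    tibble::tibble(pos = 1:3, similarity = c(1, 0.5, NA),
                   error_A = c(0, 3.5, NA)),
    global_scores = list(modfold8 = 0.5)
  )
  est2 <- quality_estimate(
    "model_b",
    tibble::tibble(pos = 1:3, similarity = rep(1, 3), error_A = rep(0, 3)),
    global_scores = list(modfold8 = 1.0)
  )
  f <- withr::local_tempfile(fileext = ".txt")
  write_casp_qa(list(est1, est2), "T0001", f)
  txt <- readLines(f)
  expect_true("PFRMAT QA" %in% txt)
  expect_true(any(grepl("^model_a 0\\.5000$", txt)))
  expect_true(any(grepl("^0\\.00 3\\.50 X$", txt)))
  expect_true(any(grepl("^model_b 1\\.0000$", txt)))
  expect_equal(txt[length(txt)], "END")

  back <- read_casp_qa(f)
  expect_equal(back$target_id, "T0001")
  expect_equal(back$models$global, c(0.5, 1.0))
  expect_equal(back$models$error_A[[1]], c(0, 3.5, NA))

  expect_error(write_casp_qa(list(), "T0001", f), "no quality estimates")
})

test_that("per-residue errors land in the b-factor column, clamped and shared per residue", {
  b <- study_benchmark()
  f0 <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(b$native, f0)
  native <- read_model_pdb(f0, b$target)  # file-backed copy with raw records
  f <- withr::local_tempfile(fileext = ".pdb")
  err <- rep(NA_real_, b$target$length)
  err[1] <- 3.5; err[2] <- 250; err[3] <- 0
  write_annotated_pdb(native, err, f)
  m <- read_model_pdb(f, b$target)
  bf <- function(pos) unique(m$atoms$b[m$atoms$res_key ==
    m$residues$res_key[match(pos, m$residues$target_index)]])
  expect_equal(bf(1), 3.5)
  expect_equal(bf(2), 99.99)   # clamped
  expect_equal(bf(3), 0)
  expect_equal(bf(4), 99.99)   # missing -> unmapped sentinel
  # coordinates preserved exactly through annotation round-trip
  expect_identical(m$atoms[, c("x", "y", "z")], native$atoms[, c("x", "y", "z")])
  expect_error(write_annotated_pdb(native, -err, f), "non-negative")
})

test_that("score tracks enforce length, range and missing-value semantics", {
  tr <- score_track(c(1, 0.5, NA))
  expect_s3_class(tr, "score_track")
  expect_equal(track_values(tr), c(1, 0.5, NA))
  expect_error(score_track(c(0.5, 1.2)), class = "modfold_domain_error")
  # global penalises missing coverage against full length
  expect_equal(global_from_local(score_track(c(1, 1, NA, NA))), 0.5)
  expect_equal(global_from_local(score_track(c(1, 0.5, 0.5, 0))), 0.5)
  expect_warning(g <- global_from_local(score_track(rep(NA_real_, 4))), "all-missing")
  expect_equal(g, 0)
})
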