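#' Read predicted residue-residue contacts (CASP RR dialect)
#'
#' Accepts files with optional header lines (`PFRMAT`, `TARGET`, `MODEL`,
#' sequence lines, ...) followed by data rows `i j d_low d_high p`. Entries
#' are normalised to `i < j`; duplicated pairs keep the maximum probability.
#' The distance-bound columns are parsed but unused downstream.
#'
#' @param path Path to an RR file.
#' @param source Text tag for the contact predictor (e.g. `"cda"`,
#'   `"cda_dmp"`, `"cda_sc"`).
#' @return A tibble of class `contact_prediction` with columns `i`, `j`, `p`
#'   and a `source` attribute. An empty file yields an empty prediction.
#' @export
read_contacts_rr <- function(path, source = "generic") {
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  header_re <- "^(PFRMAT|TARGET|AUTHOR|REMARK|METHOD|MODEL|END|RMODE)\\b"
  for (ln in seq_along(lines)) {
    l <- trimws(lines[ln])
    if (l == "" || grepl(header_re, l, ignore.case = TRUE)) next
    if (grepl("^[A-Za-z]+$", l)) next  # sequence line
    tok <- strsplit(l, "\\s+")[[1]]
    if (length(tok) < 5L) {
      abort_format(sprintf("line %d of '%s': expected 'i j d_low d_high p'", ln, path))
    }
    v <- suppressWarnings(as.numeric(tok[1:5]))
    if (anyNA(v)) {
      abort_format(sprintf("line %d of '%s': non-numeric field in contact record", ln, path))
    }
    entries[[length(entries) + 1L]] <- v
  }
  if (length(entries) == 0L) {
    out <- tibble::tibble(i = integer(), j = integer(), p = numeric())
  } else {
    m <- do.call(rbind, entries)
    i <- as.integer(pmin(m[, 1], m[, 2]))
    j <- as.integer(pmax(m[, 1], m[, 2]))
    p <- m[, 5]
    if (any(i == j)) abort_format("self-contact (i == j) in '", path, "'")
    if (any(p < 0 | p > 1)) abort_format("contact probability outside [0, 1] in '", path, "'")
    out <- tibble::tibble(i = i, j = j, p = p) |>
      dplyr::group_by(.data$i, .data$j) |>
      dplyr::summarise(p = max(.data$p), .groups = "drop")
  }
  contact_prediction(out, source = source)
}

#' Construct a contact prediction from a tibble
#'
#' @param entries Tibble or data frame with columns `i`, `j`, `p`.
#' @param source Text tag for the predictor.
#' @return A `contact_prediction` tibble, normalised to `i < j` with
#'   duplicates resolved to the maximum probability.
#' @export
contact_prediction <- function(entries, source = "generic") {
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) > 0L) {
    ii <- pmin(entries$i, entries$j); jj <- pmax(entries$i, entries$j)
    entries$i <- as.integer(ii); entries$j <- as.integer(jj)
    entries <- entries |>
      dplyr::group_by(.data$i, .data$j) |>
      dplyr::summarise(p = max(.data$p), .groups = "drop") |>
      dplyr::arrange(.data$i, .data$j)
  }
  attr(entries, "source") <- source
  class(entries) <- c("contact_prediction", class(entries))
  entries
}

#' Read a 3-state secondary-structure prediction (ss2-style table)
#'
#' Expects whitespace-separated rows `pos aa state pC pH pE` (PSIPRED ss2
#' column order: coil, helix, strand); `#` comment lines and blank lines are
#' skipped. The three probabilities must sum to 1 within 0.02. The file's
#' stated state is kept even where it is not the argmax of the triple.
#'
#' @param path Path to the table.
#' @param L Optional target length; positions outside `1..L` are an error.
#' @return A tibble of class `ss_prediction` with columns `pos`, `aa`,
#'   `state`, `p_c`, `p_h`, `p_e`.
#' @export
read_ss2 <- function(path, L = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != "" & !startsWith(trimws(lines), "#")]
  rows <- lapply(seq_along(lines), function(k) {
    tok <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(tok) < 6L) abort_format(sprintf("ss2 line %d: expected 'pos aa state pC pH pE'", k))
    pos <- suppressWarnings(as.integer(tok[1]))
    pr <- suppressWarnings(as.numeric(tok[4:6]))
    if (is.na(pos) || anyNA(pr)) abort_format(sprintf("ss2 line %d: non-numeric field", k))
    list(pos = pos, aa = tok[2], state = toupper(tok[3]), pr = pr)
  })
  pos <- vapply(rows, `[[`, integer(1), "pos")
  if (!is.null(L) && any(pos < 1L | pos > L)) {
    abort_format("ss2 position outside 1..", L)
  }
  pr <- do.call(rbind, lapply(rows, `[[`, "pr"))
  sums <- rowSums(pr)
  if (any(abs(sums - 1) > 0.02)) {
    abort_format(sprintf(
      "ss2 probabilities at position %d sum to %.3f (must be 1 within 0.02)",
      pos[which(abs(sums - 1) > 0.02)[1L]], sums[which(abs(sums - 1) > 0.02)[1L]]
    ))
  }
  state <- vapply(rows, `[[`, character(1), "state")
  if (!all(state %in% c("H", "E", "C"))) abort_format("ss2 state must be one of H/E/C")
  out <- tibble::tibble(
    pos = pos, aa = vapply(rows, `[[`, character(1), "aa"),
    state = state, p_c = pr[, 1], p_h = pr[, 2], p_e = pr[, 3]
  ) |> dplyr::arrange(.data$pos)
  class(out) <- c("ss_prediction", class(out))
  out
}

#' Read per-residue disorder probabilities
#'
#' Expects whitespace-separated rows `pos prob`. Positions in `1..L` absent
#' from the file are filled with the neutral probability 0.5 and flagged.
#'
#' @param path Path to the table.
#' @param L Target length.
#' @return A tibble of class `disorder_prediction` with columns `pos`,
#'   `prob`, `filled` (TRUE where the value was imputed).
#' @export
read_disorder <- function(path, L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != "" & !startsWith(trimws(lines), "#")]
  prob <- rep(NA_real_, L)
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(tok[1:2]))
    if (anyNA(v)) abort_format(sprintf("disorder line %d: non-numeric field", k))
    pos <- as.integer(v[1])
    if (pos < 1L || pos > L) abort_format(sprintf("disorder position %d outside 1..%d", pos, L))
    if (v[2] < 0 || v[2] > 1) abort_format(sprintf("disorder probability %.3f outside [0, 1]", v[2]))
    prob[pos] <- v[2]
  }
  filled <- is.na(prob)
  if (any(filled)) {
    rlang::warn(sprintf("disorder prediction missing %d position(s); filled with 0.5", sum(filled)))
    prob[filled] <- 0.5
  }
  out <- tibble::tibble(pos = seq_len(L), prob = prob, filled = filled)
  class(out) <- c("disorder_prediction", class(out))
  out
}

#' Construct a disorder prediction from probabilities
#'
#' @param prob Numeric vector of disorder probabilities over `1..L`.
#' @return A `disorder_prediction` tibble.
#' @export
disorder_prediction <- function(prob) {
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) abort_domain("disorder probabilities must lie in [0, 1]")
  filled <- is.na(prob)
  prob[filled] <- 0.5
  out <- tibble::tibble(pos = seq_along(prob), prob = prob, filled = filled)
  class(out) <- c("disorder_prediction", class(out))
  out
}

#' Ingest an externally computed per-residue score track
#'
#' Reads a `pos score` table produced by an external single-model scoring
#' program. Scores must lie in \[0, 1\] unless `as_distance = TRUE`, in which
#' case values are interpreted as per-residue error estimates in Angstroms
#' and converted to similarities with [s_from_d()].
#'
#' @param path Path to the table.
#' @param method_name Name recorded on the returned track.
#' @param L Target length.
#' @param as_distance Interpret values as Angstrom errors.
#' @param params [sscore_params()] used when `as_distance = TRUE`.
#' @return A [score_track()] with provenance `"ingested"`; positions absent
#'   from the file are missing.
#' @export
ingest_external_track <- function(path, method_name, L, as_distance = FALSE,
                                  params = sscore_params()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != "" & !startsWith(trimws(lines), "#")]
  v <- rep(NA_real_, L)
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(tok[1:2]))
    if (anyNA(val)) abort_format(sprintf("track line %d: non-numeric field", k))
    pos <- as.integer(val[1])
    if (pos < 1L || pos > L) {
      abort_format(sprintf("track position %d outside 1..%d", pos, L))
    }
    s <- val[2]
    if (as_distance) {
      if (s < 0) abort_format("distance-valued track has negative value")
      s <- s_from_d(s, params)
    } else if (s < 0 || s > 1) {
      abort_format(sprintf(
        "score %.3f outside [0, 1] at position %d (use as_distance = TRUE for Angstrom tracks)",
        s, pos
      ))
    }
    v[pos] <- s
  }
  score_track(v, method = method_name, provenance = "ingested")
}
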