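#' Per-residue score track
#'
#' A score track holds one scoring method's per-residue values over the full
#' target sequence: a tibble with columns `pos` (1..L) and `score` (in
#' \[0, 1\], `NA` marking positions the method could not score). The method
#' name and provenance (`"computed"` for in-package scores, `"ingested"` for
#' externally supplied tracks) travel as attributes.
#'
#' @param values Numeric vector of length L with scores in \[0, 1\] or `NA`.
#' @param method Method name, e.g. `"cda"`, `"mf5s"`.
#' @param provenance `"computed"` or `"ingested"`.
#' @return A tibble of class `score_track`.
#' @export
score_track <- function(values, method = "score", provenance = "computed") {
  values <- as.numeric(values)
  ok <- is.na(values) | (values >= -1e-9 & values <= 1 + 1e-9)
  if (!all(ok)) {
    abort_domain(sprintf(
      "score track '%s' has value %.6g outside [0, 1] at position %d",
      method, values[!ok][1L], which(!ok)[1L]
    ))
  }
  values <- ifelse(is.na(values), NA_real_, clamp(values, 0, 1))
  out <- tibble::tibble(pos = seq_along(values), score = values)
  attr(out, "method") <- method
  attr(out, "provenance") <- match.arg(provenance, c("computed", "ingested"))
  class(out) <- c("score_track", class(out))
  out
}

track_method <- function(track) attr(track, "method") %||% "score"

#' Extract score values from a track
#'
#' @param track A [score_track()] or numeric vector.
#' @return Numeric vector of per-position scores (`NA` = missing).
#' @export
track_values <- function(track) {
  if (is.numeric(track)) return(as.numeric(track))
  track$score
}

# Build a length-L track from values named by target position.
track_from_named <- function(named, L, method, provenance = "computed") {
  v <- rep(NA_real_, L)
  if (length(named) > 0L) {
    idx <- as.integer(names(named))
    v[idx] <- unname(named)
  }
  score_track(v, method = method, provenance = provenance)
}

#' Global score as the mean of local scores
#'
#' The global score of a model under any per-residue method is the mean of
#' its local scores over the full target length: missing positions count as
#' zero, so partial models are penalised in proportion to the coverage they
#' lack.
#'
#' @param track A [score_track()] or numeric vector of per-residue scores.
#' @param L Target length (defaults to the track length).
#' @return A single score in \[0, 1\].
#' @export
global_from_local <- function(track, L = NULL) {
  v <- track_values(track)
  L <- L %||% length(v)
  if (length(v) != L) {
    abort_domain(sprintf("track length %d does not match target length %d", length(v), L))
  }
  if (all(is.na(v))) {
    rlang::warn("all-missing score track; global score is 0")
    return(0)
  }
  sum(v, na.rm = TRUE) / L
}

#' Combine score tracks into a wide tibble
#'
#' @param tracks Named list of [score_track()]s over the same target.
#' @return A tibble with `pos` plus one column per method.
#' @export
bind_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  nms <- names(tracks) %||% vapply(tracks, track_method, character(1))
  L <- nrow(tracks[[1L]])
  cols <- lapply(tracks, function(t) {
    v <- track_values(t)
    if (length(v) != L) abort_domain("tracks have differing lengths")
    v
  })
  names(cols) <- nms
  dplyr::bind_cols(tibble::tibble(pos = seq_len(L)), tibble::as_tibble(cols))
}
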