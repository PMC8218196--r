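#' Write quality estimates in CASP QA format (QMODE 2)
#'
#' Produces the standard machine-readable QA file: `PFRMAT QA`, `TARGET`,
#' `AUTHOR`, `METHOD` and `QMODE 2` headers, then one record per model
#' holding the model name, the global score (4 decimals) and the per-residue
#' predicted C-alpha errors in Angstroms (2 decimals, `X` for unmapped
#' positions), wrapped 20 values per line, terminated by `END`.
#'
#' @param estimates A `modfold_result` (see [score_models()]) or a list of
#'   `quality_estimate` objects for the same target.
#' @param target_id Target identifier written on the `TARGET` line.
#' @param out_path Output path.
#' @param variant Which global score variant to report (default
#'   `"modfold8"`).
#' @param author,method Free-text header fields.
#' @export
write_casp_qa <- function(estimates, target_id, out_path, variant = "modfold8",
                          author = "modfoldkit", method = "hybrid per-residue quality estimation") {
  ests <- as_estimate_list(estimates)
  if (length(ests) == 0L) abort_domain("no quality estimates to write")
  lines <- c(
    "PFRMAT QA",
    paste("TARGET", target_id),
    paste("AUTHOR", author),
    paste("METHOD", method),
    "QMODE 2"
  )
  for (e in ests) {
    g <- e$global_scores[[variant]]
    if (is.null(g)) abort_domain("estimate lacks global variant '", variant, "'")
    err <- e$local$error_A
    tokens <- ifelse(is.na(err), "X", sprintf("%.2f", clamp(err, 0, 99.99)))
    lines <- c(lines, sprintf("%s %.4f", e$model_id, g))
    for (start in seq(1L, length(tokens), by = 20L)) {
      lines <- c(lines, paste(tokens[start:min(start + 19L, length(tokens))], collapse = " "))
    }
  }
  writeLines(c(lines, "END"), out_path)
  invisible(out_path)
}

#' Read a CASP QA (QMODE 2) file
#'
#' Round-trip companion of [write_casp_qa()].
#'
#' @param path Path to a QA file.
#' @return A list with `target_id` and a tibble `models` holding `model_id`,
#'   `global`, and a list-column `error_A` of per-residue errors (`NA` where
#'   the file holds `X`).
#' @export
read_casp_qa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  target_id <- sub("^TARGET\\s+", "", grep("^TARGET\\b", lines, value = TRUE)[1])
  body <- lines[!grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|QMODE|REMARK|MODEL|END)\\b", lines)]
  models <- list()
  cur <- NULL
  for (l in body) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    first_num <- suppressWarnings(as.numeric(tok[1]))
    if (is.na(first_num) && tok[1] != "X") {
      if (!is.null(cur)) models[[cur$model_id]] <- cur
      cur <- list(model_id = tok[1], global = as.numeric(tok[2]), err = character())
      if (length(tok) > 2L) cur$err <- c(cur$err, tok[-(1:2)])
    } else {
      if (is.null(cur)) abort_format("QA file '", path, "': data before first model record")
      cur$err <- c(cur$err, tok)
    }
  }
  if (!is.null(cur)) models[[cur$model_id]] <- cur
  tbl <- tibble::tibble(
    model_id = unname(vapply(models, `[[`, character(1), "model_id")),
    global = unname(vapply(models, `[[`, numeric(1), "global")),
    error_A = unname(lapply(models, function(m) {
      suppressWarnings(ifelse(m$err == "X", NA_real_, as.numeric(m$err)))
    }))
  )
  list(target_id = target_id, models = tbl)
}

as_estimate_list <- function(x) {
  if (inherits(x, "modfold_result")) return(x$estimates)
  if (inherits(x, "quality_estimate")) return(list(x))
  x
}
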