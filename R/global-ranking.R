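#' Default global-variant weights
#'
#' Three global score variants are produced by convex combinations of
#' component global scores: a ranking-optimised variant leaning on the
#' selection-strong quasi-single scores, a correlation-optimised variant
#' leaning on the neural-network outputs trained to the observed metrics,
#' and a balanced variant averaging all four. All weights are
#' user-overridable; each variant's weights must sum to 1.
#'
#' @return A named list of named numeric weight vectors, one per variant
#'   (`modfold8_rank`, `modfold8_cor`, `modfold8`).
#' @export
default_variant_weights <- function() {
  list(
    modfold8_rank = c(nn_sscore = 1 / 3, mf5s = 1 / 3, mfcqs = 1 / 3),
    modfold8_cor = c(nn_lddt = 0.5, nn_sscore = 0.5),
    modfold8 = c(nn_sscore = 0.25, nn_lddt = 0.25, mf5s = 0.25, mfcqs = 0.25)
  )
}

#' Combine component global scores into the three variants
#'
#' @param component_globals Named numeric vector/list of component global
#'   scores (e.g. `mf5s`, `mfcqs`, `cda`, ...).
#' @param nn_globals Named numeric vector/list of the neural-network global
#'   scores, names `nn_sscore` and `nn_lddt` (a bare `sscore`/`lddt` naming
#'   is also accepted and prefixed).
#' @param weights Variant weights as in [default_variant_weights()].
#' @return Named numeric vector of variant scores in \[0, 1\].
#' @export
combine_global_variants <- function(component_globals, nn_globals,
                                    weights = default_variant_weights()) {
  nn <- unlist(nn_globals)
  bare <- !startsWith(names(nn), "nn_")
  names(nn)[bare] <- paste0("nn_", names(nn)[bare])
  pool <- c(unlist(component_globals), nn)
  out <- vapply(names(weights), function(vn) {
    w <- weights[[vn]]
    if (any(w < 0)) abort_domain("variant weights must be non-negative")
    if (abs(sum(w) - 1) > 1e-6) {
      abort_domain(sprintf("weights for variant '%s' sum to %.4f, not 1", vn, sum(w)))
    }
    missing <- setdiff(names(w), names(pool))
    if (length(missing) > 0L) {
      abort_domain(sprintf("variant '%s' needs missing component score(s): %s",
                           vn, paste(missing, collapse = ", ")))
    }
    sum(w * pool[names(w)])
  }, numeric(1))
  out
}

#' Empirical confidence P-value and tier for a global score
#'
#' Compares a model's global score to a calibration sample of global scores
#' of known-poor models using the add-one empirical upper tail:
#' `p = (1 + #\{null >= score\}) / (1 + #null)`. Tiers: p < 0.001 CERT,
#' < 0.01 HIGH, < 0.05 MEDIUM, < 0.1 LOW, else POOR (strict inequalities).
#'
#' @param global Global score(s) in \[0, 1\].
#' @param calibration Numeric sample of null (poor-model) global scores;
#'   defaults to the packaged synthetic-decoy null.
#' @return A tibble with columns `global`, `p_value`, `tier`.
#' @export
confidence_from_score <- function(global, calibration = default_null_scores()) {
  calibration <- as.numeric(calibration)
  if (length(calibration) == 0L) abort_domain("calibration sample is empty")
  n <- length(calibration)
  p <- vapply(global, function(g) (1 + sum(calibration >= g)) / (1 + n), numeric(1))
  tier <- dplyr::case_when(
    p < 0.001 ~ "CERT",
    p < 0.01 ~ "HIGH",
    p < 0.05 ~ "MEDIUM",
    p < 0.1 ~ "LOW",
    TRUE ~ "POOR"
  )
  tibble::tibble(global = as.numeric(global), p_value = p, tier = tier)
}

#' Packaged synthetic null calibration scores
#'
#' Global scores of deliberately poor (high-noise) synthetic decoys,
#' generated once with a fixed seed and shipped with the package; used as
#' the default calibration for [confidence_from_score()]. Users assessing
#' real targets can and should supply their own null sample.
#'
#' @return Numeric vector of null global scores.
#' @export
default_null_scores <- function() {
  path <- system.file("extdata", "synthetic_null_global_scores.tsv",
                      package = "modfoldkit")
  if (path == "") abort_domain("packaged null calibration not found")
  utils::read.table(path, header = TRUE)$global
}

#' Rank models by a global score variant
#'
#' Descending by the chosen variant; ties are broken by mean local
#' similarity, then by model id (lexicographic), so the ranking is stable
#' under input permutation.
#'
#' @param estimates A `modfold_result` or its summary tibble (columns
#'   `model_id`, variant scores, `mean_local`).
#' @param variant Variant column to rank by (default `"modfold8_rank"`).
#' @return The summary tibble sorted, with a `rank` column prepended.
#' @export
rank_models <- function(estimates, variant = "modfold8_rank") {
  tbl <- if (inherits(estimates, "modfold_result")) estimates$summary else tibble::as_tibble(estimates)
  if (nrow(tbl) < 1L) abort_domain("no estimates to rank")
  if (!variant %in% names(tbl)) abort_domain("unknown variant '", variant, "'")
  if (!"mean_local" %in% names(tbl)) tbl$mean_local <- NA_real_
  ord <- order(-tbl[[variant]], -ifelse(is.na(tbl$mean_local), -Inf, tbl$mean_local),
               tbl$model_id, method = "radix")
  out <- tbl[ord, , drop = FALSE]
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}

#' Compare predicted quality estimates with observed scores
#'
#' @param estimates A `modfold_result` or list of `quality_estimate`s.
#' @param observed Named list (by model id) of observed [score_track()]s
#'   (e.g. from [observed_sscore_track()] or [lddt_per_residue()]).
#' @param variant Global variant compared against the observed global score
#'   (default `"modfold8"`).
#' @return An object of class `modfold_evaluation`: tibbles `per_model`
#'   (predicted/observed globals and absolute differences) and `summary`
#'   (one row: global and pooled residue-level Pearson r, mean absolute
#'   global difference). Correlations over fewer than 2 points are `NA`.
#' @export
evaluate_predictions <- function(estimates, observed, variant = "modfold8") {
  ests <- as_estimate_list(estimates)
  ids <- intersect(names(ests) %||% vapply(ests, `[[`, character(1), "model_id"),
                   names(observed))
  if (length(ids) == 0L) abort_domain("no shared models between estimates and observations")
  names(ests) <- vapply(ests, `[[`, character(1), "model_id")
  per_model <- purrr::map_dfr(ids, function(id) {
    e <- ests[[id]]
    obs <- observed[[id]]
    tibble::tibble(
      model_id = id,
      predicted_global = e$global_scores[[variant]],
      observed_global = global_from_local(obs),
      abs_diff = abs(predicted_global - observed_global)
    )
  })
  pooled_pred <- unlist(lapply(ids, function(id) ests[[id]]$local$similarity))
  pooled_obs <- unlist(lapply(ids, function(id) track_values(observed[[id]])))
  keep <- !is.na(pooled_pred) & !is.na(pooled_obs)
  safe_cor <- function(x, y) {
    if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y)
  }
  summary <- tibble::tibble(
    n_models = length(ids),
    global_pearson_r = safe_cor(per_model$predicted_global, per_model$observed_global),
    residue_pearson_r = safe_cor(pooled_pred[keep], pooled_obs[keep]),
    mean_abs_global_diff = mean(per_model$abs_diff)
  )
  structure(list(per_model = per_model, summary = summary),
            class = "modfold_evaluation")
}

#' @export
print.modfold_evaluation <- function(x, ...) {
  cat("<modfold_evaluation>\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.modfold_evaluation <- function(x, ...) x$summary
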