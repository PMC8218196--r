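#' Quality estimate for a single model
#'
#' @param model_id Model identifier.
#' @param local Tibble with columns `pos`, `similarity`, `error_A` over the
#'   full target (missing at unmapped positions).
#' @param global_scores Named numeric: component globals, NN globals and the
#'   three variants.
#' @param p_value,tier Confidence calibration results.
#' @return A list of class `quality_estimate`.
#' @export
quality_estimate <- function(model_id, local, global_scores,
                             p_value = NA_real_, tier = NA_character_) {
  structure(
    list(model_id = model_id, local = local, global_scores = global_scores,
         p_value = p_value, tier = tier),
    class = "quality_estimate"
  )
}

#' @export
print.quality_estimate <- function(x, ...) {
  cat(sprintf("<quality_estimate> %s: modfold8 %.4f (rank %.4f, cor %.4f), p = %.3g [%s]\n",
              x$model_id,
              x$global_scores[["modfold8"]] %||% NA,
              x$global_scores[["modfold8_rank"]] %||% NA,
              x$global_scores[["modfold8_cor"]] %||% NA,
              x$p_value, x$tier))
  invisible(x)
}

# Compute the full 13-track set for one model. external_tracks: named list of
# score_tracks for the ingested methods; absent methods become all-missing
# tracks (imputed neutrally by the combiner).
compute_model_tracks <- function(model, contacts, ss_pred, dba_track,
                                 refset, config = combiner_config(),
                                 external_tracks = NULL,
                                 cda_pars = cda_params(),
                                 ssa_pars = ssa_params(),
                                 s_pars = sscore_params(),
                                 q_pars = q_params()) {
  L <- model$target_length
  tracks <- list()
  for (src in c("cda", "cda_dmp", "cda_sc")) {
    tracks[[src]] <- if (!is.null(contacts[[src]])) {
      tr <- cda_per_residue(model, contacts[[src]], cda_pars)
      attr(tr, "method") <- src
      tr
    } else {
      score_track(rep(NA_real_, L), method = src)
    }
  }
  tracks$ssa <- ssa_per_residue(model, ss_pred, ssa_pars)
  tracks$dba <- dba_track
  tracks$mf5s <- mf5s_per_residue(model, refset, s_pars)
  tracks$mfcqs <- mfcqs_per_residue(model, refset, q_pars)
  for (m in setdiff(config$methods, names(tracks))) {
    tracks[[m]] <- external_tracks[[m]] %||% score_track(rep(NA_real_, L), method = m)
  }
  tracks[config$methods]
}

#' Score a set of models against a target
#'
#' Runs the full hybrid quality-estimation pipeline: per-model score tracks
#' from the pure-single methods (three contact-distance agreement variants,
#' secondary-structure agreement, plus any ingested external tracks) and
#' the quasi-single methods (disorder/B-factor agreement, MF5s, MFcQs
#' against the reference set), windowed neural-network combination under
#' both trained variants, conversion of predicted similarities to Angstrom
#' errors, composition of the three global score variants, and confidence
#' tiers with empirical P-values.
#'
#' @param target A [target_sequence()].
#' @param models Named list of `structure_model`s (names default to model
#'   ids).
#' @param contacts Named list of [contact_prediction()]s with any of the
#'   names `cda`, `cda_dmp`, `cda_sc`; absent sources yield all-missing
#'   tracks.
#' @param ss_pred An `ss_prediction`.
#' @param disorder A `disorder_prediction`.
#' @param refset A [reference_set()].
#' @param combiner_sscore,combiner_lddt Trained `combiner_model`s (S-score
#'   and lDDT target variants).
#' @param external_tracks Optional list (by model id) of named lists of
#'   ingested [score_track()]s for the external methods.
#' @param weights Variant weights ([default_variant_weights()]).
#' @param calibration Null calibration sample for
#'   [confidence_from_score()].
#' @param confidence_variant Variant used for the confidence P-value
#'   (default `"modfold8"`).
#' @return An object of class `modfold_result`: `summary` tibble (one row
#'   per model: variants, mean local similarity, p-value, tier), `estimates`
#'   (named list of [quality_estimate()]s) and `locals` (long tibble of
#'   per-residue predictions for all models).
#' @export
score_models <- function(target, models, contacts, ss_pred, disorder, refset,
                         combiner_sscore, combiner_lddt,
                         external_tracks = NULL,
                         weights = default_variant_weights(),
                         calibration = default_null_scores(),
                         confidence_variant = "modfold8") {
  if (length(models) == 0L) abort_domain("no models to score")
  ids <- names(models) %||% vapply(models, `[[`, character(1), "model_id")
  if (is.null(names(models))) names(models) <- ids
  rmsf <- rmsf_from_reference_set(refset)
  dba_track <- dba_per_residue(disorder, refset, rmsf = rmsf)
  estimates <- list()
  for (id in ids) {
    model <- models[[id]]
    tracks <- compute_model_tracks(
      model, contacts, ss_pred, dba_track, refset,
      config = combiner_sscore$config,
      external_tracks = external_tracks[[id]]
    )
    loc_s <- predict_local_quality(tracks, combiner_sscore, structure = model)
    loc_l <- predict_local_quality(tracks, combiner_lddt, structure = model)
    nn_globals <- c(
      nn_sscore = global_from_local(loc_s$similarity),
      nn_lddt = global_from_local(loc_l$similarity)
    )
    component_globals <- vapply(tracks, function(t) {
      v <- track_values(t)
      if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE) / length(v)
    }, numeric(1))
    component_globals <- component_globals[!is.na(component_globals)]
    variants <- combine_global_variants(component_globals, nn_globals, weights)
    qe <- quality_estimate(
      model_id = id,
      local = loc_s,
      global_scores = c(as.list(component_globals), as.list(nn_globals),
                        as.list(variants)),
      p_value = NA_real_, tier = NA_character_
    )
    qe$local_lddt <- loc_l
    estimates[[id]] <- qe
  }
  summary <- purrr::map_dfr(estimates, function(e) {
    tibble::tibble(
      model_id = e$model_id,
      modfold8 = e$global_scores$modfold8,
      modfold8_rank = e$global_scores$modfold8_rank,
      modfold8_cor = e$global_scores$modfold8_cor,
      mean_local = mean(e$local$similarity, na.rm = TRUE)
    )
  })
  conf <- confidence_from_score(summary[[confidence_variant]], calibration)
  summary$p_value <- conf$p_value
  summary$tier <- conf$tier
  for (k in seq_along(estimates)) {
    estimates[[k]]$p_value <- summary$p_value[k]
    estimates[[k]]$tier <- summary$tier[k]
  }
  locals <- purrr::map_dfr(estimates, function(e) {
    dplyr::bind_cols(tibble::tibble(model_id = e$model_id), e$local)
  })
  structure(
    list(target = target, summary = summary, estimates = estimates,
         locals = locals),
    class = "modfold_result"
  )
}

#' @export
print.modfold_result <- function(x, ...) {
  cat(sprintf("<modfold_result> target %s (%d residues), %d model(s)\n",
              x$target$id, x$target$length, nrow(x$summary)))
  print(rank_models(x))
  invisible(x)
}

#' Tidy a scoring result into its per-model summary
#'
#' @param x A `modfold_result`.
#' @param ... Unused.
#' @return The per-model summary tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.modfold_result <- function(x, ...) x$summary

#' One-row overview of a scoring result
#'
#' @param x A `modfold_result`.
#' @param ... Unused.
#' @return A one-row tibble: number of models, target length, best model
#'   and score under the ranking variant.
#' @export
#' @exportS3Method generics::glance
glance.modfold_result <- function(x, ...) {
  rk <- rank_models(x)
  tibble::tibble(
    n_models = nrow(rk),
    target_length = x$target$length,
    best_model = rk$model_id[1L],
    best_modfold8_rank = rk$modfold8_rank[1L]
  )
}

#' Write the standard output bundle for a scoring result
#'
#' Produces the machine-readable outputs: a ranked summary TSV, the CASP QA
#' (QMODE 2) file, one b-factor-annotated PDB per model, a per-residue
#' error TSV per model, and (optionally) per-residue error plots.
#'
#' @param result A `modfold_result`.
#' @param models The named list of `structure_model`s that was scored.
#' @param out_dir Output directory (created if needed).
#' @param plots Also write per-residue error plots as PNG files.
#' @return Invisibly, the output directory.
#' @export
write_result_bundle <- function(result, models, out_dir, plots = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rk <- rank_models(result)
  utils::write.table(rk, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_casp_qa(result, result$target$id, file.path(out_dir, "casp_qa.txt"))
  for (id in names(result$estimates)) {
    e <- result$estimates[[id]]
    utils::write.table(
      e$local, file.path(out_dir, paste0(id, ".residue_errors.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    if (!is.null(models[[id]])) {
      write_annotated_pdb(models[[id]], e$local$error_A,
                          file.path(out_dir, paste0(id, ".annotated.pdb")))
    }
    if (plots) {
      p <- plot_residue_errors(result, models = id)
      ggplot2::ggsave(file.path(out_dir, paste0(id, ".errors.png")), p,
                      width = 7, height = 3.5, dpi = 120)
    }
  }
  invisible(out_dir)
}
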