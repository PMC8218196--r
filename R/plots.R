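#' Per-residue predicted error profile plot
#'
#' The standard local-quality view: predicted distance in Angstroms of each
#' C-alpha atom from the native structure, along the target sequence, one
#' panel per model.
#'
#' @param result A `modfold_result`.
#' @param models Optional character vector of model ids to include.
#' @return A ggplot object.
#' @export
plot_residue_errors <- function(result, models = NULL) {
  dat <- result$locals
  if (!is.null(models)) dat <- dat[dat$model_id %in% models, , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos, y = .data$error_A)) +
    ggplot2::geom_line(colour = "#2c7fb8", na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, colour = "#2c7fb8", na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$model_id)) +
    ggplot2::labs(x = "Residue position", y = "Predicted CA error (Å)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_residue_errors
#' @param object A `modfold_result`.
#' @param ... Passed to [plot_residue_errors()].
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.modfold_result <- function(object, ...) {
  plot_residue_errors(object, ...)
}

#' Plot a per-residue score track
#'
#' @param track A [score_track()].
#' @return A ggplot object.
#' @export
plot_track <- function(track) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$pos, y = .data$score)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Residue position", y = track_method(track)) +
    ggplot2::theme_minimal()
}

#' Predicted versus observed global score scatter
#'
#' @param object A `modfold_evaluation` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.modfold_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$per_model,
                  ggplot2::aes(x = .data$observed_global, y = .data$predicted_global)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Observed global score", y = "Predicted global score") +
    ggplot2::theme_minimal()
}
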