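#' Canonical scoring-method order
#'
#' The thirteen per-residue scoring methods feeding the neural-network
#' combiner, in the canonical order serialized with every trained model:
#' nine pure-single inputs (three contact-distance agreement variants,
#' secondary-structure agreement, and five ingested external single-model
#' scores) followed by four quasi-single inputs (disorder/B-factor
#' agreement, superposition-based and superposition-free reference
#' agreement, and the ingested template-based error estimate).
#'
#' @return Character vector of 13 method names.
#' @export
modfold_methods <- function() {
  c("cda", "cda_dmp", "cda_sc", "ssa",
    "proq2", "proq2d", "proq3d", "proq4", "voromqa",
    "dba", "mf5s", "mfcqs", "resq")
}

#' Combiner configuration
#'
#' The combiner is a single-hidden-layer perceptron reading a sliding
#' window (default size 5) of per-residue scores from all scoring methods:
#' with 13 methods this gives 65 input neurons, 33 hidden and 1 output,
#' logistic sigmoid activations throughout. One variant is trained against
#' observed S-scores, the other against observed lDDT.
#'
#' @param window Odd window size (default 5).
#' @param methods Canonical method order (default [modfold_methods()]).
#' @param hidden_units Hidden layer width (default 33).
#' @param target_metric `"sscore"` or `"lddt"`.
#' @param seed Integer seed controlling weight initialisation.
#' @param epochs Number of full-batch gradient descent epochs.
#' @param learning_rate Gradient descent step size.
#' @param d0 S-score distance constant used when converting predictions to
#'   Angstrom errors.
#' @return A list of class `combiner_config`.
#' @export
combiner_config <- function(window = 5L, methods = modfold_methods(),
                            hidden_units = 33L,
                            target_metric = c("sscore", "lddt"),
                            seed = 1L, epochs = 1500L, learning_rate = 2,
                            d0 = 3.5) {
  window <- as.integer(window)
  if (window %% 2L != 1L || window < 1L) abort_domain("window must be a positive odd integer")
  if (hidden_units < 1L) abort_domain("hidden_units must be >= 1")
  structure(
    list(window = window, methods = methods, n_methods = length(methods),
         hidden_units = as.integer(hidden_units),
         target_metric = match.arg(target_metric),
         seed = as.integer(seed), epochs = as.integer(epochs),
         learning_rate = learning_rate, d0 = d0),
    class = "combiner_config"
  )
}

n_features <- function(config) config$window * config$n_methods

# Tracks (named list of score_track / numeric, or wide tibble with pos
# column) -> L x n_methods matrix in canonical order, NAs imputed with 0.5.
tracks_to_matrix <- function(tracks, config, impute = TRUE) {
  if (is.data.frame(tracks)) {
    nms <- setdiff(names(tracks), "pos")
    tracks <- as.list(tracks[nms])
  }
  if (length(tracks) != config$n_methods) {
    abort_domain(sprintf(
      "expected %d score tracks (one per method), got %d",
      config$n_methods, length(tracks)
    ))
  }
  missing <- setdiff(config$methods, names(tracks))
  if (length(missing) > 0L) {
    abort_domain("missing score track(s): ", paste(missing, collapse = ", "))
  }
  L <- length(track_values(tracks[[1L]]))
  m <- vapply(config$methods, function(nm) track_values(tracks[[nm]]), numeric(L))
  if (L == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, config$methods))
  if (impute) m[is.na(m)] <- 0.5
  m
}

#' Build windowed feature vectors from score tracks
#'
#' Concatenates, over window offsets (for window 5: -2..+2, ascending), the
#' values of all methods (canonical order within each offset) at position
#' `i + offset`. Offsets falling outside `1..L` replicate the nearest valid
#' position; missing scores are imputed with the neutral value 0.5.
#'
#' @param tracks Named list of [score_track()]s (or a wide tibble with a
#'   `pos` column) covering all configured methods.
#' @param config A [combiner_config()].
#' @param positions Target positions to build features for (default all).
#' @return A numeric matrix, one row per position, `window * n_methods`
#'   columns named `<method>@<offset>`.
#' @export
build_window_features <- function(tracks, config = combiner_config(),
                                  positions = NULL) {
  m <- tracks_to_matrix(tracks, config)
  L <- nrow(m)
  positions <- positions %||% seq_len(L)
  half <- (config$window - 1L) %/% 2L
  offs <- seq.int(-half, half)
  blocks <- lapply(offs, function(o) {
    idx <- clamp(positions + o, 1L, L)
    m[idx, , drop = FALSE]
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- as.vector(vapply(
    offs, function(o) paste0(config$methods, "@", o), character(config$n_methods)
  ))
  rownames(out) <- positions
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Train the neural-network combiner
#'
#' Fits a single-hidden-layer perceptron (logistic sigmoid hidden and output
#' units) to per-residue observed-quality targets by full-batch gradient
#' descent on the mean-squared error. Training is deterministic given the
#' configuration seed.
#'
#' @param features Numeric matrix of windowed features (rows = examples),
#'   values in \[0, 1\].
#' @param targets Numeric vector of observed similarities in \[0, 1\].
#' @param config A [combiner_config()].
#' @return An object of class `combiner_model` holding the configuration,
#'   weight matrices, and the training record (per-epoch loss curve).
#' @export
mlp_train <- function(features, targets, config = combiner_config()) {
  X <- as.matrix(features)
  y <- as.numeric(targets)
  if (nrow(X) < 1L) abort_domain("at least one training example is required")
  if (length(y) != nrow(X)) abort_domain("features and targets disagree in length")
  if (any(y < 0 | y > 1, na.rm = TRUE)) abort_domain("targets must lie in [0, 1]")
  if (anyNA(y) || anyNA(X)) abort_domain("training data must not contain missing values")
  p <- ncol(X)
  if (p != n_features(config)) {
    abort_domain(sprintf("feature width %d does not match window x methods = %d",
                         p, n_features(config)))
  }
  h <- config$hidden_units
  set.seed(config$seed)
  W1 <- matrix(stats::runif(p * h, -1, 1) / sqrt(p), p, h)
  b1 <- rep(0, h)
  W2 <- matrix(stats::runif(h, -1, 1) / sqrt(h), h, 1)
  b2 <- 0
  n <- nrow(X)
  lr <- config$learning_rate
  loss_curve <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    H <- sigmoid(sweep(X %*% W1, 2, b1, `+`))
    yh <- as.numeric(sigmoid(H %*% W2 + b2))
    err <- yh - y
    loss <- mean(err^2)
    if (!is.finite(loss)) {
      rlang::abort(sprintf("training diverged (non-finite loss at epoch %d)", epoch),
                   class = "modfold_training_error")
    }
    loss_curve[epoch] <- loss
    dz2 <- (2 / n) * err * yh * (1 - yh)        # n
    gW2 <- crossprod(H, dz2)                     # h x 1
    gb2 <- sum(dz2)
    dH <- (dz2 %*% t(W2)) * H * (1 - H)          # n x h
    gW1 <- crossprod(X, dH)                      # p x h
    gb1 <- colSums(dH)
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
    W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
  }
  structure(
    list(
      config = config,
      W1 = W1, b1 = b1, W2 = W2, b2 = b2,
      training_record = list(
        loss_curve = loss_curve,
        final_loss = loss_curve[length(loss_curve)],
        n_examples = n,
        target_mean = mean(y),
        seed = config$seed
      )
    ),
    class = "combiner_model"
  )
}

#' Predict per-residue similarity from windowed features
#'
#' @param model A `combiner_model`.
#' @param features Feature vector or matrix (width `window * n_methods`).
#' @return Numeric vector of similarities, each strictly in (0, 1).
#' @export
mlp_predict <- function(model, features) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1L) else as.matrix(features)
  if (ncol(X) != nrow(model$W1)) {
    abort_domain(sprintf("feature width %d does not match model input width %d",
                         ncol(X), nrow(model$W1)))
  }
  H <- sigmoid(sweep(X %*% model$W1, 2, model$b1, `+`))
  as.numeric(sigmoid(H %*% model$W2 + model$b2))
}

#' Predict local quality and Angstrom errors for a model
#'
#' Runs the combiner over all target positions and converts the predicted
#' similarities to per-residue C-alpha error estimates via the inverse
#' S-score function `d = d0 * sqrt(1/s - 1)` (capped at 99.99 A). When the
#' assessed structure is supplied, positions it does not cover are reported
#' missing.
#'
#' @param tracks Named list of [score_track()]s (or wide tibble).
#' @param model A `combiner_model`.
#' @param params [sscore_params()] for the similarity-to-distance
#'   conversion.
#' @param structure Optional `structure_model`; unmapped positions are
#'   masked.
#' @return A tibble with columns `pos`, `similarity`, `error_A`.
#' @export
predict_local_quality <- function(tracks, model, params = NULL, structure = NULL) {
  params <- params %||% sscore_params(model$config$d0)
  feats <- build_window_features(tracks, model$config)
  s <- mlp_predict(model, feats)
  err <- pmin(d_from_s(s, params), 99.99)
  out <- tibble::tibble(pos = seq_along(s), similarity = s, error_A = err)
  if (!is.null(structure)) {
    mapped <- model_mapped_positions(structure)
    mask <- !(out$pos %in% mapped)
    out$similarity[mask] <- NA_real_
    out$error_A[mask] <- NA_real_
  }
  out
}

#' Serialize / restore a trained combiner
#'
#' Models are stored as JSON holding the full configuration (including the
#' canonical track order, so a trained combiner cannot silently be applied
#' to misordered inputs) and full-precision weight matrices; predictions
#' round-trip bit-identically.
#'
#' @param model A `combiner_model`.
#' @param path Output / input path.
#' @return `read_combiner()` returns the restored `combiner_model`.
#' @export
write_combiner <- function(model, path) {
  payload <- list(
    format = "modfoldkit_combiner_v1",
    config = model$config[c("window", "methods", "hidden_units", "target_metric",
                            "seed", "epochs", "learning_rate", "d0")],
    W1 = model$W1, b1 = model$b1,
    W2 = as.numeric(model$W2), b2 = model$b2,
    training_record = model$training_record
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_combiner
#' @export
read_combiner <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "modfoldkit_combiner_v1")) {
    abort_format("'", path, "' is not a serialized combiner model")
  }
  cfg <- combiner_config(
    window = j$config$window, methods = j$config$methods,
    hidden_units = j$config$hidden_units, target_metric = j$config$target_metric,
    seed = j$config$seed, epochs = j$config$epochs,
    learning_rate = j$config$learning_rate, d0 = j$config$d0
  )
  structure(
    list(
      config = cfg,
      W1 = matrix(j$W1, nrow = n_features(cfg), ncol = cfg$hidden_units),
      b1 = as.numeric(j$b1),
      W2 = matrix(j$W2, ncol = 1L),
      b2 = as.numeric(j$b2),
      training_record = j$training_record
    ),
    class = "combiner_model"
  )
}

#' @export
print.combiner_model <- function(x, ...) {
  cat(sprintf(
    "<combiner_model> %d-%d-1 MLP (window %d x %d methods), target = %s\n",
    nrow(x$W1), ncol(x$W1), x$config$window, x$config$n_methods,
    x$config$target_metric
  ))
  cat(sprintf("  trained %d epochs on %d examples; final MSE %.5f\n",
              x$config$epochs, x$training_record$n_examples %||% NA,
              x$training_record$final_loss %||% NA))
  invisible(x)
}

#' Tidy a trained combiner into a per-weight tibble
#'
#' @param x A `combiner_model`.
#' @param ... Unused.
#' @return A tibble with columns `layer`, `from`, `to`, `weight`.
#' @export
#' @exportS3Method generics::tidy
tidy.combiner_model <- function(x, ...) {
  feats <- colnames(x$W1) %||% paste0("f", seq_len(nrow(x$W1)))
  in_feats <- {
    half <- (x$config$window - 1L) %/% 2L
    as.vector(vapply(seq.int(-half, half),
                     function(o) paste0(x$config$methods, "@", o),
                     character(x$config$n_methods)))
  }
  w1 <- tibble::tibble(
    layer = "hidden",
    from = rep(in_feats, times = ncol(x$W1)),
    to = rep(paste0("h", seq_len(ncol(x$W1))), each = nrow(x$W1)),
    weight = as.numeric(x$W1)
  )
  w2 <- tibble::tibble(
    layer = "output",
    from = paste0("h", seq_len(nrow(x$W2))),
    to = "output",
    weight = as.numeric(x$W2)
  )
  dplyr::bind_rows(w1, w2)
}

#' One-row summary of a trained combiner
#'
#' @param x A `combiner_model`.
#' @param ... Unused.
#' @return A one-row tibble with architecture and training summaries.
#' @export
#' @exportS3Method generics::glance
glance.combiner_model <- function(x, ...) {
  tibble::tibble(
    target_metric = x$config$target_metric,
    window = x$config$window,
    n_methods = x$config$n_methods,
    n_inputs = n_features(x$config),
    hidden_units = x$config$hidden_units,
    epochs = x$config$epochs,
    learning_rate = x$config$learning_rate,
    n_examples = x$training_record$n_examples %||% NA_integer_,
    final_loss = x$training_record$final_loss %||% NA_real_
  )
}
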