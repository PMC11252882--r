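# Base-model contract and a simulated base-model family.
#
# A base model maps a tile to a continuous invasive-cancer score in [0, 1].
# In production this is a CNN softmax output; here a seeded simulator with
# controllable accuracy, calibration shift (its Dice-optimal threshold need
# not be 0.5) and inter-model correlation stands in, so the ensemble theory
# is testable without trained networks.

#' Specify one simulated base model
#'
#' @param model_id model identifier (scalar string).
#' @param p_correct marginal probability, in (0, 1), that the model's vote
#'   (its score binarized at `true_threshold`) matches the tile label.
#' @param true_threshold the score value separating the model's "votes 0"
#'   and "votes 1" regions; the simulator's planted Dice-optimal threshold.
#'   Values away from 0.5 emulate uncalibrated softmax outputs.
#' @param concentration positive sharpness of the score distribution:
#'   larger values push scores towards 0 / 1, away from the threshold.
#' @param rho common-noise mixing weight in `[0, 1)`: the probability that a
#'   tile's shared draw replaces the model's own draw, inducing vote
#'   correlation between models. 0 gives conditionally independent votes.
#' @return an object of class `sim_model_spec`.
#' @export
sim_model_spec <- function(model_id, p_correct = 0.8, true_threshold = 0.5,
                           concentration = 2, rho = 0) {
  stopifnot(length(model_id) == 1,
            p_correct > 0, p_correct < 1,
            true_threshold > 0, true_threshold < 1,
            concentration > 0, rho >= 0, rho < 1)
  structure(list(model_id = as.character(model_id), p_correct = p_correct,
                 true_threshold = true_threshold,
                 concentration = concentration, rho = rho),
            class = "sim_model_spec")
}

# inverse-CDF score draws: u in (0,1) mapped to the side of tau requested.
# Above tau the density rises towards 1 (Beta(c, 1) stretched to [tau, 1]);
# below it falls away from tau towards 0 (Beta(1, c) on [0, tau]).
score_from_u <- function(u, above, tau, conc) {
  ifelse(above,
         tau + (1 - tau) * u^(1 / conc),
         tau * (1 - (1 - u)^(1 / conc)))
}

#' Simulate a score matrix from labeled tiles
#'
#' For each tile and model the vote is drawn correct with probability
#' `p_correct`, then a score is drawn on the corresponding side of the
#' model's `true_threshold` from a bounded unimodal density whose sharpness
#' is `concentration`. With probability `rho` a per-tile shared draw (the
#' shared correctness indicator and quantile, generated once per tile)
#' replaces the model's own draw, correlating votes across models. All
#' randomness derives from `seed`: the shared per-tile stream is drawn
#' first, then each model's stream in column order.
#'
#' @param labels labeled tile table (needs columns `tile_id`, `l`).
#' @param specs list of [sim_model_spec()] objects.
#' @param seed integer RNG seed.
#' @return numeric matrix of scores in `[0, 1]`, rows named by `tile_id`,
#'   columns by `model_id`.
#' @export
simulate_scores <- function(labels, specs, seed) {
  stopifnot(nrow(labels) >= 1, length(specs) >= 1)
  if (inherits(specs, "sim_model_spec")) specs <- list(specs)
  m <- nrow(labels)
  l <- labels$l
  set.seed(seed)
  shared_correct <- stats::runif(m) < specs[[1]]$p_correct
  shared_u <- stats::runif(m)
  scores <- matrix(NA_real_, nrow = m, ncol = length(specs),
                   dimnames = list(labels$tile_id,
                                   vapply(specs, `[[`, character(1), "model_id")))
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    use_shared <- stats::runif(m) < sp$rho
    own_correct <- stats::runif(m) < sp$p_correct
    own_u <- stats::runif(m)
    correct <- ifelse(use_shared, shared_correct, own_correct)
    u <- ifelse(use_shared, shared_u, own_u)
    above <- (l == 1) == correct   # vote 1 when correct on a positive tile
    scores[, j] <- score_from_u(u, above, sp$true_threshold, sp$concentration)
  }
  scores
}

#' Read / write score matrices
#'
#' CSV with first column `tile_id` and one column per model id; values in
#' `[0, 1]`.
#' @param scores score matrix (rows tiles, columns models).
#' @param path CSV file path.
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(tile_id = rownames(scores), scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(tile_id = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$tile_id
  m
}

#' Read / write simulated-model specification lists (YAML)
#' @param specs list of [sim_model_spec()] objects.
#' @param path YAML file path.
#' @export
write_model_specs <- function(specs, path) {
  yaml::write_yaml(lapply(specs, unclass), path)
  invisible(path)
}

#' @rdname write_model_specs
#' @export
read_model_specs <- function(path) {
  lapply(yaml::read_yaml(path), function(x)
    sim_model_spec(x$model_id, x$p_correct, x$true_threshold,
                   x$concentration, x$rho))
}

#' The real-CNN adapter contract (documentation only)
#'
#' Describes, without executing, how a production deep-learning base model
#' plugs into this pipeline: an adapter maps a batch of H&E tile images to
#' the softmax probability of the invasive-cancer class (a score in
#' `[0, 1]`, one per tile, forming one column of the score matrix). The
#' recorded training recipe is transfer learning from ImageNet weights,
#' cross-entropy loss over the two classes, the AdaBelief optimizer, and
#' early stopping on a tuning set carved from the model's own training
#' division (tuning fraction is a free parameter of the adapter). Which
#' softmax class is reported is fixed here as "probability of IC". This
#' function performs no computation and is not exercised by the test suite
#' beyond its shape.
#'
#' @return a list describing the adapter contract.
#' @export
cnn_adapter_contract <- function() {
  list(
    input = "batch of RGB tile images (one tile = one grid cell of a WSI)",
    output = "numeric vector in [0, 1]: softmax probability of the IC class",
    architecture = "InceptionV3-class CNN, two-class softmax head",
    training = list(
      initialisation = "ImageNet pretrained weights",
      loss = "cross-entropy",
      optimizer = "AdaBelief",
      stopping = "early stopping on a tuning subset of the model's division",
      tuning_fraction = "free parameter; carved within the training division"
    ),
    assumption = "score = probability of the IC class; no temperature scaling",
    note = "documentation-level contract; not executed in tests"
  )
}
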