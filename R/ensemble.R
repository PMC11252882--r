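# Majority-vote aggregation, the agreement statistic and the binomial
# ensemble-success theory.
#
# Votes: t_i(x) = 1 iff score_i(x) >= tau_i (the ">=" branch takes the
# threshold itself). Agreement a(x) counts votes for the TRUE class:
# a = vote_sum when l = 1, n - vote_sum when l = 0, so 0 is total
# disagreement with the ground truth and n unanimity.

#' Binarize a score matrix into votes
#'
#' @param scores score matrix (rows tiles, columns models).
#' @param taus threshold table from [calibrate_thresholds()] (columns
#'   `model_id`, `tau`) or a named numeric vector of thresholds.
#' @return integer 0/1 vote matrix with the thresholds attached as the
#'   `taus` attribute.
#' @export
binarize <- function(scores, taus) {
  tv <- if (is.data.frame(taus))
    stats::setNames(taus$tau, taus$model_id) else taus
  missing <- setdiff(colnames(scores), names(tv))
  if (length(missing))
    stop("no threshold for model(s): ", paste(missing, collapse = ", "))
  tv <- tv[colnames(scores)]
  votes <- matrix(0L, nrow = nrow(scores), ncol = ncol(scores),
                  dimnames = dimnames(scores))
  for (j in seq_len(ncol(scores)))
    votes[, j] <- as.integer(scores[, j] >= tv[j])
  attr(votes, "taus") <- tv
  votes
}

#' Aggregate votes by majority
#'
#' The predicted label is 1 when more than half of the models vote 1 and 0
#' when fewer than half do. With an even number of models an exact tie is
#' possible; it is flagged and broken deterministically by comparing the
#' tile's mean raw score against the mean of the calibrated thresholds
#' (`>=` maps to 1). `self_agreement` counts votes for the predicted class
#' (available without ground truth, in contrast to [agreement()]).
#'
#' @param votes vote matrix from [binarize()].
#' @param scores raw score matrix, required to break ties when the number
#'   of models is even.
#' @return data.frame with columns `tile_id`, `vote_sum`,
#'   `predicted_label`, `self_agreement`, `tie_flag`.
#' @export
majority_vote <- function(votes, scores = NULL) {
  n <- ncol(votes)
  vote_sum <- as.integer(rowSums(votes))
  pred <- as.integer(vote_sum > n / 2)
  tie <- vote_sum * 2L == n
  if (any(tie)) {
    if (is.null(scores))
      stop("ties occurred (vote_sum == n/2); raw scores are required ",
           "for the tie-break")
    tv <- attr(votes, "taus")
    if (is.null(tv)) stop("vote matrix carries no thresholds")
    pred[tie] <- as.integer(rowMeans(scores[tie, , drop = FALSE]) >= mean(tv))
  }
  self_agreement <- as.integer(ifelse(pred == 1, vote_sum, n - vote_sum))
  data.frame(tile_id = rownames(votes), vote_sum = vote_sum,
             predicted_label = pred, self_agreement = self_agreement,
             tie_flag = tie, stringsAsFactors = FALSE)
}

#' Per-tile agreement with the ground truth
#'
#' The number of base models voting for the tile's true class:
#' `vote_sum` on positive tiles, `n - vote_sum` on negative tiles.
#'
#' @param votes vote matrix from [binarize()].
#' @param labels labeled tile table covering all voted tiles.
#' @return integer vector in `0..n`, named by `tile_id`.
#' @export
agreement <- function(votes, labels) {
  ids <- rownames(votes)
  idx <- match(ids, labels$tile_id)
  if (anyNA(idx))
    stop("labels missing for ", sum(is.na(idx)), " tile(s); ",
         "use self_agreement for unlabeled deployment")
  l <- labels$l[idx]
  n <- ncol(votes)
  vote_sum <- rowSums(votes)
  a <- as.integer(ifelse(l == 1, vote_sum, n - vote_sum))
  names(a) <- ids
  a
}

#' Full per-tile ensemble result
#'
#' Convenience wrapper combining [majority_vote()] and (when labels are
#' supplied) [agreement()].
#'
#' @param votes vote matrix.
#' @param scores raw score matrix (tie-break).
#' @param labels optional labeled tile table; adds the `agreement` column.
#' @return data.frame with columns `tile_id, vote_sum, predicted_label,
#'   agreement (NA without labels), self_agreement, tie_flag`.
#' @export
ensemble_result <- function(votes, scores = NULL, labels = NULL) {
  out <- majority_vote(votes, scores)
  out$agreement <- if (is.null(labels)) NA_integer_ else
    unname(agreement(votes, labels))
  out[, c("tile_id", "vote_sum", "predicted_label", "agreement",
          "self_agreement", "tie_flag")]
}

#' Write / read ensemble results (CSV)
#' @param x ensemble result table.
#' @param path CSV file path.
#' @export
write_ensemble_result <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_ensemble_result
#' @export
read_ensemble_result <- function(path) {
  utils::read.csv(path, colClasses = c(tile_id = "character"))
}

#' Closed-form probability of ensemble success
#'
#' For `T` independent voters each correct with probability `p`, the
#' probability that a strict majority is correct:
#' `sum_{k = floor(T/2)+1}^{T} choose(T, k) p^k (1-p)^(T-k)`.
#' For even `T` an exact tie counts as failure. As `T` grows this tends to
#' 1 whenever `p > 0.5` — the rationale for majority voting.
#'
#' @param T number of voters (positive integer).
#' @param p per-voter success probability in `[0, 1]`; may be a vector.
#' @return numeric vector of ensemble success probabilities.
#' @examples
#' ensemble_success_probability(3, 0.8)   # 0.896
#' ensemble_success_probability(10, 0.8)  # ~0.9672
#' @export
ensemble_success_probability <- function(T, p) {
  stopifnot(T >= 1, T == round(T), all(p >= 0), all(p <= 1))
  k0 <- floor(T / 2) + 1
  ks <- k0:T
  vapply(p, function(pp)
    sum(choose(T, ks) * pp^ks * (1 - pp)^(T - ks)), numeric(1))
}

#' Compare the binomial ensemble theory with simulation
#'
#' Simulates `tiles` labeled tiles (half positive), scores them with the
#' given model specs, binarizes each model at its own planted threshold and
#' reports: the empirical per-model accuracy, the empirical strict-majority
#' success rate (fraction of tiles on which more than half of the votes are
#' correct — the quantity the binomial closed form describes; exact ties
#' count as failures there), the tie-broken majority-vote accuracy, the
#' closed-form prediction, and Monte-Carlo standard errors.
#'
#' @param specs list of [sim_model_spec()]; for a matched comparison all
#'   should share `p_correct` and have `rho = 0`.
#' @param tiles number of simulated tiles.
#' @param seed integer RNG seed.
#' @return a list of class `theory_report`.
#' @export
verify_theory <- function(specs, tiles, seed) {
  stopifnot(tiles >= 2)
  n <- length(specs)
  l <- rep(c(1L, 0L), length.out = tiles)
  labels <- data.frame(tile_id = sprintf("t%06d", seq_len(tiles)),
                       l = l, stringsAsFactors = FALSE)
  scores <- simulate_scores(labels, specs, seed)
  tv <- vapply(specs, `[[`, numeric(1), "true_threshold")
  names(tv) <- colnames(scores)
  votes <- binarize(scores, tv)
  correct <- votes == matrix(l, nrow = tiles, ncol = n)
  single_acc <- colMeans(correct)
  a <- agreement(votes, labels)
  k0 <- floor(n / 2) + 1
  majority_success <- mean(a >= k0)
  mv <- majority_vote(votes, scores)
  vote_accuracy <- mean(mv$predicted_label == l)
  p_bar <- mean(single_acc)
  p_ens <- ensemble_success_probability(n, p_bar)
  se <- function(x) sqrt(x * (1 - x) / tiles)
  structure(list(
    n_models = n, n_tiles = tiles,
    single_model_accuracy = single_acc,
    mean_single_accuracy = p_bar,
    empirical_majority_success = majority_success,
    empirical_vote_accuracy = vote_accuracy,
    tie_rate = mean(mv$tie_flag),
    predicted_success = p_ens,
    difference = majority_success - p_ens,
    mc_se = se(p_ens),
    within_3se = abs(majority_success - p_ens) <= 3 * se(p_ens)
  ), class = "theory_report")
}

#' @export
print.theory_report <- function(x, ...) {
  cat("Binomial ensemble-success theory check\n")
  cat(sprintf("  models: %d   tiles: %d\n", x$n_models, x$n_tiles))
  cat(sprintf("  mean single-model accuracy: %.4f\n", x$mean_single_accuracy))
  cat(sprintf("  closed-form majority success: %.4f\n", x$predicted_success))
  cat(sprintf("  empirical majority success:   %.4f (diff %+.4f, MC SE %.4f)\n",
              x$empirical_majority_success, x$difference, x$mc_se))
  cat(sprintf("  tie rate: %.4f   tie-broken vote accuracy: %.4f\n",
              x$tie_rate, x$empirical_vote_accuracy))
  invisible(x)
}
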