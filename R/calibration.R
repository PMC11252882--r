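# Per-model Dice-optimal binarization thresholds.
#
# CNN softmax outputs are not guaranteed to be calibrated, so instead of
# cutting at 0.5 each base model gets its own threshold: the value that
# maximises the Dice score of its binarized predictions pooled over all
# training divisions the model was NOT trained on (model i trains on
# division i, calibrates on divisions != i). The held-out test set is
# never used for calibration.

#' Dice score of a binary prediction
#'
#' `2 TP / (2 TP + FP + FN)` with the invasive-cancer class as positive.
#' When there are no positives in either vector (TP + FP + FN = 0) the
#' score is defined as 1.
#'
#' @param pred,truth binary vectors (0/1) of equal length.
#' @return numeric in `[0, 1]`.
#' @examples
#' dice_score(c(1, 1, 1, 0, 1), c(1, 1, 1, 1, 0))  # TP=3 FP=1 FN=1 -> 0.75
#' @export
dice_score <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth have different lengths")
  if (length(pred) < 1) stop("empty vectors")
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Candidate thresholds for an exact Dice search
#'
#' The Dice score of `score >= tau` is piecewise constant in `tau`, changing
#' only at observed score values; searching the midpoints between
#' consecutive distinct sorted scores, plus the endpoints 0 and 1, is
#' therefore equivalent to searching all real thresholds.
#'
#' @param scores numeric vector in `[0, 1]`.
#' @return sorted numeric vector of candidate thresholds.
#' @export
threshold_candidates <- function(scores) {
  s <- sort(unique(scores))
  mids <- if (length(s) > 1) (s[-length(s)] + s[-1]) / 2 else numeric(0)
  sort(unique(c(0, mids, 1)))
}

# pooled Dice at every candidate, via sorted cumulative counts.
# Candidates other than 0 and 1 never coincide with a score value, so
# "number of scores < tau" = findInterval(tau, sorted scores).
dice_at_candidates <- function(scores, truth, candidates) {
  ord <- order(scores)
  s <- scores[ord]
  t <- truth[ord]
  n <- length(s)
  cum_pos <- c(0, cumsum(t == 1))
  total_pos <- cum_pos[n + 1]
  n_below <- findInterval(candidates, s)
  n_below[candidates == 0] <- 0L
  n_below[candidates == 1] <- sum(s < 1)
  fn <- cum_pos[n_below + 1]
  tp <- total_pos - fn
  fp <- (n - n_below) - tp
  denom <- 2 * tp + fp + fn
  ifelse(denom == 0, 1, 2 * tp / denom)
}

#' Calibrate one model's binarization threshold
#'
#' Pools the labeled training tiles from every division except the model's
#' own, evaluates the pooled Dice score of `score >= tau` at all candidate
#' thresholds ([threshold_candidates()]) and returns the maximiser, ties
#' broken towards the smallest threshold (favouring sensitivity).
#'
#' @param scores numeric score vector named by `tile_id` (one model's
#'   column), or the full score matrix together with `model_id`.
#' @param labels labeled tile table covering the scored tiles.
#' @param plan partition plan with divisions filled
#'   (see [make_divisions()]).
#' @param own_division the division the model was trained on (excluded).
#' @param model_id column to use when `scores` is a matrix.
#' @return a list with `tau`, `dice` (pooled Dice at `tau`),
#'   `divisions_used` and `n_tiles`.
#' @export
calibrate_threshold <- function(scores, labels, plan, own_division,
                                model_id = NULL) {
  if (is.matrix(scores)) {
    stopifnot(!is.null(model_id))
    scores <- scores[, model_id]
  }
  train_wsis <- plan$wsi_id[plan$split == "train" &
                              !is.na(plan$division) &
                              plan$division != own_division]
  keep <- labels$wsi_id %in% train_wsis
  if (!any(keep))
    stop("no tiles outside division ", own_division, " to calibrate on")
  ids <- labels$tile_id[keep]
  if (!all(ids %in% names(scores)))
    stop("scores do not cover all out-of-division training tiles")
  sc <- scores[ids]
  tr <- labels$l[keep]
  cand <- threshold_candidates(sc)
  d <- dice_at_candidates(sc, tr, cand)
  best <- which.max(d)   # first maximum = smallest tau
  divs <- sort(unique(plan$division[plan$split == "train" &
                                      !is.na(plan$division)]))
  list(tau = cand[best], dice = d[best],
       divisions_used = setdiff(divs, own_division), n_tiles = length(sc))
}

#' Calibrate thresholds for every model in a score matrix
#'
#' Applies [calibrate_threshold()] to each column; by default model `i` is
#' taken to have been trained on division `i`.
#'
#' @param scores score matrix (rows tiles, columns models).
#' @param labels labeled tile table.
#' @param plan partition plan with divisions.
#' @param model_divisions integer vector mapping each column to its own
#'   training division; default `1:ncol(scores)`.
#' @return data.frame with columns `model_id`, `tau`, `dice`, `n_tiles`,
#'   plus a `divisions_excluded` attribute; this is the threshold vector
#'   consumed by [binarize()].
#' @export
calibrate_thresholds <- function(scores, labels, plan,
                                 model_divisions = seq_len(ncol(scores))) {
  stopifnot(length(model_divisions) == ncol(scores))
  res <- lapply(seq_len(ncol(scores)), function(j)
    calibrate_threshold(scores[, j], labels, plan, model_divisions[j]))
  out <- data.frame(
    model_id = colnames(scores),
    tau = vapply(res, `[[`, numeric(1), "tau"),
    dice = vapply(res, `[[`, numeric(1), "dice"),
    n_tiles = vapply(res, `[[`, numeric(1), "n_tiles"),
    stringsAsFactors = FALSE
  )
  attr(out, "divisions_excluded") <- model_divisions
  out
}

#' Read / write threshold vectors (JSON)
#'
#' Serialized as `{model_id: {tau, dice, divisions_excluded}}`.
#' @param taus threshold table from [calibrate_thresholds()].
#' @param path JSON file path.
#' @export
write_thresholds <- function(taus, path) {
  excl <- attr(taus, "divisions_excluded")
  obj <- stats::setNames(lapply(seq_len(nrow(taus)), function(i)
    list(tau = taus$tau[i], dice = taus$dice[i],
         divisions_excluded = if (!is.null(excl)) excl[i] else NA)),
    taus$model_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  data.frame(model_id = names(obj),
             tau = vapply(obj, function(x) x$tau, numeric(1)),
             dice = vapply(obj, function(x) x$dice, numeric(1)),
             stringsAsFactors = FALSE)
}
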