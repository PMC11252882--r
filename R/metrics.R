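# Per-WSI and pooled evaluation: accuracy, Dice, specificity, precision,
# and the per-WSI ensemble-vs-single-model win rate. The invasive-cancer
# class (l = 1) is the positive class throughout. Ratios with a zero
# denominator are reported as NA ("not available"), never imputed as 0.

#' Confusion counts for a binary prediction
#'
#' @param pred,truth binary vectors (0/1) of equal length; positive class
#'   is invasive cancer (1).
#' @return named integer vector `(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth have different lengths")
  c(tp = sum(pred == 1 & truth == 1),
    fp = sum(pred == 1 & truth == 0),
    tn = sum(pred == 0 & truth == 0),
    fn = sum(pred == 0 & truth == 1))
}

# metrics from counts; zero denominators -> NA
metrics_from_counts <- function(cc) {
  tp <- cc[["tp"]]; fp <- cc[["fp"]]; tn <- cc[["tn"]]; fn <- cc[["fn"]]
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = ratio(tp + tn, tp + tn + fp + fn),
       dice = ratio(2 * tp, 2 * tp + fp + fn),
       specificity = ratio(tn, tn + fp),
       precision = ratio(tp, tp + fp))
}

metrics_row <- function(scope, system, pred, truth) {
  cc <- confusion_counts(pred, truth)
  m <- metrics_from_counts(cc)
  data.frame(scope = scope, system = system,
             tp = cc[["tp"]], fp = cc[["fp"]], tn = cc[["tn"]], fn = cc[["fn"]],
             accuracy = m$accuracy, dice = m$dice,
             specificity = m$specificity, precision = m$precision,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-WSI and pooled metrics with the ensemble-vs-single comparison
#'
#' Computes accuracy, Dice, specificity and precision per slide and pooled
#' over all tiles, for the ensemble and for one designated single base
#' model, and the fraction of slides on which the ensemble's accuracy is
#' strictly greater than the single model's (ties counted as non-wins and
#' reported separately). On a slide with no IC tiles and no predicted IC,
#' Dice (`2TP + FP + FN = 0`) and precision (`TP + FP = 0`) are undefined
#' and reported as not available; specificity is still computed. Note this
#' reporting convention differs from [dice_score()], whose calibration
#' objective defines the empty case as 1.
#'
#' @param ensemble ensemble result table ([ensemble_result()]).
#' @param single a result table for the single-model baseline: any
#'   data.frame with `tile_id` and `predicted_label` (e.g. built from one
#'   vote column).
#' @param labels labeled tile table with `tile_id`, `wsi_id`, `l`.
#' @return a list of class `metrics_report` with elements `per_wsi` and
#'   `pooled` (flat data.frames, one row per slide x system plus pooled
#'   rows) and `comparison` (`win_rate`, `ties`, `n_wsis`).
#' @export
wsi_metrics <- function(ensemble, single, labels) {
  idx_e <- match(labels$tile_id, ensemble$tile_id)
  idx_s <- match(labels$tile_id, single$tile_id)
  if (anyNA(idx_e) || anyNA(idx_s))
    stop("result tables do not cover all labeled tiles")
  pe <- ensemble$predicted_label[idx_e]
  ps <- single$predicted_label[idx_s]
  truth <- labels$l
  wsis <- sort(unique(labels$wsi_id))
  rows <- list()
  wins <- 0L; ties <- 0L; used <- 0L
  for (w in wsis) {
    k <- labels$wsi_id == w
    if (!any(k)) {
      warning("slide ", w, " has zero tiles; excluded")
      next
    }
    re <- metrics_row(w, "ensemble", pe[k], truth[k])
    rs <- metrics_row(w, "single", ps[k], truth[k])
    rows[[length(rows) + 1L]] <- re
    rows[[length(rows) + 1L]] <- rs
    used <- used + 1L
    if (isTRUE(re$accuracy > rs$accuracy)) wins <- wins + 1L
    else if (isTRUE(re$accuracy == rs$accuracy)) ties <- ties + 1L
  }
  per_wsi <- do.call(rbind, rows)
  pooled <- rbind(metrics_row("pooled", "ensemble", pe, truth),
                  metrics_row("pooled", "single", ps, truth))
  structure(list(per_wsi = per_wsi, pooled = pooled,
                 comparison = list(win_rate = wins / used,
                                   ties = ties, n_wsis = used)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Pooled metrics (positive class = invasive cancer):\n")
  print(x$pooled, row.names = FALSE)
  cat(sprintf("Ensemble beats single model on %.1f%% of %d slides (%d ties)\n",
              100 * x$comparison$win_rate, x$comparison$n_wsis,
              x$comparison$ties))
  invisible(x)
}

#' Write a metrics report to CSV and JSON
#'
#' The CSV is flat (one row per slide x system plus pooled rows, columns
#' `scope, system, tp, fp, tn, fn, accuracy, dice, specificity, precision`);
#' the JSON mirrors the full report including the win-rate comparison.
#' Undefined metrics are empty cells / nulls.
#'
#' @param report metrics report from [wsi_metrics()].
#' @param csv_path,json_path output paths (either may be NULL to skip).
#' @export
write_metrics_report <- function(report, csv_path = NULL, json_path = NULL) {
  flat <- rbind(report$per_wsi, report$pooled)
  if (!is.null(csv_path))
    utils::write.csv(flat, csv_path, row.names = FALSE, quote = TRUE, na = "")
  if (!is.null(json_path))
    jsonlite::write_json(list(per_wsi = report$per_wsi,
                              pooled = report$pooled,
                              comparison = report$comparison),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  invisible(report)
}
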