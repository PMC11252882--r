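# Synthetic study generator: tile grids, multi-class blob annotations,
# clinical covariates and simulated score matrices, in exactly the formats
# the rest of the pipeline reads. Only geometry, labels and scores are
# synthesized - never pixel textures.

#' Specify a synthetic study
#'
#' Defines a complete desk-scale study emulating the structure of an
#' annotated breast-cancer WSI cohort: a regular tile grid per slide,
#' overlapping multi-class polygon annotations (invasive cancer plus
#' confusable classes such as DCIS), per-slide clinical covariates, and a
#' family of simulated base models.
#'
#' Annotation regions are randomized star-convex blobs (random radii at
#' fixed angular steps around a random center), giving ragged borders where
#' center-rule labeling is nontrivial. When `target_ic_fraction` is set,
#' a global radius multiplier is tuned by bisection until the realized IC
#' tile fraction is within `ic_fraction_tol` of the target.
#'
#' @param n_wsis number of slides; default 10.
#' @param grid_rows,grid_cols tile-grid shape per slide; default 30 x 30.
#' @param side_px tile side in pixels; default 598.
#' @param n_ic_blobs invasive-cancer blobs per slide; default 2.
#' @param ic_radius_range blob radius range in tile units; default c(5, 9).
#' @param other_classes confusable annotation classes; default
#'   `c("DCIS", "benign epithelium")`.
#' @param n_other_blobs blobs per other class per slide; default 1.
#' @param other_radius_range radius range for other classes; default c(2, 5).
#' @param target_ic_fraction optional target fraction of IC tiles per
#'   slide (e.g. 0.3); NULL disables tuning.
#' @param ic_fraction_tol tolerance for the tuned fraction; default 0.03.
#' @param nhg_probs,er_probs,her2_probs,ki67_probs covariate sampling
#'   probabilities (named vectors; defaults reflect a typical breast-cancer
#'   cohort mix with a small missing share).
#' @param model_specs list of [sim_model_spec()]; default 10 models with
#'   `p_correct = 0.8`, `true_threshold = 0.5`, `concentration = 2`,
#'   `rho = 0`.
#' @param seed integer seed (mandatory).
#' @return an object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(
    n_wsis = 10, grid_rows = 30, grid_cols = 30, side_px = 598,
    n_ic_blobs = 2, ic_radius_range = c(5, 9),
    other_classes = c("DCIS", "benign epithelium"),
    n_other_blobs = 1, other_radius_range = c(2, 5),
    target_ic_fraction = 0.3, ic_fraction_tol = 0.03,
    nhg_probs = c("1" = 0.2, "2" = 0.45, "3" = 0.3, missing = 0.05),
    er_probs = c(positive = 0.75, negative = 0.2, missing = 0.05),
    her2_probs = c(positive = 0.15, negative = 0.8, missing = 0.05),
    ki67_probs = c(positive = 0.5, negative = 0.45, missing = 0.05),
    model_specs = NULL, seed) {
  stopifnot(n_wsis >= 1, grid_rows >= 2, grid_cols >= 2,
            ic_radius_range[1] > 0,
            ic_radius_range[2] <= min(grid_rows, grid_cols),
            is.numeric(seed))
  for (p in list(nhg_probs, er_probs, her2_probs, ki67_probs))
    stopifnot(all(p >= 0), all(p <= 1), abs(sum(p) - 1) < 1e-8)
  if (is.null(model_specs))
    model_specs <- lapply(1:10, function(i)
      sim_model_spec(sprintf("model%02d", i), p_correct = 0.8,
                     true_threshold = 0.5, concentration = 2, rho = 0))
  structure(list(
    n_wsis = n_wsis, grid_rows = grid_rows, grid_cols = grid_cols,
    side_px = side_px, n_ic_blobs = n_ic_blobs,
    ic_radius_range = ic_radius_range, other_classes = other_classes,
    n_other_blobs = n_other_blobs, other_radius_range = other_radius_range,
    target_ic_fraction = target_ic_fraction,
    ic_fraction_tol = ic_fraction_tol,
    nhg_probs = nhg_probs, er_probs = er_probs, her2_probs = her2_probs,
    ki67_probs = ki67_probs, model_specs = model_specs, seed = seed
  ), class = "synthetic_study_spec")
}

# one star-convex blob: radii drawn per angular step, scaled by `mult`,
# snapped to pixel coordinates
make_blob <- function(cx, cy, radius_range, side_px, mult = 1,
                      n_angles = 12) {
  r <- stats::runif(n_angles, radius_range[1], radius_range[2]) * mult *
    side_px
  th <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  cbind(x = round(cx + r * cos(th), 1), y = round(cy + r * sin(th), 1))
}

# blobs for one slide at a given radius multiplier (seeded by caller)
slide_blobs <- function(spec, wsi_id, mult) {
  w <- spec$grid_cols * spec$side_px
  h <- spec$grid_rows * spec$side_px
  polys <- list()
  for (b in seq_len(spec$n_ic_blobs)) {
    polys[[length(polys) + 1L]] <- list(
      wsi_id = wsi_id, class_label = "invasive cancer",
      outer = make_blob(stats::runif(1, 0.2 * w, 0.8 * w),
                        stats::runif(1, 0.2 * h, 0.8 * h),
                        spec$ic_radius_range, spec$side_px, mult),
      holes = list())
  }
  for (cl in spec$other_classes) {
    for (b in seq_len(spec$n_other_blobs)) {
      polys[[length(polys) + 1L]] <- list(
        wsi_id = wsi_id, class_label = cl,
        outer = make_blob(stats::runif(1, 0.1 * w, 0.9 * w),
                          stats::runif(1, 0.1 * h, 0.9 * h),
                          spec$other_radius_range, spec$side_px, 1),
        holes = list())
    }
  }
  polys
}

#' Generate a complete synthetic study
#'
#' Produces, for each slide, a tile grid and overlapping polygon
#' annotations; assigns ground-truth tile labels by the center rule;
#' samples clinical covariates; and simulates the score matrix over all
#' tiles. When `dir` is given, writes `tiles.csv`, `labels.csv` (the
#' generator's intended labels), `clinical.csv`, `scores.csv`,
#' `model_specs.yaml` and one `annotations_<wsi>.geojson` per slide - the
#' exact formats the other modules read. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [synthetic_study_spec()].
#' @param dir optional output directory (created if missing).
#' @return a list with `tiles`, `labels` (labeled tile table), `polys`,
#'   `clinical`, `scores`, `spec`, invisibly when `dir` is given.
#' @export
generate_study <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  if (spec$ic_radius_range[2] > min(spec$grid_rows, spec$grid_cols))
    stop("blob radius exceeds the tile grid")
  set.seed(spec$seed)
  wsi_ids <- sprintf("wsi%03d", seq_len(spec$n_wsis))
  all_tiles <- list(); all_polys <- list(); all_labels <- list()
  for (w in wsi_ids) {
    tiles <- tile_grid(w, spec$grid_rows, spec$grid_cols, spec$side_px)
    # tune a radius multiplier toward the target IC fraction (bisection
    # on a fixed blob draw; blob shape scales continuously with it)
    blob_seed <- sample.int(2^30, 1)
    draw <- function(mult) {
      set.seed(blob_seed)
      slide_blobs(spec, w, mult)
    }
    frac_of <- function(polys) {
      lab <- assign_labels(tiles, polys)
      mean(lab$l)
    }
    mult <- 1
    polys <- draw(mult)
    if (!is.null(spec$target_ic_fraction)) {
      lo <- 0.05; hi <- 3
      for (it in 1:25) {
        f <- frac_of(draw(mult))
        if (abs(f - spec$target_ic_fraction) <= spec$ic_fraction_tol) break
        if (f < spec$target_ic_fraction) lo <- mult else hi <- mult
        mult <- (lo + hi) / 2
      }
      polys <- draw(mult)
    }
    set.seed(blob_seed + 1)  # advance past the blob draw deterministically
    labels <- assign_labels(tiles, polys)
    all_tiles[[w]] <- tiles
    all_polys <- c(all_polys, polys)
    all_labels[[w]] <- labels
  }
  tiles <- do.call(rbind, all_tiles)
  labels <- do.call(rbind, all_labels)
  rownames(tiles) <- rownames(labels) <- NULL
  # clinical covariates
  set.seed(spec$seed + 1)
  draw_cat <- function(p, n) sample(names(p), n, replace = TRUE, prob = p)
  clinical <- data.frame(
    wsi_id = wsi_ids,
    nhg = draw_cat(spec$nhg_probs, spec$n_wsis),
    er = draw_cat(spec$er_probs, spec$n_wsis),
    her2 = draw_cat(spec$her2_probs, spec$n_wsis),
    ki67 = draw_cat(spec$ki67_probs, spec$n_wsis),
    stringsAsFactors = FALSE
  )
  scores <- simulate_scores(labels, spec$model_specs, spec$seed + 2)
  out <- list(tiles = tiles, labels = labels, polys = all_polys,
              clinical = clinical, scores = scores, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_tiles(tiles, file.path(dir, "tiles.csv"))
    write_labeled_tiles(labels, file.path(dir, "labels.csv"))
    write_clinical(clinical, file.path(dir, "clinical.csv"))
    write_scores(scores, file.path(dir, "scores.csv"))
    write_model_specs(spec$model_specs, file.path(dir, "model_specs.yaml"))
    for (w in wsi_ids)
      write_annotations(Filter(function(p) p$wsi_id == w, all_polys),
                        file.path(dir, sprintf("annotations_%s.geojson", w)))
    return(invisible(out))
  }
  out
}

#' Run the whole pipeline on a synthetic study
#'
#' The end-to-end smoke demo: generate a study, relabel the tiles from the
#' emitted GeoJSON (exercising the serialisation round trip), split slides
#' 80/20 stratified on the clinical covariates, divide the training slides
#' into `N` groups, calibrate each model's Dice-optimal threshold on its
#' out-of-division training tiles, vote on the held-out test tiles,
#' evaluate per-slide and pooled metrics against a single-model baseline,
#' and write every artifact (CSV/JSON tables and, optionally, the overlay,
#' histogram and confusion plots).
#'
#' @param spec a [synthetic_study_spec()]; needs at least
#'   `ceiling(N / (1 - test_fraction))` slides.
#' @param N number of divisions / base models; default
#'   `length(spec$model_specs)`.
#' @param seed integer seed for the partition.
#' @param dir output directory.
#' @param test_fraction held-out slide fraction; default 0.2.
#' @param single_model baseline model column; default 1.
#' @param plots also render PNG figures; default FALSE (tables are always
#'   written).
#' @return a list with `labels`, `plan`, `taus`, `result` (test tiles),
#'   `report` ([wsi_metrics()] output) and `paths`.
#' @export
end_to_end_demo <- function(spec, N = NULL, seed, dir,
                            test_fraction = 0.2, single_model = 1,
                            plots = FALSE) {
  if (is.null(N)) N <- length(spec$model_specs)
  stopifnot(length(spec$model_specs) == N)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_study(spec, dir)
  # round trip: recover labels from the emitted GeoJSON files
  polys <- list()
  for (f in sort(list.files(dir, pattern = "^annotations_.*\\.geojson$",
                            full.names = TRUE)))
    polys <- c(polys, read_annotations(f))
  labels <- assign_labels(study$tiles, polys)
  plan <- split_train_test(study$clinical, test_fraction, seed)
  plan <- make_divisions(plan, study$clinical, N, seed + 1)
  write_partition_plan(plan, file.path(dir, "partition.csv"))
  taus <- calibrate_thresholds(study$scores, labels, plan)
  write_thresholds(taus, file.path(dir, "thresholds.json"))
  test_wsis <- plan$wsi_id[plan$split == "test"]
  test_labels <- labels[labels$wsi_id %in% test_wsis, ]
  test_scores <- study$scores[test_labels$tile_id, , drop = FALSE]
  votes <- binarize(test_scores, taus)
  result <- ensemble_result(votes, test_scores, test_labels)
  write_ensemble_result(result, file.path(dir, "ensemble_result.csv"))
  single <- data.frame(tile_id = rownames(votes),
                       predicted_label = votes[, single_model],
                       stringsAsFactors = FALSE)
  report <- wsi_metrics(result, single, test_labels)
  write_metrics_report(report, file.path(dir, "metrics.csv"),
                       file.path(dir, "metrics.json"))
  hist_tab <- agreement_histogram(
    result, test_labels, n = N,
    out_png = if (plots) file.path(dir, "agreement_histogram.png") else NULL,
    out_csv = file.path(dir, "agreement_histogram.csv"))
  conf_tab <- multilabel_confusion(
    test_labels, result,
    out_png = if (plots) file.path(dir, "confusion.png") else NULL,
    out_csv = file.path(dir, "confusion.csv"))
  if (plots) {
    w1 <- test_wsis[1]
    render_overlay(study$tiles[study$tiles$wsi_id == w1, ],
                   test_labels[test_labels$wsi_id == w1, ],
                   result[result$tile_id %in%
                            test_labels$tile_id[test_labels$wsi_id == w1], ],
                   n = N, out = file.path(dir, "overlay.png"))
  }
  list(labels = labels, plan = plan, taus = taus, result = result,
       report = report, histogram = hist_tab, confusion = conf_tab,
       paths = dir)
}
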