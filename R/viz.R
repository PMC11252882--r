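# Agreement visualisations: the per-tile glyph overlay (ground-truth
# square, greyscale agreement diamond, prediction X), the agreement
# histogram, and the original-class x predicted-binary confusion matrix.
# Every plot has a CSV twin so numeric checks never depend on pixels.

# class colours: orange = invasive cancer, blue = not IC
tv_colors <- function() c(ic = "#FF8C00", not_ic = "#1F77B4")

#' Render the per-tile agreement overlay for one slide
#'
#' For every tile three glyphs are drawn at the tile center: a square
#' outline coloured by the ground-truth class, a filled diamond on a
#' greyscale ramp encoding agreement (black = 0 of `n` models voted for
#' the true class, white = all `n`), and an X coloured by the predicted
#' class. Orange is invasive cancer, blue is not. Glyph sizes are 90%
#' (square), 60% (diamond) and 40% (X) of the tile cell so all three stay
#' visible.
#'
#' @param tiles tile table for one slide.
#' @param labels labeled tile table for the same tiles.
#' @param result ensemble result table with `agreement` filled.
#' @param n number of base models (greyscale maximum).
#' @param out output PNG path.
#' @param background optional raster (e.g. from `png::readPNG`) drawn
#'   under the glyphs, spanning the tile grid.
#' @param px_per_tile rendered pixels per tile cell; default 20.
#' @return `out`, invisibly.
#' @export
render_overlay <- function(tiles, labels, result, n, out, background = NULL,
                           px_per_tile = 20) {
  if (length(unique(tiles$wsi_id)) != 1)
    stop("render_overlay draws one slide at a time")
  if (!setequal(tiles$tile_id, result$tile_id) ||
      !setequal(tiles$tile_id, labels$tile_id))
    stop("tiles, labels and result cover different tile sets")
  il <- match(tiles$tile_id, labels$tile_id)
  ir <- match(tiles$tile_id, result$tile_id)
  cen <- tile_centers(tiles)
  side <- tiles$x1[1] - tiles$x0[1]
  a <- result$agreement[ir]
  if (anyNA(a)) stop("result carries no agreement values")
  cols <- tv_colors()
  df <- data.frame(
    x = cen[, 1], y = cen[, 2],
    truth = factor(ifelse(labels$l[il] == 1, "IC", "not IC"),
                   levels = c("IC", "not IC")),
    pred = factor(ifelse(result$predicted_label[ir] == 1, "IC", "not IC"),
                  levels = c("IC", "not IC")),
    grey = grDevices::rgb(round(255 * a / n), round(255 * a / n),
                          round(255 * a / n), maxColorValue = 255)
  )
  cell_pt <- px_per_tile * 72 / 96 / ggplot2::.pt  # cell size in ggplot size units
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(background))
    p <- p + ggplot2::annotation_raster(
      background, xmin = min(tiles$x0), xmax = max(tiles$x1),
      ymin = -max(tiles$y1), ymax = -min(tiles$y0))
  p <- p +
    ggplot2::aes(y = -.data$y) +  # image convention: row 0 on top
    ggplot2::geom_point(ggplot2::aes(colour = .data$truth), shape = 0,
                        size = 0.9 * cell_pt, stroke = 0.6) +
    ggplot2::geom_point(shape = 18, colour = df$grey, size = 0.6 * cell_pt) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$pred), shape = 4,
                        size = 0.4 * cell_pt, stroke = 0.6) +
    ggplot2::scale_colour_manual(
      values = c("IC" = unname(cols["ic"]), "not IC" = unname(cols["not_ic"])),
      name = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = unique(tiles$wsi_id),
      subtitle = sprintf(
        "square = ground truth, diamond = agreement (black 0 .. white %d), X = prediction", n),
      caption = "orange = invasive cancer, blue = not IC",
      x = NULL, y = NULL) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "bottom",
                   plot.title = ggplot2::element_text(hjust = 0.5),
                   plot.subtitle = ggplot2::element_text(hjust = 0.5, size = 8))
  n_cols <- max(tiles$col) + 1
  n_rows <- max(tiles$row) + 1
  ggplot2::ggsave(out, p, width = max(4, n_cols * px_per_tile / 96),
                  height = max(4, n_rows * px_per_tile / 96 + 1), dpi = 96,
                  device = grDevices::png, units = "in", limitsize = FALSE)
  invisible(out)
}

#' Agreement histogram
#'
#' Counts test tiles at each agreement value `0..n`, split by true class,
#' and optionally renders the bar chart and writes the counts as CSV.
#'
#' @param result ensemble result table with `agreement`.
#' @param labels labeled tile table.
#' @param n number of base models; default `max(agreement)` observed.
#' @param out_png,out_csv optional output paths.
#' @return data.frame with columns `agreement`, `class`, `count` (all
#'   `0..n` x class combinations, zero counts included).
#' @export
agreement_histogram <- function(result, labels, n = NULL,
                                out_png = NULL, out_csv = NULL) {
  if (nrow(result) == 0) {
    warning("empty ensemble result; no histogram produced")
    return(data.frame(agreement = integer(0), class = character(0),
                      count = integer(0)))
  }
  idx <- match(result$tile_id, labels$tile_id)
  cls <- ifelse(labels$l[idx] == 1, "IC", "not IC")
  a <- result$agreement
  if (is.null(n)) n <- max(a)
  tab <- expand.grid(agreement = 0:n, class = c("IC", "not IC"),
                     stringsAsFactors = FALSE)
  tab$count <- mapply(function(ag, cl) sum(a == ag & cls == cl),
                      tab$agreement, tab$class)
  if (!is.null(out_csv))
    utils::write.csv(tab, out_csv, row.names = FALSE, quote = TRUE)
  if (!is.null(out_png)) {
    cols <- tv_colors()
    p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$agreement,
                                           y = .data$count,
                                           fill = .data$class)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::scale_fill_manual(
        values = c("IC" = unname(cols["ic"]),
                   "not IC" = unname(cols["not_ic"]))) +
      ggplot2::scale_x_continuous(breaks = 0:n) +
      ggplot2::labs(x = sprintf("agreement (models voting for the true class, of %d)", n),
                    y = "tiles", fill = NULL) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(out_png, p, width = 7, height = 4, dpi = 96,
                    device = grDevices::png, units = "in")
  }
  tab
}

#' Original-class vs predicted-binary confusion matrix
#'
#' For each annotation class appearing in the labeled tiles, counts how its
#' tiles were predicted (IC vs not IC). Annotation polygons overlap, so a
#' tile carrying several labels contributes to every matching row; tiles
#' with an empty label set form their own "unannotated" row when
#' `include_unlabeled` is TRUE. Optionally renders an annotated heatmap
#' with a per-class total bar chart, and writes the table as CSV.
#'
#' @param labels labeled tile table (original labels retained).
#' @param result ensemble result table.
#' @param include_unlabeled add a row for tiles with no annotation;
#'   default TRUE.
#' @param out_png,out_csv optional output paths.
#' @return data.frame with columns `class`, `n_pred_ic`, `n_pred_not_ic`,
#'   `pct_pred_ic`, `pct_pred_not_ic`, `total`.
#' @export
multilabel_confusion <- function(labels, result, include_unlabeled = TRUE,
                                 out_png = NULL, out_csv = NULL) {
  idx <- match(labels$tile_id, result$tile_id)
  if (anyNA(idx)) stop("result does not cover all labeled tiles")
  pred <- result$predicted_label[idx]
  sets <- strsplit(labels$labels, ";", fixed = TRUE)
  classes <- sort(unique(unlist(sets)))
  classes <- classes[classes != ""]
  rows <- lapply(classes, function(cl) {
    k <- vapply(sets, function(s) cl %in% s, logical(1))
    data.frame(class = cl, n_pred_ic = sum(pred[k] == 1),
               n_pred_not_ic = sum(pred[k] == 0),
               stringsAsFactors = FALSE)
  })
  if (include_unlabeled) {
    k <- labels$labels == ""
    if (any(k))
      rows[[length(rows) + 1L]] <- data.frame(
        class = "unannotated", n_pred_ic = sum(pred[k] == 1),
        n_pred_not_ic = sum(pred[k] == 0), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    return(data.frame(class = character(0), n_pred_ic = integer(0),
                      n_pred_not_ic = integer(0), pct_pred_ic = numeric(0),
                      pct_pred_not_ic = numeric(0), total = integer(0)))
  tab$total <- tab$n_pred_ic + tab$n_pred_not_ic
  tab$pct_pred_ic <- 100 * tab$n_pred_ic / tab$total
  tab$pct_pred_not_ic <- 100 * tab$n_pred_not_ic / tab$total
  tab <- tab[, c("class", "n_pred_ic", "n_pred_not_ic",
                 "pct_pred_ic", "pct_pred_not_ic", "total")]
  if (!is.null(out_csv))
    utils::write.csv(tab, out_csv, row.names = FALSE, quote = TRUE)
  if (!is.null(out_png)) {
    long <- rbind(
      data.frame(class = tab$class, predicted = "IC",
                 pct = tab$pct_pred_ic, count = tab$n_pred_ic),
      data.frame(class = tab$class, predicted = "not IC",
                 pct = tab$pct_pred_not_ic, count = tab$n_pred_not_ic))
    p1 <- ggplot2::ggplot(long, ggplot2::aes(x = .data$predicted,
                                             y = .data$class,
                                             fill = .data$pct)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(
        label = sprintf("%.1f%%\n(%d)", .data$pct, .data$count)), size = 3) +
      ggplot2::scale_fill_gradient(low = "white", high = "#FF8C00",
                                   limits = c(0, 100), name = "%") +
      ggplot2::labs(x = "ensemble prediction", y = NULL) +
      ggplot2::theme_minimal()
    p2 <- ggplot2::ggplot(tab, ggplot2::aes(y = .data$class,
                                            x = .data$total)) +
      ggplot2::geom_col(fill = "#1F77B4") +
      ggplot2::labs(x = "tiles with this label", y = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.y = ggplot2::element_blank())
    g <- cbind(ggplot2::ggplotGrob(p1), ggplot2::ggplotGrob(p2),
               size = "first")
    grDevices::png(out_png, width = 9 * 96, height = 96 *
                     max(3, 0.6 * nrow(tab) + 1.5), res = 96)
    grid::grid.draw(g)
    grDevices::dev.off()
  }
  tab
}
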