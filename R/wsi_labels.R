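# Tile grids, polygon annotations, and tile labeling by the center rule.
#
# Coordinates are 0-based WSI pixels. Tile bounding boxes are half-open:
# a tile occupies [x0, x1) x [y0, y1) with x1 - x0 == y1 - y0 == side_px.
# Grid indices (row, col) are 0-based.

#' Build a rectangular tile grid for one slide
#'
#' Creates the tile table for a whole-slide image analysed as a regular grid
#' of square tiles. The default tile geometry is 598 x 598 pixels at 20X
#' magnification (0.4532 microns per pixel, i.e. 271 x 271 micrometres).
#'
#' @param wsi_id slide identifier (scalar string).
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param side_px tile side length in pixels; default 598.
#' @param microns_per_px physical pixel size; default 0.4532.
#' @return data.frame with columns `tile_id`, `wsi_id`, `row`, `col`,
#'   `x0`, `y0`, `x1`, `y1` (0-based, half-open pixel boxes). Tile centers
#'   are `(x0 + x1) / 2`, `(y0 + y1) / 2`.
#' @examples
#' tiles <- tile_grid("slide1", 4, 4, side_px = 1)
#' nrow(tiles)  # 16
#' @export
tile_grid <- function(wsi_id, n_rows, n_cols, side_px = 598,
                      microns_per_px = 0.4532) {
  stopifnot(length(wsi_id) == 1, n_rows >= 1, n_cols >= 1, side_px > 0,
            microns_per_px > 0)
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  out <- data.frame(
    tile_id = sprintf("%s_r%d_c%d", wsi_id, row, col),
    wsi_id = as.character(wsi_id),
    row = row, col = col,
    x0 = col * side_px, y0 = row * side_px,
    x1 = (col + 1L) * side_px, y1 = (row + 1L) * side_px,
    stringsAsFactors = FALSE
  )
  attr(out, "side_px") <- side_px
  attr(out, "microns_per_px") <- microns_per_px
  out
}

tile_centers <- function(tiles) {
  cbind(x = (tiles$x0 + tiles$x1) / 2, y = (tiles$y0 + tiles$y1) / 2)
}

#' Read polygon annotations from a GeoJSON file
#'
#' Parses an RFC 7946 FeatureCollection of Polygon / MultiPolygon features
#' into a list of annotation polygons. The class label is read from
#' `properties.classification.name`, falling back to `properties.label`;
#' the slide identifier from `properties.wsi_id`. MultiPolygons are expanded
#' to one annotation per outer ring, holes preserved.
#'
#' @param path GeoJSON file path.
#' @param wsi_id optional slide id applied to features that carry none.
#' @return list of annotations; each is a list with elements `wsi_id`,
#'   `class_label`, `outer` (vertex matrix) and `holes` (list of matrices).
#' @export
read_annotations <- function(path, wsi_id = NULL) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection in ", path)
  feats <- gj$features
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    lab <- f$properties$classification$name
    if (is.null(lab)) lab <- f$properties$label
    if (is.null(lab))
      stop("feature ", i, " has neither properties.classification.name ",
           "nor properties.label")
    wid <- f$properties$wsi_id
    if (is.null(wid)) wid <- wsi_id
    if (is.null(wid))
      stop("feature ", i, " has no wsi_id and none was supplied")
    g <- f$geometry
    ring_to_matrix <- function(r)
      matrix(unlist(r), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
    if (identical(g$type, "Polygon")) {
      polys <- list(g$coordinates)
    } else if (identical(g$type, "MultiPolygon")) {
      polys <- g$coordinates
    } else {
      stop("feature ", i, " has unsupported geometry type '", g$type,
           "'; only Polygon and MultiPolygon are accepted")
    }
    for (p in polys) {
      rings <- lapply(p, ring_to_matrix)
      out[[length(out) + 1L]] <- list(
        wsi_id = as.character(wid),
        class_label = as.character(lab),
        outer = rings[[1]],
        holes = if (length(rings) > 1) rings[-1] else list()
      )
    }
  }
  out
}

#' Write polygon annotations to a GeoJSON file
#'
#' Inverse of [read_annotations()]: writes one Polygon feature per
#' annotation with the class label under `properties.classification.name`
#' and the slide id under `properties.wsi_id`.
#'
#' @param polys list of annotations as returned by [read_annotations()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(polys, path) {
  close_ring <- function(m) {
    n <- nrow(m)
    if (!(m[n, 1] == m[1, 1] && m[n, 2] == m[1, 2])) m <- rbind(m, m[1, ])
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  }
  feats <- lapply(polys, function(p) {
    rings <- c(list(close_ring(p$outer)), lapply(p$holes, close_ring))
    list(
      type = "Feature",
      properties = list(
        classification = list(name = p$class_label),
        wsi_id = p$wsi_id
      ),
      geometry = list(type = "Polygon", coordinates = rings)
    )
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# case-insensitive, whitespace-normalised class-name key
normalise_class <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Default invasive-carcinoma class set
#'
#' The annotation classes mapped to the positive (IC) binary label:
#' invasive cancer and invasive lobular cancer.
#' @return character vector.
#' @export
default_ic_classes <- function() c("invasive cancer", "invasive lobular cancer")

#' Assign annotation labels to tiles by the center rule
#'
#' Each tile receives an annotation class when the tile's center point lies
#' inside (or on the boundary of) a polygon of that class on the same slide.
#' When `min_area_fraction > 0`, the tile additionally must overlap the
#' polygon by at least that fraction of the tile area. Annotations of
#' different classes may overlap, so a tile can carry several labels. The
#' binary label `l` is 1 iff the tile's label set intersects `ic_classes`
#' (matched case-insensitively after whitespace normalisation); tiles
#' covered by no polygon get an empty label set and `l = 0`.
#'
#' @param tiles tile table (see [tile_grid()]); may span several slides.
#' @param polys annotation list (see [read_annotations()]).
#' @param ic_classes classes mapped to the positive label;
#'   default [default_ic_classes()].
#' @param min_area_fraction minimum tile-polygon overlap as a fraction of
#'   tile area, in `[0, 1]`; default 0 (pure center rule).
#' @return the tile table with added columns `labels` (";"-joined class
#'   names, "" when empty) and `l` (integer 0/1).
#' @export
assign_labels <- function(tiles, polys, ic_classes = default_ic_classes(),
                          min_area_fraction = 0) {
  stopifnot(min_area_fraction >= 0, min_area_fraction <= 1)
  cen <- tile_centers(tiles)
  tile_area <- (tiles$x1 - tiles$x0) * (tiles$y1 - tiles$y0)
  label_sets <- vector("list", nrow(tiles))
  for (p in polys) {
    idx <- which(tiles$wsi_id == p$wsi_id)
    if (length(idx) == 0) next
    hit <- point_in_polygon(cen[idx, 1], cen[idx, 2], p$outer, p$holes)
    if (min_area_fraction > 0 && any(hit)) {
      for (k in which(hit)) {
        i <- idx[k]
        a <- polygon_rect_intersection_area(
          p$outer, p$holes, tiles$x0[i], tiles$y0[i], tiles$x1[i], tiles$y1[i])
        if (a < min_area_fraction * tile_area[i]) hit[k] <- FALSE
      }
    }
    for (i in idx[hit])
      label_sets[[i]] <- union(label_sets[[i]], p$class_label)
  }
  ic_norm <- normalise_class(ic_classes)
  labels <- vapply(label_sets, function(s)
    if (is.null(s)) "" else paste(sort(s), collapse = ";"), character(1))
  l <- vapply(label_sets, function(s)
    as.integer(!is.null(s) && any(normalise_class(s) %in% ic_norm)),
    integer(1))
  out <- tiles
  out$labels <- labels
  out$l <- l
  out
}

#' Read / write labeled tile tables
#'
#' CSV with columns `tile_id, wsi_id, row, col, x0, y0, x1, y1, labels, l`;
#' `labels` is a ";"-joined list (empty string for no label). Coordinates
#' are 0-based pixels with half-open tile boxes.
#'
#' @param x labeled tile table.
#' @param path CSV file path.
#' @return `read_labeled_tiles` returns the table; `write_labeled_tiles`
#'   returns `path` invisibly.
#' @export
write_labeled_tiles <- function(x, path) {
  utils::write.csv(x[, c("tile_id", "wsi_id", "row", "col",
                         "x0", "y0", "x1", "y1", "labels", "l")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_labeled_tiles
#' @export
read_labeled_tiles <- function(path) {
  out <- utils::read.csv(path, colClasses = c(
    tile_id = "character", wsi_id = "character", labels = "character"))
  out$labels[is.na(out$labels)] <- ""
  out
}

#' @rdname write_labeled_tiles
#' @export
write_tiles <- function(x, path) {
  utils::write.csv(x[, c("tile_id", "wsi_id", "row", "col",
                         "x0", "y0", "x1", "y1")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_labeled_tiles
#' @export
read_tiles <- function(path) {
  utils::read.csv(path, colClasses = c(tile_id = "character",
                                       wsi_id = "character"))
}
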