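# Planar polygon primitives used by the tile-labeling module.
# Conventions: 0-based WSI pixel coordinates; rings are n x 2 matrices of
# vertices, closed implicitly (last vertex connects back to the first);
# a point exactly on a ring edge counts as inside (closed-polygon rule).

#' Test points against a single polygon ring
#'
#' Even-odd (ray casting) containment of points in one ring. Points lying
#' exactly on an edge or vertex are counted as inside.
#'
#' @param px,py numeric vectors of point coordinates (equal length).
#' @param ring numeric matrix with columns x, y; vertices in order, not
#'   necessarily repeated at the end.
#' @param eps tolerance for the on-edge test, in coordinate units.
#' @return logical vector, one entry per point.
#' @keywords internal
point_in_ring <- function(px, py, ring, eps = 1e-9) {
  stopifnot(length(px) == length(py), is.matrix(ring), ncol(ring) == 2)
  rx <- ring[, 1]; ry <- ring[, 2]
  nv <- length(rx)
  if (nv < 3) stop("ring must have at least 3 vertices")
  # drop an explicitly repeated closing vertex
  if (rx[nv] == rx[1] && ry[nv] == ry[1]) {
    rx <- rx[-nv]; ry <- ry[-nv]; nv <- nv - 1L
    if (nv < 3) stop("ring must have at least 3 distinct vertices")
  }
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  jx <- rx[nv]; jy <- ry[nv]
  for (i in seq_len(nv)) {
    ix <- rx[i]; iy <- ry[i]
    # on-segment check: collinear and within the bounding box of the edge
    cross <- (px - jx) * (iy - jy) - (py - jy) * (ix - jx)
    seg_len2 <- (ix - jx)^2 + (iy - jy)^2
    col_ok <- abs(cross) <= eps * sqrt(pmax(seg_len2, 1))
    in_box <- px >= pmin(ix, jx) - eps & px <= pmax(ix, jx) + eps &
      py >= pmin(iy, jy) - eps & py <= pmax(iy, jy) + eps
    on_edge <- on_edge | (col_ok & in_box)
    # even-odd crossing of a horizontal ray to +infinity
    crosses <- ((iy > py) != (jy > py)) &
      (px < (jx - ix) * (py - iy) / (jy - iy) + ix)
    inside <- xor(inside, crosses)
    jx <- ix; jy <- iy
  }
  inside | on_edge
}

#' Test points against a polygon with optional holes
#'
#' A point is inside when an even-odd count over the outer ring and all hole
#' rings is odd, or when it lies on any ring boundary. Points strictly inside
#' a hole are therefore outside; points on a hole edge are inside.
#'
#' @param px,py numeric point coordinates.
#' @param outer outer ring matrix (columns x, y).
#' @param holes list of hole ring matrices (possibly empty).
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, outer, holes = list()) {
  res <- point_in_ring(px, py, outer)
  for (h in holes) {
    in_h <- point_in_ring(px, py, h, eps = 0)        # strict interior + edge
    on_h <- point_on_ring_edge(px, py, h)
    res <- res & (!in_h | on_h)
  }
  res
}

# on-edge test alone (used to keep hole boundaries inside the polygon)
point_on_ring_edge <- function(px, py, ring, eps = 1e-9) {
  rx <- ring[, 1]; ry <- ring[, 2]
  nv <- length(rx)
  if (rx[nv] == rx[1] && ry[nv] == ry[1]) {
    rx <- rx[-nv]; ry <- ry[-nv]; nv <- nv - 1L
  }
  on_edge <- rep(FALSE, length(px))
  jx <- rx[nv]; jy <- ry[nv]
  for (i in seq_len(nv)) {
    ix <- rx[i]; iy <- ry[i]
    cross <- (px - jx) * (iy - jy) - (py - jy) * (ix - jx)
    seg_len2 <- (ix - jx)^2 + (iy - jy)^2
    col_ok <- abs(cross) <= eps * sqrt(pmax(seg_len2, 1))
    in_box <- px >= pmin(ix, jx) - eps & px <= pmax(ix, jx) + eps &
      py >= pmin(iy, jy) - eps & py <= pmax(iy, jy) + eps
    on_edge <- on_edge | (col_ok & in_box)
    jx <- ix; jy <- iy
  }
  on_edge
}

#' Unsigned area of a ring (shoelace formula)
#' @param ring vertex matrix (columns x, y).
#' @return non-negative numeric scalar.
#' @keywords internal
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (x[n] == x[1] && y[n] == y[1]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Clip a ring to an axis-aligned rectangle (Sutherland-Hodgman)
#'
#' @param ring vertex matrix.
#' @param x0,y0,x1,y1 rectangle bounds, x0 < x1, y0 < y1.
#' @return clipped vertex matrix (possibly with 0 rows).
#' @keywords internal
clip_ring_rect <- function(ring, x0, y0, x1, y1) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (n >= 2 && x[n] == x[1] && y[n] == y[1]) { x <- x[-n]; y <- y[-n] }
  clip_side <- function(x, y, keep, intersect) {
    n <- length(x)
    if (n == 0) return(list(x = numeric(0), y = numeric(0)))
    ox <- numeric(0); oy <- numeric(0)
    jx <- x[n]; jy <- y[n]; jkeep <- keep(jx, jy)
    for (i in seq_len(n)) {
      ix <- x[i]; iy <- y[i]; ikeep <- keep(ix, iy)
      if (ikeep) {
        if (!jkeep) {
          p <- intersect(jx, jy, ix, iy)
          ox <- c(ox, p[1]); oy <- c(oy, p[2])
        }
        ox <- c(ox, ix); oy <- c(oy, iy)
      } else if (jkeep) {
        p <- intersect(jx, jy, ix, iy)
        ox <- c(ox, p[1]); oy <- c(oy, p[2])
      }
      jx <- ix; jy <- iy; jkeep <- ikeep
    }
    list(x = ox, y = oy)
  }
  v <- list(x = x, y = y)
  v <- clip_side(v$x, v$y, function(x, y) x >= x0, function(ax, ay, bx, by) {
    t <- (x0 - ax) / (bx - ax); c(x0, ay + t * (by - ay)) })
  v <- clip_side(v$x, v$y, function(x, y) x <= x1, function(ax, ay, bx, by) {
    t <- (x1 - ax) / (bx - ax); c(x1, ay + t * (by - ay)) })
  v <- clip_side(v$x, v$y, function(x, y) y >= y0, function(ax, ay, bx, by) {
    t <- (y0 - ay) / (by - ay); c(ax + t * (bx - ax), y0) })
  v <- clip_side(v$x, v$y, function(x, y) y <= y1, function(ax, ay, bx, by) {
    t <- (y1 - ay) / (by - ay); c(ax + t * (bx - ax), y1) })
  cbind(x = v$x, y = v$y)
}

#' Area of the intersection of a polygon (with holes) and a rectangle
#'
#' Valid for simple rings; hole areas clipped to the rectangle are
#' subtracted from the clipped outer area.
#'
#' @param outer outer ring matrix.
#' @param holes list of hole rings.
#' @param x0,y0,x1,y1 rectangle bounds.
#' @return non-negative numeric scalar.
#' @keywords internal
polygon_rect_intersection_area <- function(outer, holes, x0, y0, x1, y1) {
  cl <- clip_ring_rect(outer, x0, y0, x1, y1)
  if (nrow(cl) < 3) return(0)
  a <- ring_area(cl)
  for (h in holes) {
    ch <- clip_ring_rect(h, x0, y0, x1, y1)
    if (nrow(ch) >= 3) a <- a - ring_area(ch)
  }
  max(a, 0)
}
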