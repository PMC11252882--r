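make_square_poly <- function(wsi, cls, x0, y0, x1, y1)
  list(wsi_id = wsi, class_label = cls,
       outer = cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1)),
       holes = list())

test_that("GeoJSON annotations round-trip through read/write", {
  polys <- list(
    make_square_poly("w1", "invasive cancer", 0, 0, 2, 2),
    list(wsi_id = "w1", class_label = "DCIS",
         outer = cbind(x = c(0, 6, 6, 0), y = c(0, 0, 6, 6)),
         holes = list(cbind(x = c(2, 4, 4, 2), y = c(2, 2, 4, 4))))
  )
  f <- withr::local_tempfile(fileext = ".geojson")
  write_annotations(polys, f)
  got <- read_annotations(f)
  expect_length(got, 2)
  expect_equal(got[[1]]$class_label, "invasive cancer")
  expect_equal(got[[2]]$wsi_id, "w1")
  expect_length(got[[2]]$holes, 1)
  # vertices preserved (up to ring closure)
  expect_equal(got[[1]]$outer[1:4, ], polys[[1]]$outer,
               ignore_attr = TRUE)
})

test_that("read_annotations rejects bad features with informative errors", {
  f <- withr::local_tempfile(fileext = ".geojson")
  # empty collection is fine
  jsonlite::write_json(list(type = "FeatureCollection", features = list()),
                       f, auto_unbox = TRUE)
  expect_length(read_annotations(f), 0)
  # point geometry
  jsonlite::write_json(list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(label = "x", wsi_id = "w"),
    geometry = list(type = "Point", coordinates = c(1, 2))))),
    f, auto_unbox = TRUE)
  expect_error(read_annotations(f), "Point")
  # missing label
  jsonlite::write_json(list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(wsi_id = "w"),
    geometry = list(type = "Polygon",
                    coordinates = list(list(c(0, 0), c(1, 0), c(1, 1), c(0, 0))))))),
    f, auto_unbox = TRUE)
  expect_error(read_annotations(f), "feature 1")
})

test_that("center rule labels a half-covering polygon exactly", {
  tiles <- tile_grid("w1", 4, 4, side_px = 1)
  poly <- make_square_poly("w1", "invasive cancer", 0, 0, 2, 4)
  lab <- assign_labels(tiles, list(poly))
  expect_equal(sum(lab$l), 8)
  expect_setequal(lab$col[lab$l == 1], c(0, 1))
})

test_that("overlapping polygons stack labels; IC mapping is set intersection", {
  tiles <- tile_grid("w1", 2, 2, side_px = 1)
  polys <- list(make_square_poly("w1", "DCIS", 0, 0, 2, 2),
                make_square_poly("w1", "Invasive  Cancer", 0, 0, 1, 1))
  lab <- assign_labels(tiles, polys)
  expect_equal(sort(strsplit(lab$labels[1], ";")[[1]]),
               c("DCIS", "Invasive  Cancer"))
  expect_equal(lab$l, c(1L, 0L, 0L, 0L))  # case/space-insensitive IC match
})

test_that("label assignment matches the point-in-polygon oracle on random scenes", {
  set.seed(99)
  for (rep in 1:25) {
    tiles <- tile_grid("w1", 8, 8, side_px = 1)
    polys <- lapply(1:3, function(i)
      list(wsi_id = "w1", class_label = "invasive cancer",
           outer = random_star_ring(runif(1, 2, 6), runif(1, 2, 6), 0.5, 3.5),
           holes = list()))
    lab <- assign_labels(tiles, polys)
    cen <- cbind((tiles$x0 + tiles$x1) / 2, (tiles$y0 + tiles$y1) / 2)
    want <- vapply(seq_len(nrow(tiles)), function(i)
      any(vapply(polys, function(p)
        oracle_point_in_ring(cen[i, 1], cen[i, 2], p$outer), logical(1))),
      logical(1))
    expect_equal(lab$l, as.integer(want))
  }
})

test_that("labels are invariant to tile and polygon ordering", {
  set.seed(7)
  tiles <- tile_grid("w1", 6, 6, side_px = 1)
  polys <- list(make_square_poly("w1", "invasive cancer", 0, 0, 3.3, 3.3),
                make_square_poly("w1", "DCIS", 2.2, 2.2, 6, 6))
  a <- assign_labels(tiles, polys)
  perm <- sample(nrow(tiles))
  b <- assign_labels(tiles[perm, ], rev(polys))
  b <- b[order(match(b$tile_id, a$tile_id)), ]
  expect_equal(a$labels, b$labels, ignore_attr = TRUE)
  expect_equal(a$l, b$l, ignore_attr = TRUE)
})

test_that("min_area_fraction filters center hits with small overlap", {
  tiles <- tile_grid("w1", 1, 1, side_px = 1)
  # sliver covering the center but only 20% of the tile area
  poly <- make_square_poly("w1", "invasive cancer", 0.4, 0, 0.6, 1)
  expect_equal(assign_labels(tiles, list(poly))$l, 1L)
  expect_equal(assign_labels(tiles, list(poly), min_area_fraction = 0.1)$l, 1L)
  expect_equal(assign_labels(tiles, list(poly), min_area_fraction = 0.5)$l, 0L)
})

test_that("hole in an annotation removes tiles whose center falls in it", {
  tiles <- tile_grid("w1", 4, 4, side_px = 1)
  poly <- list(wsi_id = "w1", class_label = "invasive cancer",
               outer = cbind(x = c(0, 4, 4, 0), y = c(0, 0, 4, 4)),
               holes = list(cbind(x = c(1, 3, 3, 1), y = c(1, 1, 3, 3))))
  lab <- assign_labels(tiles, list(poly))
  expect_equal(sum(lab$l), 12)  # the central 2x2 centers fall in the hole
})

test_that("labeled tile tables survive the CSV round trip", {
  tiles <- tile_grid("w1", 3, 3, side_px = 2)
  lab <- assign_labels(tiles, list(make_square_poly("w1", "invasive cancer",
                                                    0, 0, 3, 3)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_labeled_tiles(lab, f)
  got <- read_labeled_tiles(f)
  expect_equal(got$tile_id, lab$tile_id)
  expect_equal(got$l, lab$l)
  expect_equal(got$labels, lab$labels)
})
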