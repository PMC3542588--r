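test_that("the prediction grid spans the bounding box evenly", {
  d <- ed_dataset(data.frame(x = c(0, 10, 3), y = c(0, 4, 2), day = 1:3,
                             outcome = c(0, 1, 0), age = 1:3))
  g2 <- make_grid(d, 2, 2)
  expect_equal(g2$points$x, c(0, 10, 0, 10))
  expect_equal(g2$points$y, c(0, 0, 4, 4))
  g3 <- make_grid(d, 3, 2)
  expect_equal(g3$xs, c(0, 5, 10))
  g <- make_grid(d, 50, 40)
  expect_equal(nrow(g$points), 2000)
  expect_equal(diff(g$xs)[1], 10 / 49)
  expect_equal(diff(g$ys)[1], 4 / 39)
  dd <- ed_dataset(data.frame(x = rep(1, 3), y = rep(1, 3), day = 1:3,
                              outcome = c(0, 1, 0), age = 1:3))
  expect_error(make_grid(dd, 5, 5), "degenerate")
})

test_that("masking clips by polygon and by distance to data", {
  box <- ed_dataset(data.frame(x = c(0, 10), y = c(0, 10), day = 1:2,
                               outcome = 0:1, age = 1:2))
  d <- ed_dataset(data.frame(x = seq(0, 10, length.out = 11),
                             y = rep(5, 11), day = 1:11,
                             outcome = rep(c(0, 1), length.out = 11),
                             age = 1:11))
  g <- make_grid(box, 11, 11)
  expect_true(all(apply_mask(g)$active))
  # polygon covering the left half keeps exactly the left-half lattice
  left <- list(rbind(c(-0.1, -1), c(5.01, -1), c(5.01, 11), c(-0.1, 11)))
  gm <- apply_mask(g, polygon = left)
  expect_identical(gm$active, g$points$x <= 5.01)
  # distance mask keeps only nodes adjacent to the data line y = 5
  gd <- apply_mask(g, data = d, max_mask_distance = 0.5 * 1)
  expect_identical(gd$active, abs(g$points$y - 5) <= 0.5)
  # min_points raises the density bar
  one <- ed_dataset(data.frame(x = 5, y = 5, day = 1, outcome = 1, age = 1))
  expect_error(apply_mask(g, data = one, max_mask_distance = 0.4,
                          min_points = 2), "excludes every")
})

test_that("point-in-polygon uses the even-odd rule with closed boundaries", {
  sq <- list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)))
  pip <- function(x, y, poly) edgam:::point_in_polygon(
    data.frame(x = x, y = y), edgam:::as_ed_polygon(poly))
  expect_true(pip(0.5, 0.5, sq))
  expect_false(pip(1.5, 0.5, sq))
  expect_true(pip(1, 0.5, sq))     # boundary counts as inside
  expect_true(pip(0, 0, sq))       # corner counts as inside
  # square with a hole: even-odd excludes the hole interior
  holed <- list(rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)),
                rbind(c(1, 1), c(3, 1), c(3, 3), c(1, 3)))
  expect_false(pip(2, 2, holed))
  expect_true(pip(0.5, 0.5, holed))
  expect_true(pip(2, 3.5, holed))
})

test_that("GeoJSON masks parse into rings", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    type = "Feature", properties = NULL,
    geometry = list(type = "MultiPolygon", coordinates = list(
      list(list(c(0, 0), c(4, 0), c(4, 4), c(0, 4), c(0, 0)),
           list(c(1, 1), c(3, 1), c(3, 3), c(1, 3), c(1, 1)))))),
    auto_unbox = TRUE, digits = NA), p)
  pg <- read_mask(p)
  expect_s3_class(pg, "ed_polygon")
  expect_length(pg, 2)
  inside <- edgam:::point_in_polygon(
    data.frame(x = c(0.5, 2, 2), y = c(0.5, 2, 3.5)), pg)
  expect_identical(inside, c(TRUE, FALSE, TRUE))
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"type": "Point", "coordinates": [1, 2]}', bad)
  expect_error(read_mask(bad), "unsupported")
})
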