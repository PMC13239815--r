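write_square_geojson <- function(path, cx, cy, half_deg, n_features = 1,
                                 offset = 0) {
  feat <- function(dx) {
    ring <- lapply(list(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1), c(-1, -1)),
                   function(s) c(cx + dx + s[1] * half_deg,
                                 cy + s[2] * half_deg))
    list(type = "Feature", properties = list(),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  }
  jsonlite::write_json(list(
    type = "FeatureCollection",
    features = lapply(seq_len(n_features) - 1, function(i) feat(i * offset))
  ), path, auto_unbox = TRUE, digits = 10)
  path
}

test_that("a square boundary projects to its known area", {
  path <- write_square_geojson(tempfile(fileext = ".geojson"),
                               -78.2, 0, 0.05)
  b <- read_boundary(path)
  pb <- project_boundary(b, list(center = c(-78.2, 0)))
  side_km <- haversine_km(c(-78.2, -0.05), c(-78.2, 0.05))
  expect_equal(boundary_area_km2(pb), side_km^2, tolerance = 1e-3)
})

test_that("overlapping features dissolve without double counting", {
  # two 0.1-degree squares offset by half a side: union = 1.5 squares
  path <- write_square_geojson(tempfile(fileext = ".geojson"),
                               -78.2, 0, 0.05, n_features = 2, offset = 0.05)
  b <- read_boundary(path)
  pb <- project_boundary(b, list(center = c(-78.2, 0)))
  side_km <- haversine_km(c(-78.2, -0.05), c(-78.2, 0.05))
  expect_equal(boundary_area_km2(pb), 1.5 * side_km^2, tolerance = 0.01)
})

test_that("files without polygons are rejected", {
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(list(
    type = "FeatureCollection",
    features = list(list(type = "Feature", properties = list(),
                         geometry = list(type = "Point",
                                         coordinates = c(-78.2, 2.9))))
  ), path, auto_unbox = TRUE)
  expect_error(read_boundary(path), "no polygon")
})

test_that("containment is 100/50/0 on constructed overlaps", {
  contour <- square_ring(0, 0, 500) # 1 km square at the origin
  inside <- percent_contained(contour, square_ring(0, 0, 5000))
  expect_equal(inside$percent, 100, tolerance = 1e-9)
  # boundary covering exactly the left half
  half <- rbind(c(-500, -500), c(0, -500), c(0, 500), c(-500, 500),
                c(-500, -500))
  expect_equal(percent_contained(contour, half)$percent, 50,
               tolerance = 0.1)
  disjoint <- percent_contained(contour, square_ring(10000, 0, 500))
  expect_equal(disjoint$percent, 0, tolerance = 1e-9)
})

test_that("containment is invariant under joint rigid motions", {
  set.seed(51)
  contour <- square_ring(200, -100, 700)
  boundary <- square_ring(600, 100, 900)
  base <- percent_contained(contour, boundary)$percent
  for (theta in c(0.3, 1.1, 2.5)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    shift <- runif(2, -5000, 5000)
    rot <- function(m) sweep(m %*% R, 2, -shift)
    got <- percent_contained(rot(contour), rot(boundary))$percent
    expect_equal(got, base, tolerance = 0.1)
  }
})

test_that("buffering the boundary never decreases containment", {
  contour <- square_ring(0, 0, 1000)
  prev <- -1
  for (half in c(300, 600, 900, 1200, 2000)) {
    pc <- percent_contained(contour, square_ring(400, 0, half))$percent
    expect_gte(pc, prev - 1e-9)
    prev <- pc
  }
})

test_that("the raster fallback agrees with exact convex clipping", {
  set.seed(52)
  spec <- grid_spec(cell = 100)
  pts <- cbind(rnorm(40, 0, 2000), rnorm(40, 0, 1200))
  ct <- ud_contour(weighted_kde(pts, runif(40), spec, 900), 0.5)
  # one convex square vs the same region split into two touching
  # rectangles: the two-polygon form takes the subsampled-cell path
  exact <- percent_contained(ct, square_ring(500, 200, 2500))$percent
  split_boundary <- structure(list(polygons = list(
    list(outer = rbind(c(-2000, -2300), c(3000, -2300), c(3000, 200),
                       c(-2000, 200), c(-2000, -2300)), holes = list()),
    list(outer = rbind(c(-2000, 200), c(3000, 200), c(3000, 2700),
                       c(-2000, 2700), c(-2000, 200)), holes = list())
  ), name = "split", source = NA), class = "mpaud_boundary_planar")
  approx <- percent_contained(ct, split_boundary)$percent
  expect_equal(approx, exact, tolerance = 0.3 / max(exact, 1))
})

test_that("empty contours are rejected", {
  expect_error(percent_contained(list(), square_ring(0, 0, 100)), "empty")
})
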