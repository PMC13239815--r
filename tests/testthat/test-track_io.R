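test_that("read_fixes parses the canonical dialect into per-animal tracks", {
  path <- write_fix_csv(data.frame(
    animal_id = "T01",
    timestamp_utc = c("2010-01-01T00:00:00", "2010-01-01T06:00:00",
                      "2010-01-01T12:00:00"),
    lon = c(-78.2, -78.21, -78.19), lat = c(2.95, 2.96, 2.94),
    lc = c("3", "B", "Z")))
  tracks <- read_fixes(path)
  expect_length(tracks, 1)
  expect_equal(nrow(tracks$T01), 3)
  expect_equal(as.character(tracks$T01$lc), c("3", "B", "Z"))
})

test_that("read_fixes sorts fixes ascending in time", {
  path <- write_fix_csv(data.frame(
    animal_id = "X",
    timestamp_utc = c("2010-01-02T00:00:00", "2010-01-01T00:00:00"),
    lon = c(-78.2, -78.3), lat = c(2.9, 3.0), lc = c("1", "2")))
  tr <- read_fixes(path)$X
  expect_true(all(diff(as.numeric(tr$time)) >= 0))
  expect_equal(as.character(tr$lc), c("2", "1"))
})

test_that("rows with invalid LC or timestamp are rejected, others kept", {
  path <- write_fix_csv(data.frame(
    animal_id = "X",
    timestamp_utc = c("2010-01-01T00:00:00", "2010-01-01T06:00:00",
                      "not-a-time"),
    lon = c(-78.2, -78.2, -78.2), lat = c(2.9, 2.9, 2.9),
    lc = c("3", "Q", "A")))
  expect_warning(tracks <- read_fixes(path), "rejected 2")
  expect_equal(nrow(tracks$X), 1)
  expect_equal(attr(tracks, "rejected"), c(3L, 4L)) # line numbers after header
})

test_that("a missing required column is a hard error", {
  path <- write_fix_csv(data.frame(
    animal_id = "X", timestamp_utc = "2010-01-01T00:00:00",
    lon = -78.2, lat = 2.9))
  expect_error(read_fixes(path), "lc")
})

test_that("a dialect mapping renames foreign columns", {
  path <- write_fix_csv(data.frame(
    id = "X", date = "2010-01-01 06:00:00",
    longitude = -78.2, latitude = 2.9, quality = "A"))
  tracks <- read_fixes(path, dialect = c(
    animal_id = "id", timestamp_utc = "date",
    lon = "longitude", lat = "latitude", lc = "quality"))
  expect_equal(as.character(tracks$X$lc), "A")
})

test_that("filtering regimes retain the stated LC sets, preserving order", {
  tr <- make_track(lcs = c("3", "2", "1", "0", "A", "B", "Z"))
  hr <- filter_fixes(tr, "home_range")
  expect_equal(as.character(hr$lc), c("3", "2", "1", "A"))
  mg <- filter_fixes(tr, "migration")
  expect_equal(as.character(mg$lc), c("3", "2", "1", "0", "A", "B"))
  lg <- attr(hr, "filter_log")
  expect_equal(lg$n_raw, 7)
  expect_equal(sum(lg$excluded_by_lc), 3)
  expect_equal(unname(lg$excluded_by_lc[c("0", "B", "Z")]), c(1L, 1L, 1L))
})

test_that("an all-B track filters to an empty track with a warning", {
  tr <- make_track(lcs = rep("B", 5))
  expect_warning(out <- filter_fixes(tr, "home_range"), "excluded")
  expect_equal(nrow(out), 0)
})

test_that("filtering is idempotent and home_range is nested in migration", {
  set.seed(11)
  for (rep in 1:5) {
    tr <- make_track(lcs = sample(LC_LEVELS, 20, replace = TRUE))
    for (regime in c("home_range", "migration")) {
      once <- suppressWarnings(filter_fixes(tr, regime))
      twice <- suppressWarnings(filter_fixes(once, regime))
      expect_equal(as.data.frame(twice)[, 1:5], as.data.frame(once)[, 1:5])
    }
    hr <- suppressWarnings(filter_fixes(tr, "home_range"))
    mg <- suppressWarnings(filter_fixes(tr, "migration"))
    key <- function(t) paste(t$time, t$lon, t$lat, t$lc)
    expect_true(all(key(hr) %in% key(mg)))
  }
})

test_that("write_fixes / read_fixes round-trips on the canonical dialect", {
  tr <- make_track(lcs = c("3", "A", "B", "2", "Z"))
  path <- tempfile(fileext = ".csv")
  write_fixes(tr, path)
  back <- read_fixes(path)[[1]]
  expect_equal(back$animal_id, tr$animal_id)
  expect_equal(as.numeric(back$time), as.numeric(tr$time))
  expect_equal(back$lon, tr$lon, tolerance = 1e-9)
  expect_equal(back$lat, tr$lat, tolerance = 1e-9)
  expect_equal(as.character(back$lc), as.character(tr$lc))
})

test_that("duplicate timestamps are kept, ordered by LC accuracy", {
  t0 <- as.POSIXct("2010-01-01", tz = "UTC")
  tr <- track("X", c(t0, t0), c(-78.2, -78.3), c(2.9, 3.0), c("B", "1"))
  expect_equal(nrow(tr), 2)
  expect_equal(as.character(tr$lc), c("1", "B"))
})

test_that("invalid LC codes error at parse time", {
  expect_error(parse_lc(c("3", "Q")), "Q")
  expect_error(track("X", Sys.time(), 200, 2.9, "3"), "range")
})

test_that("haversine distance matches the closed form and is symmetric", {
  expect_equal(haversine_km(c(0, 0), c(0, 0)), 0)
  # one degree of latitude = 2 pi R / 360
  expect_equal(haversine_km(c(0, 0), c(0, 1)), 2 * pi * 6371 / 360,
               tolerance = 0.01 / 111)
  a <- c(-78.2, 2.9); b <- c(-77.8, 3.4)
  expect_equal(haversine_km(a, b), haversine_km(b, a))
})

test_that("mean_fix_interval is the mean successive gap in days", {
  t0 <- as.POSIXct("2010-01-01", tz = "UTC")
  tr <- track("X", t0 + c(0, 1, 2) * 86400, rep(-78.2, 3), rep(2.9, 3),
              rep("3", 3))
  expect_equal(mean_fix_interval(tr), 1)
  tr2 <- track("X", t0 + c(0, 1.3, 2.6) * 86400, rep(-78.2, 3), rep(2.9, 3),
               rep("3", 3))
  expect_equal(mean_fix_interval(tr2), 1.3)
  tr3 <- track("X", t0 + seq(0, 9.1, length.out = 8) * 86400, rep(-78.2, 8),
               rep(2.9, 8), rep("B", 8))
  expect_equal(mean_fix_interval(tr3), 9.1 / 7, tolerance = 1e-9)
  expect_error(mean_fix_interval(tr3[1, ]), "2 fixes")
})
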