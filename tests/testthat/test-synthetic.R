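test_that("resident simulation is deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 7)
  set.seed(7); a <- simulate_resident(cfg, 1)
  set.seed(7); b <- simulate_resident(cfg, 1)
  expect_identical(a$track, b$track)
  expect_identical(a$truth$mu, b$truth$mu)
})

test_that("the LC mix matches its configured probabilities", {
  cfg <- synthetic_config(seed = 7, duration_days_range = c(160, 170),
                          fix_count_range = c(10000, 10000))
  set.seed(7)
  sim <- simulate_resident(cfg, 1)
  share_b <- mean(sim$track$lc == "B")
  expect_lt(abs(share_b - cfg$lc_probs[["B"]]), 0.02)
})

test_that("all fix times fall in the on-half of the 6-h duty cycle", {
  cfg <- synthetic_config(seed = 8, duration_days_range = c(60, 90),
                          fix_count_range = c(300, 400))
  set.seed(8)
  sim <- simulate_resident(cfg, 1)
  t_s <- as.numeric(sim$track$time) - as.numeric(cfg$t0)
  expect_true(all(t_s %% (12 * 3600) < 6 * 3600))
})

test_that("OU transition sampling is exact", {
  # standardized one-step residuals of the true path must be IID N(0, 1)
  cfg <- synthetic_config(seed = 9, duration_days_range = c(165, 170),
                          fix_count_range = c(60000, 60000))
  set.seed(9)
  sim <- simulate_resident(cfg, 1)
  tr <- sim$truth
  x <- tr$xy_true; t <- tr$times
  phi <- exp(-diff(t) / tr$tau)
  n <- nrow(x)
  z <- (x[-1, ] - tr$mu[col(x[-1, ])] -
          phi * (x[-n, ] - tr$mu[col(x[-n, ])])) /
    sqrt(tr$sigma2 * (1 - phi^2))
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(sd(z) - 1), 0.02)
  expect_lt(abs(cor(z[-nrow(z), 1], z[-1, 1])), 0.02)
  # stationary variance matches sigma2
  expect_equal(mean(apply(x, 2, var)), tr$sigma2, tolerance = 0.1)
})

test_that("a jitter-free, error-free migrant moves at exactly its speed", {
  cfg <- synthetic_config(seed = 10, migrant_heading_jitter_deg = 0,
                          lc_error_table = setNames(rep(1e-6, 7), LC_LEVELS))
  set.seed(10)
  sim <- simulate_migrant(cfg, 10)
  tr <- sim$track
  d <- haversine_km(cbind(tr$lon[-nrow(tr)], tr$lat[-nrow(tr)]),
                    cbind(tr$lon[-1], tr$lat[-1]))
  dt <- diff(as.numeric(tr$time)) / 86400
  expect_true(all(abs(d / dt - 18) < 0.01))
  # net displacement after 10 days is 180 km southward
  net <- haversine_km(c(tr$lon[1], tr$lat[1]),
                      c(tr$lon[nrow(tr)], tr$lat[nrow(tr)]))
  span_d <- diff(range(as.numeric(tr$time))) / 86400
  expect_equal(net, 18 * span_d, tolerance = 1e-3)
  expect_lt(tr$lat[nrow(tr)], tr$lat[1]) # southward
})

test_that("with heading jitter the mean speed stays unbiased", {
  cfg <- synthetic_config(seed = 11,
                          lc_error_table = setNames(rep(1e-6, 7), LC_LEVELS))
  speeds <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    tr <- simulate_migrant(cfg, 10)$track
    d <- haversine_km(cbind(tr$lon[-nrow(tr)], tr$lat[-nrow(tr)]),
                      cbind(tr$lon[-1], tr$lat[-1]))
    sum(d) / (diff(range(as.numeric(tr$time))) / 86400)
  }, 0)
  expect_lt(abs(mean(speeds) / 18 - 1), 0.05)
})

test_that("make_island_scenario writes a complete, seeded dataset", {
  cfg <- synthetic_config(seed = 12, duration_days_range = c(12, 30),
                          fix_count_range = c(15, 40))
  dir <- file.path(tempdir(), "scen-test")
  out <- make_island_scenario(cfg, dir)
  expect_true(all(file.exists(out$fixes, out$boundary, out$truth)))
  tracks <- suppressWarnings(read_fixes(out$fixes))
  expect_length(tracks, 10)
  truth <- jsonlite::read_json(out$truth, simplifyVector = TRUE)
  expect_equal(truth$seed, 12)
  expect_equal(truth$migrant_id, "T10")
  # resident home centers lie inside the MPA rectangle
  for (id in setdiff(names(tracks), "T10")) {
    mu <- unlist(truth$animals[[id]]$mu)
    expect_true(abs(mu[1]) < cfg$mpa_half_extent_m[1])
    expect_true(abs(mu[2]) < cfg$mpa_half_extent_m[2])
  }
  # rerunning with the same seed reproduces the fix table byte-for-byte
  dir2 <- file.path(tempdir(), "scen-test-2")
  out2 <- make_island_scenario(cfg, dir2)
  expect_identical(readLines(out$fixes), readLines(out2$fixes))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(), "seed")
  expect_error(synthetic_config(seed = 1, lc_probs = c("3" = 0.5, "B" = 0.4)),
               "sum to 1")
})
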