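test_that("autocorrelation weights are uniform in the IID limit", {
  expect_equal(autocorr_weights(list(tau = 0), c(0, 100, 5000)), rep(1 / 3, 3))
  expect_equal(autocorr_weights(list(tau = 1e-12), 1:10 * 3600),
               rep(0.1, 10))
  expect_equal(autocorr_weights(list(tau = 3600), 42), 1)
})

test_that("clustered fixes are downweighted relative to isolated ones", {
  tau <- 3600
  times <- c(0, 0.01 * tau, 10 * tau)
  w <- autocorr_weights(list(tau = tau), times)
  # explicit 3x3 oracle
  C <- exp(-abs(outer(times, times, "-")) / tau)
  w0 <- solve(C, rep(1, 3)); w0[w0 < 0] <- 0; w0 <- w0 / sum(w0)
  expect_equal(w, w0, tolerance = 1e-12)
  expect_lt(w[1], w[3]); expect_lt(w[2], w[3])
  # the two clustered fixes roughly share one slot against the isolated fix
  expect_equal(w[1] + w[2], w[3], tolerance = 0.05)
  expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("duplicate times with tau > 0 are handled via jitter", {
  expect_message(w <- autocorr_weights(list(tau = 3600), c(0, 0, 7200)),
                 "jitter")
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_equal(w[1], w[2], tolerance = 1e-3)
})

test_that("Argos error weights are inverse to class error, max-scaled", {
  expect_equal(argos_error_weights(c("3", "A"), c("3" = 500, "A" = 1000)),
               c(1, 0.5))
  expect_equal(argos_error_weights(rep("B", 4), c(B = 9000)), rep(1, 4))
  w <- argos_error_weights(c("1", "A"), c("1" = 1000, "A" = 2000))
  expect_equal(w[1] / w[2], 2)
  expect_error(argos_error_weights(c("3", "B"), c("3" = 500)), "B")
})

test_that("combined weights are the normalized product", {
  w <- combine_weights(c(0.2, 0.3, 0.5), c(1, 1, 1))
  expect_equal(w$w, c(0.2, 0.3, 0.5))
  w2 <- combine_weights(rep(1 / 4, 4), c(1, 0.5, 1, 0.5))
  expect_equal(w2$w, c(1, 0.5, 1, 0.5) / 3)
  expect_equal(sum(w2$w), 1)
  expect_error(combine_weights(c(1, 2), c(1, 2, 3)), "length")
})

test_that("IID fit and a single LC give exactly uniform combined weights", {
  set.seed(2)
  n <- 4 # below the OU-fit threshold: IID fallback path
  xy <- matrix(rnorm(2 * n, 0, 500), ncol = 2)
  p <- make_ptrack(xy, seq_len(n) * 3600, lcs = rep("A", n))
  ws <- weighted_fixes(p, c(A = 1000))
  expect_equal(ws$w, rep(1 / n, n), tolerance = 1e-12)
  expect_equal(ws$w_auto, rep(1 / n, n))
  expect_equal(ws$w_error, rep(1, n))
})

test_that("per-animal autocorrelation weights sum to one on synthetic tracks", {
  cfg <- synthetic_config(seed = 99, n_residents = 4,
                          duration_days_range = c(15, 40),
                          fix_count_range = c(20, 60))
  set.seed(cfg$seed)
  for (i in 1:4) {
    sim <- simulate_resident(cfg, i)
    tr <- suppressWarnings(filter_fixes(sim$track, "home_range"))
    if (nrow(tr) < 2) next
    p <- project_track(tr)
    ws <- weighted_fixes(p, cfg$lc_error_table)
    expect_equal(sum(ws$w_auto), 1, tolerance = 1e-9)
    expect_equal(sum(ws$w), 1, tolerance = 1e-9)
  }
})

test_that("pooling gives every animal equal total weight", {
  set.seed(17)
  pool <- lapply(1:3, function(i) {
    n <- 5 + i * 3
    xy <- matrix(rnorm(2 * n, 0, 800), ncol = 2)
    p <- make_ptrack(xy, cumsum(runif(n, 1, 10)) * 3600,
                     lcs = sample(c("3", "1", "A"), n, replace = TRUE),
                     id = paste0("T", i))
    weighted_fixes(p, c("3" = 500, "1" = 1200, "A" = 6200))
  })
  per_animal <- vapply(pool, function(ws) sum(ws$w), 0)
  expect_equal(per_animal, rep(1, 3), tolerance = 1e-9)
  expect_equal(sum(do.call(rbind, pool)$w), 3, tolerance = 1e-9)
})

test_that("weights are permutation-equivariant", {
  set.seed(23)
  n <- 12
  times <- sort(runif(n, 0, 20)) * 3600
  lcs <- sample(c("3", "2", "A"), n, replace = TRUE)
  perm <- sample(n)
  w1 <- autocorr_weights(list(tau = 2 * 3600), times)
  w2 <- autocorr_weights(list(tau = 2 * 3600), times[perm])
  expect_equal(w2, w1[perm], tolerance = 1e-10)
  e1 <- argos_error_weights(lcs, c("3" = 500, "2" = 1000, "A" = 6200))
  e2 <- argos_error_weights(lcs[perm], c("3" = 500, "2" = 1000, "A" = 6200))
  expect_equal(e2, e1[perm])
})

test_that("the shipped LC error table is valid and complete", {
  tab <- read_lc_error_table()
  expect_setequal(names(tab), LC_LEVELS)
  expect_true(all(tab > 0))
  ord <- tab[c("3", "2", "1", "0", "A", "B")]
  expect_true(all(diff(ord) >= 0))
})
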