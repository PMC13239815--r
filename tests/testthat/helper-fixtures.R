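# Shared fixtures and independent oracles for the test suite.

# --- tracks -----------------------------------------------------------------

# A minimal track: fixes every `dt_h` hours at small lon/lat offsets.
make_track <- function(id = "A", lcs = c("3", "2", "1"), dt_h = 6,
                       lon0 = -78.2, lat0 = 2.95, spread = 0.01) {
  n <- length(lcs)
  set.seed(n * 1000 + 7)
  track(id,
        as.POSIXct("2010-01-01", tz = "UTC") + (seq_len(n) - 1) * dt_h * 3600,
        lon0 + runif(n, -spread, spread),
        lat0 + runif(n, -spread, spread),
        lcs)
}

write_fix_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# A hand-built projected track (planar coordinates given directly).
make_ptrack <- function(xy, times_s, lcs = rep("3", nrow(xy)),
                        center = c(0, 0), id = "sim") {
  structure(list(
    animal_id = id, xy = cbind(xy),
    times = times_s, lc = parse_lc(lcs),
    time0 = as.POSIXct("2010-01-01", tz = "UTC"),
    proj = list(type = "aeqd_spherical", center = center,
                radius_m = 6371000)
  ), class = "mpaud_ptrack")
}

# --- independent oracles ----------------------------------------------------

# Brute-force weighted Gaussian mixture (explicit double loop).
oracle_mixture <- function(points, weights, h, eval_xy) {
  W <- sum(weights)
  out <- numeric(nrow(eval_xy))
  for (i in seq_len(nrow(eval_xy))) {
    acc <- 0
    for (j in seq_len(nrow(points))) {
      d2 <- (eval_xy[i, 1] - points[j, 1])^2 +
        (eval_xy[i, 2] - points[j, 2])^2
      acc <- acc + weights[j] / W * exp(-d2 / (2 * h^2)) / (2 * pi * h^2)
    }
    out[i] <- acc
  }
  out
}

# Exhaustive bandwidth sweep applying the selection rule from its
# statement, independently of select_bandwidth's control flow.
oracle_bandwidth <- function(points, weights, spec, h_start, h_min,
                             step = 250) {
  hs <- seq(h_start, h_min, by = -step)
  ncomp <- vapply(hs, function(h) {
    n_effective_components(ud_contour(weighted_kde(points, weights, spec, h),
                                      0.5))
  }, 0L)
  contig <- ncomp == 1L
  split_after <- which(!contig & c(FALSE, utils::head(contig, -1)))
  if (length(split_after)) {
    return(list(chosen_h = hs[split_after[1]] + step,
                rule = "last_contiguous"))
  }
  two <- which(ncomp == 2L)
  if (length(two)) {
    return(list(chosen_h = min(hs[two]), rule = "two_polygon_fallback"))
  }
  list(chosen_h = h_min, rule = "two_polygon_fallback")
}

# Exact OU sample path at given times (direct transition recursion).
sim_ou <- function(times_s, mu, sigma, tau) {
  n <- length(times_s)
  xy <- matrix(0, n, 2)
  xy[1, ] <- mu + rnorm(2, 0, sigma)
  for (i in 2:n) {
    phi <- exp(-(times_s[i] - times_s[i - 1]) / tau)
    xy[i, ] <- mu + phi * (xy[i - 1, ] - mu) +
      rnorm(2, 0, sigma * sqrt(1 - phi^2))
  }
  xy
}

# Simulate the CRW state-space model exactly as specified: daily velocity
# persistence gamma, process scale sigma_p (m/d), observations by linear
# interpolation between daily positions plus Normal error.
sim_crw_obs <- function(gamma, sigma_p, ndays, fix_interval_d = 1.3,
                        err_sd = 0) {
  v <- matrix(0, ndays, 2)
  for (t in seq_len(ndays)) {
    prev <- if (t == 1) c(0, 0) else v[t - 1, ]
    v[t, ] <- gamma * prev + rnorm(2, 0, sigma_p)
  }
  x <- rbind(c(0, 0), apply(v, 2, cumsum)) # daily positions, day 0..ndays
  t_obs <- seq(0, ndays, by = fix_interval_d)
  obs <- cbind(approx(0:ndays, x[, 1], xout = t_obs)$y,
               approx(0:ndays, x[, 2], xout = t_obs)$y) +
    matrix(rnorm(2 * length(t_obs), 0, err_sd), ncol = 2)
  list(truth_daily = x, t_obs = t_obs, obs = obs)
}

# Two weighted point clusters separated along x, centered on the grid.
two_cluster_points <- function(sep_m, n_each = 25, spread_m = 150) {
  cbind(c(rnorm(n_each, -sep_m / 2, spread_m),
          rnorm(n_each, sep_m / 2, spread_m)),
        c(rnorm(2 * n_each, 0, spread_m)))
}

# Closed square ring (counterclockwise) as a planar matrix.
square_ring <- function(cx, cy, half) {
  rbind(c(cx - half, cy - half), c(cx + half, cy - half),
        c(cx + half, cy + half), c(cx - half, cy + half),
        c(cx - half, cy - half))
}
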