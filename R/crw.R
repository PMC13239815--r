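#' Fit a daily-step correlated random walk to a migratory track
#'
#' Linear-Gaussian state-space model estimating one "true" location per
#' day from irregular, error-prone Argos fixes. Per axis the daily state
#' carries position and velocity:
#' `x_t = x_{t-1} + v_t`, `v_t = gamma v_{t-1} + eta_t`,
#' `eta_t ~ Normal(0, sigma_p^2)`, where `gamma` in (0, 1) is the move
#' persistence and `sigma_p` the process scale (m/day). A fix at
#' fractional day `s` between daily states `t-1` and `t` is observed as
#' the linear interpolation of the two positions plus Argos error,
#' `y ~ Normal((1-a) x_{t-1} + a x_t, (k err_lc)^2)` with `a = s-(t-1)`;
#' the single inflation factor `k` absorbs the known optimism of nominal
#' Argos errors. `(gamma, sigma_p, k)` are fitted by maximum likelihood
#' through the Kalman filter (the state is augmented with the previous
#' day's position so interpolated observations stay linear), and daily
#' positions come from the Rauch-Tung-Striebel smoothing pass.
#'
#' @param ptrack projected track of migration-regime fixes (>= 4 fixes
#'   spanning >= 2 days).
#' @param lc_error_table per-LC mean error, meters ([read_lc_error_table()]).
#' @param step time step in days (the model is formulated per day).
#' @return object of class `mpaud_crwfit`: `gamma`, `sigma_p` (m/d), `k`,
#'   `loglik`, `converged`, `daily` (data frame `day,x,y,lon,lat,speed_kmd`
#'   with `ceil(span)+1` rows), `mean_speed`/`sd_speed` (km/d over
#'   smoothed daily displacements), `raw_mean_speed`/`raw_sd_speed`
#'   (segment speeds between consecutive raw fixes), `proj`.
#' @export
fit_crw <- function(ptrack, lc_error_table, step = 1) {
  xy <- ptrack$xy
  n <- nrow(xy)
  td <- ptrack$times / 86400 / step
  if (n < 4) stop("fit_crw needs >= 4 fixes (got ", n, ")")
  if (max(td) < 2) stop("fit_crw needs fixes spanning >= 2 days")
  table <- as_lc_error_table(lc_error_table)
  err <- unname(table[as.character(ptrack$lc)])
  T <- as.integer(ceiling(max(td)))

  # observation bookkeeping: interval index (day t covers (t-1, t]) and
  # interpolation weight
  t_of <- pmax(1L, as.integer(ceiling(td - 1e-9)))
  a_of <- td - (t_of - 1L)
  scale0 <- stats::median(abs(diff(xy[, 1])) + abs(diff(xy[, 2]))) /
    max(stats::median(diff(td)), 0.1)
  if (!is.finite(scale0) || scale0 <= 0) scale0 <- 1000

  nll <- function(theta) {
    g <- stats::plogis(theta[1])
    sp <- exp(theta[2])
    k <- exp(theta[3])
    out <- crw_filter(xy, t_of, a_of, td, err, T, g, sp, k, smooth = FALSE)
    if (!is.finite(out$loglik)) return(1e12)
    -out$loglik
  }
  theta0 <- c(stats::qlogis(0.5), log(scale0), 0)
  opt <- stats::optim(theta0, nll, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-10))
  g <- stats::plogis(opt$par[1])
  sp <- exp(opt$par[2])
  k <- exp(opt$par[3])
  sm <- crw_filter(xy, t_of, a_of, td, err, T, g, sp, k, smooth = TRUE)

  ll <- unproject(sm$states, ptrack$proj)
  seg_km <- haversine_km(ll[-nrow(ll), , drop = FALSE], ll[-1, , drop = FALSE])
  speed <- c(NA, seg_km / step)
  daily <- data.frame(day = 0:T, x = sm$states[, 1], y = sm$states[, 2],
                      lon = ll[, 1], lat = ll[, 2], speed_kmd = speed)

  raw_ll <- unproject(xy, ptrack$proj)
  raw_d <- haversine_km(raw_ll[-n, , drop = FALSE], raw_ll[-1, , drop = FALSE])
  raw_dt <- diff(td) * step
  pos <- raw_dt > 1e-9
  raw_speed <- raw_d[pos] / raw_dt[pos]

  structure(list(
    gamma = g, sigma_p = sp, k = k, loglik = -opt$value,
    converged = opt$convergence == 0,
    daily = daily,
    mean_speed = mean(speed[-1]), sd_speed = stats::sd(speed[-1]),
    raw_mean_speed = mean(raw_speed), raw_sd_speed = stats::sd(raw_speed),
    n_fixes = n, span_days = max(td) * step,
    proj = ptrack$proj
  ), class = "mpaud_crwfit")
}

# Kalman filter (and optional RTS smoother) for the augmented per-axis
# state (x_t, v_t, x_{t-1}). The covariance recursion is shared by the
# two axes; only the means differ.
crw_filter <- function(xy, t_of, a_of, td, err, T, g, sp, k, smooth = TRUE) {
  F <- matrix(c(1, 0, 1,
                g, g, 0,
                0, 0, 0), 3, 3) # column-major: x_t = x_{t-1} + g v_{t-1} + eta
  Q <- sp^2 * matrix(c(1, 1, 0,
                       1, 1, 0,
                       0, 0, 0), 3, 3)
  m <- matrix(0, 3, 2)
  m[1, ] <- xy[1, ]; m[3, ] <- xy[1, ]
  big <- (1e5)^2
  P <- matrix(c(big, 0, big,
                0, (5e4)^2, 0,
                big, 0, big), 3, 3)
  loglik <- 0
  update_obs <- function(i, H) {
    # floor keeps the recursion finite when the optimizer probes
    # vanishing process/observation variances on noise-free tracks
    S <- max(drop(H %*% P %*% H) + (k * err[i])^2, 1e-12)
    K <- (P %*% H) / S
    innov <- xy[i, ] - drop(crossprod(H, m))
    m <<- m + K %*% rbind(innov)
    P <<- P - K %*% crossprod(H, P)
    P <<- (P + t(P)) / 2
    loglik <<- loglik + sum(-0.5 * (log(2 * pi * S) + innov^2 / S))
  }
  # observations at day 0 exactly
  for (i in which(td <= 1e-9)) update_obs(i, c(1, 0, 0))
  mp <- vector("list", T); Pp <- vector("list", T)
  mf <- vector("list", T + 1); Pf <- vector("list", T + 1)
  mf[[1]] <- m; Pf[[1]] <- P
  for (t in seq_len(T)) {
    m <- F %*% m
    P <- F %*% P %*% t(F) + Q
    P <- (P + t(P)) / 2
    mp[[t]] <- m; Pp[[t]] <- P
    for (i in which(t_of == t & td > 1e-9)) {
      update_obs(i, c(a_of[i], 0, 1 - a_of[i]))
    }
    mf[[t + 1]] <- m; Pf[[t + 1]] <- P
  }
  if (!smooth) return(list(loglik = loglik))
  ms <- mf
  # the augmented state makes P_pred rank-deficient by construction
  # (x_{t-1} enters twice), so the smoother gain uses a pseudo-inverse
  pinv <- function(M) {
    s <- svd(M)
    tol <- 3 * max(s$d) * 1e-12
    d <- ifelse(s$d > tol, 1 / s$d, 0)
    s$v %*% (d * t(s$u))
  }
  for (t in T:1) {
    J <- Pf[[t]] %*% t(F) %*% pinv(Pp[[t]])
    ms[[t]] <- mf[[t]] + J %*% (ms[[t + 1]] - mp[[t]])
  }
  states <- t(vapply(ms, function(mm) mm[1, ], numeric(2)))
  list(loglik = loglik, states = states)
}

#' @export
print.mpaud_crwfit <- function(x, ...) {
  cat(sprintf(
    "<mpaud_crwfit> gamma=%.2f, sigma_p=%.0f m/d, k=%.2f, %d daily states, mean speed %.2f +/- %.2f km/d\n",
    x$gamma, x$sigma_p, x$k, nrow(x$daily), x$mean_speed, x$sd_speed))
  invisible(x)
}

#' Travel-speed statistics of a fitted daily path
#'
#' Sample mean and standard deviation (n - 1 denominator) of the daily
#' great-circle displacements of the smoothed path.
#'
#' @param fit a `mpaud_crwfit`, or a numeric vector of daily speeds.
#' @return named numeric `c(mean, sd)` in km/d.
#' @export
speed_stats <- function(fit) {
  speeds <- if (inherits(fit, "mpaud_crwfit")) {
    fit$daily$speed_kmd[-1]
  } else {
    as.numeric(fit)
  }
  if (length(speeds) < 1) stop("speed_stats needs >= 2 daily states")
  c(mean = mean(speeds), sd = stats::sd(speeds))
}

#' Write the daily migratory path as CSV
#' @param fit a `mpaud_crwfit`.
#' @param path output CSV (`day,lon,lat,speed_kmd`).
#' @return `path`, invisibly.
#' @export
write_daily_path_csv <- function(fit, path) {
  utils::write.csv(fit$daily[, c("day", "lon", "lat", "speed_kmd")], path,
                   row.names = FALSE)
  invisible(path)
}
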