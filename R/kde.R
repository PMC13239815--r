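#' Define the fixed estimation grid
#'
#' All utilization distributions of a run share one conservatively large
#' planar extent, by default 33,700 m x 19,300 m, discretized into square
#' cells. The default 100-m cell is far below the smallest bandwidth the
#' selection sweep considers, so discretization error is negligible
#' relative to the kernel scale.
#'
#' @param x0,y0 lower-left corner (m) in the working projection.
#' @param width,height extent (m).
#' @param cell cell side (m).
#' @return object of class `mpaud_gridspec` with cell-center coordinate
#'   vectors `xc`, `yc` and counts `nx`, `ny`.
#' @export
grid_spec <- function(x0 = -33700 / 2, y0 = -19300 / 2,
                      width = 33700, height = 19300, cell = 100) {
  stopifnot(cell > 0, width > 0, height > 0)
  nx <- max(2L, as.integer(round(width / cell)))
  ny <- max(2L, as.integer(round(height / cell)))
  structure(list(
    x0 = x0, y0 = y0, width = nx * cell, height = ny * cell,
    cell = cell, nx = nx, ny = ny,
    xc = x0 + (seq_len(nx) - 0.5) * cell,
    yc = y0 + (seq_len(ny) - 0.5) * cell
  ), class = "mpaud_gridspec")
}

#' Weighted Gaussian kernel density estimate on a fixed grid
#'
#' Evaluates the weighted isotropic-Gaussian mixture
#' `f(u) = sum_i (w_i / W) (2 pi h^2)^-1 exp(-|u - x_i|^2 / (2 h^2))`
#' at every cell center, then renormalizes so the gridded density
#' integrates to exactly one over the extent (the Gaussian kernels are
#' separable, so the evaluation is two small matrix products rather than a
#' double loop).
#'
#' @param points n x 2 matrix of planar fix coordinates (m).
#' @param weights non-negative per-point weights, not all zero.
#' @param spec a [grid_spec()].
#' @param h bandwidth (m), > 0.
#' @return object of class `mpaud_udgrid`: list with `spec`, `density`
#'   (`nx` x `ny` matrix, m^-2, integrating to 1), `h`, and
#'   `normalization` (the factor applied after mixture evaluation, useful
#'   for checking against the un-normalized mixture).
#' @export
weighted_kde <- function(points, weights, spec, h) {
  points <- rbind(points)
  n <- nrow(points)
  stopifnot(n >= 1, h > 0, length(weights) == n)
  if (any(weights < 0)) stop("weights must be non-negative")
  W <- sum(weights)
  if (W <= 0) stop("weights must not all be zero")
  inside <- points[, 1] >= spec$x0 & points[, 1] <= spec$x0 + spec$width &
    points[, 2] >= spec$y0 & points[, 2] <= spec$y0 + spec$height
  if (!any(inside)) stop("all points fall outside the estimation extent")
  if (!all(inside)) {
    warning(sprintf(
      "%d point(s) outside the extent; ~%.1f%% of kernel weight may leak",
      sum(!inside), 100 * sum(weights[!inside]) / W))
  }
  w <- weights / W
  Kx <- exp(-0.5 * (outer(spec$xc, points[, 1], "-") / h)^2) # nx x n
  Ky <- exp(-0.5 * (outer(spec$yc, points[, 2], "-") / h)^2) # ny x n
  dens <- (Kx %*% (w * t(Ky))) / (2 * pi * h^2)              # nx x ny
  cell_area <- spec$cell^2
  norm <- 1 / (sum(dens) * cell_area)
  structure(list(spec = spec, density = dens * norm, h = h,
                 normalization = norm),
            class = "mpaud_udgrid")
}

#' @export
print.mpaud_udgrid <- function(x, ...) {
  cat(sprintf("<mpaud_udgrid> %dx%d cells of %.0f m, h = %.0f m\n",
              x$spec$nx, x$spec$ny, x$spec$cell, x$h))
  invisible(x)
}

#' Write a UD grid as CSV
#'
#' Long-format export (`x,y,density`) of the gridded density, cell
#' centers in the working projection.
#'
#' @param grid a `mpaud_udgrid`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_udgrid_csv <- function(grid, path) {
  df <- data.frame(
    x = rep(grid$spec$xc, times = grid$spec$ny),
    y = rep(grid$spec$yc, each = grid$spec$nx),
    density = as.vector(grid$density)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
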