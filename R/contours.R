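# Connected-component labelling of a cell set under 8-connectivity.
# `cells` are linear indices into the nx x ny grid (column ix, row iy with
# index = ix + (iy - 1) * nx). Returns an integer label per cell.
label_components <- function(cells, nx, ny) {
  if (length(cells) == 0) return(integer(0))
  member <- integer(nx * ny) # 0 = not included, else position in `cells`
  member[cells] <- seq_along(cells)
  labels <- integer(length(cells))
  ix <- ((cells - 1L) %% nx) + 1L
  iy <- ((cells - 1L) %/% nx) + 1L
  current <- 0L
  stack <- integer(length(cells))
  for (s in seq_along(cells)) {
    if (labels[s] != 0L) next
    current <- current + 1L
    labels[s] <- current
    stack[1] <- s; top <- 1L
    while (top > 0L) {
      c0 <- stack[top]; top <- top - 1L
      x0 <- ix[c0]; y0 <- iy[c0]
      nbx <- x0 + c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
      nby <- y0 + c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
      ok <- nbx >= 1L & nbx <= nx & nby >= 1L & nby <= ny
      pos <- member[nbx[ok] + (nby[ok] - 1L) * nx]
      pos <- pos[pos != 0L]
      pos <- pos[labels[pos] == 0L]
      if (length(pos)) {
        labels[pos] <- current
        stack[(top + 1L):(top + length(pos))] <- pos
        top <- top + length(pos)
      }
    }
  }
  labels
}

# Trace the outline(s) of a union of grid cells as rectilinear rings.
# Boundary edges are directed with the interior on the left, so outer
# rings come out counterclockwise (positive shoelace area) and hole rings
# clockwise (negative). At vertices where cells touch diagonally the walk
# takes the left-most turn, which keeps every ring simple.
trace_cell_rings <- function(cells, spec) {
  if (length(cells) == 0) return(list())
  nx <- spec$nx; ny <- spec$ny
  member <- logical(nx * ny)
  member[cells] <- TRUE
  ix <- ((cells - 1L) %% nx) + 1L
  iy <- ((cells - 1L) %/% nx) + 1L
  has <- function(x, y) x >= 1L & x <= nx & y >= 1L & y <= ny &
    member[pmax(1L, pmin(nx * ny, x + (y - 1L) * nx))]
  # edge endpoints in lattice (vertex) coordinates 0..nx, 0..ny
  sx <- integer(0); sy <- integer(0); ex <- integer(0); ey <- integer(0)
  add <- function(cond, x1, y1, x2, y2) {
    sx <<- c(sx, x1[cond]); sy <<- c(sy, y1[cond])
    ex <<- c(ex, x2[cond]); ey <<- c(ey, y2[cond])
  }
  add(!has(ix, iy - 1L), ix - 1L, iy - 1L, ix, iy - 1L)       # bottom ->
  add(!has(ix + 1L, iy), ix, iy - 1L, ix, iy)                 # right  ^
  add(!has(ix, iy + 1L), ix, iy, ix - 1L, iy)                 # top    <-
  add(!has(ix - 1L, iy), ix - 1L, iy, ix - 1L, iy - 1L)       # left   v
  m <- length(sx)
  key <- function(x, y) x + y * (nx + 2L)
  from <- key(sx, sy)
  out_by_vertex <- split(seq_len(m), from)
  used <- logical(m)
  rings <- list()
  for (e0 in seq_len(m)) {
    if (used[e0]) next
    ring_x <- sx[e0]; ring_y <- sy[e0]
    e <- e0
    repeat {
      used[e] <- TRUE
      ring_x <- c(ring_x, ex[e]); ring_y <- c(ring_y, ey[e])
      if (ex[e] == sx[e0] && ey[e] == sy[e0]) break
      cand <- out_by_vertex[[as.character(key(ex[e], ey[e]))]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break # should not happen on a valid edge set
      if (length(cand) > 1) {
        # left-most turn relative to incoming direction
        dx <- ex[e] - sx[e]; dy <- ey[e] - sy[e]
        turn <- dx * (ey[cand] - sy[cand]) - dy * (ex[cand] - sx[cand])
        cand <- cand[order(-turn)]
      }
      e <- cand[1]
    }
    rings[[length(rings) + 1L]] <-
      cbind(x = spec$x0 + ring_x * spec$cell,
            y = spec$y0 + ring_y * spec$cell)
  }
  rings
}

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Extract a probability-level isopleth from a UD grid
#'
#' Highest-density-region contour: cells are ranked by density and
#' accumulated, highest first, until their mass reaches the requested
#' level `p`; the contour is the outline of that cell set. Components are
#' counted under 8-connectivity of the included cells; polygons are the
#' rectilinear outlines of the cell union (outer rings counterclockwise,
#' holes clockwise).
#'
#' @param grid a `mpaud_udgrid`.
#' @param p probability level in (0, 1).
#' @return object of class `mpaud_udcontour`: list with `level`,
#'   `polygons` (list of two-column rings, m), `n_components`, `area`
#'   (m^2), `mass` (enclosed probability, >= p), `threshold` (density of
#'   the last cell admitted), `cells`, `component_mass`, and the grid
#'   `spec`.
#' @export
ud_contour <- function(grid, p) {
  stopifnot(inherits(grid, "mpaud_udgrid"), p > 0, p < 1)
  spec <- grid$spec
  cell_area <- spec$cell^2
  d <- as.vector(grid$density)
  ord <- order(d, decreasing = TRUE)
  mass <- cumsum(d[ord]) * cell_area
  if (mass[length(mass)] < p - 1e-9) {
    stop("degenerate grid: total mass below requested level")
  }
  k <- which(mass >= p)[1]
  cells <- ord[seq_len(k)]
  labels <- label_components(cells, spec$nx, spec$ny)
  comp_mass <- as.numeric(tapply(d[cells] * cell_area, labels, sum))
  structure(list(
    level = p,
    polygons = trace_cell_rings(cells, spec),
    n_components = max(labels),
    area = k * cell_area,
    mass = mass[k],
    threshold = d[ord[k]],
    cells = cells,
    cell_labels = labels,
    component_mass = comp_mass,
    spec = spec
  ), class = "mpaud_udcontour")
}

#' @export
print.mpaud_udcontour <- function(x, ...) {
  cat(sprintf(
    "<mpaud_udcontour> %.0f%% level: %.2f km^2, %d component(s), mass %.4f\n",
    100 * x$level, x$area / 1e6, x$n_components, x$mass))
  invisible(x)
}

#' Is an isopleth contiguous?
#'
#' A contour counts as contiguous when it has a single 8-connected
#' component after discarding slivers — components holding less than 1%
#' of the contour's enclosed mass — which raster contouring can emit as
#' one-cell fragments without changing the polygon a practitioner would
#' draw.
#'
#' @param contour a `mpaud_udcontour`.
#' @param sliver_frac mass fraction below which a component is ignored.
#' @return logical.
#' @export
is_contiguous <- function(contour, sliver_frac = 0.01) {
  keep <- contour$component_mass >= sliver_frac * sum(contour$component_mass)
  sum(keep) == 1
}

#' Effective component count of an isopleth
#' @inheritParams is_contiguous
#' @return number of components holding at least `sliver_frac` of the mass.
#' @export
n_effective_components <- function(contour, sliver_frac = 0.01) {
  sum(contour$component_mass >= sliver_frac * sum(contour$component_mass))
}

#' Write isopleths as GeoJSON
#'
#' Converts contour rings back to lon/lat through the run projection and
#' writes a FeatureCollection with `level` and `n_components` properties.
#'
#' @param contours list of `mpaud_udcontour` (or a single one).
#' @param proj projection metadata (see [unproject()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contours_geojson <- function(contours, proj, path) {
  if (inherits(contours, "mpaud_udcontour")) contours <- list(contours)
  features <- lapply(contours, function(ct) {
    rings <- lapply(ct$polygons, function(r) {
      ll <- unproject(r, proj)
      lapply(seq_len(nrow(ll)), function(i) c(ll[i, 1], ll[i, 2]))
    })
    list(
      type = "Feature",
      properties = list(level = ct$level, n_components = ct$n_components,
                        area_m2 = ct$area),
      geometry = list(type = "MultiPolygon",
                      coordinates = lapply(rings, list))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
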