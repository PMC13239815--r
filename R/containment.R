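#' Read a protected-area boundary from GeoJSON
#'
#' Accepts a FeatureCollection, Feature or bare geometry holding one or
#' more `Polygon` / `MultiPolygon` geometries in lon/lat degrees. All
#' polygon features are pooled into a single multipolygon (union
#' semantics: overlap between features is never double-counted by the
#' containment computations). Rings are lightly repaired (duplicate
#' consecutive vertices dropped, rings closed); anything not reducible to
#' a valid polygon is an error.
#'
#' @param path GeoJSON file.
#' @param name optional display name; defaults to the file name.
#' @return object of class `mpaud_boundary`: list with `polygons` (each a
#'   list with `outer` ring matrix and `holes` list, lon/lat degrees),
#'   `name`, `source`.
#' @export
read_boundary <- function(path, name = NULL) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geoms <- list()
  collect <- function(node) {
    if (is.null(node$type)) return()
    switch(node$type,
      FeatureCollection = lapply(node$features, collect),
      Feature = collect(node$geometry),
      Polygon = geoms[[length(geoms) + 1]] <<- node,
      MultiPolygon = {
        for (p in node$coordinates) {
          geoms[[length(geoms) + 1]] <<- list(type = "Polygon",
                                              coordinates = p)
        }
      },
      GeometryCollection = lapply(node$geometries, collect),
      NULL
    )
    invisible()
  }
  collect(gj)
  if (length(geoms) == 0) {
    stop("no polygon features found in ", path)
  }
  fix_ring <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    dup <- c(FALSE, rowSums(abs(diff(m))) == 0)
    m <- m[!dup, , drop = FALSE]
    if (nrow(m) < 3) stop("degenerate ring in ", path)
    if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ]) # close ring
    if (nrow(m) < 4) stop("degenerate ring in ", path)
    colnames(m) <- c("lon", "lat")
    m
  }
  polygons <- lapply(geoms, function(g) {
    rings <- lapply(g$coordinates, fix_ring)
    list(outer = rings[[1]],
         holes = if (length(rings) > 1) rings[-1] else list())
  })
  structure(list(polygons = polygons,
                 name = name %||% basename(path),
                 source = path),
            class = "mpaud_boundary")
}

#' Project a boundary into the working planar frame
#'
#' @param boundary a `mpaud_boundary`.
#' @param proj projection metadata (a `mpaud_ptrack` or its `$proj`).
#' @return the boundary with rings in planar meters (class
#'   `mpaud_boundary_planar`).
#' @export
project_boundary <- function(boundary, proj) {
  if (inherits(proj, "mpaud_ptrack")) proj <- proj$proj
  fw <- function(r) aeqd_forward(r[, 1], r[, 2], proj$center)
  polys <- lapply(boundary$polygons, function(p) {
    list(outer = fw(p$outer), holes = lapply(p$holes, fw))
  })
  structure(list(polygons = polys, name = boundary$name,
                 source = boundary$source, proj = proj),
            class = "mpaud_boundary_planar")
}

boundary_rings <- function(b) {
  unlist(lapply(b$polygons, function(p) c(list(p$outer), p$holes)),
         recursive = FALSE)
}

#' Planar area of a boundary, km^2
#'
#' Exact (shoelace) when polygons do not overlap; grid-integrated over the
#' joint bounding box when features overlap, so union semantics hold.
#'
#' @param b a `mpaud_boundary_planar`.
#' @return area in km^2.
#' @export
boundary_area_km2 <- function(b) {
  polys <- b$polygons
  bbs <- lapply(polys, function(p) apply(p$outer, 2, range))
  overlap <- FALSE
  if (length(polys) > 1) {
    for (i in seq_along(polys)[-1]) for (j in seq_len(i - 1)) {
      if (bbs[[i]][1, 1] <= bbs[[j]][2, 1] && bbs[[j]][1, 1] <= bbs[[i]][2, 1] &&
          bbs[[i]][1, 2] <= bbs[[j]][2, 2] && bbs[[j]][1, 2] <= bbs[[i]][2, 2]) {
        overlap <- TRUE
      }
    }
  }
  if (!overlap) {
    a <- sum(vapply(polys, function(p) {
      abs(ring_signed_area(p$outer)) -
        sum(vapply(p$holes, function(h) abs(ring_signed_area(h)), 0))
    }, 0))
    return(a / 1e6)
  }
  # overlapping features: integrate the union on a fine grid
  bb <- Reduce(function(a, b) cbind(pmin(a[, 1], b[, 1]), pmax(a[, 2], b[, 2])),
               lapply(bbs, t))
  gx <- seq(bb[1, 1], bb[1, 2], length.out = 600)
  gy <- seq(bb[2, 1], bb[2, 2], length.out = 600)
  px <- rep(gx, times = length(gy)); py <- rep(gy, each = length(gx))
  inside <- point_in_boundary(px, py, b)
  mean(inside) * diff(range(gx)) * diff(range(gy)) *
    (length(gx) / (length(gx) - 1)) * (length(gy) / (length(gy) - 1)) / 1e6
}

# Union point-in-polygon over a planar boundary (even-odd within each
# polygon, OR across polygons).
point_in_boundary <- function(px, py, b) {
  inside <- rep(FALSE, length(px))
  for (p in b$polygons) {
    inp <- pracma::inpolygon(px, py, p$outer[, 1], p$outer[, 2],
                             boundary = TRUE)
    for (h in p$holes) {
      inp <- inp & !pracma::inpolygon(px, py, h[, 1], h[, 2],
                                      boundary = FALSE)
    }
    inside <- inside | inp
  }
  inside
}

is_convex_ring <- function(ring) {
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  nnx <- nxt[nxt]
  e1 <- ring[nxt, , drop = FALSE] - ring
  e2 <- ring[nnx, , drop = FALSE] - ring[nxt, , drop = FALSE]
  cr <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  all(cr >= -1e-9 * max(abs(cr))) || all(cr <= 1e-9 * max(abs(cr)))
}

# Sutherland-Hodgman: clip `subject` (any simple ring, open or closed)
# against a convex ring `clip`; orientation of the subject is preserved.
clip_ring_convex <- function(subject, clip) {
  n <- nrow(clip)
  if (all(clip[1, ] == clip[n, ])) clip <- clip[-n, , drop = FALSE]
  if (ring_signed_area(rbind(clip, clip[1, ])) < 0) {
    clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE] # force CCW
  }
  ns <- nrow(subject)
  if (all(subject[1, ] == subject[ns, ])) {
    subject <- subject[-ns, , drop = FALSE]
  }
  out <- subject
  m <- nrow(clip)
  for (k in seq_len(m)) {
    if (nrow(out) == 0) break
    a <- clip[k, ]; b <- clip[if (k == m) 1 else k + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1]) # >=0 inside
    nn <- nrow(out)
    res <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nn)) {
      j <- if (i == nn) 1 else i + 1
      ci <- side[i] >= 0; cj <- side[j] >= 0
      if (ci) res <- rbind(res, out[i, ])
      if (xor(ci, cj)) {
        t <- side[i] / (side[i] - side[j])
        res <- rbind(res, out[i, ] + t * (out[j, ] - out[i, ]))
      }
    }
    out <- res
  }
  if (nrow(out) >= 3) rbind(out, out[1, ]) else matrix(numeric(0), ncol = 2)
}

contour_rings <- function(contour) {
  if (inherits(contour, "mpaud_udcontour")) return(contour$polygons)
  if (is.matrix(contour)) return(list(contour))
  contour
}

contour_area_m2 <- function(contour) {
  if (inherits(contour, "mpaud_udcontour")) return(contour$area)
  rings <- contour_rings(contour)
  if (length(rings) == 1) return(abs(ring_signed_area(rings[[1]])))
  # multiple rings: orientation convention (CCW outer, CW holes)
  sum(vapply(rings, ring_signed_area, 0))
}

#' Percent of an isopleth contained in a protected-area boundary
#'
#' Area-based containment: `100 * area(contour intersect boundary) /
#' area(contour)`, computed over the union of all contour components.
#' When the boundary is a single convex polygon without holes the
#' intersection is exact (Sutherland-Hodgman clipping of each contour
#' ring, hole rings subtracting by orientation); otherwise the contour
#' region is integrated on a fine subgrid against the boundary
#' (point-in-polygon union), which resolves well below 0.1 percentage
#' points at the defaults.
#'
#' @param contour a `mpaud_udcontour`, a closed ring matrix, or a list of
#'   rings (counterclockwise outer, clockwise holes), planar meters.
#' @param boundary a `mpaud_boundary_planar`, or a single ring matrix in
#'   the same frame.
#' @param subsample per-cell (or per-bbox-axis) sampling density for the
#'   raster fallback.
#' @return object of class `mpaud_containment`: list with `level`,
#'   `contour_km2`, `intersect_km2`, `percent` (0..100).
#' @export
percent_contained <- function(contour, boundary, subsample = 8) {
  if (is.matrix(boundary)) {
    boundary <- structure(
      list(polygons = list(list(outer = boundary, holes = list())),
           name = "boundary", source = NA),
      class = "mpaud_boundary_planar")
  }
  rings <- contour_rings(contour)
  if (length(rings) == 0) stop("empty contour")
  c_area <- contour_area_m2(contour)
  if (!is.finite(c_area) || c_area <= 0) stop("empty contour")

  single_convex <- length(boundary$polygons) == 1 &&
    length(boundary$polygons[[1]]$holes) == 0 &&
    is_convex_ring(boundary$polygons[[1]]$outer)

  if (single_convex) {
    clip <- boundary$polygons[[1]]$outer
    inter <- sum(vapply(rings, function(r) {
      cl <- clip_ring_convex(r, clip)
      if (nrow(cl) == 0) 0 else ring_signed_area(cl)
    }, 0))
    if (!inherits(contour, "mpaud_udcontour") && length(rings) == 1) {
      inter <- abs(inter)
    }
  } else if (inherits(contour, "mpaud_udcontour")) {
    inter <- cell_intersection_area(contour, boundary, subsample)
  } else {
    inter <- raster_intersection_area(rings, boundary, n = 64 * subsample)
  }
  inter <- min(max(inter, 0), c_area)
  structure(list(
    level = if (inherits(contour, "mpaud_udcontour")) contour$level else NA,
    contour_km2 = c_area / 1e6,
    intersect_km2 = inter / 1e6,
    percent = 100 * inter / c_area
  ), class = "mpaud_containment")
}

#' @export
print.mpaud_containment <- function(x, ...) {
  cat(sprintf(
    "<mpaud_containment> %s%.2f km^2 contour, %.2f km^2 inside (%.1f%%)\n",
    if (is.na(x$level)) "" else sprintf("%.0f%%-level ", 100 * x$level),
    x$contour_km2, x$intersect_km2, x$percent))
  invisible(x)
}

# Intersection area for a grid-backed contour: per included cell, fully
# in/out cells are decided by their corners; straddling cells are
# subsampled.
cell_intersection_area <- function(contour, boundary, subsample = 8) {
  spec <- contour$spec
  cell <- spec$cell
  ix <- ((contour$cells - 1L) %% spec$nx) + 1L
  iy <- ((contour$cells - 1L) %/% spec$nx) + 1L
  x1 <- spec$x0 + (ix - 1L) * cell; y1 <- spec$y0 + (iy - 1L) * cell
  corners_in <- sapply(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(.5, .5)),
                       function(o) {
                         point_in_boundary(x1 + o[1] * cell,
                                           y1 + o[2] * cell, boundary)
                       })
  n_in <- rowSums(corners_in)
  full <- n_in == 5L
  empty <- n_in == 0L
  area <- sum(full) * cell^2
  mixed <- which(!full & !empty)
  if (length(mixed)) {
    s <- (seq_len(subsample) - 0.5) / subsample
    offx <- rep(s, times = subsample) * cell
    offy <- rep(s, each = subsample) * cell
    px <- rep(x1[mixed], each = subsample^2) + offx
    py <- rep(y1[mixed], each = subsample^2) + offy
    frac <- point_in_boundary(px, py, boundary)
    area <- area + sum(frac) / subsample^2 * cell^2
  }
  area
}

# Intersection area for arbitrary rings: even-odd rasterization of the
# contour over its bounding box against the boundary union.
raster_intersection_area <- function(rings, boundary, n = 512) {
  allpts <- do.call(rbind, rings)
  bb <- apply(allpts, 2, range)
  gx <- seq(bb[1, 1], bb[2, 1], length.out = n)
  gy <- seq(bb[1, 2], bb[2, 2], length.out = n)
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  px <- rep(gx, times = n); py <- rep(gy, each = n)
  parity <- rep(0L, length(px))
  for (r in rings) {
    parity <- parity + pracma::inpolygon(px, py, r[, 1], r[, 2],
                                         boundary = FALSE)
  }
  inc <- parity %% 2L == 1L
  if (!any(inc)) return(0)
  inb <- point_in_boundary(px[inc], py[inc], boundary)
  sum(inb) * dx * dy
}

#' Write a containment report CSV
#'
#' @param results list of `mpaud_containment`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_containment_csv <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(level = r$level, contour_km2 = r$contour_km2,
               intersect_km2 = r$intersect_km2,
               percent = round(r$percent, 1))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
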