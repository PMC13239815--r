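#' Weighted Silverman reference bandwidth
#'
#' Weighted version of the two-dimensional normal-reference rule,
#' `h = sigma * n_eff^(-1/6)` with `sigma` the mean of the weighted
#' marginal standard deviations and `n_eff = (sum w)^2 / sum w^2` the
#' effective sample size. Used only to start the selection sweep.
#'
#' @param points n x 2 matrix (m).
#' @param weights per-point weights.
#' @return bandwidth in meters.
#' @export
silverman_bandwidth <- function(points, weights) {
  points <- rbind(points)
  w <- weights / sum(weights)
  mu <- colSums(points * w)
  v <- colSums(sweep(points, 2, mu)^2 * w)
  sigma <- mean(sqrt(pmax(v, 1)))
  n_eff <- 1 / sum(w^2)
  max(sigma * n_eff^(-1 / 6), 1)
}

#' Select a bandwidth by the contiguity sweep
#'
#' Ad hoc bandwidth selection for utilization distributions: candidate
#' bandwidths descend in fixed 250-m decrements from `h_start` to
#' `h_min`; at each the 50% isopleth is computed and tested for
#' contiguity, and the chosen bandwidth is the final one before the
#' polygon first becomes non-contiguous. If every candidate down to the
#' floor stays contiguous, the fallback picks the smallest bandwidth
#' yielding exactly two components; failing that the floor itself is
#' returned with `floor_reached = TRUE`.
#'
#' @param points n x 2 matrix of fix coordinates (m), n >= 2.
#' @param weights per-point KDE weights.
#' @param spec a [grid_spec()].
#' @param h_start first (largest) candidate; defaults to the weighted
#'   Silverman bandwidth rounded up to the next 250-m multiple.
#' @param h_min sweep floor (m).
#' @param step decrement between candidates (m); 250 by construction.
#' @param level isopleth level tested for contiguity.
#' @return object of class `mpaud_bwsel`: list with `candidates`,
#'   `n_components` per candidate, `contiguous` per candidate, `chosen_h`,
#'   `rule` (`"last_contiguous"` or `"two_polygon_fallback"`), and
#'   `floor_reached`.
#' @export
select_bandwidth <- function(points, weights, spec,
                             h_start = NULL, h_min = 250, step = 250,
                             level = 0.5) {
  points <- rbind(points)
  stopifnot(nrow(points) >= 2)
  if (is.null(h_start)) {
    h_start <- ceiling(silverman_bandwidth(points, weights) / step) * step
    h_start <- max(h_start, h_min + step)
  }
  if (h_start <= h_min) stop("h_start must exceed h_min")
  candidates <- seq(h_start, h_min, by = -step)
  ncomp <- integer(length(candidates))
  contig <- logical(length(candidates))
  chosen_h <- NA_real_
  rule <- NA_character_
  floor_reached <- FALSE
  for (i in seq_along(candidates)) {
    ct <- ud_contour(weighted_kde(points, weights, spec, candidates[i]),
                     level)
    ncomp[i] <- n_effective_components(ct)
    contig[i] <- is_contiguous(ct)
    if (!contig[i] && i > 1 && contig[i - 1]) {
      chosen_h <- candidates[i] + step
      rule <- "last_contiguous"
      candidates <- candidates[seq_len(i)]
      ncomp <- ncomp[seq_len(i)]
      contig <- contig[seq_len(i)]
      break
    }
  }
  if (is.na(chosen_h)) {
    two <- which(ncomp == 2L)
    if (length(two)) {
      chosen_h <- min(candidates[two])
      rule <- "two_polygon_fallback"
    } else if (all(contig)) {
      chosen_h <- h_min
      rule <- "two_polygon_fallback"
      floor_reached <- TRUE
    } else {
      # non-contiguous from the very first candidate and never exactly two:
      # keep the largest candidate, flagged
      chosen_h <- candidates[1]
      rule <- "last_contiguous"
      floor_reached <- TRUE
    }
  }
  structure(list(
    candidates = candidates, n_components = ncomp, contiguous = contig,
    chosen_h = chosen_h, rule = rule, floor_reached = floor_reached,
    step = step, level = level
  ), class = "mpaud_bwsel")
}

#' @export
print.mpaud_bwsel <- function(x, ...) {
  cat(sprintf("<mpaud_bwsel> chosen h = %.0f m (%s%s), %d candidates\n",
              x$chosen_h, x$rule,
              if (x$floor_reached) ", floor reached" else "",
              length(x$candidates)))
  invisible(x)
}
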