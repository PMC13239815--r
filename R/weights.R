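#' Autocorrelation weights for kernel density estimation
#'
#' Downweights temporally clustered fixes so that serially correlated
#' tracking data do not over-represent oversampled periods. From the
#' fitted OU correlation matrix `C[i,j] = exp(-|t_i - t_j| / tau)` the
#' minimum-variance weights for estimating a mean under correlation are
#' `w` proportional to `solve(C, 1)`; negative entries are clipped to zero
#' and the vector renormalized, so the weights for an individual always
#' sum to one. An IID fit (`tau = 0`) yields uniform `1/n`.
#'
#' @param fit an `mpaud_oufit`, or any list with a `tau` element
#'   (`list(tau = 0)` is the IID fallback).
#' @param times numeric fix times in seconds.
#' @return numeric vector of weights, `sum(w) == 1`.
#' @export
autocorr_weights <- function(fit, times) {
  n <- length(times)
  if (n < 1) stop("autocorr_weights needs at least one fix")
  tau <- fit$tau
  if (n == 1) return(1)
  if (!is.finite(tau) || tau <= 0) return(rep(1 / n, n))
  C <- exp(-abs(outer(times, times, "-")) / tau)
  w <- tryCatch(solve(C, rep(1, n)), error = function(e) {
    message("autocorr_weights: singular correlation matrix, ",
            "adding 1e-8 diagonal jitter")
    solve(C + diag(1e-8, n), rep(1, n))
  })
  w[w < 0] <- 0
  if (sum(w) <= 0) return(rep(1 / n, n)) # pathological: fall back to uniform
  w / sum(w)
}

#' Argos-error weights from a location-class error table
#'
#' Weight proportional to the inverse of the mean metric error of each
#' fix's location class, rescaled so the most accurate class present has
#' weight one (the proportionality constant is free; this scaling keeps
#' the combined weights interpretable).
#'
#' @param lcs location-class codes (anything [parse_lc()] accepts).
#' @param table named numeric vector of per-class mean errors in meters
#'   (see [read_lc_error_table()]).
#' @return numeric vector of weights in (0, 1].
#' @export
argos_error_weights <- function(lcs, table) {
  table <- as_lc_error_table(table)
  lcs <- as.character(parse_lc(lcs))
  missing <- setdiff(unique(lcs), names(table))
  if (length(missing)) {
    stop("LC(s) missing from error table: ", paste(missing, collapse = ", "))
  }
  inv <- 1 / table[lcs]
  unname(inv / max(inv))
}

#' Combine autocorrelation and Argos-error weights
#'
#' Multiplies the two per-fix weights into the single kernel-density
#' weight, then renormalizes the product per individual so each animal
#' contributes total weight one to population-level pooling.
#'
#' @param w_auto autocorrelation weights ([autocorr_weights()]).
#' @param w_error Argos-error weights ([argos_error_weights()]).
#' @return list with `w_raw` (elementwise product) and `w` (renormalized
#'   to sum to one).
#' @export
combine_weights <- function(w_auto, w_error) {
  if (length(w_auto) != length(w_error)) {
    stop("w_auto and w_error must have equal length")
  }
  w_raw <- w_auto * w_error
  s <- sum(w_raw)
  if (s <= 0) stop("combined weights sum to zero")
  list(w_raw = w_raw, w = w_raw / s)
}

#' Per-fix KDE weights for a projected track
#'
#' Convenience wrapper running the full weighting chain: OU fit (or IID
#' fallback for tracks too short to fit), autocorrelation weights,
#' Argos-error weights, and their combination.
#'
#' @param ptrack projected track.
#' @param lc_error_table per-class error table.
#' @param fit optional pre-computed `mpaud_oufit`; fitted here when `NULL`
#'   (IID fallback below 5 fixes).
#' @return data frame (`animal_id`, `x`, `y`, `lc`, `w_auto`, `w_error`,
#'   `w`) with the fit attached as attribute `oufit`.
#' @export
weighted_fixes <- function(ptrack, lc_error_table, fit = NULL) {
  if (is.null(fit)) {
    fit <- if (nrow(ptrack$xy) >= 5 && length(unique(ptrack$times)) >= 2) {
      fit_ou(ptrack)
    } else {
      list(tau = 0, iid_fallback = TRUE)
    }
  }
  w_auto <- autocorr_weights(fit, ptrack$times)
  w_error <- argos_error_weights(ptrack$lc, lc_error_table)
  comb <- combine_weights(w_auto, w_error)
  out <- data.frame(
    animal_id = ptrack$animal_id,
    x = ptrack$xy[, 1], y = ptrack$xy[, 2],
    lc = as.character(ptrack$lc),
    w_auto = w_auto, w_error = w_error, w = comb$w,
    stringsAsFactors = FALSE
  )
  attr(out, "oufit") <- fit
  out
}
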