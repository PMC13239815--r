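#' Argos location classes
#'
#' The Argos system labels every fix with one of seven location classes
#' (LCs) ordered by nominal accuracy: 3 > 2 > 1 > 0 > A > B > Z. `mpaud`
#' stores the class as a factor with these levels so that ordering and
#' tabulation are consistent across the package.
#'
#' @format Character vector of the seven valid codes, most accurate first.
#' @export
LC_LEVELS <- c("3", "2", "1", "0", "A", "B", "Z")

#' Parse Argos location-class codes
#'
#' Validates a vector of LC codes against the Argos taxonomy and returns a
#' factor ordered from most to least accurate. Any symbol outside
#' \{3, 2, 1, 0, A, B, Z\} is an error.
#'
#' @param x character (or factor) vector of codes.
#' @return factor with levels `LC_LEVELS`.
#' @export
parse_lc <- function(x) {
  x <- toupper(trimws(as.character(x)))
  bad <- !(x %in% LC_LEVELS)
  if (any(bad)) {
    stop("invalid Argos location class code(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = LC_LEVELS)
}

#' Read a location-class error table
#'
#' Reads a two-column CSV (`lc,error_m`) mapping each Argos location class
#' to a mean metric error in meters. The table must cover every class it
#' lists with a positive error and must be non-decreasing in error from
#' LC 3 to LC B (Z, which carries no accuracy estimate, is exempt from the
#' monotonicity check).
#'
#' @param path CSV file path. Defaults to the table shipped with the
#'   package, whose values are literature-scale placeholders (the original
#'   per-class magnitudes are not published alongside the method).
#' @return named numeric vector, names in `LC_LEVELS` order.
#' @export
read_lc_error_table <- function(path = system.file("extdata", "lc_errors.csv",
                                                   package = "mpaud")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lc", "error_m") %in% names(df))) {
    stop("LC error table must have columns 'lc' and 'error_m': ", path)
  }
  lc <- parse_lc(df$lc)
  err <- as.numeric(df$error_m)
  if (anyDuplicated(lc)) stop("duplicate LC entries in error table")
  if (any(!is.finite(err)) || any(err <= 0)) {
    stop("all LC errors must be finite and > 0")
  }
  tab <- err[order(lc)]
  names(tab) <- as.character(sort(lc))
  ord <- tab[names(tab) %in% c("3", "2", "1", "0", "A", "B")]
  if (length(ord) > 1 && any(diff(ord) < 0)) {
    stop("LC errors must be non-decreasing from class 3 to class B")
  }
  tab
}

#' Validate an in-memory LC error table
#' @param table named numeric vector (names are LC codes).
#' @return the table, names normalised, after validation.
#' @keywords internal
as_lc_error_table <- function(table) {
  if (is.null(names(table))) stop("LC error table must be named by LC code")
  nm <- as.character(parse_lc(names(table)))
  table <- as.numeric(table)
  if (any(!is.finite(table)) || any(table <= 0)) {
    stop("all LC errors must be finite and > 0")
  }
  names(table) <- nm
  table
}
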