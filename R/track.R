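#' Construct a track of Argos fixes
#'
#' A track is a data frame with columns `animal_id`, `time` (POSIXct, UTC),
#' `lon`, `lat` and `lc` (factor over the Argos taxonomy), sorted by time.
#' Duplicate timestamps are kept; ties are ordered by LC accuracy (most
#' accurate first) and then input order, which preserves information from
#' multiple satellite passes.
#'
#' @param animal_id scalar id shared by all fixes.
#' @param time POSIXct vector (UTC) or anything `as.POSIXct` accepts.
#' @param lon,lat numeric degrees, lon in \[-180, 180\], lat in \[-90, 90\].
#' @param lc location-class codes (see [parse_lc()]).
#' @param meta optional named list (e.g. CCL cm, mass kg, capture site).
#' @return object of class `mpaud_track` (a data frame).
#' @export
track <- function(animal_id, time, lon, lat, lc, meta = NULL) {
  animal_id <- as.character(animal_id)
  if (length(unique(animal_id)) > 1) {
    stop("all fixes in a track must share one animal_id")
  }
  time <- as.POSIXct(time, tz = "UTC")
  lon <- as.numeric(lon)
  lat <- as.numeric(lat)
  lc <- parse_lc(lc)
  n <- length(time)
  stopifnot(length(lon) == n, length(lat) == n, length(lc) == n)
  if (n > 0) {
    if (any(!is.finite(as.numeric(time)))) stop("non-finite timestamp")
    if (any(!is.finite(lon)) || any(!is.finite(lat))) {
      stop("non-finite coordinates")
    }
    if (any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90)) {
      stop("coordinates outside valid lon/lat range")
    }
  }
  df <- data.frame(
    animal_id = rep_len(if (n) animal_id[1] else character(0), n),
    time = time, lon = lon, lat = lat, lc = lc,
    stringsAsFactors = FALSE
  )
  # stable sort: time, then LC accuracy, then original order
  df <- df[order(df$time, as.integer(df$lc)), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("mpaud_track", "data.frame"), meta = meta)
}

#' @export
print.mpaud_track <- function(x, ...) {
  cat(sprintf("<mpaud_track> %s: %d fixes", track_id(x), nrow(x)))
  if (nrow(x) > 1) {
    cat(sprintf(", %.1f days, LCs: %s",
                track_duration_days(x),
                paste(names(table(droplevels(x$lc))), collapse = ",")))
  }
  cat("\n")
  NextMethod()
}

#' @rdname track
#' @param x a track.
#' @export
track_id <- function(x) {
  if (nrow(x) == 0) attr(x, "animal_id") %||% NA_character_ else x$animal_id[1]
}

#' @rdname track
#' @export
track_duration_days <- function(x) {
  if (nrow(x) < 2) return(0)
  as.numeric(difftime(max(x$time), min(x$time), units = "days"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Lenient ISO-8601-ish parser: tries each format, NA where none matches
# (a malformed row must be reportable, not fatal).
parse_utc_time <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
  }
  out
}

#' Read Argos fix tables into tracks
#'
#' Parses a CSV of satellite fixes into one track per animal. The canonical
#' column names are `animal_id, timestamp_utc, lon, lat, lc` with ISO-8601
#' timestamps; a `dialect` mapping renames other schemas onto them. Rows
#' with unparseable timestamps, coordinates or location classes are
#' rejected individually (with their line numbers reported via a warning
#' and the `rejected` attribute); a missing required column is a hard
#' error. LC Z rows are retained — exclusion accounting happens in
#' [filter_fixes()], never at read time.
#'
#' @param path CSV file.
#' @param dialect named character vector mapping canonical names to the
#'   file's column names, e.g. `c(animal_id = "id", timestamp_utc = "date")`.
#'   Unmentioned canonical names are looked up verbatim.
#' @return named list of `mpaud_track`, one per animal, time-sorted.
#' @export
read_fixes <- function(path, dialect = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  canonical <- c("animal_id", "timestamp_utc", "lon", "lat", "lc")
  cols <- stats::setNames(canonical, canonical)
  if (!is.null(dialect)) cols[names(dialect)] <- unname(dialect)
  missing <- setdiff(unname(cols), names(raw))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  df <- data.frame(
    animal_id = raw[[cols["animal_id"]]],
    timestamp_utc = raw[[cols["timestamp_utc"]]],
    lon = suppressWarnings(as.numeric(raw[[cols["lon"]]])),
    lat = suppressWarnings(as.numeric(raw[[cols["lat"]]])),
    lc = toupper(trimws(raw[[cols["lc"]]])),
    stringsAsFactors = FALSE
  )
  time <- parse_utc_time(df$timestamp_utc)
  ok_time <- !is.na(time)
  ok_coord <- is.finite(df$lon) & is.finite(df$lat) &
    df$lon >= -180 & df$lon <= 180 & df$lat >= -90 & df$lat <= 90
  ok_lc <- df$lc %in% LC_LEVELS
  ok <- ok_time & ok_coord & ok_lc
  rejected <- which(!ok) + 1L  # data line numbers incl. header offset
  if (length(rejected)) {
    warning(sprintf("%s: rejected %d malformed row(s) at line(s) %s",
                    basename(path), length(rejected),
                    paste(utils::head(rejected, 20), collapse = ", ")))
  }
  df <- df[ok, , drop = FALSE]
  time <- time[ok]
  ids <- unique(df$animal_id)
  tracks <- lapply(ids, function(id) {
    sel <- df$animal_id == id
    track(id, time[sel], df$lon[sel], df$lat[sel], df$lc[sel])
  })
  names(tracks) <- ids
  attr(tracks, "rejected") <- rejected
  tracks
}

#' Write tracks back to the canonical fix CSV
#'
#' Inverse of [read_fixes()] on the canonical dialect: columns
#' `animal_id,timestamp_utc,lon,lat,lc`, ISO-8601 UTC timestamps. A
#' `regime` column is appended when the tracks carry a filtering regime.
#'
#' @param tracks a track or list of tracks.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(tracks, path) {
  if (inherits(tracks, "mpaud_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    out <- data.frame(
      animal_id = tr$animal_id,
      timestamp_utc = format(tr$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      lon = sprintf("%.10g", tr$lon),
      lat = sprintf("%.10g", tr$lat),
      lc = as.character(tr$lc),
      stringsAsFactors = FALSE
    )
    regime <- attr(tr, "regime")
    if (!is.null(regime)) out$regime <- regime
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter fixes by Argos location class
#'
#' Applies one of the two filtering regimes used for telemetry at a
#' fine-scale extent: `home_range` retains the more accurate classes
#' \{3, 2, 1, A\} (dropping 0, B and Z, the classes with the largest
#' errors), while `migration` drops only the unusable class Z so that
#' directional information is kept over a broad extent. Fix order is
#' preserved and per-class exclusion counts are recorded in the
#' `filter_log` attribute.
#'
#' @param track a track.
#' @param regime `"home_range"` or `"migration"`.
#' @return filtered track with attributes `regime` and `filter_log`
#'   (named integer vector of excluded fixes per LC, plus `n_raw`,
#'   `n_kept`). An empty result is returned with a warning, not an error.
#' @export
filter_fixes <- function(track, regime = c("home_range", "migration")) {
  regime <- match.arg(regime)
  keep_lcs <- switch(regime,
    home_range = c("3", "2", "1", "A"),
    migration  = c("3", "2", "1", "0", "A", "B")
  )
  keep <- as.character(track$lc) %in% keep_lcs
  excluded <- table(factor(as.character(track$lc)[!keep], levels = LC_LEVELS))
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(track)
  attr(out, "meta") <- attr(track, "meta")
  attr(out, "animal_id") <- track_id(track)
  attr(out, "regime") <- regime
  attr(out, "filter_log") <- list(
    excluded_by_lc = stats::setNames(as.integer(excluded), LC_LEVELS),
    n_raw = nrow(track), n_kept = sum(keep)
  )
  if (nrow(out) == 0) {
    warning("all fixes of ", track_id(track), " excluded under regime '",
            regime, "'")
  }
  out
}

#' Mean interval between successive raw fixes
#'
#' @param track a track with at least two fixes.
#' @return mean of successive time differences, in days.
#' @export
mean_fix_interval <- function(track) {
  if (nrow(track) < 2) stop("mean_fix_interval needs at least 2 fixes")
  mean(diff(as.numeric(track$time))) / 86400
}
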