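#' Build a run configuration
#'
#' Collects every setting of an end-to-end run. The fixed choices of the
#' analysis — the LC filtering regimes, the 33.7 x 19.3 km estimation
#' extent, the 250-m bandwidth decrement and the 50%/90% isopleth levels
#' — are the defaults; everything is overridable.
#'
#' @param fixes path to the fix CSV (canonical dialect; see [read_fixes()]).
#' @param boundary path to the MPA boundary GeoJSON.
#' @param outdir output directory for persisted intermediates.
#' @param lc_error_table path to a per-class error CSV, or a named
#'   vector; defaults to the table shipped with the package.
#' @param center optional `c(lon, lat)` projection center; defaults to
#'   the centroid of the filtered resident fixes.
#' @param grid_width,grid_height,grid_cell estimation extent and cell (m).
#' @param h_start,h_min,h_step bandwidth sweep settings (m); the step is
#'   250 m by construction.
#' @param levels isopleth levels for the population UD.
#' @param residents,migrants optional explicit animal-id lists; when
#'   `NULL`, [classify_residency()] decides.
#' @param migrant_threshold_km net-displacement threshold of the
#'   residency rule.
#' @param dialect optional CSV dialect mapping for [read_fixes()].
#' @param seed integer seed recorded with the run.
#' @return list of class `mpaud_runconfig`.
#' @export
run_config <- function(fixes, boundary, outdir,
                       lc_error_table = NULL, center = NULL,
                       grid_width = 33700, grid_height = 19300,
                       grid_cell = 100,
                       h_start = NULL, h_min = 250, h_step = 250,
                       levels = c(0.5, 0.9),
                       residents = NULL, migrants = NULL,
                       migrant_threshold_km = 50,
                       dialect = NULL, seed = 1L) {
  if (is.null(lc_error_table)) {
    lc_error_table <- read_lc_error_table()
  } else if (is.character(lc_error_table)) {
    lc_error_table <- read_lc_error_table(lc_error_table)
  } else {
    lc_error_table <- as_lc_error_table(lc_error_table)
  }
  stopifnot(all(levels > 0), all(levels < 1))
  structure(as.list(environment()), class = "mpaud_runconfig")
}

#' Read a run configuration from YAML or JSON
#'
#' File keys mirror the arguments of [run_config()]; relative paths are
#' resolved against the config file's directory.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return `mpaud_runconfig`.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- dirname(normalizePath(path))
  for (key in c("fixes", "boundary", "outdir", "lc_error_table")) {
    if (!is.null(vals[[key]]) && is.character(vals[[key]]) &&
        !grepl("^/", vals[[key]])) {
      vals[[key]] <- file.path(base, vals[[key]])
    }
  }
  do.call(run_config, vals)
}

#' Classify animals as resident or migrant
#'
#' Default rule: an animal is a migrant iff its net great-circle
#' displacement from the first fix exceeds `threshold_km` and that
#' displacement is monotone non-decreasing (within a `backtrack_km`
#' tolerance) over the final third of its fixes. The tolerance absorbs
#' Argos error: differences of consecutive displacements combine two
#' positional errors, about `sqrt(2) * 9 km` for the coarse classes 0/B,
#' so the default allows 25 km (roughly two such standard deviations) of
#' apparent backtracking per step. Explicit id lists in the run config
#' override the rule. Tracks with a single fix are residents by default,
#' with a warning.
#'
#' @param tracks list of tracks (ideally migration-filtered so LC Z noise
#'   does not distort displacements).
#' @param threshold_km net-displacement threshold (default 50 km).
#' @param backtrack_km tolerated decrease per step in the final third.
#' @return named character vector, `"resident"` or `"migrant"` per animal.
#' @export
classify_residency <- function(tracks, threshold_km = 50, backtrack_km = 25) {
  vapply(tracks, function(tr) {
    n <- nrow(tr)
    if (n < 2) {
      warning("track ", track_id(tr),
              " has < 2 fixes; classified resident by default")
      return("resident")
    }
    d <- haversine_km(cbind(tr$lon[1], tr$lat[1]), cbind(tr$lon, tr$lat))
    if (max(d) <= threshold_km) return("resident")
    tail_idx <- seq.int(max(1L, n - ceiling(n / 3) + 1L), n)
    monotone <- all(diff(d[tail_idx]) > -backtrack_km)
    if (monotone) "migrant" else "resident"
  }, "")
}

#' Run the residency analysis end to end
#'
#' Stages: read fixes, split residents from migrants, apply the
#' home-range LC filter (\{3,2,1,A\} retained), project to the shared
#' planar frame, fit the OU model and derive combined KDE weights per
#' animal, select the population bandwidth by the 250-m contiguity sweep,
#' estimate the population UD and its isopleths, and overlay them on the
#' MPA boundary. Every intermediate is persisted under `config$outdir`
#' and the returned report is recomputable from those files. The run is
#' deterministic given the same config and inputs.
#'
#' @param config a [run_config()].
#' @return list of class `mpaud_report`; see the `population`,
#'   `per_animal`, `containment` and `totals` elements.
#' @export
run_residency <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  tracks <- read_fixes(config$fixes, dialect = config$dialect)
  # classify on Z-filtered fixes: class-Z outliers of tens of km would
  # otherwise distort the displacement rule
  status <- classify_residency(
    suppressWarnings(lapply(tracks, filter_fixes, regime = "migration")),
    threshold_km = config$migrant_threshold_km)
  names(status) <- names(tracks)
  if (!is.null(config$residents)) {
    status[] <- ifelse(names(status) %in% config$residents,
                       "resident", "migrant")
  }
  if (!is.null(config$migrants)) status[config$migrants] <- "migrant"
  res_ids <- names(status)[status == "resident"]
  if (length(res_ids) == 0) {
    stop("no resident tracks to analyse (residency rule: net displacement ",
         "> ", config$migrant_threshold_km, " km and monotone tail)")
  }

  filtered <- lapply(tracks[res_ids], filter_fixes, regime = "home_range")
  filtered <- filtered[vapply(filtered, nrow, 0L) > 0]
  if (length(filtered) == 0) stop("home-range filtering left no fixes")
  write_fixes(filtered, file.path(config$outdir, "filtered_fixes.csv"))

  exclusion <- do.call(rbind, lapply(tracks[res_ids], function(tr) {
    lg <- attr(filter_fixes(tr, "home_range"), "filter_log")
    data.frame(animal_id = track_id(tr), n_raw = lg$n_raw,
               n_kept = lg$n_kept, t(as.matrix(lg$excluded_by_lc)),
               check.names = FALSE)
  }))
  utils::write.csv(exclusion,
                   file.path(config$outdir, "exclusion_report.csv"),
                   row.names = FALSE)

  center <- config$center
  if (is.null(center)) {
    all_fix <- do.call(rbind, lapply(filtered, function(tr) {
      cbind(tr$lon, tr$lat)
    }))
    center <- c(mean(all_fix[, 1]), mean(all_fix[, 2]))
  }
  ptracks <- lapply(filtered, project_track, center = center)
  wsets <- lapply(ptracks, weighted_fixes, lc_error_table = config$lc_error_table)
  pool <- do.call(rbind, wsets)
  utils::write.csv(pool, file.path(config$outdir, "weights.csv"),
                   row.names = FALSE)
  fits <- do.call(rbind, lapply(wsets, function(ws) {
    f <- attr(ws, "oufit")
    data.frame(animal_id = ws$animal_id[1],
               mu_x = if (is.null(f$mu)) NA else f$mu[1],
               mu_y = if (is.null(f$mu)) NA else f$mu[2],
               sigma2 = f$sigma2 %||% NA, tau_s = f$tau %||% 0,
               loglik = f$loglik %||% NA,
               iid_fallback = isTRUE(f$iid_fallback))
  }))
  utils::write.csv(fits, file.path(config$outdir, "ou_fits.csv"),
                   row.names = FALSE)

  spec <- grid_spec(x0 = -config$grid_width / 2, y0 = -config$grid_height / 2,
                    width = config$grid_width, height = config$grid_height,
                    cell = config$grid_cell)
  pts <- cbind(pool$x, pool$y)
  sel <- select_bandwidth(pts, pool$w, spec,
                          h_start = config$h_start, h_min = config$h_min,
                          step = config$h_step)
  per_animal_h <- lapply(wsets, function(ws) {
    if (nrow(ws) < 2) return(NULL)
    tryCatch(select_bandwidth(cbind(ws$x, ws$y), ws$w, spec,
                              h_start = config$h_start,
                              h_min = config$h_min, step = config$h_step),
             error = function(e) NULL)
  })

  grid <- weighted_kde(pts, pool$w, spec, sel$chosen_h)
  write_udgrid_csv(grid, file.path(config$outdir, "population_ud.csv"))
  contours <- lapply(config$levels, function(p) ud_contour(grid, p))
  proj <- ptracks[[1]]$proj
  write_contours_geojson(contours, proj,
                         file.path(config$outdir, "population_contours.geojson"))

  boundary <- read_boundary(config$boundary)
  pboundary <- project_boundary(boundary, proj)
  containment <- lapply(contours, percent_contained, boundary = pboundary)
  write_containment_csv(containment,
                        file.path(config$outdir, "containment.csv"))

  n_raw <- sum(exclusion$n_raw)
  n_kept <- sum(exclusion$n_kept)
  report <- structure(list(
    version = as.character(utils::packageVersion("mpaud")),
    seed = config$seed,
    projection = proj,
    status = status,
    per_animal = data.frame(
      animal_id = exclusion$animal_id,
      n_raw = exclusion$n_raw, n_filtered = exclusion$n_kept,
      pct_excluded = 100 * (1 - exclusion$n_kept / exclusion$n_raw),
      chosen_h = vapply(exclusion$animal_id, function(id) {
        s <- per_animal_h[[id]]
        if (is.null(s)) NA_real_ else s$chosen_h
      }, 0),
      stringsAsFactors = FALSE
    ),
    population = list(
      n_residents = length(filtered),
      pool_size = nrow(pool),
      chosen_h = sel$chosen_h, rule = sel$rule,
      floor_reached = sel$floor_reached,
      sweep = sel
    ),
    containment = data.frame(
      level = vapply(containment, `[[`, 0, "level"),
      contour_km2 = vapply(containment, `[[`, 0, "contour_km2"),
      intersect_km2 = vapply(containment, `[[`, 0, "intersect_km2"),
      percent = vapply(containment, `[[`, 0, "percent")
    ),
    totals = list(n_raw = n_raw, n_filtered = n_kept,
                  pct_excluded = 100 * (1 - n_kept / n_raw))
  ), class = "mpaud_report")
  report_for_json <- report
  report_for_json$population$sweep <- unclass(sel)
  jsonlite::write_json(
    lapply(unclass(report_for_json), unclass),
    file.path(config$outdir, "report.json"),
    auto_unbox = TRUE, digits = 10, force = TRUE)
  report
}

#' @export
print.mpaud_report <- function(x, ...) {
  cat(sprintf(
    "<mpaud_report> %d residents, %d/%d fixes kept (%.0f%% excluded), h = %.0f m (%s)\n",
    x$population$n_residents, x$totals$n_filtered, x$totals$n_raw,
    x$totals$pct_excluded, x$population$chosen_h, x$population$rule))
  for (i in seq_len(nrow(x$containment))) {
    cat(sprintf("  %2.0f%% UD: %.2f km^2, %.1f%% inside MPA\n",
                100 * x$containment$level[i], x$containment$contour_km2[i],
                x$containment$percent[i]))
  }
  invisible(x)
}

#' Run the migration branch for one animal
#'
#' Applies the migration LC filter (only Z excluded), fits the daily-step
#' correlated random walk, and writes the daily path and speed summary.
#'
#' @param config a [run_config()].
#' @param animal_id id of the migratory animal.
#' @return list of class `mpaud_migration_report` with the `mpaud_crwfit`
#'   and summary statistics.
#' @export
run_migration <- function(config, animal_id) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  tracks <- read_fixes(config$fixes, dialect = config$dialect)
  if (!animal_id %in% names(tracks)) {
    stop("animal ", animal_id, " not found in ", config$fixes)
  }
  tr <- filter_fixes(tracks[[animal_id]], "migration")
  if (nrow(tr) < 4) {
    stop("animal ", animal_id, " has only ", nrow(tr),
         " migration-regime fixes; >= 4 required")
  }
  status <- classify_residency(list(tr),
                               threshold_km = config$migrant_threshold_km)
  if (status[[1]] != "migrant") {
    warning("animal ", animal_id, " does not meet the departure rule ",
            "(net displacement <= ", config$migrant_threshold_km,
            " km or non-monotone tail); fitting anyway")
  }
  ptr <- project_track(tr) # own centroid: the migration frame is track-local
  fit <- fit_crw(ptr, config$lc_error_table)
  write_daily_path_csv(fit,
                       file.path(config$outdir,
                                 paste0("daily_path_", animal_id, ".csv")))
  rep <- structure(list(
    animal_id = animal_id,
    n_fixes = nrow(tr),
    mean_fix_interval_d = mean_fix_interval(tr),
    fit = fit,
    mean_speed = fit$mean_speed, sd_speed = fit$sd_speed,
    raw_mean_speed = fit$raw_mean_speed, raw_sd_speed = fit$raw_sd_speed
  ), class = "mpaud_migration_report")
  summ <- rep; summ$fit <- NULL
  summ$gamma <- fit$gamma; summ$sigma_p <- fit$sigma_p; summ$k <- fit$k
  jsonlite::write_json(unclass(summ),
                       file.path(config$outdir,
                                 paste0("migration_", animal_id, ".json")),
                       auto_unbox = TRUE, digits = 10)
  rep
}

#' @export
print.mpaud_migration_report <- function(x, ...) {
  cat(sprintf(
    "<mpaud_migration_report> %s: %d fixes (mean interval %.2f d), speed %.2f +/- %.2f km/d (smoothed), %.2f +/- %.2f km/d (raw)\n",
    x$animal_id, x$n_fixes, x$mean_fix_interval_d,
    x$mean_speed, x$sd_speed, x$raw_mean_speed, x$raw_sd_speed))
  invisible(x)
}
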