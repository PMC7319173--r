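# Orchestration: a declarative analysis configuration, input validation, and
# a reproducible end-to-end driver from raw fixes and sensor streams to
# budgets and forays.

#' Analysis configuration
#'
#' Every threshold of the pipeline as a named constant with its default:
#' the 80% percent-dry haul-out rule, the 10-min resting boundary, the
#' 5-dive / 15% repetitive-bout criterion, the 75% bottom-dive ratio above
#' 10 m of water, the 300/1,000-m shelf/basin partition, the 25-km standard
#' error cutoff on location estimates, the 50-km ice-averaging radius, the
#' 15% / 10-pixel ice-edge qualification, the 5-km coastal exclusion, the
#' 10% dive-series sample floor, the 6-hr estimation grid, the UTC-10 local
#' clock, and first-week exclusion.
#'
#' @param ... Overrides of the defaults listed above.
#' @return Object of class `analysis_config` (a validated named list).
#' @export
analysis_config <- function(...) {
  cfg <- list(
    dry_threshold = 80, rest_surface_min = 10, rep_min_dives = 5,
    rep_tol = 0.15, bottom_frac = 0.75, min_bottom_ocean_depth = 10,
    shelf_max = 300, basin_min = 1000, se_max = 25, ice_radius = 50,
    ice_edge_conc = 15, ice_edge_min_pixels = 10, coast_excl = 5,
    sample_min = 0.10, grid_step = 6, local_offset = -10,
    max_speed = 10, spike_angle = 15, spike_speed = 5,
    depth_split = 25, min_ref_depth = 2, bridge_max = 1,
    first_week_excluded = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown analysis_config fields: ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  pos <- c("dry_threshold", "rest_surface_min", "rep_min_dives", "rep_tol",
           "bottom_frac", "min_bottom_ocean_depth", "shelf_max", "basin_min",
           "se_max", "ice_radius", "ice_edge_conc", "ice_edge_min_pixels",
           "coast_excl", "sample_min", "grid_step", "max_speed",
           "spike_angle", "spike_speed", "depth_split", "min_ref_depth")
  for (f in pos) if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
    stop("analysis_config field ", f, " must be positive")
  if (cfg$dry_threshold > 100 || cfg$rep_tol >= 1 || cfg$bottom_frac > 1 ||
      cfg$sample_min > 1 || cfg$shelf_max >= cfg$basin_min)
    stop("analysis_config field out of physical range")
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (f in names(x)) cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Validate input tables and rasters
#'
#' Schema and sanity checks: required columns, coordinate and percent ranges,
#' per-seal timestamp ordering, dive interval validity, and raster
#' georeferencing.  Inputs may be data frames / `grid_raster`s or file paths
#' to the exchange formats.
#'
#' @param fixes,dives,drytimes Tables (or CSV paths); any may be `NULL`.
#' @param bathy A [grid_raster()] (or path); may be `NULL`.
#' @return `data.frame` of violations (`source`, `row`, `field`, `problem`);
#'   zero rows when everything is well formed.
#' @export
validate_inputs <- function(fixes = NULL, dives = NULL, drytimes = NULL,
                            bathy = NULL) {
  v <- list()
  bad <- function(source, row, field, problem) {
    v[[length(v) + 1L]] <<- data.frame(source = source, row = row,
                                       field = field, problem = problem)
  }
  need <- function(x, cols, source) {
    miss <- setdiff(cols, names(x))
    for (m in miss) bad(source, NA_integer_, m, "missing column")
    length(miss) == 0
  }
  if (is.character(fixes)) fixes <- read_fixes(fixes)
  if (is.character(dives)) dives <- read_dives(dives)
  if (is.character(drytimes)) drytimes <- read_drytimes(drytimes)
  if (is.character(bathy)) bathy <- read_grid_raster(bathy)

  if (!is.null(fixes) &&
      need(fixes, c("seal_id", "timestamp", "lon", "lat", "lc"), "fixes")) {
    for (r in which(is.na(fixes$timestamp)))
      bad("fixes", r, "timestamp", "unparseable timestamp")
    for (r in which(abs(fixes$lat) > 90))
      bad("fixes", r, "lat", "latitude outside [-90, 90]")
    for (r in which(abs(fixes$lon) > 180))
      bad("fixes", r, "lon", "longitude outside [-180, 180]")
    for (r in which(!fixes$lc %in% QUALITY_ORDER))
      bad("fixes", r, "lc", "unknown location class")
    for (d in split(seq_len(nrow(fixes)), fixes$seal_id)) {
      tt <- fixes$timestamp[d]
      dec <- d[which(diff(as.numeric(tt)) < 0) + 1L]
      for (r in dec) bad("fixes", r, "timestamp", "timestamps not ordered")
    }
  }
  if (!is.null(dives) &&
      need(dives, c("seal_id", "start", "end", "max_depth_m"), "dives")) {
    for (r in which(!(dives$end > dives$start)))
      bad("dives", r, "end", "dive end not after start")
    for (r in which(dives$max_depth_m <= 0))
      bad("dives", r, "max_depth_m", "non-positive depth")
    for (d in split(seq_len(nrow(dives)), dives$seal_id)) {
      o <- d[order(dives$start[d])]
      n <- length(o)
      if (n > 1) {
        ovl <- o[which(as.numeric(dives$start[o][-1]) <
                         as.numeric(dives$end[o][-n]) - 1e-6) + 1L]
        for (r in ovl) bad("dives", r, "start", "overlapping dives")
      }
    }
  }
  if (!is.null(drytimes) &&
      need(drytimes, c("seal_id", "date", "hour", "percent_dry"), "drytimes")) {
    for (r in which(!(drytimes$hour %in% 0:23)))
      bad("drytimes", r, "hour", "hour outside 0-23")
    for (r in which(drytimes$percent_dry < 0 | drytimes$percent_dry > 100))
      bad("drytimes", r, "percent_dry", "outside [0, 100]")
  }
  if (!is.null(bathy)) {
    if (!inherits(bathy, "grid_raster")) {
      bad("bathy", NA_integer_, "class", "not a grid_raster")
    } else if (bathy$dx <= 0 || bathy$dy <= 0 ||
               any(!is.finite(bathy$center)) || abs(bathy$center[2]) > 90) {
      bad("bathy", NA_integer_, "georeferencing", "invalid grid geometry")
    }
  }
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(source = character(), row = integer(), field = character(),
               problem = character())
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input validation, first-week exclusion, fix
#' plausibility filtering, per-seal movement-model fitting and 6-hourly
#' prediction with the SE cutoff, daily summaries, habitat annotation, foray
#' detection, haul-out classification, dive-bout segmentation, bottom-dive
#' calls, diel profiles, the depth-duration regression, and monthly budget
#' extrapolation.  Stage record counts are logged with [message()]; outputs
#' are deterministic given inputs and configuration.
#'
#' @param fixes,dives,drytimes Input tables or CSV paths.
#' @param bathy Bathymetry [grid_raster()] or path; required.
#' @param ice Optional [raster_stack()] of daily ice fields.
#' @param config An [analysis_config()].
#' @param outdir Optional directory; when given, every stage table is written
#'   as CSV plus a `manifest.json` of configuration and counts.
#' @return A list bundle: `rejections`, `track`, `daily`, `habitat`,
#'   `forays`, `haulout`, `seg`, `bottom`, `profiles`, `depth_duration`,
#'   `budgets`, `budget_table`, `fits`.
#' @export
run_pipeline <- function(fixes, dives, drytimes, bathy, ice = NULL,
                         config = analysis_config(), outdir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(bathy)) {
    if (!file.exists(bathy)) stop("missing raster: ", bathy)
    bathy <- read_grid_raster(bathy)
  }
  if (!inherits(bathy, "grid_raster")) stop("missing raster: bathy")
  if (is.character(fixes)) fixes <- read_fixes(fixes)
  if (is.character(dives)) dives <- read_dives(dives)
  if (is.character(drytimes)) drytimes <- read_drytimes(drytimes)
  viol <- validate_inputs(fixes, dives, drytimes, bathy)
  if (nrow(viol)) {
    stop("invalid inputs: ", paste(utils::head(
      sprintf("%s row %s field %s: %s", viol$source, viol$row, viol$field,
              viol$problem), 5), collapse = "; "))
  }
  log <- function(...) message(sprintf(...))

  if (isTRUE(config$first_week_excluded)) {
    n0 <- c(nrow(dives), nrow(drytimes))
    dives <- drop_first_week(dives)
    drytimes <- drop_first_week(drytimes)
    log("first-week exclusion: dives %d -> %d, dry hours %d -> %d",
        n0[1], nrow(dives), n0[2], nrow(drytimes))
  }

  pf <- prefilter_fixes(fixes, land = bathy, max_speed = config$max_speed,
                        spike_angle = config$spike_angle,
                        spike_speed = config$spike_speed)
  log("prefilter: %d fixes in, %d retained, %d rejected",
      nrow(fixes), nrow(pf$retained), nrow(pf$rejected))

  fits <- list(); track <- list(); daily <- list()
  for (sid in sort(unique(pf$retained$seal_id))) {
    fx <- pf$retained[pf$retained$seal_id == sid, , drop = FALSE]
    if (nrow(fx) < 10) {
      log("seal %s: only %d fixes, skipping movement model", sid, nrow(fx))
      next
    }
    fit <- fit_ctcrw(fx, center = bathy$center)
    est <- predict_track(fit, grid_step = config$grid_step,
                         se_max = config$se_max, seal_id = sid)
    log("seal %s: beta %.3g, sigma %.3g; %d estimates (%d dropped by SE>%g km)",
        sid, fit$beta, fit$sigma, nrow(est), attr(est, "n_dropped"),
        config$se_max)
    fits[[sid]] <- fit
    track[[sid]] <- est
    if (nrow(est) >= 2) daily[[sid]] <- daily_summaries(est)
  }
  track <- do.call(rbind, track)
  daily <- do.call(rbind, daily)
  rownames(track) <- rownames(daily) <- NULL

  habitat <- annotate_habitat(daily, bathy, ice, ice_radius = config$ice_radius,
                              conc_min = config$ice_edge_conc,
                              min_pixels = config$ice_edge_min_pixels)
  log("habitat: %d seal-days (%d shelf, %d break, %d basin)",
      nrow(habitat), sum(habitat$zone == "shelf", na.rm = TRUE),
      sum(habitat$zone == "break", na.rm = TRUE),
      sum(habitat$zone == "basin", na.rm = TRUE))

  ho <- classify_haulout_hours(drytimes, threshold = config$dry_threshold)
  forays <- detect_forays(habitat, ho$hours, bridge_max = config$bridge_max)
  log("forays: %d detected", nrow(forays))

  seg <- segment_behavior(dives, rest_gap_min = config$rest_surface_min,
                          rep_min_dives = config$rep_min_dives,
                          rep_tol = config$rep_tol,
                          min_ref_depth = config$min_ref_depth)
  log("segmentation: %d dives into %d episodes", nrow(seg$dives),
      nrow(seg$episodes))

  # bottom calls: join each dive to its day's mapped ocean depth
  dd <- seg$dives
  dkey <- paste(dd$seal_id, format(dd$start, "%Y-%m-%d"))
  hkey <- paste(habitat$seal_id, format(habitat$date, "%Y-%m-%d"))
  od <- habitat$ocean_depth[match(dkey, hkey)]
  bottom <- data.frame(dd[, c("seal_id", "start", "max_depth_m")],
                       ocean_depth = od,
                       call = classify_bottom_dive(dd$max_depth_m, od,
                                                   config$bottom_frac,
                                                   config$min_bottom_ocean_depth))
  log("bottom calls: %d bottom / %d pelagic / %d indeterminate",
      sum(bottom$call == "bottom"), sum(bottom$call == "pelagic"),
      sum(bottom$call == "indeterminate"))

  profiles <- diel_monthly_profiles(seg, ho$hours,
                                    local_offset = config$local_offset,
                                    depth_split = config$depth_split)
  depth_duration <- tryCatch(fit_depth_duration_curve(dives),
                             error = function(e) {
                               log("depth-duration fit skipped: %s",
                                   conditionMessage(e))
                               NULL
                             })

  budgets <- monthly_budgets(ho$hours, seg, dives, habitat,
                             min_sample = config$sample_min,
                             coast_excl_km = config$coast_excl,
                             dry_threshold = config$dry_threshold)
  btab <- tryCatch(budget_table(budgets), error = function(e) NULL)
  log("budgets: %d seal-months, %d included", nrow(budgets),
      sum(is.na(budgets$exclusion_reason)))

  bundle <- list(rejections = pf$rejected, track = track, daily = daily,
                 habitat = habitat, forays = forays, haulout = ho, seg = seg,
                 bottom = bottom, profiles = profiles,
                 depth_duration = depth_duration, budgets = budgets,
                 budget_table = btab, fits = fits, config = config)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  invisible(bundle)
}

# write every stage table plus a manifest (no timestamps: reruns are
# byte-identical)
#' @keywords internal
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name, times = character()) {
    for (cl in times) x[[cl]] <- fmt_time(x[[cl]])
    utils::write.csv(x, file.path(outdir, name), row.names = FALSE,
                     quote = FALSE)
    name
  }
  files <- c(
    wt(bundle$rejections, "rejections.csv", "timestamp"),
    wt(bundle$track, "track.csv", "timestamp"),
    wt(bundle$daily, "daily.csv"),
    wt(bundle$habitat, "habitat.csv"),
    wt(bundle$forays, "forays.csv"),
    wt(bundle$seg$episodes, "episodes.csv", c("start", "end")),
    wt(bundle$bottom, "bottom_calls.csv", "start"),
    wt(bundle$budgets, "budgets.csv"))
  if (!is.null(bundle$budget_table))
    files <- c(files, wt(bundle$budget_table, "budget_table.csv"))
  manifest <- list(
    config = unclass(bundle$config),
    counts = list(rejected_fixes = nrow(bundle$rejections),
                  track_estimates = nrow(bundle$track),
                  habitat_days = nrow(bundle$habitat),
                  forays = nrow(bundle$forays),
                  episodes = nrow(bundle$seg$episodes),
                  seal_months = nrow(bundle$budgets)),
    files = files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
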