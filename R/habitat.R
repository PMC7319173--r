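# Habitat annotation: bathymetry lookup, coast distance (islands excluded),
# sea-ice metrics on the 25-km grid, depth-zone classification, and detection
# of multi-day off-shelf forays into the deep basin.

#' Ocean depth at a position
#'
#' Nearest-cell bathymetry lookup.  Land cells (and points off the grid)
#' return `NA`; use [raster_is_land()] for the land flag.
#'
#' @param bathy Bathymetry [grid_raster()] (positive depths, metres).
#' @param lon,lat Position in decimal degrees.
#' @return Numeric depth in metres, `NA` over land.
#' @export
sample_depth <- function(bathy, lon, lat) {
  raster_lookup(bathy, lon, lat)
}

#' Great-circle distance to the mainland, islands excluded
#'
#' The mainland is the largest 8-connected component of the land mask; all
#' other land components are islands and are ignored.  The distance is the
#' great-circle distance from the point to the nearest mainland cell centre
#' (0 when the point itself sits on a mainland cell).
#'
#' @param lon,lat Position in decimal degrees (scalars or vectors).
#' @param land A [grid_raster()] whose land mask defines land.
#' @return Distance(s) in km; `NA` if there is no land on the grid.
#' @export
distance_to_mainland <- function(lon, lat, land) {
  lab <- label_components(land$land)
  if (!any(lab > 0)) return(rep(NA_real_, length(lon)))
  sizes <- tabulate(lab[lab > 0])
  main <- which.max(sizes)
  cells <- which(lab == main, arr.ind = TRUE)
  xy <- raster_xy(land, cells[, 1], cells[, 2])
  cll <- laea_inverse(xy[, "x"], xy[, "y"], land$center)
  pxy <- laea_project(lon, lat, land$center)
  ij <- raster_index(land, pxy$x, pxy$y)
  vapply(seq_along(lon), function(k) {
    if (!is.na(ij[k, "i"]) && lab[ij[k, "i"], ij[k, "j"]] == main) return(0)
    min(gc_dist_km(lon[k], lat[k], cll$lon, cll$lat))
  }, numeric(1))
}

#' Mean sea-ice concentration around a position
#'
#' Unweighted mean concentration over sea cells whose centres lie within
#' `radius` km (great-circle) of the point, excluding land.  Returns `NA`
#' when no sea cell centre falls inside the disc.
#'
#' @param ice An ice-concentration [grid_raster()] (percent, land `NA`).
#' @param lon,lat Position in decimal degrees.
#' @param radius Disc radius, km.
#' @return Mean concentration in percent, or `NA`.
#' @export
mean_ice_concentration <- function(ice, lon, lat, radius = 50) {
  cells <- raster_cells(ice)
  sea <- !ice$land[cbind(cells$i, cells$j)]
  d <- gc_dist_km(lon, lat, cells$lon, cells$lat)
  sel <- sea & d <= radius
  if (!any(sel)) return(NA_real_)
  mean(ice$values[cbind(cells$i[sel], cells$j[sel])], na.rm = TRUE)
}

# qualifying ice components and their periphery cells
#' @keywords internal
ice_edge_cells <- function(ice, conc_min, min_pixels) {
  qual <- !is.na(ice$values) & ice$values >= conc_min & !ice$land
  lab <- label_components(qual)
  if (!any(lab > 0)) return(NULL)
  sizes <- tabulate(lab[lab > 0])
  big <- which(sizes >= min_pixels)
  if (!length(big)) return(NULL)
  member <- matrix(lab %in% big, nrow(lab), ncol(lab))
  # periphery: member cell with at least one in-grid sea neighbour below the
  # concentration threshold (8-neighbourhood)
  ny <- nrow(lab); nx <- ncol(lab)
  open_sea <- !qual & !ice$land
  peri <- matrix(FALSE, ny, nx)
  for (cell in which(member)) {
    i <- ((cell - 1L) %% ny) + 1L
    j <- ((cell - 1L) %/% ny) + 1L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= ny && jj >= 1 && jj <= nx && open_sea[ii, jj]) {
        peri[cell] <- TRUE
      }
    }
  }
  list(member = member, peri = peri)
}

#' Signed distance to the sea-ice edge
#'
#' Qualifying ice is any 8-connected component of cells at or above
#' `conc_min` percent concentration spanning at least `min_pixels` grid
#' cells.  The edge is the periphery of qualifying ice: member cells with at
#' least one open-sea neighbour below the threshold.  The result is the
#' great-circle distance from the point to the nearest periphery cell centre,
#' negative when the point lies inside a qualifying component (inside the
#' pack ice) and positive outside.  Returns `NA` when no qualifying ice
#' exists anywhere on the grid.
#'
#' @param ice An ice-concentration [grid_raster()].
#' @param lon,lat Position in decimal degrees.
#' @param conc_min Concentration threshold, percent.
#' @param min_pixels Minimum component size, cells.
#' @return Signed distance in km, or `NA`.
#' @export
distance_to_ice_edge <- function(ice, lon, lat, conc_min = 15, min_pixels = 10) {
  edge <- ice_edge_cells(ice, conc_min, min_pixels)
  if (is.null(edge) || !any(edge$peri)) return(NA_real_)
  cells <- which(edge$peri, arr.ind = TRUE)
  xy <- raster_xy(ice, cells[, 1], cells[, 2])
  cll <- laea_inverse(xy[, "x"], xy[, "y"], ice$center)
  d <- min(gc_dist_km(lon, lat, cll$lon, cll$lat))
  pxy <- laea_project(lon, lat, ice$center)
  ij <- raster_index(ice, pxy$x, pxy$y)
  inside <- !is.na(ij[1, "i"]) && edge$member[ij[1, "i"], ij[1, "j"]]
  if (inside) -d else d
}

#' Depth-zone classification
#'
#' Shelf below 300 m, basin beyond 1,000 m, and the steep shelf-break band in
#' between (300-1,000 m inclusive), which daily dive analyses exclude.
#'
#' @param ocean_depth Positive depth(s) in metres.
#' @return Character vector over `"shelf"`, `"break"`, `"basin"` (`NA` in,
#'   `NA` out).
#' @export
classify_zone <- function(ocean_depth) {
  ifelse(is.na(ocean_depth), NA_character_,
         ifelse(ocean_depth < 300, "shelf",
                ifelse(ocean_depth <= 1000, "break", "basin")))
}

#' Annotate daily positions with habitat metrics
#'
#' For each daily (midday) position: ocean depth, distance to the mainland,
#' mean ice concentration within `ice_radius` km, signed distance to the ice
#' edge, and the depth zone.
#'
#' @param daily Output of [daily_summaries()] (or any frame with `seal_id`,
#'   `date`, `lon`, `lat`).
#' @param bathy Bathymetry [grid_raster()].
#' @param ice Optional [raster_stack()] of daily ice fields.
#' @param ice_radius Disc radius for the concentration mean, km.
#' @param conc_min,min_pixels Ice-edge qualification (see
#'   [distance_to_ice_edge()]).
#' @return `data.frame` of per-seal-day habitat rows (`HabitatDay`):
#'   `seal_id`, `date`, `lon`, `lat`, `ocean_depth`, `dist_mainland`,
#'   `ice_conc_mean`, `dist_ice_edge`, `zone`.
#' @export
annotate_habitat <- function(daily, bathy, ice = NULL, ice_radius = 50,
                             conc_min = 15, min_pixels = 10) {
  daily <- daily[!is.na(daily$lon), , drop = FALSE]
  depth <- sample_depth(bathy, daily$lon, daily$lat)
  dmain <- distance_to_mainland(daily$lon, daily$lat, bathy)
  conc <- edge <- rep(NA_real_, nrow(daily))
  if (!is.null(ice)) {
    for (k in seq_len(nrow(daily))) {
      r <- tryCatch(stack_on(ice, daily$date[k]), error = function(e) NULL)
      if (is.null(r)) next
      conc[k] <- mean_ice_concentration(r, daily$lon[k], daily$lat[k],
                                        radius = ice_radius)
      edge[k] <- distance_to_ice_edge(r, daily$lon[k], daily$lat[k],
                                      conc_min = conc_min,
                                      min_pixels = min_pixels)
    }
  }
  data.frame(seal_id = daily$seal_id, date = daily$date,
             lon = daily$lon, lat = daily$lat,
             ocean_depth = depth, dist_mainland = dmain,
             ice_conc_mean = conc, dist_ice_edge = edge,
             zone = classify_zone(depth))
}

#' Detect off-shelf forays
#'
#' A foray is a maximal run of consecutive basin-zone days.  A single
#' shelf-break day sandwiched between basin days bridges the run rather than
#' splitting it (configurable via `bridge_max`); shelf days and gaps in the
#' daily series always end a run.  Haul-out hours recorded on foray days are
#' attached when hourly flags are supplied.
#'
#' @param habitat_days Output of [annotate_habitat()] (one seal or several).
#' @param haulout_hours Optional hourly flag frame from
#'   [classify_haulout_hours()] (`seal_id`, `date`, `hour`, `haulout`).
#' @param bridge_max Maximum number of consecutive break-zone days bridged
#'   inside a foray.
#' @return `data.frame` with one row per foray: `seal_id`, `start_date`,
#'   `end_date`, `duration_days`, `max_depth_visited`, `haulout_hours`.
#' @export
detect_forays <- function(habitat_days, haulout_hours = NULL, bridge_max = 1) {
  out <- lapply(split(habitat_days, habitat_days$seal_id), function(h) {
    h <- h[order(h$date), ]
    z <- h$zone
    # bridge short break-day runs flanked by basin days
    r <- rle(z)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!is.na(r$values[k]) && r$values[k] == "break" &&
          r$lengths[k] <= bridge_max && k > 1 && k < length(r$values) &&
          identical(r$values[k - 1], "basin") &&
          identical(r$values[k + 1], "basin") &&
          all(diff(h$date[starts[k - 1]:ends[k + 1]]) == 1)) {
        z[starts[k]:ends[k]] <- "basin"
      }
    }
    run_id <- cumsum(c(TRUE, !(z[-1] == "basin" & z[-length(z)] == "basin" &
                                 diff(h$date) == 1)))
    keep <- which(z == "basin")
    if (!length(keep)) return(NULL)
    do.call(rbind, lapply(split(keep, run_id[keep]), function(idx) {
      hh <- 0L
      if (!is.null(haulout_hours)) {
        sel <- haulout_hours$seal_id == h$seal_id[1] &
          haulout_hours$date %in% h$date[idx]
        hh <- sum(haulout_hours$haulout[sel])
      }
      data.frame(seal_id = h$seal_id[1],
                 start_date = min(h$date[idx]), end_date = max(h$date[idx]),
                 duration_days = as.integer(max(h$date[idx]) -
                                              min(h$date[idx])) + 1L,
                 max_depth_visited = suppressWarnings(
                   max(h$ocean_depth[idx], na.rm = TRUE)),
                 haulout_hours = hh)
    }))
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(seal_id = character(), start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      duration_days = integer(),
                      max_depth_visited = numeric(), haulout_hours = integer())
  }
  rownames(res) <- NULL
  res
}
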