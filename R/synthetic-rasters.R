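# Synthetic bathymetry, land mask and seasonal sea-ice fields on the 25-km
# equal-area study grid.  The geometry emulates a shelf-to-basin transect:
# a mainland band in the south, a shallow continental shelf (< 300 m), a steep
# shelf-break ramp (300-1,000+ m), and a deep basin, with a small offshore
# island for coast-distance tests.  Ice concentration follows a seasonal edge
# that retreats poleward to the basin in September and advances south past the
# whole shelf in late winter.

#' Generate synthetic bathymetry and daily sea-ice rasters
#'
#' Deterministic given `config$seed`.  The bathymetry/land raster and each
#' daily ice field share one 60 x 60 grid of 25-km cells centred on the study
#' area.  Ice concentration is in percent on \[0, 100\] with land cells `NA`;
#' in mid-winter the entire shelf is covered at >= 80%, and in early autumn
#' the edge sits over the basin.
#'
#' @param config A [sim_config()].
#' @param dates Optional `Date` vector for the ice stack; defaults to every
#'   day of the configured simulation span.
#' @return A list with elements `bathy` (a [grid_raster()] of positive ocean
#'   depths in metres, land masked) and `ice` (a [raster_stack()] of daily
#'   concentration fields).
#' @export
simulate_rasters <- function(config, dates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(dates)) {
    dates <- seq(as.Date(config$start_date), as.Date(config$end_date), by = "day")
  }
  set.seed(child_seed(config$seed, 0L, 3L))
  nx <- ny <- 60L
  dx <- dy <- 25
  x0 <- y0 <- -725
  xs <- x0 + (seq_len(nx) - 1) * dx
  ys <- y0 + (seq_len(ny) - 1) * dy
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)

  # smooth pseudo-random field from a handful of random-phase plane waves
  waves <- lapply(seq_len(4), function(k) {
    list(theta = stats::runif(1, 0, pi), lambda = stats::runif(1, 250, 700),
         phase = stats::runif(1, 0, 2 * pi), amp = stats::runif(1, 0.4, 1))
  })
  wave_field <- function(xm, ym, scale) {
    f <- 0
    for (w in waves) {
      f <- f + w$amp * sin(2 * pi * (xm * cos(w$theta) + ym * sin(w$theta)) /
                             w$lambda + w$phase)
    }
    scale * f / length(waves)
  }

  land <- Y <= -100
  # small 2x2 offshore island on the shelf
  land[Y >= 125 & Y <= 150 & X >= -325 & X <= -300] <- TRUE

  depth <- matrix(NA_real_, ny, nx)
  shelf <- Y > -100 & Y <= 400
  ramp <- Y > 400 & Y <= 600
  basin <- Y > 600
  depth[shelf] <- 10 + (Y[shelf] + 100) / 500 * 280
  depth[ramp] <- 300 + (Y[ramp] - 400) / 200 * 900
  depth[basin] <- 1200 + (Y[basin] - 600) * 15
  noise <- wave_field(X, Y, 8)
  depth[shelf] <- pmin(pmax(depth[shelf] + noise[shelf], 5), 298)
  bathy <- grid_raster(depth, x0, y0, dx, dy, config$center, land)

  ice_phase <- stats::runif(1, 0, 2 * pi)
  ice <- lapply(dates, function(d) {
    doy <- as.integer(format(d, "%j"))
    edge_y <- -100 + 700 * cos(2 * pi * (doy - 258) / 365)
    conc <- 100 * stats::plogis((Y - edge_y) / 40)
    wob <- wave_field(X + doy * 3, Y, 6) +
      2 * sin(2 * pi * doy / 365 + ice_phase)
    conc <- pmin(pmax(conc + wob, 0), 100)
    grid_raster(conc, x0, y0, dx, dy, config$center, land)
  })
  names(ice) <- format(dates, "%Y-%m-%d")
  list(bathy = bathy, ice = raster_stack(ice))
}
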