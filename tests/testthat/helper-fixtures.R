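# Small programmatic fixtures shared across test files.

T0 <- as.POSIXct("2016-08-01 00:00:00", tz = "UTC")

# dive frame from depths and the surface gaps (minutes) between dives
make_dives <- function(depths, gaps_min = rep(1, length(depths) - 1),
                       dur_min = 3, start = T0, seal_id = "S01") {
  n <- length(depths)
  if (!n) {
    return(data.frame(seal_id = character(), start = as.POSIXct(character()),
                      end = as.POSIXct(character()), max_depth_m = numeric()))
  }
  dur <- rep_len(dur_min, n)
  starts <- numeric(n)
  starts[1] <- as.numeric(start)
  if (n > 1) {
    for (k in 2:n) starts[k] <- starts[k - 1] + dur[k - 1] * 60 +
        gaps_min[k - 1] * 60
  }
  data.frame(seal_id = seal_id,
             start = as.POSIXct(starts, origin = "1970-01-01", tz = "UTC"),
             end = as.POSIXct(starts + dur * 60, origin = "1970-01-01",
                              tz = "UTC"),
             max_depth_m = depths)
}

# drytimes frame from a named vector of percent-dry values per consecutive hour
make_drytimes <- function(percent_dry, start = T0, seal_id = "S01") {
  hrs <- start + (seq_along(percent_dry) - 1) * 3600
  data.frame(seal_id = seal_id, date = as.Date(format(hrs, "%Y-%m-%d")),
             hour = as.integer(format(hrs, "%H")), percent_dry = percent_dry)
}

# a small raster with a southern mainland band, one offshore island, and a
# linear south-to-north depth ramp
tiny_raster <- function(ny = 12, nx = 12, dx = 25, center = c(-156.8, 71.3),
                        land_rows = 2, island = c(8, 4)) {
  ys <- (seq_len(ny) - 1) * dx
  depth <- matrix(rep(10 + ys * 1.2, nx), ny, nx)
  land <- matrix(FALSE, ny, nx)
  land[seq_len(land_rows), ] <- TRUE
  if (!is.null(island)) land[island[1], island[2]] <- TRUE
  grid_raster(depth, 0, 0, dx, dx, center, land)
}

# ice raster from a concentration matrix on the tiny grid
ice_raster <- function(conc, land = NULL, dx = 25, center = c(-156.8, 71.3)) {
  grid_raster(conc, 0, 0, dx, dx, center, land)
}

# lon/lat of a planar point on the tiny grid
tiny_lonlat <- function(x, y, center = c(-156.8, 71.3)) {
  laea_inverse(x, y, center)
}

# random blobby concentration field (smoothed uniform noise rescaled to 0-100)
random_ice_field <- function(ny, nx, smooth_passes = 2) {
  m <- matrix(stats::runif(ny * nx), ny, nx)
  for (p in seq_len(smooth_passes)) {
    padded <- rbind(m[1, ], m, m[ny, ])
    padded <- cbind(padded[, 1], padded, padded[, nx])
    m <- (padded[1:ny, 1:nx] + padded[1:ny, 2:(nx + 1)] +
            padded[1:ny, 3:(nx + 2)] +
            padded[2:(ny + 1), 1:nx] + padded[2:(ny + 1), 2:(nx + 1)] +
            padded[2:(ny + 1), 3:(nx + 2)] +
            padded[3:(ny + 2), 1:nx] + padded[3:(ny + 2), 2:(nx + 1)] +
            padded[3:(ny + 2), 3:(nx + 2)]) / 9
  }
  100 * (m - min(m)) / max(max(m) - min(m), 1e-9)
}

# random depth/gap sequences exercising every segmentation rule
random_dive_sequence <- function(n_max = 12) {
  n <- sample.int(n_max, 1)
  depths <- numeric(n)
  depths[1] <- exp(stats::runif(1, log(3), log(300)))
  for (k in seq_len(n)[-1]) {
    depths[k] <- if (stats::runif(1) < 0.6) {
      depths[k - 1] * (1 + stats::runif(1, -0.2, 0.2))
    } else {
      exp(stats::runif(1, log(3), log(300)))
    }
  }
  depths <- round(depths * 2) / 2
  depths[depths < 0.5] <- 0.5
  gaps <- ifelse(stats::runif(max(n - 1, 0)) < 0.2,
                 stats::runif(max(n - 1, 0), 11, 60),
                 stats::runif(max(n - 1, 0), 0.3, 9))
  list(depths = depths, gaps = gaps)
}
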