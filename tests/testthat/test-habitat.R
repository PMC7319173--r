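ctr <- c(-156.8, 71.3)

test_that("depth sampling and zone classification follow the thresholds", {
  r <- tiny_raster()
  ll <- tiny_lonlat(50, 100)
  expect_equal(sample_depth(r, ll$lon, ll$lat), 130)
  lland <- tiny_lonlat(75, 0)
  expect_true(is.na(sample_depth(r, lland$lon, lland$lat)))
  expect_true(raster_is_land(r, lland$lon, lland$lat))

  expect_identical(classify_zone(299.9), "shelf")
  expect_identical(classify_zone(300), "break")
  expect_identical(classify_zone(1000), "break")
  expect_identical(classify_zone(1000.1), "basin")
  expect_identical(classify_zone(1500), "basin")
  expect_identical(classify_zone(NA_real_), NA_character_)
})

test_that("mainland distance ignores islands", {
  r <- tiny_raster()  # mainland rows 1-2 (y = 0, 25), island at cell [8, 4]
  # on a mainland cell: 0
  on_main <- tiny_lonlat(100, 25)
  expect_equal(distance_to_mainland(on_main$lon, on_main$lat, r), 0)
  # one cell north of the mainland coast: ~ cell size
  adj <- tiny_lonlat(100, 50)
  expect_equal(distance_to_mainland(adj$lon, adj$lat, r), 25, tolerance = 0.02)
  # next to the island (cell centre (75, 175)): distance measured past the
  # island to the mainland band, not 25 km to the island
  near_isl <- tiny_lonlat(75, 200)
  d <- distance_to_mainland(near_isl$lon, near_isl$lat, r)
  expect_equal(d, 175, tolerance = 0.5)
})

test_that("mean ice concentration averages sea cells within the radius", {
  conc <- matrix(50, 12, 12)
  r <- ice_raster(conc)
  ll <- tiny_lonlat(150, 150)
  expect_equal(mean_ice_concentration(r, ll$lon, ll$lat, radius = 50), 50)

  # half the disc at 100, half at 0 (split along x): mean 50
  conc2 <- matrix(0, 12, 12)
  conc2[, 1:6] <- 100
  r2 <- ice_raster(conc2)
  # point on the boundary between columns 6 and 7 (x = 137.5), radius catches
  # equal cell counts either side
  llb <- tiny_lonlat(137.5, 150)
  expect_equal(mean_ice_concentration(r2, llb$lon, llb$lat, radius = 30), 50)

  # disc entirely over land: missing
  land <- matrix(TRUE, 12, 12)
  r3 <- ice_raster(matrix(0, 12, 12), land = land)
  expect_true(is.na(mean_ice_concentration(r3, ll$lon, ll$lat, radius = 50)))
})

test_that("ice-edge distance honours the contiguity rule and the sign", {
  # a single 3x3 (9-cell) component is below the 10-pixel floor: missing
  conc <- matrix(0, 12, 12)
  conc[5:7, 5:7] <- 90
  r <- ice_raster(conc)
  ll <- tiny_lonlat(150, 150)
  expect_true(is.na(distance_to_ice_edge(r, ll$lon, ll$lat)))

  # grow it to 12 cells: qualifies; centre point is inside => negative
  conc[8, 5:7] <- 90
  r2 <- ice_raster(conc)
  centre <- tiny_lonlat(125, 150)  # cell [7, 6]
  d_in <- distance_to_ice_edge(r2, centre$lon, centre$lat)
  expect_lt(d_in, 0)
  # one cell outside the edge: ~ +25 km
  out1 <- tiny_lonlat(125, 225)  # cell [10, 6]; edge row is i = 8 (y = 175)
  d_out <- distance_to_ice_edge(r2, out1$lon, out1$lat)
  expect_gt(d_out, 0)
  expect_equal(d_out, 50, tolerance = 1)
  expect_equal(distance_to_ice_edge(r2, tiny_lonlat(125, 200)$lon,
                                    tiny_lonlat(125, 200)$lat),
               25, tolerance = 0.5)
})

test_that("ice-edge sign flips exactly with qualifying-component membership", {
  set.seed(31)
  for (k in 1:20) {
    ny <- sample(8:20, 1); nx <- sample(8:20, 1)
    r <- ice_raster(random_ice_field(ny, nx))
    px <- runif(1, 0, (nx - 1) * 25); py <- runif(1, 0, (ny - 1) * 25)
    ll <- tiny_lonlat(px, py)
    d <- distance_to_ice_edge(r, ll$lon, ll$lat)
    if (is.na(d)) next
    edge <- sealdive:::ice_edge_cells(r, 15, 10)
    ij <- sealdive:::raster_index(r, px, py)
    inside <- edge$member[ij[1, "i"], ij[1, "j"]]
    expect_identical(unname(d < 0), unname(inside))
  }
})

test_that("forays are maximal basin runs with single break-day bridging", {
  mk <- function(zones, dates = seq(as.Date("2016-08-01"), by = "day",
                                    length.out = length(zones))) {
    depth <- c(shelf = 100, `break` = 500, basin = 2000)[zones]
    data.frame(seal_id = "S01", date = dates, lon = -156.8, lat = 71.3,
               ocean_depth = unname(depth), dist_mainland = 100,
               ice_conc_mean = NA_real_, dist_ice_edge = NA_real_,
               zone = zones)
  }
  expect_identical(nrow(detect_forays(mk(rep("shelf", 10)))), 0L)

  f <- detect_forays(mk(c("shelf", rep("basin", 7), "shelf")))
  expect_identical(nrow(f), 1L)
  expect_identical(f$duration_days, 7L)
  expect_identical(f$start_date, as.Date("2016-08-02"))

  # basin, break, basin bridges into one 3-day foray
  f2 <- detect_forays(mk(c("shelf", "basin", "break", "basin", "shelf")))
  expect_identical(nrow(f2), 1L)
  expect_identical(f2$duration_days, 3L)

  # two break days do not bridge
  f3 <- detect_forays(mk(c("basin", "break", "break", "basin")))
  expect_identical(nrow(f3), 2L)

  # a date gap splits a run
  h <- mk(rep("basin", 6))
  h <- h[-3, ]
  f4 <- detect_forays(h)
  expect_identical(nrow(f4), 2L)

  # haul-out hours on foray days are attached
  hh <- data.frame(seal_id = "S01",
                   date = rep(seq(as.Date("2016-08-02"), by = "day",
                                  length.out = 2), each = 24),
                   hour = rep(0:23, 2),
                   percent_dry = 0, haulout = FALSE)
  hh$haulout[1:5] <- TRUE
  f5 <- detect_forays(mk(c("shelf", rep("basin", 7), "shelf")), hh)
  expect_identical(f5$haulout_hours, 5L)
})

test_that("habitat annotation assembles per-day rows", {
  cfg <- sim_config(seed = 12, n_seals = 1,
                    start_date = "2016-08-01", end_date = "2016-08-06")
  ras <- simulate_rasters(cfg)
  daily <- data.frame(seal_id = "S01",
                      date = seq(as.Date("2016-08-01"), by = "day",
                                 length.out = 5),
                      lon = rep(-156.8, 5), lat = 71.3 + (0:4) * 0.8)
  h <- annotate_habitat(daily, ras$bathy, ras$ice)
  expect_identical(nrow(h), 5L)
  expect_true(all(h$ocean_depth > 0, na.rm = TRUE))
  expect_true(all(h$ice_conc_mean >= 0 & h$ice_conc_mean <= 100, na.rm = TRUE))
  expect_identical(h$zone, classify_zone(h$ocean_depth))
})
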