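ctr <- c(-156.8, 71.3)

# fixes along a plausible straight line, 4 km / hr eastward
straight_fixes <- function(n = 20, speed_kmh = 4, seal_id = "S01") {
  t <- T0 + (0:(n - 1)) * 3600
  ll <- laea_inverse((0:(n - 1)) * speed_kmh, rep(200, n), ctr)
  data.frame(seal_id = seal_id, timestamp = t, lon = ll$lon, lat = ll$lat,
             lc = "1")
}

test_that("prefilter removes land, speed and spike violations with reasons", {
  r <- tiny_raster()
  fx <- straight_fixes()
  # plausible straight track: nothing removed
  out <- prefilter_fixes(fx, land = r)
  expect_identical(nrow(out$rejected), 0L)
  expect_identical(nrow(out$retained), nrow(fx))

  # a fix on a land cell is removed with reason on_land
  lland <- tiny_lonlat(100, 25)
  fx2 <- fx
  fx2$lon[5] <- lland$lon; fx2$lat[5] <- lland$lat
  out2 <- prefilter_fixes(fx2, land = r)
  expect_identical(out2$rejected$reason, "on_land")
  expect_identical(out2$rejected$timestamp, fx$timestamp[5])

  # A, B, A' with 100 km legs in 1 hr: B removed by the speed rule
  ll <- laea_inverse(c(0, 100, 0.5), c(200, 250, 200.5), ctr)
  fx3 <- data.frame(seal_id = "S01", timestamp = T0 + (0:2) * 3600,
                    lon = ll$lon, lat = ll$lat, lc = "1")
  out3 <- prefilter_fixes(fx3, land = NULL, max_speed = 10)
  expect_identical(out3$rejected$reason, "speed")
  expect_equal(nrow(out3$retained), 2L)

  # an out-and-back spike below the angle threshold at sub-max speed
  ll4 <- laea_inverse(c(0, 4, 5, 5.5, 12), c(200, 200, 208, 200.2, 200.4), ctr)
  fx4 <- data.frame(seal_id = "S01", timestamp = T0 + (0:4) * 3600,
                    lon = ll4$lon, lat = ll4$lat, lc = "1")
  out4 <- prefilter_fixes(fx4, land = NULL, max_speed = 10,
                          spike_angle = 15, spike_speed = 5)
  expect_true("spike" %in% out4$rejected$reason)

  # idempotence: re-running on retained fixes removes nothing
  again <- prefilter_fixes(out2$retained, land = r)
  expect_identical(nrow(again$rejected), 0L)
})

test_that("prefilter drops class Z, de-duplicates timestamps, warns on tiny input", {
  fx <- straight_fixes(6)
  fx$lc[3] <- "Z"
  dup <- fx[4, ]; dup$lc <- "B"
  fx <- rbind(fx, dup)
  out <- prefilter_fixes(fx)
  expect_setequal(out$rejected$reason, c("class_Z", "duplicate_time"))
  expect_identical(out$rejected$lc[out$rejected$reason == "duplicate_time"], "B")
  expect_warning(prefilter_fixes(fx[1, ]), "fewer than 2")
})

test_that("smoother means match a direct GLS solve on a 3-fix toy problem", {
  beta <- 0.8; sigma <- 1.5
  t_hr <- c(0, 2, 5)
  yx <- c(0, 3, 4); yy <- c(1, 2, 0)
  ev <- c(0.5, 1, 0.25)
  kf <- sealdive:::ctcrw_kalman(t_hr, cbind(yx, yy), ev, beta, sigma,
                                smooth = TRUE)
  expect_equal(kf$m_smooth[, 1, 1], ref_gls_smoother(t_hr, yx, ev, beta, sigma),
               tolerance = 1e-6)
  expect_equal(kf$m_smooth[, 1, 2], ref_gls_smoother(t_hr, yy, ev, beta, sigma),
               tolerance = 1e-6)
})

test_that("fitting improves the likelihood and passes through noise-free fixes", {
  cfg <- sim_config(seed = 4, n_seals = 1, start_date = "2016-08-01",
                    end_date = "2016-08-11",
                    argos_class_probs = c(`3` = 1, `2` = 0, `1` = 0, `0` = 0,
                                          A = 0, B = 0, Z = 0),
                    argos_class_sd_km = c(`3` = 0.001, `2` = 0.5, `1` = 1.5,
                                          `0` = 4, A = 8, B = 15, Z = 80))
  tr <- simulate_track(cfg, 1)
  fit <- fit_ctcrw(tr$fixes, center = cfg$center,
                   class_sd = cfg$argos_class_sd_km)
  expect_gte(fit$loglik, fit$loglik_init)
  est <- predict_track(fit, grid_step = 6, se_max = Inf, seal_id = "S01")
  expect_identical(attr(est, "n_dropped"), 0L)
  # grid spacing exactly 6 hr, aligned to 00/06/12/18 UTC
  expect_true(all(diff(as.numeric(est$timestamp)) == 6 * 3600))
  expect_true(all(as.numeric(est$timestamp) %% (6 * 3600) == 0))
  # at fix times the smoother passes through the (noise-free) fixes
  on_fix <- est$timestamp %in% tr$fixes$timestamp
  m <- match(est$timestamp[on_fix], tr$fixes$timestamp)
  expect_lt(max(gc_dist_km(est$lon[on_fix], est$lat[on_fix],
                           tr$fixes$lon[m], tr$fixes$lat[m])), 0.02)
  expect_lt(max(est$se_km[on_fix]), 0.05)
})

test_that("standard errors grow into data gaps and the SE cutoff drops estimates", {
  # sparse noise-free-ish fixes 12 hr apart; predict hourly
  t <- T0 + c(0, 12, 24, 36) * 3600
  ll <- laea_inverse(c(0, 5, 8, 12), rep(200, 4), ctr)
  fx <- data.frame(seal_id = "S01", timestamp = t, lon = ll$lon, lat = ll$lat,
                   lc = "3")
  fx <- rbind(fx, straight_fixes(8)[0, ])  # keep schema
  fit <- structure(list(beta = 1, sigma = 2, error_scale = 1,
                        center = ctr,
                        class_sd = c(`3` = 0.25),
                        t_hr = as.numeric(difftime(t, t[1], units = "hours")),
                        Y = as.matrix(laea_project(fx$lon, fx$lat, ctr)),
                        err_var = rep(0.25^2, 4), t0 = t[1]),
                   class = "ctcrw_fit")
  est <- predict_track(fit, grid_step = 1, se_max = Inf, seal_id = "S01")
  gap <- est[est$timestamp > t[2] & est$timestamp < t[3], ]
  mid <- which.max(as.numeric(gap$timestamp))  # monotone up to the midpoint
  half <- gap$se_km[gap$timestamp <= t[2] + 6 * 3600]
  expect_true(all(diff(half) > 0))
  # a tight cutoff drops the mid-gap estimates, and reports the count
  est2 <- predict_track(fit, grid_step = 1, se_max = max(half) * 0.8,
                        seal_id = "S01")
  expect_gt(attr(est2, "n_dropped"), 0)
  expect_true(all(est2$se_km <= max(half) * 0.8))
})

test_that("daily summaries accumulate great-circle distance day by day", {
  # constant 4 km per 6-hr step for 10 full days: 160 km, 16 km/day
  n <- 41
  t <- T0 + (0:(n - 1)) * 6 * 3600
  ll <- laea_inverse((0:(n - 1)) * 4, rep(200, n), ctr)
  track <- data.frame(seal_id = "S01", timestamp = t, x_km = (0:(n - 1)) * 4,
                      y_km = 200, lon = ll$lon, lat = ll$lat, se_km = 1)
  ds <- daily_summaries(track)
  full_days <- ds[1:10, ]
  expect_equal(full_days$step_km, rep(16, 10), tolerance = 1e-3)
  expect_equal(ds$cum_km[10], 160, tolerance = 1e-2)
  expect_equal(full_days$rate_km_day, rep(16, 10), tolerance = 1e-3)
  # midday position is the estimate nearest 12:00 UTC
  expect_equal(ds$lon[1], track$lon[3])

  # stationary track: zero cumulative distance
  st <- track; st$lon <- track$lon[1]; st$lat <- track$lat[1]
  expect_equal(max(daily_summaries(st)$cum_km), 0)

  # a missing day is flagged, not interpolated, and adds no distance
  gap <- track[!(as.Date(format(track$timestamp, "%Y-%m-%d")) ==
                   as.Date("2016-08-03")), ]
  dg <- daily_summaries(gap)
  expect_true(dg$missing[dg$date == as.Date("2016-08-03")])
  expect_true(is.na(dg$lon[dg$date == as.Date("2016-08-03")]))
  expect_equal(max(dg$cum_km), 160, tolerance = 1e-2)
})
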