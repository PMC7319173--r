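# A controllable seal-month: explicit haul-out flags and an episode record
# with a known diving:resting time ratio.
budget_fixture <- function(obs_hours = 240, haul_hours = 24,
                           dive_rest_ratio = 3, month = "2016-09") {
  mb <- sealdive:::month_bounds(month)
  hrs <- mb$start + (seq_len(obs_hours) - 1) * 3600
  drytimes <- data.frame(seal_id = "S01",
                         date = as.Date(format(hrs, "%Y-%m-%d")),
                         hour = as.integer(format(hrs, "%H")),
                         percent_dry = 0,
                         haulout = c(rep(TRUE, haul_hours),
                                     rep(FALSE, obs_hours - haul_hours)))
  # one diving and one resting episode with the requested time ratio,
  # placed outside the haul-out hours
  t0 <- mb$start + (haul_hours + 1) * 3600
  dive_h <- 6 * dive_rest_ratio / (dive_rest_ratio + 1)
  episodes <- data.frame(
    seal_id = "S01", episode_id = 1:2,
    class = c("repetitive", "resting"),
    start = c(t0, t0 + dive_h * 3600),
    end = c(t0 + dive_h * 3600, t0 + 6 * 3600),
    n_dives = c(50L, 0L), median_depth = c(40, NA))
  # dive rows covering enough of the month to pass the 10% sample rule
  dives <- data.frame(seal_id = "S01",
                      start = mb$start + seq(0, obs_hours - 1, by = 1) * 3600,
                      end = mb$start + (seq(0, obs_hours - 1, by = 1)) * 3600 + 1800,
                      max_depth_m = 40)
  list(drytimes = drytimes, seg = list(dives = dives, episodes = episodes),
       dives = dives, month = month)
}

test_that("budget extrapolation follows the stated ratio arithmetic", {
  fx <- budget_fixture()  # 720-hr month, 240 observed, 24 hauled out, 3:1
  b <- extrapolate_monthly_budget(fx$month, fx$drytimes, fx$seg,
                                  dives = fx$dives)
  expect_true(is.na(b$exclusion_reason))
  expect_equal(b$haulout_h, 72)            # 24/240 * 720
  expect_equal(b$dive_h, 486)              # (720-72) * 3/4
  expect_equal(b$rest_h, 162)
  expect_equal(b$diving_h_per_day, 16.2)
  expect_equal(b$repetitive_pct, 100)      # the only diving was repetitive
  # conservation to 1e-6
  expect_equal(b$haulout_h + b$dive_h + b$rest_h, 720, tolerance = 1e-6)
})

test_that("budget components always conserve month hours", {
  for (ratio in c(0.5, 1, 3, 9)) {
    for (haul in c(0, 24, 120)) {
      fx <- budget_fixture(haul_hours = haul, dive_rest_ratio = ratio)
      b <- extrapolate_monthly_budget(fx$month, fx$drytimes, fx$seg,
                                      dives = fx$dives)
      expect_equal(b$haulout_h + b$dive_h + b$rest_h, 720, tolerance = 1e-6)
      expect_true(all(c(b$haulout_h, b$dive_h, b$rest_h,
                        b$repetitive_h, b$mixed_h) >= 0))
      expect_equal(b$repetitive_h + b$mixed_h, b$dive_h, tolerance = 1e-6)
    }
  }
})

test_that("seal-months are excluded for the stated reasons", {
  fx <- budget_fixture()
  # mean coast distance below 5 km
  b1 <- extrapolate_monthly_budget(fx$month, fx$drytimes, fx$seg,
                                   dives = fx$dives, dist_mainland = rep(4.9, 30))
  expect_identical(b1$exclusion_reason, "near_coast")
  expect_true(is.na(b1$haulout_h))
  b1b <- extrapolate_monthly_budget(fx$month, fx$drytimes, fx$seg,
                                    dives = fx$dives, dist_mainland = rep(5.1, 30))
  expect_true(is.na(b1b$exclusion_reason))

  # dive-series sample below 10%
  short <- fx$dives[1:50, ]  # 50 half-hour dives bridged: ~50 h of 720
  b2 <- extrapolate_monthly_budget(fx$month, fx$drytimes, fx$seg, dives = short)
  expect_identical(b2$exclusion_reason, "low_dive_sample")

  # no wet/dry data at all
  empty_dry <- fx$drytimes[0, ]
  b3 <- extrapolate_monthly_budget(fx$month, empty_dry, fx$seg,
                                   dives = fx$dives)
  expect_identical(b3$exclusion_reason, "no_dry_data")
})

test_that("sampled fractions are plain coverage ratios", {
  fx <- budget_fixture()
  # 74.4 covered hours in a 744-hour month -> 0.10
  mb <- sealdive:::month_bounds("2016-08")
  dv <- data.frame(seal_id = "S01", start = mb$start,
                   end = mb$start + 74.4 * 3600, max_depth_m = 40)
  sf <- monthly_sample_fraction(dv, fx$drytimes[0, ], "2016-08")
  expect_equal(sf$frac_dive, 0.1)
  expect_equal(sf$frac_dry, 0)
  # full coverage -> 1.0
  dv2 <- data.frame(seal_id = "S01", start = mb$start,
                    end = mb$end, max_depth_m = 40)
  expect_equal(monthly_sample_fraction(dv2, fx$drytimes[0, ],
                                       "2016-08")$frac_dive, 1)
  # no data -> 0
  expect_equal(monthly_sample_fraction(dv2[0, ], fx$drytimes[0, ],
                                       "2016-08")$frac_dive, 0)
})

test_that("more observed haul-out never lowers the extrapolated haul-out", {
  prev <- -1
  for (haul in c(0, 12, 24, 48, 96, 180)) {
    fx <- budget_fixture(haul_hours = haul)
    b <- extrapolate_monthly_budget(fx$month, fx$drytimes, fx$seg,
                                    dives = fx$dives)
    expect_gte(b$haulout_h, prev)
    prev <- b$haulout_h
  }
})

test_that("the budget table aggregates seal-months with a pooled row", {
  fx1 <- budget_fixture()
  b1 <- extrapolate_monthly_budget(fx1$month, fx1$drytimes, fx1$seg,
                                   dives = fx1$dives)
  b2 <- b1
  b2$seal_id <- "S02"
  b2$diving_h_per_day <- 20    # second seal at 20 h/day vs 16.2
  b1$diving_h_per_day <- 10
  b2$diving_h_per_day <- 20
  tab <- budget_table(rbind(b1, b2))
  row <- tab[tab$month == "2016-09", ]
  expect_identical(row$n, 2L)
  expect_equal(row$diving_h_mean, 15)
  expect_equal(row$diving_h_sd, sd(c(10, 20)))
  pooled <- tab[tab$month == "pooled", ]
  expect_identical(pooled$n, sum(tab$n[tab$month != "pooled"]))
  # single seal-month: mean equals the value, SD is NA by convention
  tab1 <- budget_table(b1)
  expect_equal(tab1$diving_h_mean[1], 10)
  expect_true(is.na(tab1$diving_h_sd[1]))
})

test_that("first-week exclusion drops the first seven days per seal", {
  d <- make_dives(rep(50, 20), gaps_min = rep(60 * 12, 19))  # every ~12 hr
  out <- drop_first_week(d)
  expect_true(all(out$start >= min(d$start) + 7 * 86400))
  expect_lt(nrow(out), nrow(d))
  dt <- make_drytimes(rep(0, 24 * 10))
  expect_identical(nrow(drop_first_week(dt)), 24L * 3L)
})
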