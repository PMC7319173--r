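test_that("haul-out hours use the 80% rule and bouts break on gaps", {
  dt <- make_drytimes(c(80.0, 79.9, 95, 100, 10, 85))
  ho <- classify_haulout_hours(dt)
  expect_identical(ho$hours$haulout, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  # flags 1,0,1,1,0,1 -> bouts of 1, 2 and 1 hours
  expect_identical(ho$bouts$duration_hr, c(1L, 2L, 1L))

  # flags 1,1,1,0,1 -> bouts of 3 hr and 1 hr
  ho2 <- classify_haulout_hours(make_drytimes(c(90, 90, 90, 0, 90)))
  expect_identical(ho2$bouts$duration_hr, c(3L, 1L))

  # a missing hour breaks a bout even when both sides are dry
  dt3 <- make_drytimes(c(90, 90, 90, 90))
  dt3 <- dt3[-2, ]
  ho3 <- classify_haulout_hours(dt3)
  expect_identical(ho3$bouts$duration_hr, c(1L, 2L))

  expect_error(classify_haulout_hours(make_drytimes(c(50, 101))), "percent_dry")
})

test_that("surface intervals pair consecutive dives and flag haul-out overlap", {
  d <- make_dives(c(20, 22, 21, 23), gaps_min = c(0.7, 5, 70))
  dt <- make_drytimes(rep(0, 6))
  dt$percent_dry[2] <- 100  # hour [01:00, 02:00) is a haul-out hour
  ho <- classify_haulout_hours(dt)
  si <- derive_surface_intervals(d, ho$hours)
  expect_identical(nrow(si), 3L)
  expect_equal(si$duration_min, c(0.7, 5, 70), tolerance = 1e-9)
  # dives end by 00:21; only the 70-min interval reaches past 01:00
  expect_identical(si$overlaps_haulout, c(FALSE, FALSE, TRUE))
  # a single dive yields no intervals
  expect_identical(nrow(derive_surface_intervals(d[1, ])), 0L)
})

test_that("segmentation reproduces the worked examples of the bout rules", {
  # five matched dives with short surfaces: one repetitive episode
  s1 <- segment_behavior(make_dives(c(100, 101, 99, 100, 102)))
  expect_identical(unique(s1$dives$class), "repetitive")
  expect_identical(nrow(s1$episodes), 1L)
  expect_identical(s1$episodes$n_dives, 5L)

  # a single deviant dive is allowable within a repetitive episode
  s2 <- segment_behavior(make_dives(c(60, 62, 61, 300, 60, 63, 59)))
  expect_identical(nrow(s2$episodes), 1L)
  expect_identical(s2$episodes$class, "repetitive")
  expect_identical(s2$episodes$n_dives, 7L)

  # four matched dives stay below the 5-dive minimum: mixed
  s3 <- segment_behavior(make_dives(c(100, 101, 99, 100)))
  expect_identical(unique(s3$dives$class), "mixed")

  # a surface interval over 10 min splits the record and becomes resting
  s4 <- segment_behavior(make_dives(rep(100, 10),
                                    gaps_min = c(rep(1, 4), 30, rep(1, 4))))
  expect_identical(s4$episodes$class, c("repetitive", "resting", "repetitive"))
  expect_identical(sum(s4$episodes$n_dives), 10L)

  # two consecutive deviants terminate the episode
  s5 <- segment_behavior(make_dives(c(100, 101, 99, 100, 102, 300, 20, 100)))
  expect_identical(s5$dives$class,
                   c(rep("repetitive", 5), "mixed", "mixed", "mixed"))

  # empty input: empty output
  s6 <- segment_behavior(make_dives(numeric(0))[0, ])
  expect_identical(nrow(s6$episodes), 0L)
})

test_that("segmentation matches the reference implementation on random records", {
  set.seed(77)
  for (k in 1:150) {
    seqs <- random_dive_sequence()
    d <- make_dives(seqs$depths, seqs$gaps)
    got <- segment_behavior(d)
    want <- ref_segment_classes(seqs$depths, seqs$gaps)
    expect_identical(got$dives$class, want)
  }
})

test_that("every dive lands in exactly one episode and bouts have >= 5 dives", {
  set.seed(99)
  for (k in 1:25) {
    seqs <- random_dive_sequence(40)
    d <- make_dives(seqs$depths, seqs$gaps)
    s <- segment_behavior(d)
    expect_false(any(is.na(s$dives$episode_id)))
    expect_identical(sum(s$episodes$n_dives), nrow(d))
    expect_true(all(s$episodes$n_dives[s$episodes$class == "repetitive"] >= 5))
    # no two adjacent resting episodes
    cls <- s$episodes$class[order(s$episodes$start)]
    expect_false(any(cls[-1] == "resting" & cls[-length(cls)] == "resting"))
  }
})

test_that("bottom-dive calls follow the 75% rule with a shallow-water guard", {
  expect_identical(classify_bottom_dive(75, 100), "bottom")
  expect_identical(classify_bottom_dive(74.9, 100), "pelagic")
  expect_identical(classify_bottom_dive(120, 100), "bottom")  # ratio > 1
  expect_identical(classify_bottom_dive(8, 9), "indeterminate")
  expect_identical(classify_bottom_dive(8, NA), "indeterminate")
  # monotone in max_depth at fixed ocean depth
  calls <- classify_bottom_dive(seq(1, 150, by = 1), 100)
  expect_identical(calls, calls[order(match(calls, c("pelagic", "bottom")))])
})

test_that("diel profiles normalise by month and localise hours", {
  # all dives at 13:00 UTC = 03:00 local (UTC-10)
  d <- make_dives(rep(100, 6), gaps_min = rep(1, 5),
                  start = as.POSIXct("2016-08-05 13:00:00", tz = "UTC"))
  seg <- segment_behavior(d)
  pr <- diel_monthly_profiles(seg)
  m <- pr$dive$repetitive_deep
  expect_equal(unname(m["2016-08", "03"]), 1)
  expect_equal(sum(m["2016-08", ]), 1)
  # shallow repetitive episodes go to the shallow matrix
  d2 <- make_dives(rep(20, 6), gaps_min = rep(1, 5),
                   start = as.POSIXct("2016-08-05 13:00:00", tz = "UTC"))
  pr2 <- diel_monthly_profiles(segment_behavior(d2))
  expect_equal(unname(pr2$dive$repetitive_shallow["2016-08", "03"]), 1)
  expect_true(all(is.na(pr2$dive$repetitive_deep["2016-08", ])))

  # haul-out profile: mean over seals with SE
  dtA <- make_drytimes(rep(c(100, 0), 12))           # hauled out odd hours
  dtB <- make_drytimes(rep(0, 24), seal_id = "S02")  # never hauled out
  ho <- classify_haulout_hours(rbind(dtA, dtB))
  pr3 <- diel_monthly_profiles(seg, ho$hours)
  # UTC hour 0 on Aug 1 = local hour 14 on Jul 31; A hauled out, B not => 0.5
  expect_equal(unname(pr3$haulout_mean["2016-07", "14"]), 0.5)
  expect_equal(unname(pr3$haulout_se["2016-07", "14"]), sd(c(1, 0)) / sqrt(2))
})

test_that("dive histograms conserve counts under the [lo,hi) convention", {
  d <- make_dives(c(2, 3.5, 10, 19.9, 20, 55, 400), gaps_min = rep(1, 6),
                  start = as.POSIXct("2016-08-05 21:00:00", tz = "UTC"))
  bins <- c(0, 10, 20, 50, 100, Inf)
  h <- bin_dive_histograms(d, depth_bins = bins)
  # the 2-m dive is below the 3.5-m histogram floor
  expect_identical(sum(h), 6L)
  # local 11:00 falls in the 10-16 period
  expect_identical(sum(h[, "10-16"]), 6L)
  # 3.5 m sits in [0,10); 20 m sits in [20,50), not [10,20)
  expect_identical(unname(h["[0,10)", "10-16"]), 1L)
  expect_identical(unname(h["[10,20)", "10-16"]), 2L)
  expect_identical(unname(h["[20,50)", "10-16"]), 1L)
  expect_identical(unname(h["[100,Inf)", "10-16"]), 1L)
  # one dive alone gives total count 1
  expect_identical(sum(bin_dive_histograms(d[3, ], depth_bins = bins)), 1L)
})

test_that("depth-duration regression recovers a noiseless logarithmic law", {
  depths <- rep(seq(5, 295, by = 10), each = 20)
  dur <- 2 + 1.5 * log(depths)
  n <- length(depths)
  starts <- T0 + cumsum(rep(1200, n))
  d <- data.frame(seal_id = "S01", start = starts,
                  end = starts + dur * 60, max_depth_m = depths)
  fit <- fit_depth_duration_curve(d)
  expect_equal(fit$duration$a, 2, tolerance = 1e-6)
  expect_equal(fit$duration$b, 1.5, tolerance = 1e-6)
  expect_equal(fit$duration$S, 0, tolerance = 1e-6)

  # bins with fewer than 10 dives are excluded from the fit
  extra <- data.frame(seal_id = "S01", start = T0 - 86400,
                      end = T0 - 86400 + 600, max_depth_m = 500)
  fit2 <- fit_depth_duration_curve(rbind(d, extra))
  expect_identical(fit2$duration$n_bins, fit$duration$n_bins)

  # dives over 15 min are excluded before binning
  long <- d[1:30, ]
  long$end <- long$start + 16 * 60
  fit3 <- fit_depth_duration_curve(rbind(d, long))
  expect_equal(fit3$duration$a, 2, tolerance = 1e-9)
  expect_error(fit_depth_duration_curve(d[1:25, ]), "fewer than 3")
})
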