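# Synthetic dive records and hourly wet/dry series, driven by an interval
# behaviour schedule with known (planted) classes.  The schedule is the ground
# truth that downstream segmentation and budget extrapolation are tested
# against, so it is interval-based rather than Markovian: every minute of the
# simulated span belongs to exactly one planted class.

#' Generate a planted behaviour schedule for one seal
#'
#' Tiles the simulation span, day by day, with non-overlapping intervals of
#' four classes: `haulout` (a nightly-biased block snapped to whole hours),
#' `repetitive` (bouts of diving to a near-constant target depth), `mixed`
#' (diving to scattered depths) and `resting` (surface gaps longer than
#' 10 min).  Repetitive targets track 80% of the local ocean depth on the
#' shelf and the upper water column off-shelf.
#'
#' @param config A [sim_config()].
#' @param truth A `sim_truth` from [simulate_track()] (for positions).
#' @param bathy Bathymetry [grid_raster()].
#' @param seal Integer seal index (seeds the schedule stream).
#' @return `data.frame` with `seal_id`, `start`, `end` (`POSIXct` UTC),
#'   `class`, `target_depth_m` (`NA` except for repetitive blocks).
#' @export
default_schedule <- function(config, truth, bathy, seal = 1L) {
  set.seed(child_seed(config$seed, seal, 4L))
  span0 <- config$start_date
  span1 <- config$end_date
  days <- seq(as.POSIXct(trunc(span0, "days"), tz = "UTC"), span1, by = "day")
  blocks <- list()
  for (d in days) {
    d0 <- max(as.POSIXct(d, tz = "UTC", origin = "1970-01-01"), span0)
    d1 <- min(as.POSIXct(d, tz = "UTC", origin = "1970-01-01") + 86400, span1)
    if (d1 <= d0) next
    # haul-out block: whole hours, biased to local night (UTC 06-16)
    ho_len <- sample(0:6, 1, prob = c(0.15, 0.15, 0.2, 0.2, 0.15, 0.1, 0.05))
    free <- list(c(d0, d1))
    if (ho_len > 0) {
      first_hr <- ceiling(as.numeric(d0) / 3600)
      last_hr <- floor(as.numeric(d1) / 3600) - ho_len
      if (last_hr >= first_hr) {
        cand <- first_hr:last_hr
        hod <- cand %% 24
        w <- ifelse(hod >= 6 & hod <= 16, 4, 1)
        h0 <- sample(cand, 1, prob = w)
        ho_start <- as.POSIXct(h0 * 3600, origin = "1970-01-01", tz = "UTC")
        ho_end <- ho_start + ho_len * 3600
        blocks[[length(blocks) + 1L]] <-
          data.frame(start = ho_start, end = ho_end, class = "haulout",
                     target_depth_m = NA_real_)
        free <- list(c(d0, ho_start), c(ho_end, d1))
      }
    }
    for (iv in free) {
      t0 <- iv[1]; t1 <- iv[2]
      if (as.numeric(t1) - as.numeric(t0) < 60) next
      cls_cycle <- c("repetitive", "mixed", "resting")
      ci <- sample(1:3, 1)  # random phase of the cycle
      while (t0 < t1) {
        cls <- cls_cycle[(ci - 1L) %% 3L + 1L]
        ci <- ci + 1L
        len_hr <- switch(cls,
                         repetitive = stats::runif(1, 1.5, 3.5),
                         mixed = stats::runif(1, 0.5, 1.5),
                         resting = stats::runif(1, 20, 50) / 60)
        bend <- min(t0 + round(len_hr * 3600), t1)
        if (as.numeric(t1) - as.numeric(bend) < 0.35 * 3600) bend <- t1
        target <- NA_real_
        if (cls == "repetitive") {
          pos <- truth_position_at(truth, t0)
          b <- raster_lookup(bathy, pos$lon, pos$lat)
          if (is.na(b)) {
            stop(sprintf("bathymetry missing under track at %s",
                         format(t0, "%Y-%m-%d")))
          }
          target <- if (b > 320) stats::runif(1, 40, 80) else
            max(4, min(0.8 * b, 280))
        }
        blocks[[length(blocks) + 1L]] <-
          data.frame(start = t0, end = bend, class = cls,
                     target_depth_m = target)
        t0 <- bend
      }
    }
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$start), ]
  out <- cbind(seal_id = truth$seal_id, out)
  rownames(out) <- NULL
  out
}

#' Simulate the dive record and hourly wet/dry series
#'
#' Emits individual dive records (start, end, maximum depth at 0.5-m
#' resolution) and hourly percent-dry values that realise the planted
#' behaviour schedule: repetitive blocks produce runs of dives within a few
#' percent of the block target (bounded by 95% of the local ocean depth) with
#' surface gaps under 10 min; mixed blocks produce log-uniform scattered
#' depths; resting blocks produce surface gaps over 10 min; haul-out blocks
#' suppress dives and drive the dry mode of the wet/dry mixture.  Dive
#' durations follow the logarithmic depth-duration law
#' `a + b*log(depth) + noise` of the config.
#'
#' @param config A [sim_config()].
#' @param truth A `sim_truth` from [simulate_track()].
#' @param bathy Bathymetry [grid_raster()]; an error names the date if the
#'   track runs over missing bathymetry.
#' @param seal Integer seal index (seeds the dive stream).
#' @param schedule Optional schedule `data.frame`; defaults to
#'   `config$behavior_schedule` for this seal, else [default_schedule()].
#' @return A list: `dives` (`seal_id`, `start`, `end`, `max_depth_m`),
#'   `drytimes` (`seal_id`, `date`, `hour`, `percent_dry`), and `truth`
#'   updated with the `schedule` and the planted `true_budget`
#'   (see [true_monthly_budget()]).
#' @export
simulate_dive_series <- function(config, truth, bathy, seal = 1L,
                                 schedule = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"),
            inherits(bathy, "grid_raster"))
  if (is.null(schedule)) {
    schedule <- config$behavior_schedule
    if (!is.null(schedule)) {
      schedule <- schedule[schedule$seal_id == truth$seal_id, , drop = FALSE]
      if (!nrow(schedule)) schedule <- NULL
    }
  }
  if (is.null(schedule)) {
    schedule <- default_schedule(config, truth, bathy, seal)
  }
  schedule <- schedule[order(schedule$start), ]
  if (any(as.numeric(schedule$end[-nrow(schedule)]) >
            as.numeric(schedule$start[-1]) + 1e-6)) {
    stop("behaviour schedule intervals overlap")
  }

  set.seed(child_seed(config$seed, seal, 5L))
  a <- config$depth_dur[["a"]]; b <- config$depth_dur[["b"]]
  dsd <- config$depth_dur[["sd"]]
  dives <- vector("list", nrow(schedule))
  prev2 <- c(NA_real_, NA_real_)  # last two emitted depths within a segment
  for (r in seq_len(nrow(schedule))) {
    cls <- schedule$class[r]
    if (!cls %in% c("repetitive", "mixed")) {
      prev2 <- c(NA_real_, NA_real_)  # resting/haul-out gap breaks the lookback
      next
    }
    t0 <- schedule$start[r]; t1 <- schedule$end[r]
    pos <- truth_position_at(truth, t0)
    bloc <- raster_lookup(bathy, pos$lon, pos$lat)
    if (is.na(bloc)) {
      stop(sprintf("bathymetry missing under track at %s",
                   format(t0, "%Y-%m-%d")))
    }
    starts <- ends <- depths <- numeric(0)
    tcur <- as.numeric(t0)
    tend <- as.numeric(t1)
    while (tcur < tend - 60) {
      pos_i <- truth_position_at(truth, as.POSIXct(tcur, origin = "1970-01-01",
                                                   tz = "UTC"))
      b_i <- raster_lookup(bathy, pos_i$lon, pos_i$lat)
      if (is.na(b_i)) b_i <- bloc
      cap <- 0.95 * b_i
      if (cls == "repetitive") {
        d <- schedule$target_depth_m[r] *
          (1 + stats::runif(1, -config$rep_jitter, config$rep_jitter))
      } else {
        # mixed diving: scattered depths; the generator contract is >15%
        # scatter, so redraw until the depth is inconsistent (beyond 15%)
        # with both of the two preceding dives of the segment
        hi <- max(min(0.9 * b_i, 300), 4)
        lo <- min(5, hi / 2)
        for (try in 1:25) {
          d <- exp(stats::runif(1, log(lo), log(hi)))
          refs <- prev2[!is.na(prev2)]
          if (!length(refs) || all(abs(d - refs) / refs > 0.17)) break
        }
      }
      d <- min(d, cap)
      d <- max(round(d * 2) / 2, max(config$detect_floor_m, 0.5))
      prev2 <- c(prev2[2], d)
      dur_min <- min(max(a + b * log(d) + stats::rnorm(1, 0, dsd), 0.5), 14.9)
      surf_min <- min(stats::rlnorm(1, config$surface_meanlog,
                                    config$surface_sdlog), 9)
      if (tcur + dur_min * 60 > tend) {
        if (tend - tcur >= 60) {
          starts <- c(starts, tcur); ends <- c(ends, tend); depths <- c(depths, d)
        }
        break
      }
      starts <- c(starts, tcur)
      ends <- c(ends, tcur + dur_min * 60)
      depths <- c(depths, d)
      tcur <- tcur + (dur_min + surf_min) * 60
    }
    if (length(starts)) {
      # tags stamp dives at whole seconds
      dives[[r]] <- data.frame(
        seal_id = truth$seal_id,
        start = as.POSIXct(round(starts), origin = "1970-01-01", tz = "UTC"),
        end = as.POSIXct(pmax(round(ends), round(starts) + 30),
                         origin = "1970-01-01", tz = "UTC"),
        max_depth_m = depths)
    }
  }
  dives <- do.call(rbind, dives[!vapply(dives, is.null, logical(1))])
  if (is.null(dives)) {
    dives <- data.frame(seal_id = character(), start = as.POSIXct(character()),
                        end = as.POSIXct(character()), max_depth_m = numeric())
  }
  rownames(dives) <- NULL

  # hourly percent-dry: dry mode inside haul-out blocks, wet mode elsewhere
  set.seed(child_seed(config$seed, seal, 6L))
  h0 <- as.numeric(config$start_date) %/% 3600
  h1 <- (as.numeric(config$end_date) - 1) %/% 3600
  hours <- as.POSIXct((h0:h1) * 3600, origin = "1970-01-01", tz = "UTC")
  ho <- schedule[schedule$class == "haulout", , drop = FALSE]
  in_ho <- rep(FALSE, length(hours))
  for (r in seq_len(nrow(ho))) {
    in_ho <- in_ho | (hours >= ho$start[r] & (hours + 3600) <= ho$end[r] + 1)
  }
  pd <- numeric(length(hours))
  ndry <- sum(in_ho)
  pd[in_ho] <- 80 + 20 * stats::rbeta(ndry, config$dry_modes$dry[1],
                                      config$dry_modes$dry[2])
  pd[!in_ho] <- 25 * stats::rbeta(length(hours) - ndry,
                                  config$dry_modes$wet[1],
                                  config$dry_modes$wet[2])
  drytimes <- data.frame(seal_id = truth$seal_id,
                         date = as.Date(format(hours, "%Y-%m-%d")),
                         hour = as.integer(format(hours, "%H")),
                         percent_dry = round(pd, 1))

  truth$schedule <- schedule
  truth$true_budget <- true_monthly_budget(schedule, config$start_date,
                                           config$end_date)
  list(dives = dives, drytimes = drytimes, truth = truth)
}

#' Planted monthly activity budget of a behaviour schedule
#'
#' Clips the schedule's intervals to each calendar month within the span and
#' sums hours by class.  Because the schedule tiles the span, the four
#' components sum exactly to the covered hours of each month.
#'
#' @param schedule Schedule `data.frame` (see [default_schedule()]).
#' @param span_start,span_end `POSIXct` bounds of the simulated span.
#' @return `data.frame` with `seal_id`, `month` (`YYYY-MM`), `haulout_h`,
#'   `repetitive_h`, `mixed_h`, `rest_h`, `total_h`.
#' @export
true_monthly_budget <- function(schedule, span_start, span_end) {
  months <- unique(format(
    seq(as.Date(span_start), as.Date(span_end - 1), by = "day"), "%Y-%m"))
  out <- lapply(months, function(m) {
    mb <- month_bounds(m)
    lo <- max(mb$start, span_start)
    hi <- min(mb$end, span_end)
    ov_h <- pmax(0, as.numeric(pmin(schedule$end, hi)) -
                   as.numeric(pmax(schedule$start, lo))) / 3600
    h <- tapply(ov_h, schedule$class, sum)
    g <- function(k) if (k %in% names(h)) unname(h[k]) else 0
    data.frame(seal_id = schedule$seal_id[1], month = m,
               haulout_h = g("haulout"), repetitive_h = g("repetitive"),
               mixed_h = g("mixed"), rest_h = g("resting"),
               total_h = as.numeric(hi - lo, units = "hours"))
  })
  do.call(rbind, out)
}

# First instant of a "YYYY-MM" month and of the next month (UTC).
#' @keywords internal
month_bounds <- function(month) {
  start <- as.POSIXct(paste0(month, "-01 00:00:00"), tz = "UTC")
  nxt <- seq(start, by = "month", length.out = 2)[2]
  list(start = start, end = nxt)
}

#' Thin a dive record to partial sensor coverage
#'
#' Keeps only dives whose start falls in a seeded random subset of fixed-width
#' windows, emulating intermittent satellite retrieval of the dive time
#' series.
#'
#' @param dives Dive `data.frame`.
#' @param frac Target fraction of windows retained.
#' @param window_hr Window width in hours.
#' @param seed Integer seed.
#' @return Thinned dive `data.frame`.
#' @export
thin_dive_coverage <- function(dives, frac, window_hr = 12, seed = 1L) {
  if (!nrow(dives)) return(dives)
  set.seed(as.integer(seed))
  out <- lapply(split(dives, dives$seal_id), function(d) {
    w <- floor(as.numeric(d$start) / (window_hr * 3600))
    uw <- unique(w)
    keep <- sample(uw, max(1L, round(length(uw) * frac)))
    d[w %in% keep, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Thin hourly wet/dry rows to partial coverage
#'
#' @param drytimes Hourly percent-dry `data.frame`.
#' @param frac Fraction of hours retained (uniformly at random per seal).
#' @param seed Integer seed.
#' @return Thinned `data.frame`.
#' @export
thin_drytimes <- function(drytimes, frac, seed = 1L) {
  if (!nrow(drytimes)) return(drytimes)
  set.seed(as.integer(seed))
  out <- lapply(split(drytimes, drytimes$seal_id), function(d) {
    d[sort(sample(nrow(d), max(1L, round(nrow(d) * frac)))), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete multi-seal study
#'
#' Convenience wrapper: rasters, then per seal a track, fixes, dive series and
#' wet/dry series, all deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `config`, `bathy`, `ice`, `fixes`, `dives`, `drytimes`
#'   (combined data frames) and `truth` (list of per-seal `sim_truth`).
#' @export
simulate_study <- function(config) {
  ras <- simulate_rasters(config)
  fixes <- dives <- drytimes <- list()
  truth <- list()
  for (s in seq_len(config$n_seals)) {
    tr <- simulate_track(config, s, domain = ras$bathy)
    dv <- simulate_dive_series(config, tr$truth, ras$bathy, seal = s)
    fixes[[s]] <- tr$fixes
    dives[[s]] <- dv$dives
    drytimes[[s]] <- dv$drytimes
    truth[[dv$truth$seal_id]] <- dv$truth
  }
  list(config = config, bathy = ras$bathy, ice = ras$ice,
       fixes = do.call(rbind, fixes), dives = do.call(rbind, dives),
       drytimes = do.call(rbind, drytimes), truth = truth)
}
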