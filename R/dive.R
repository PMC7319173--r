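# Dive-behaviour analysis: haul-out hour classification, surface intervals,
# segmentation of the dive record into resting / repetitive / mixed episodes,
# benthic dive calls, diel-by-month profiles, 6-hr dive histograms, and the
# depth-duration regression.

#' Classify haul-out hours from hourly percent-dry values
#'
#' An hour is a haul-out hour when the tag was dry for at least `threshold`
#' percent of it.  Haul-out bouts are maximal runs of consecutive flagged
#' hours; a missing hour always breaks a bout (no bridging).
#'
#' @param drytimes `data.frame` with `seal_id`, `date`, `hour` (0-23 UTC),
#'   `percent_dry`.
#' @param threshold Percent-dry cutoff (>= comparison).
#' @return A list: `hours` (input plus logical `haulout`) and `bouts`
#'   (`seal_id`, `start`, `end`, `duration_hr` in whole hours).
#' @export
classify_haulout_hours <- function(drytimes, threshold = 80) {
  stopifnot(all(c("seal_id", "date", "hour", "percent_dry") %in% names(drytimes)))
  if (any(drytimes$percent_dry < 0 | drytimes$percent_dry > 100))
    stop("percent_dry outside [0, 100]")
  hours <- drytimes
  hours$haulout <- hours$percent_dry >= threshold
  bouts <- lapply(split(hours, hours$seal_id), function(h) {
    ht <- as.POSIXct(h$date, tz = "UTC") + h$hour * 3600
    o <- order(ht)
    h <- h[o, ]; ht <- ht[o]
    flg <- h$haulout
    if (!any(flg)) return(NULL)
    new_bout <- c(TRUE, diff(as.numeric(ht)) != 3600 | !flg[-length(flg)])
    bid <- cumsum(new_bout)
    idx <- which(flg)
    do.call(rbind, lapply(split(idx, bid[idx]), function(ii) {
      data.frame(seal_id = h$seal_id[1], start = ht[min(ii)],
                 end = ht[max(ii)] + 3600,
                 duration_hr = length(ii))
    }))
  })
  bouts <- do.call(rbind, bouts[!vapply(bouts, is.null, logical(1))])
  if (is.null(bouts)) {
    bouts <- data.frame(seal_id = character(), start = as.POSIXct(character()),
                        end = as.POSIXct(character()), duration_hr = integer())
  }
  rownames(bouts) <- NULL
  list(hours = hours, bouts = bouts)
}

#' Surface intervals between consecutive dives
#'
#' One interval per consecutive dive pair (so `n` dives give `n - 1`
#' intervals), with its duration in minutes and a flag marking overlap with
#' any classified haul-out hour.
#'
#' @param dives Dive `data.frame` (`seal_id`, `start`, `end`, `max_depth_m`),
#'   non-overlapping within seal.
#' @param haulout_hours Optional `hours` frame from
#'   [classify_haulout_hours()].
#' @return `data.frame` with `seal_id`, `start`, `end`, `duration_min`,
#'   `overlaps_haulout`.
#' @export
derive_surface_intervals <- function(dives, haulout_hours = NULL) {
  out <- lapply(split(dives, dives$seal_id), function(d) {
    d <- d[order(d$start), ]
    n <- nrow(d)
    if (n < 2) return(NULL)
    if (any(as.numeric(d$start[-1]) < as.numeric(d$end[-n]) - 1e-6))
      stop("overlapping dives for seal ", d$seal_id[1])
    s <- d$end[-n]; e <- d$start[-1]
    ov <- rep(FALSE, n - 1)
    if (!is.null(haulout_hours)) {
      hh <- haulout_hours[haulout_hours$seal_id == d$seal_id[1] &
                            haulout_hours$haulout, , drop = FALSE]
      if (nrow(hh)) {
        hs <- sort(as.numeric(as.POSIXct(hh$date, tz = "UTC") + hh$hour * 3600))
        lo <- findInterval(as.numeric(s) - 3600, hs)
        hi <- findInterval(as.numeric(e) - 1e-6, hs)
        ov <- hi > lo
      }
    }
    data.frame(seal_id = d$seal_id[1], start = s, end = e,
               duration_min = as.numeric(e - s, units = "mins"),
               overlaps_haulout = ov)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(seal_id = character(), start = as.POSIXct(character()),
                      end = as.POSIXct(character()), duration_min = numeric(),
                      overlaps_haulout = logical())
  }
  rownames(res) <- NULL
  res
}

# Core segmentation of one depth sequence (one gap-free segment).
# Returns an integer label per dive: k > 0 = member of candidate run k,
# and a parallel logical "regular" flag (FALSE = tolerated deviant).
# Semantics: a dive is consistent when its depth is within `tol` of the depth
# of either of the two immediately preceding dives of the current run
# (relative to that preceding depth, which must be at least `min_ref`).  A
# single inconsistent dive is tolerated inside a run; a second consecutive
# inconsistent dive closes the run, and the pending deviant restarts a new
# one.  A deviant left dangling at the end of a run is pushed out of it.
#' @keywords internal
segment_depths <- function(depths, tol = 0.15, min_ref = 2) {
  n <- length(depths)
  run_of <- integer(n)
  regular <- logical(n)
  if (!n) return(list(run = run_of, regular = regular))
  consistent <- function(d, refs) {
    any(refs >= min_ref & abs(d - refs) / refs <= tol)
  }
  run_id <- 1L
  members <- 1L
  regular[1] <- TRUE
  run_of[1] <- run_id
  pending <- NA_integer_
  k <- 2L
  while (k <= n) {
    m <- length(members)
    refs <- depths[members[max(1, m - 1):m]]
    if (consistent(depths[k], refs)) {
      members <- c(members, k)
      regular[k] <- TRUE
      run_of[k] <- run_id
      pending <- NA_integer_
    } else if (is.na(pending)) {
      pending <- k
      members <- c(members, k)
      regular[k] <- FALSE
      run_of[k] <- run_id
    } else {
      # two consecutive inconsistent dives: close the run before the pending
      # deviant and restart from it
      members <- members[members != pending]
      run_id <- run_id + 1L
      run_of[pending] <- run_id
      regular[pending] <- TRUE
      members <- pending
      pending <- NA_integer_
      next_k <- k  # re-examine current dive against the new run
      k <- next_k - 1L
    }
    k <- k + 1L
  }
  if (!is.na(pending)) {
    run_id <- run_id + 1L
    run_of[pending] <- run_id
    regular[pending] <- TRUE
  }
  list(run = run_of, regular = regular)
}

#' Segment a dive record into resting, repetitive and mixed episodes
#'
#' The dive sequence of each seal is first split at resting boundaries
#' (surface intervals longer than `rest_gap_min` minutes, each of which
#' becomes a resting episode).  Within a gap-free segment, a dive is
#' *consistent* when its maximum depth is within `rep_tol` (relative) of the
#' depth of either of the two immediately preceding dives; maximal runs with
#' at least `rep_min_dives` consistent dives form *repetitive* episodes, in
#' which a single interposed inconsistent dive is tolerated, while two
#' consecutive inconsistent dives terminate the episode.  All remaining dives
#' are *mixed*, grouped into maximal contiguous mixed episodes.
#'
#' @param dives Dive `data.frame` (`seal_id`, `start`, `end`, `max_depth_m`).
#' @param rest_gap_min Resting boundary, minutes.
#' @param rep_min_dives Minimum consistent dives for a repetitive episode.
#' @param rep_tol Relative depth tolerance.
#' @param min_ref_depth Minimum reference depth (m) allowed as the denominator
#'   of the relative comparison.
#' @return A list: `dives` (input plus `episode_id` and `class`) and
#'   `episodes` (`seal_id`, `episode_id`, `class`, `start`, `end`, `n_dives`,
#'   `median_depth`; resting episodes have `n_dives = 0`).  Every dive
#'   belongs to exactly one episode.
#' @export
segment_behavior <- function(dives, rest_gap_min = 10, rep_min_dives = 5,
                             rep_tol = 0.15, min_ref_depth = 2) {
  empty <- list(
    dives = cbind(dives[0, , drop = FALSE],
                  data.frame(episode_id = integer(), class = character())),
    episodes = data.frame(seal_id = character(), episode_id = integer(),
                          class = character(), start = as.POSIXct(character()),
                          end = as.POSIXct(character()), n_dives = integer(),
                          median_depth = numeric()))
  if (!nrow(dives)) return(empty)
  out_d <- list(); out_e <- list()
  for (d in split(dives, dives$seal_id)) {
    d <- d[order(d$start), ]
    n <- nrow(d)
    gap_min <- if (n > 1) {
      as.numeric(d$start[-1], units = "secs") / 60 -
        as.numeric(d$end[-n], units = "secs") / 60
    } else numeric(0)
    seg_id <- cumsum(c(1L, as.integer(gap_min > rest_gap_min)))
    d$class <- NA_character_
    d$episode_id <- NA_integer_
    eid <- 0L
    episodes <- list()
    for (seg in split(seq_len(n), seg_id)) {
      lab <- segment_depths(d$max_depth_m[seg], tol = rep_tol,
                            min_ref = min_ref_depth)
      n_reg <- tapply(lab$regular, lab$run, sum)
      rep_runs <- as.integer(names(n_reg)[n_reg >= rep_min_dives])
      is_rep <- lab$run %in% rep_runs
      d$class[seg] <- ifelse(is_rep, "repetitive", "mixed")
      # episodes: repetitive runs and maximal stretches of mixed dives
      blk <- cumsum(c(TRUE, (is_rep[-1] != is_rep[-length(is_rep)]) |
                        (is_rep[-1] & lab$run[-1] != lab$run[-length(is_rep)])))
      for (bb in split(seq_along(seg), blk)) {
        eid <- eid + 1L
        ii <- seg[bb]
        d$episode_id[ii] <- eid
        episodes[[length(episodes) + 1L]] <- data.frame(
          seal_id = d$seal_id[1], episode_id = eid,
          class = d$class[ii[1]], start = d$start[ii[1]],
          end = d$end[ii[length(ii)]], n_dives = length(ii),
          median_depth = stats::median(d$max_depth_m[ii]))
      }
      # resting episode at the boundary following this segment
      last <- seg[length(seg)]
      if (last < n && gap_min[last] > rest_gap_min) {
        eid <- eid + 1L
        episodes[[length(episodes) + 1L]] <- data.frame(
          seal_id = d$seal_id[1], episode_id = eid, class = "resting",
          start = d$end[last], end = d$start[last + 1], n_dives = 0L,
          median_depth = NA_real_)
      }
    }
    out_d[[length(out_d) + 1L]] <- d
    out_e[[length(out_e) + 1L]] <- do.call(rbind, episodes)
  }
  dd <- do.call(rbind, out_d)
  ee <- do.call(rbind, out_e)
  rownames(dd) <- rownames(ee) <- NULL
  list(dives = dd, episodes = ee)
}

#' Benthic dive classification
#'
#' A dive is a bottom dive when its maximum depth reaches at least
#' `bottom_frac` of the mapped ocean depth at its location (ratios above 1,
#' which arise from location or bathymetry error, still count as bottom).
#' Dives in water shallower than `min_ocean_depth` are left indeterminate
#' because location and bathymetry error dominate there.
#'
#' @param max_depth Dive maximum depth(s), m.
#' @param ocean_depth Mapped ocean depth(s) at the dive location, m.
#' @param bottom_frac Depth ratio threshold.
#' @param min_ocean_depth Minimum classifiable ocean depth, m.
#' @return Character vector over `"bottom"`, `"pelagic"`, `"indeterminate"`.
#' @export
classify_bottom_dive <- function(max_depth, ocean_depth, bottom_frac = 0.75,
                                 min_ocean_depth = 10) {
  ifelse(is.na(ocean_depth) | ocean_depth < min_ocean_depth, "indeterminate",
         ifelse(max_depth / ocean_depth >= bottom_frac, "bottom", "pelagic"))
}

#' Diel-by-month activity profiles
#'
#' Builds hour-of-day frequency profiles per month, in local time
#' (`local_offset` hours from UTC), for four dive-behaviour classes —
#' repetitive diving deeper than `depth_split` m, repetitive diving at or
#' above it, mixed diving, and surface resting — and, when hourly haul-out
#' flags are given, the mean (with standard error) proportion of seals
#' hauled out in each local hour.  Dive-class rows are normalised to sum to
#' one over the 24 hours of each month; events are individual dives for dive
#' classes and whole episodes for resting.
#'
#' @param seg Output of [segment_behavior()].
#' @param haulout_hours Optional `hours` frame from
#'   [classify_haulout_hours()].
#' @param local_offset Hours added to UTC to get local time (default -10).
#' @param depth_split Episode median depth (m) splitting repetitive profiles.
#' @return A list: `dive` (named list of four month-by-24 matrices:
#'   `repetitive_deep`, `repetitive_shallow`, `mixed`, `resting`) and, when
#'   available, `haulout_mean` / `haulout_se` matrices.
#' @export
diel_monthly_profiles <- function(seg, haulout_hours = NULL,
                                  local_offset = -10, depth_split = 25) {
  med <- stats::setNames(seg$episodes$median_depth, seg$episodes$episode_id)
  # per-seal episode ids are reused across seals; build a composite key
  key <- function(sid, eid) paste(sid, eid, sep = "#")
  med <- stats::setNames(seg$episodes$median_depth,
                         key(seg$episodes$seal_id, seg$episodes$episode_id))
  dv <- seg$dives
  ep_med <- med[key(dv$seal_id, dv$episode_id)]
  rest_start <- seg$episodes$start[seg$episodes$class == "resting"]
  events <- rbind(
    data.frame(time = dv$start,
               class = ifelse(dv$class == "mixed", "mixed",
                              ifelse(ep_med > depth_split, "repetitive_deep",
                                     "repetitive_shallow"))),
    data.frame(time = rest_start,
               class = rep("resting", length(rest_start))))
  local <- events$time + local_offset * 3600
  month <- format(local, "%Y-%m")
  hr <- as.integer(format(local, "%H"))
  months <- sort(unique(month))
  classes <- c("repetitive_deep", "repetitive_shallow", "mixed", "resting")
  dive_mats <- lapply(classes, function(cl) {
    m <- matrix(0, length(months), 24,
                dimnames = list(months, sprintf("%02d", 0:23)))
    sel <- events$class == cl
    if (any(sel)) {
      tab <- table(factor(month[sel], months), factor(hr[sel], 0:23))
      m[] <- as.numeric(tab)
      tot <- rowSums(m)
      m[tot > 0, ] <- m[tot > 0, , drop = FALSE] / tot[tot > 0]
      m[tot == 0, ] <- NA_real_
    } else {
      m[] <- NA_real_
    }
    m
  })
  names(dive_mats) <- classes
  out <- list(dive = dive_mats)
  if (!is.null(haulout_hours)) {
    ht <- as.POSIXct(haulout_hours$date, tz = "UTC") +
      haulout_hours$hour * 3600 + local_offset * 3600
    hmon <- format(ht, "%Y-%m")
    hhr <- as.integer(format(ht, "%H"))
    hmonths <- sort(unique(hmon))
    per_seal <- lapply(split(seq_len(nrow(haulout_hours)), haulout_hours$seal_id),
                       function(idx) {
      agg <- tapply(haulout_hours$haulout[idx],
                    list(factor(hmon[idx], hmonths), factor(hhr[idx], 0:23)),
                    mean)
      agg
    })
    arr <- simplify2array(per_seal)  # month x hour x seal
    out$haulout_mean <- apply(arr, c(1, 2), mean, na.rm = TRUE)
    nseal <- apply(!is.na(arr), c(1, 2), sum)
    out$haulout_se <- apply(arr, c(1, 2), stats::sd, na.rm = TRUE) /
      sqrt(pmax(nseal, 1))
    dimnames(out$haulout_mean) <- dimnames(out$haulout_se) <-
      list(hmonths, sprintf("%02d", 0:23))
  }
  out
}

#' Dive counts by depth bin and 6-hr local period
#'
#' Tabulates dives into depth bins (left-closed, right-open `[lo, hi)`
#' intervals defined by `depth_bins`) crossed with four 6-hr local-time
#' periods anchored at `period_anchor` o'clock local.  Dives shallower than
#' `floor_m` are excluded; remaining dives land in exactly one cell.
#'
#' @param dives Dive `data.frame`.
#' @param depth_bins Ascending bin edges in metres (use `Inf` as the last
#'   edge to catch all depths).
#' @param local_offset Hours added to UTC for local time.
#' @param period_anchor Local hour starting the first 6-hr period.
#' @param floor_m Histogram detection floor, m.
#' @return Integer matrix, depth bins x 4 periods.
#' @export
bin_dive_histograms <- function(dives,
                                depth_bins = c(0, 10, 20, 50, 100, 150, 200,
                                               300, Inf),
                                local_offset = -10, period_anchor = 4,
                                floor_m = 3.5) {
  stopifnot(!is.unsorted(depth_bins, strictly = TRUE))
  d <- dives[dives$max_depth_m >= floor_m, , drop = FALSE]
  hr <- as.integer(format(d$start + local_offset * 3600, "%H"))
  period <- ((hr - period_anchor) %% 24) %/% 6
  pstart <- (period_anchor + period * 6) %% 24
  plab <- sprintf("%02d-%02d", pstart, (pstart + 6) %% 24)
  plevels <- sprintf("%02d-%02d", (period_anchor + 0:3 * 6) %% 24,
                     (period_anchor + 0:3 * 6 + 6) %% 24)
  bin <- findInterval(d$max_depth_m, depth_bins)
  keep <- bin >= 1 & bin < length(depth_bins)
  blab <- paste0("[", depth_bins[-length(depth_bins)], ",",
                 depth_bins[-1], ")")
  tab <- table(factor(blab[bin[keep]], blab), factor(plab[keep], plevels))
  m <- matrix(as.integer(tab), nrow = length(blab),
              dimnames = list(blab, plevels))
  m
}

#' Depth-duration regression on binned medians
#'
#' Bins dives no longer than `max_duration` minutes into `bin_width`-metre
#' depth intervals, keeps bins with at least `min_n` dives, and fits ordinary
#' least squares of the bin-median response on the natural log of the
#' bin-median depth — once for dive duration and once for the surface
#' interval that follows each dive.  `S` is the residual standard error of
#' the bin-level fit, in minutes.
#'
#' @param dives Dive `data.frame`.
#' @param bin_width Depth bin width, m.
#' @param min_n Minimum dives per bin.
#' @param max_duration Maximum dive duration retained, minutes.
#' @return A list with elements `duration` and `surface`, each
#'   `list(a, b, S, n_bins, bins)` for the model
#'   `response = a + b * log(depth)`.
#' @export
fit_depth_duration_curve <- function(dives, bin_width = 10, min_n = 10,
                                     max_duration = 15) {
  d <- do.call(rbind, lapply(split(dives, dives$seal_id), function(x) {
    x <- x[order(x$start), ]
    n <- nrow(x)
    x$surface_min <- c(if (n > 1)
      as.numeric(x$start[-1], units = "secs") / 60 -
        as.numeric(x$end[-n], units = "secs") / 60 else numeric(0), NA_real_)
    x
  }))
  d$duration_min <- as.numeric(d$end - d$start, units = "mins")
  d <- d[d$duration_min <= max_duration, , drop = FALSE]
  d$bin <- floor(d$max_depth_m / bin_width) * bin_width
  agg <- do.call(rbind, lapply(split(d, d$bin), function(b) {
    data.frame(bin = b$bin[1], n = nrow(b),
               med_depth = stats::median(b$max_depth_m),
               med_dur = stats::median(b$duration_min),
               med_surf = stats::median(b$surface_min, na.rm = TRUE))
  }))
  agg <- agg[agg$n >= min_n & agg$med_depth > 0, , drop = FALSE]
  if (nrow(agg) < 3) stop("fewer than 3 qualifying depth bins")
  fit1 <- function(y) {
    fm <- stats::lm(y ~ log(agg$med_depth))
    S <- sqrt(sum(stats::residuals(fm)^2) / max(nrow(agg) - 2, 1))
    list(a = unname(stats::coef(fm)[1]), b = unname(stats::coef(fm)[2]),
         S = S, n_bins = nrow(agg), bins = agg)
  }
  list(duration = fit1(agg$med_dur), surface = fit1(agg$med_surf))
}
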