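# Monthly activity budgets: extrapolate hours hauled out, diving (repetitive
# vs mixed) and surface-resting for each seal-month from the partially sampled
# wet/dry and dive-behaviour streams, with the study's inclusion filters.

#' Remove the first post-deployment week
#'
#' Capture and handling bias the first days of a record, so all behaviour
#' summaries drop the first seven days after each seal's first observation.
#'
#' @param x A fixes, dives or drytimes `data.frame`.
#' @param days Number of days to drop.
#' @param deploy_start Optional named vector of `POSIXct` deployment starts
#'   per seal; defaults to each seal's first record.
#' @return The filtered `data.frame`.
#' @export
drop_first_week <- function(x, days = 7, deploy_start = NULL) {
  tcol <- intersect(c("timestamp", "start"), names(x))[1]
  tm <- if (!is.na(tcol)) x[[tcol]] else
    as.POSIXct(x$date, tz = "UTC") + x$hour * 3600
  keep <- rep(TRUE, nrow(x))
  for (sid in unique(x$seal_id)) {
    sel <- x$seal_id == sid
    t0 <- if (!is.null(deploy_start)) deploy_start[[sid]] else min(tm[sel])
    keep[sel] <- tm[sel] >= t0 + days * 86400
  }
  x[keep, , drop = FALSE]
}

# merge dive intervals, bridging gaps <= gap_max_hr, and clip to [lo, hi];
# returns total covered hours
#' @keywords internal
covered_hours <- function(starts, ends, lo, hi, gap_max_hr = 2) {
  if (!length(starts)) return(0)
  o <- order(starts)
  s <- as.numeric(starts)[o]; e <- as.numeric(ends)[o]
  bs <- s[1]; be <- e[1]; tot <- 0
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  clip <- function(a, b) max(0, min(b, hi) - max(a, lo))
  for (k in seq_along(s)[-1]) {
    if (s[k] - be <= gap_max_hr * 3600) {
      be <- max(be, e[k])
    } else {
      tot <- tot + clip(bs, be)
      bs <- s[k]; be <- e[k]
    }
  }
  (tot + clip(bs, be)) / 3600
}

#' Sampled fraction of a month's sensor streams
#'
#' `frac_dive` is the fraction of the month (clipped to the deployment span)
#' covered by the dive-behaviour time series, counting dive and surface time
#' and bridging gaps up to `gap_max_hr` hours; `frac_dry` is the fraction of
#' the month's hours with a wet/dry value.
#'
#' @param dives One seal's dive `data.frame`.
#' @param drytimes One seal's hourly wet/dry `data.frame`.
#' @param month Month as `"YYYY-MM"`.
#' @param span Optional `c(start, end)` `POSIXct` deployment span to pro-rate
#'   partial months.
#' @param gap_max_hr Largest inter-dive gap still counted as covered, hours.
#' @return `list(frac_dive, frac_dry, month_hours)`.
#' @export
monthly_sample_fraction <- function(dives, drytimes, month, span = NULL,
                                    gap_max_hr = 2) {
  mb <- month_bounds(month)
  lo <- mb$start; hi <- mb$end
  if (!is.null(span)) {
    lo <- max(lo, span[1]); hi <- min(hi, span[2])
  }
  month_hours <- max(as.numeric(hi - lo, units = "hours"), 0)
  if (month_hours == 0) {
    return(list(frac_dive = 0, frac_dry = 0, month_hours = 0))
  }
  dsel <- dives$end > lo & dives$start < hi
  fdive <- covered_hours(dives$start[dsel], dives$end[dsel], lo, hi,
                         gap_max_hr) / month_hours
  ht <- as.POSIXct(drytimes$date, tz = "UTC") + drytimes$hour * 3600
  fdry <- sum(ht >= lo & ht < hi) / month_hours
  list(frac_dive = min(fdive, 1), frac_dry = min(fdry, 1),
       month_hours = month_hours)
}

#' Extrapolate one seal-month activity budget
#'
#' The ratio of observed haul-out hours to observed wet/dry hours scales to
#' the month's total hours hauled out.  The remaining (wet) hours are split
#' between diving and resting by the ratio of time in diving episodes
#' (repetitive plus mixed, including their internal surface intervals) to
#' time in resting episodes, where resting episodes overlapping a haul-out
#' hour are discarded (that time is already counted as hauled out).  Diving
#' hours are further split by the repetitive:mixed episode-time ratio.
#'
#' A seal-month is excluded (with a reason, no budget row values) when it has
#' no wet/dry data (`no_dry_data`), when the dive series samples less than
#' `min_sample` of the month (`low_dive_sample`), when the mean distance to
#' the mainland is below `coast_excl_km` (`near_coast`, shallow water defeats
#' the tag's dive-detection threshold), or when no behaviour episodes fall in
#' the month (`no_behavior_data`).
#'
#' @param month Month `"YYYY-MM"`.
#' @param drytimes One seal's wet/dry rows; a logical `haulout` column is
#'   used if present, else the 80% rule is applied.
#' @param seg [segment_behavior()] output for the same seal.
#' @param dives One seal's dive rows (for the coverage fraction); defaults to
#'   `seg$dives`.
#' @param dist_mainland Optional numeric vector of daily mainland distances
#'   (km) in the month.
#' @param span Optional deployment span, as in [monthly_sample_fraction()].
#' @param min_sample Minimum dive-series sample fraction.
#' @param coast_excl_km Mainland-distance exclusion, km.
#' @param dry_threshold Percent-dry haul-out threshold.
#' @param gap_max_hr Coverage gap bridging, hours.
#' @return One-row `data.frame` (`MonthlyBudget`): `seal_id`, `month`,
#'   `sample_frac_dive`, `haulout_h`, `dive_h`, `repetitive_h`, `mixed_h`,
#'   `rest_h`, `diving_h_per_day`, `repetitive_pct`, `exclusion_reason`
#'   (`NA` when included; budget columns `NA` when excluded).
#' @export
extrapolate_monthly_budget <- function(month, drytimes, seg, dives = NULL,
                                       dist_mainland = NULL, span = NULL,
                                       min_sample = 0.10, coast_excl_km = 5,
                                       dry_threshold = 80, gap_max_hr = 2) {
  if (is.null(dives)) dives <- seg$dives
  seal_id <- c(drytimes$seal_id, dives$seal_id)[1]
  sf <- monthly_sample_fraction(dives, drytimes, month, span, gap_max_hr)
  row <- data.frame(seal_id = seal_id, month = month,
                    sample_frac_dive = sf$frac_dive,
                    haulout_h = NA_real_, dive_h = NA_real_,
                    repetitive_h = NA_real_, mixed_h = NA_real_,
                    rest_h = NA_real_, diving_h_per_day = NA_real_,
                    repetitive_pct = NA_real_,
                    exclusion_reason = NA_character_)
  exclude <- function(reason) { row$exclusion_reason <- reason; row }

  mb <- month_bounds(month)
  lo <- mb$start; hi <- mb$end
  if (!is.null(span)) { lo <- max(lo, span[1]); hi <- min(hi, span[2]) }
  month_hours <- sf$month_hours
  if (month_hours <= 0) return(exclude("outside_deployment"))

  if (is.null(drytimes$haulout)) {
    drytimes$haulout <- drytimes$percent_dry >= dry_threshold
  }
  ht <- as.POSIXct(drytimes$date, tz = "UTC") + drytimes$hour * 3600
  in_m <- ht >= lo & ht < hi
  O <- sum(in_m)
  if (O == 0) return(exclude("no_dry_data"))
  if (sf$frac_dive < min_sample) return(exclude("low_dive_sample"))
  if (!is.null(dist_mainland) && length(dist_mainland) &&
      mean(dist_mainland, na.rm = TRUE) < coast_excl_km) {
    return(exclude("near_coast"))
  }

  H <- sum(drytimes$haulout[in_m])
  haulout_h <- H / O * month_hours

  ep <- seg$episodes[seg$episodes$seal_id == seal_id, , drop = FALSE]
  ov_h <- pmax(0, as.numeric(pmin(ep$end, hi)) -
                 as.numeric(pmax(ep$start, lo))) / 3600
  # resting episodes overlapping a haul-out hour are discarded (already
  # counted as hauled out), and apparent surface intervals longer than the
  # coverage gap limit are treated as unobserved record gaps, not resting
  flagged <- sort(as.numeric(ht[drytimes$haulout]))
  rest_ok <- as.numeric(ep$end - ep$start, units = "hours") <= gap_max_hr
  if (length(flagged)) {
    s <- as.numeric(ep$start); e <- as.numeric(ep$end)
    n_in <- findInterval(e - 1e-6, flagged) - findInterval(s - 3600, flagged)
    rest_ok <- rest_ok & n_in == 0
  }
  rep_h <- sum(ov_h[ep$class == "repetitive"])
  mix_h <- sum(ov_h[ep$class == "mixed"])
  rst_h <- sum(ov_h[ep$class == "resting" & rest_ok])
  D <- rep_h + mix_h
  if (D + rst_h <= 0) return(exclude("no_behavior_data"))

  remaining <- month_hours - haulout_h
  dive_h <- remaining * D / (D + rst_h)
  rest_h <- remaining - dive_h
  repetitive_h <- if (D > 0) dive_h * rep_h / D else 0
  row$haulout_h <- haulout_h
  row$dive_h <- dive_h
  row$repetitive_h <- repetitive_h
  row$mixed_h <- dive_h - repetitive_h
  row$rest_h <- rest_h
  row$diving_h_per_day <- dive_h / (month_hours / 24)
  row$repetitive_pct <- if (dive_h > 0) 100 * repetitive_h / dive_h else NA_real_
  row
}

#' Monthly budgets for every seal-month
#'
#' Applies [extrapolate_monthly_budget()] to every seal and month spanned by
#' the wet/dry record, taking deployment spans from the data and mean
#' mainland distances from a habitat table when given.
#'
#' @param drytimes Wet/dry rows for all seals (a `haulout` column is used if
#'   present).
#' @param seg [segment_behavior()] output for all seals.
#' @param dives Dive rows for all seals (defaults to `seg$dives`).
#' @param habitat Optional [annotate_habitat()] output (for `near_coast`
#'   exclusions).
#' @param ... Passed to [extrapolate_monthly_budget()].
#' @return `data.frame` of seal-month budget rows.
#' @export
monthly_budgets <- function(drytimes, seg, dives = NULL, habitat = NULL, ...) {
  if (is.null(dives)) dives <- seg$dives
  out <- list()
  for (sid in sort(unique(drytimes$seal_id))) {
    dt <- drytimes[drytimes$seal_id == sid, , drop = FALSE]
    dv <- dives[dives$seal_id == sid, , drop = FALSE]
    sg <- list(dives = seg$dives[seg$dives$seal_id == sid, , drop = FALSE],
               episodes = seg$episodes[seg$episodes$seal_id == sid, ,
                                       drop = FALSE])
    ht <- as.POSIXct(dt$date, tz = "UTC") + dt$hour * 3600
    span <- c(min(c(ht, dv$start)), max(c(ht + 3600, dv$end)))
    months <- unique(format(seq(as.Date(span[1]), as.Date(span[2] - 1),
                                by = "day"), "%Y-%m"))
    for (m in months) {
      dm <- NULL
      if (!is.null(habitat)) {
        hsel <- habitat$seal_id == sid & format(habitat$date, "%Y-%m") == m
        dm <- habitat$dist_mainland[hsel]
      }
      out[[length(out) + 1L]] <-
        extrapolate_monthly_budget(m, dt, sg, dives = dv,
                                   dist_mainland = dm, span = span, ...)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise monthly budgets across seals
#'
#' Per calendar month over included seal-months: mean and SD of diving hours
#' per day, of the repetitive share of diving, and of the dive-series sample
#' percentage, plus a pooled row over all seal-months.
#'
#' @param budgets Output of [monthly_budgets()] (or rows from
#'   [extrapolate_monthly_budget()]).
#' @return `data.frame` with `month`, `n`, `diving_h_mean`, `diving_h_sd`,
#'   `repetitive_pct_mean`, `repetitive_pct_sd`, `sample_pct_mean`,
#'   `sample_pct_sd`.
#' @export
budget_table <- function(budgets) {
  inc <- budgets[is.na(budgets$exclusion_reason), , drop = FALSE]
  if (!nrow(inc)) stop("no included seal-months")
  summ <- function(d, label) {
    data.frame(month = label, n = nrow(d),
               diving_h_mean = mean(d$diving_h_per_day),
               diving_h_sd = stats::sd(d$diving_h_per_day),
               repetitive_pct_mean = mean(d$repetitive_pct),
               repetitive_pct_sd = stats::sd(d$repetitive_pct),
               sample_pct_mean = mean(100 * d$sample_frac_dive),
               sample_pct_sd = stats::sd(100 * d$sample_frac_dive))
  }
  rows <- lapply(split(inc, inc$month), function(d) summ(d, d$month[1]))
  out <- rbind(do.call(rbind, rows), summ(inc, "pooled"))
  rownames(out) <- NULL
  out
}
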