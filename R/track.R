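# Track processing: plausibility filtering of raw Argos fixes, maximum
# likelihood fitting of the correlated random walk, 6-hourly smoothed position
# estimates with standard errors, and daily movement summaries.

QUALITY_ORDER <- c("3", "2", "1", "0", "A", "B", "Z")

#' Plausibility-filter raw Argos fixes
#'
#' Applies, in order: removal of class-Z fixes; timestamp de-duplication
#' (keeping the higher-quality class, ties keep the first); removal of fixes
#' on land; iterative removal of fixes implying speeds above `max_speed` to
#' both neighbours; and removal of out-and-back spike geometries (turning
#' angle at the fix below `spike_angle` degrees with both legs faster than
#' `spike_speed`).  Re-running the filter on its own output removes nothing
#' further.
#'
#' @param fixes Fix `data.frame` (`seal_id`, `timestamp`, `lon`, `lat`, `lc`),
#'   sorted or sortable by time within seal.
#' @param land Optional [grid_raster()] whose land mask defines "on land";
#'   `NULL` skips the land test.
#' @param max_speed Maximum plausible sustained speed, km/hr.
#' @param spike_angle Turning-angle threshold, degrees.
#' @param spike_speed Minimum leg speed for the spike test, km/hr.
#' @return A list: `retained` (filtered fixes) and `rejected` (removed fixes
#'   with a `reason` column: `class_Z`, `duplicate_time`, `on_land`, `speed`,
#'   `spike`).
#' @export
prefilter_fixes <- function(fixes, land = NULL, max_speed = 10,
                            spike_angle = 15, spike_speed = 5) {
  stopifnot(all(c("seal_id", "timestamp", "lon", "lat", "lc") %in% names(fixes)))
  if (any(abs(fixes$lat) > 90)) stop("latitude outside [-90, 90]")
  parts <- split(fixes, fixes$seal_id)
  res <- lapply(parts, prefilter_one, land = land, max_speed = max_speed,
                spike_angle = spike_angle, spike_speed = spike_speed)
  retained <- do.call(rbind, lapply(res, `[[`, "retained"))
  rejected <- do.call(rbind, lapply(res, `[[`, "rejected"))
  rownames(retained) <- rownames(rejected) <- NULL
  list(retained = retained, rejected = rejected)
}

#' @keywords internal
prefilter_one <- function(d, land, max_speed, spike_angle, spike_speed) {
  d <- d[order(d$timestamp), ]
  rej <- d[0, ]
  rej$reason <- character(0)
  drop_with <- function(d, idx, reason) {
    if (!length(idx)) return(list(d = d, r = NULL))
    r <- d[idx, ]
    r$reason <- reason
    list(d = d[-idx, ], r = r)
  }
  # class Z is never usable
  st <- drop_with(d, which(d$lc == "Z"), "class_Z")
  d <- st$d; rej <- rbind(rej, st$r)
  # duplicate timestamps: keep the best class, ties keep the first
  if (nrow(d) > 1) {
    q <- match(d$lc, QUALITY_ORDER)
    keep <- !logical(nrow(d))
    for (tt in unique(d$timestamp[duplicated(d$timestamp)])) {
      idx <- which(d$timestamp == tt)
      best <- idx[which.min(q[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
    st <- drop_with(d, which(!keep), "duplicate_time")
    d <- st$d; rej <- rbind(rej, st$r)
  }
  if (!is.null(land) && nrow(d)) {
    onland <- raster_is_land(land, d$lon, d$lat)
    st <- drop_with(d, which(onland %in% TRUE), "on_land")
    d <- st$d; rej <- rbind(rej, st$r)
  }
  if (nrow(d) < 2) {
    if (nrow(d) < 2) warning("fewer than 2 fixes for seal ",
                             d$seal_id[1] %||% "?", "; passed through")
    return(list(retained = d, rejected = rej))
  }
  repeat {
    removed <- FALSE
    # speed rule: interior fix faster than max_speed to both neighbours
    while (nrow(d) >= 3) {
      sp <- leg_speeds(d)
      bad <- which(sp$to_prev > max_speed & sp$to_next > max_speed)
      if (!length(bad)) break
      worst <- bad[which.max(sp$to_prev[bad] + sp$to_next[bad])]
      st <- drop_with(d, worst, "speed")
      d <- st$d; rej <- rbind(rej, st$r)
      removed <- TRUE
    }
    # spike rule: near-zero included angle with fast legs
    if (nrow(d) >= 3) {
      sp <- leg_speeds(d)
      ang <- turn_angles(d)
      bad <- which(ang < spike_angle & pmin(sp$to_prev, sp$to_next) > spike_speed)
      if (length(bad)) {
        st <- drop_with(d, bad[1], "spike")
        d <- st$d; rej <- rbind(rej, st$r)
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  list(retained = d, rejected = rej)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# speeds (km/hr) from each interior fix to its neighbours; NA at the ends
#' @keywords internal
leg_speeds <- function(d) {
  n <- nrow(d)
  dist <- gc_dist_km(d$lon[-n], d$lat[-n], d$lon[-1], d$lat[-1])
  dt <- pmax(as.numeric(diff(d$timestamp), units = "hours"), 1e-6)
  v <- dist / dt
  list(to_prev = c(NA, v), to_next = c(v, NA))
}

# included angle (deg, 0..180) at each interior fix between the bearings to
# its previous and next neighbours; 0 means a perfect out-and-back spike
#' @keywords internal
turn_angles <- function(d) {
  n <- nrow(d)
  ang <- rep(NA_real_, n)
  if (n < 3) return(ang)
  p <- cbind(d$lon, d$lat)
  b_prev <- geosphere::bearing(p[2:(n - 1), , drop = FALSE],
                               p[1:(n - 2), , drop = FALSE])
  b_next <- geosphere::bearing(p[2:(n - 1), , drop = FALSE],
                               p[3:n, , drop = FALSE])
  ang[2:(n - 1)] <- abs(((b_prev - b_next + 180) %% 360) - 180)
  ang
}

#' Fit the correlated random walk to a seal's fixes
#'
#' Maximises the Kalman-filter likelihood of the integrated
#' Ornstein-Uhlenbeck state-space model over `(beta, sigma)` (optionally also
#' a common multiplier on the per-class observation error SDs).  The two
#' planar axes are independent with shared parameters.
#'
#' @param fixes Fix `data.frame` for a single seal (columns `timestamp`,
#'   `lon`, `lat`, `lc`), already plausibility-filtered.
#' @param center Projection centre `c(lon, lat)`.
#' @param class_sd Named per-class observation error SD, km.
#' @param init List with starting values `beta` (1/hr) and `sigma`
#'   (km/hr^1.5).
#' @param fit_error_scale Also estimate a multiplier on `class_sd`?
#' @return An object of class `ctcrw_fit`: `beta`, `sigma`, `error_scale`,
#'   `loglik`, `convergence`, plus the projected data used.  Non-convergence
#'   raises an error whose condition carries the best parameters so far
#'   (`cond$fit`).
#' @export
fit_ctcrw <- function(fixes, center,
                      class_sd = c(`3` = 0.25, `2` = 0.5, `1` = 1.5, `0` = 4,
                                   A = 8, B = 15, Z = 80),
                      init = list(beta = 0.5, sigma = 1),
                      fit_error_scale = FALSE) {
  stopifnot(nrow(fixes) >= 10)
  fixes <- fixes[order(fixes$timestamp), ]
  if (any(duplicated(fixes$timestamp))) stop("duplicate timestamps; prefilter first")
  xy <- laea_project(fixes$lon, fixes$lat, center)
  t_hr <- as.numeric(difftime(fixes$timestamp, fixes$timestamp[1],
                              units = "hours"))
  ev <- unname(class_sd[fixes$lc])^2
  if (any(is.na(ev))) stop("unknown location class in fixes")
  Y <- cbind(xy$x, xy$y)
  par0 <- log(c(init$beta, init$sigma))
  if (fit_error_scale) par0 <- c(par0, 0)
  nll0 <- ctcrw_nll(par0, t_hr, Y, ev)
  opt <- stats::optim(par0, ctcrw_nll, t_hr = t_hr, Y = Y, err_var = ev,
                      method = "Nelder-Mead",
                      control = list(maxit = 800, reltol = 1e-8))
  fit <- structure(
    list(beta = exp(opt$par[1]), sigma = exp(opt$par[2]),
         error_scale = if (fit_error_scale) exp(opt$par[3]) else 1,
         loglik = -opt$value, loglik_init = -nll0,
         convergence = opt$convergence,
         center = center, class_sd = class_sd,
         t_hr = t_hr, Y = Y, err_var = ev, t0 = fixes$timestamp[1]),
    class = "ctcrw_fit")
  if (opt$convergence != 0) {
    cond <- simpleError(sprintf(
      "CTCRW optimisation did not converge (code %d); best beta=%.4g sigma=%.4g",
      opt$convergence, fit$beta, fit$sigma))
    cond$fit <- fit
    stop(cond)
  }
  fit
}

#' @export
print.ctcrw_fit <- function(x, ...) {
  cat(sprintf(
    "ctcrw_fit: beta %.4g /hr, sigma %.4g km/hr^1.5, logLik %.2f (n=%d fixes)\n",
    x$beta, x$sigma, x$loglik, nrow(x$Y)))
  invisible(x)
}

#' Smoothed positions on a regular grid
#'
#' Runs the Kalman smoother at the fitted parameters over the union of fix
#' times and a regular grid (default 6-hourly, aligned to 00/06/12/18 UTC)
#' and reports the smoothed position and its standard error at each grid
#' time.  Estimates with `se_km` above `se_max` are dropped; the count of
#' drops is attached as `attr(, "n_dropped")`.
#'
#' `se_km` is the root of the summed position variances of the two axes.
#'
#' @param fit A [fit_ctcrw()] result.
#' @param grid_step Grid spacing, hours.
#' @param se_max Standard-error cutoff, km (use `Inf` to keep everything).
#' @param seal_id Identifier copied into the output.
#' @return `data.frame` with `seal_id`, `timestamp`, `x_km`, `y_km`, `lon`,
#'   `lat`, `se_km`; empty (with a warning) if the grid has no points inside
#'   the data span.
#' @export
predict_track <- function(fit, grid_step = 6, se_max = 25, seal_id = "seal") {
  stopifnot(inherits(fit, "ctcrw_fit"))
  t0n <- as.numeric(fit$t0)
  span <- range(fit$t_hr)
  step_s <- grid_step * 3600
  g0 <- ceiling((t0n + span[1] * 3600) / step_s) * step_s
  g1 <- floor((t0n + span[2] * 3600) / step_s) * step_s
  if (g1 < g0) {
    warning("no grid times inside the data span")
    out <- data.frame(seal_id = character(), timestamp = as.POSIXct(character()),
                      x_km = numeric(), y_km = numeric(), lon = numeric(),
                      lat = numeric(), se_km = numeric())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  grid_hr <- (seq(g0, g1, by = step_s) - t0n) / 3600

  # merge grid times into the observation sequence as prediction-only rows
  is_near_obs <- vapply(grid_hr, function(g) any(abs(fit$t_hr - g) < 1e-7),
                        logical(1))
  all_t <- c(fit$t_hr, grid_hr[!is_near_obs])
  ord <- order(all_t)
  n_obs <- length(fit$t_hr)
  Y <- rbind(fit$Y, matrix(NA_real_, sum(!is_near_obs), 2))[ord, , drop = FALSE]
  ev <- c(fit$err_var * fit$error_scale^2, rep(NA_real_, sum(!is_near_obs)))[ord]
  t_sorted <- all_t[ord]

  kf <- ctcrw_kalman(t_sorted, Y, ev, fit$beta, fit$sigma, smooth = TRUE)
  at <- vapply(grid_hr, function(g) which.min(abs(t_sorted - g)), integer(1))
  x <- kf$m_smooth[at, 1, 1]
  y <- kf$m_smooth[at, 1, 2]
  pvar <- kf$P_smooth[at, 1, 1]
  se <- sqrt(pmax(2 * pvar, 0))
  ll <- laea_inverse(x, y, fit$center)
  out <- data.frame(seal_id = seal_id,
                    timestamp = as.POSIXct(t0n + grid_hr * 3600,
                                           origin = "1970-01-01", tz = "UTC"),
                    x_km = x, y_km = y, lon = ll$lon, lat = ll$lat, se_km = se)
  keep <- out$se_km <= se_max
  dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Daily movement summaries from a 6-hourly track
#'
#' For each tracking day: the estimate nearest 12:00 UTC (the "midday"
#' position used for habitat annotation), the great-circle distance summed
#' over the day's consecutive estimates (segments are credited to the day of
#' their starting estimate), the cumulative distance, and the daily movement
#' rate.  Days whose estimates were all dropped are flagged missing, not
#' interpolated, and contribute zero to the cumulative distance.
#'
#' @param track Output of [predict_track()] (>= 2 rows).
#' @return `data.frame` with `seal_id`, `date`, `lon`, `lat`, `se_km`,
#'   `step_km`, `cum_km`, `rate_km_day`, `missing`.
#' @export
daily_summaries <- function(track) {
  stopifnot(nrow(track) >= 2)
  track <- track[order(track$timestamp), ]
  n <- nrow(track)
  seg <- gc_dist_km(track$lon[-n], track$lat[-n], track$lon[-1], track$lat[-1])
  seg_day <- as.Date(format(track$timestamp[-n], "%Y-%m-%d"))
  day <- as.Date(format(track$timestamp, "%Y-%m-%d"))
  all_days <- seq(min(day), max(day), by = "day")
  rows <- lapply(all_days, function(d) {
    idx <- which(day == d)
    if (!length(idx)) {
      return(data.frame(seal_id = track$seal_id[1], date = d,
                        lon = NA_real_, lat = NA_real_, se_km = NA_real_,
                        step_km = 0, missing = TRUE))
    }
    noon <- as.POSIXct(paste(d, "12:00:00"), tz = "UTC")
    mid <- idx[which.min(abs(as.numeric(track$timestamp[idx]) - as.numeric(noon)))]
    data.frame(seal_id = track$seal_id[1], date = d,
               lon = track$lon[mid], lat = track$lat[mid],
               se_km = track$se_km[mid],
               step_km = sum(seg[seg_day == d]), missing = FALSE)
  })
  out <- do.call(rbind, rows)
  out$cum_km <- cumsum(out$step_km)
  out$rate_km_day <- out$step_km
  out$rate_km_day[out$missing] <- NA_real_
  rownames(out) <- NULL
  out[, c("seal_id", "date", "lon", "lat", "se_km", "step_km", "cum_km",
          "rate_km_day", "missing")]
}
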