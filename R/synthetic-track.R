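# Synthetic seal tracks: an integrated Ornstein-Uhlenbeck velocity process
# sampled exactly on a fine regular grid, with Argos-style fixes emitted at
# irregular times on that grid plus class-dependent isotropic position error.

#' Simulate one seal's true path and Argos fix series
#'
#' The true path is the same continuous-time correlated random walk family the
#' track estimator assumes: per axis, velocity is an Ornstein-Uhlenbeck process
#' with autocorrelation `ou_beta` and noise scale `ou_sigma`, integrated to
#' position, simulated by its exact discrete transition on the `step_true`
#' grid.  Fix times are a subset of that grid with geometric gaps (median
#' interval about 0.5 hr at the defaults) plus occasional long gaps; each fix
#' adds isotropic Gaussian error with the SD of its sampled Argos class.
#'
#' When `domain` is supplied, the path is kept at sea: a step that would land
#' on a land cell (or leave the grid) is replaced by a velocity reversal, so
#' the process deviates from a pure correlated random walk only near the coast.
#' Leave `domain = NULL` for an unconstrained process (e.g. parameter-recovery
#' experiments).
#'
#' @param config A [sim_config()].
#' @param seal Integer seal index in `1:n_seals` (or an id from
#'   [sim_seal_ids()]).
#' @param domain Optional [grid_raster()] with a land mask (typically the
#'   bathymetry from [simulate_rasters()]).
#' @param start_xy Optional `c(x, y)` start position in km; by default a
#'   seeded jitter on the mid-shelf.
#' @return A list with `truth` (class `sim_truth`: `seal_id` and the
#'   `positions` data frame of the full true path) and `fixes`
#'   (`seal_id`, `timestamp`, `lon`, `lat`, `lc`).
#' @export
simulate_track <- function(config, seal = 1L, domain = NULL, start_xy = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.character(seal)) seal <- match(seal, sim_seal_ids(config))
  seal <- as.integer(seal)
  stopifnot(length(seal) == 1, !is.na(seal), seal >= 1)
  seal_id <- sprintf("S%02d", seal)

  times <- sim_times(config)
  n <- length(times)
  if (n < 2) stop("degenerate date range: fewer than two true-path samples")
  t_hr <- as.numeric(difftime(times, times[1], units = "hours"))

  set.seed(child_seed(config$seed, seal, 1L))
  if (is.null(start_xy)) {
    start_xy <- c(stats::runif(1, -150, 150), 150 + stats::runif(1, -50, 50))
  }
  vsd <- if (config$ou_sigma > 0) config$ou_sigma / sqrt(2 * config$ou_beta) else 0
  v0 <- if (vsd > 0) stats::rnorm(2, 0, vsd) else c(0, 0)

  path <- sim_iou_path(t_hr, config$ou_beta, config$ou_sigma,
                       start_xy, v0, domain)
  ll <- laea_inverse(path[, 1], path[, 2], config$center)
  positions <- data.frame(time = times, x = path[, 1], y = path[, 2],
                          lon = ll$lon, lat = ll$lat)

  # irregular fix times: geometric gaps on the fine grid (+ rare long gaps)
  set.seed(child_seed(config$seed, seal, 2L))
  step_hr <- config$step_true / 60
  p <- min(1, step_hr / config$gap_mean_hr)
  n_draw <- ceiling(n * p * 1.3) + 50
  gaps <- stats::rgeom(n_draw, p) + 1L
  long <- stats::runif(n_draw) < config$long_gap_prob
  gaps[long] <- gaps[long] +
    pmax(1L, as.integer(round(stats::rexp(sum(long), 1 / config$long_gap_mean_hr) /
                                step_hr)))
  idx <- 1L + cumsum(gaps)
  idx <- idx[idx <= n]
  if (!length(idx)) idx <- n

  lc <- sample(names(config$argos_class_probs), length(idx), replace = TRUE,
               prob = config$argos_class_probs)
  sd_km <- unname(config$argos_class_sd_km[lc])
  fx <- path[idx, 1] + stats::rnorm(length(idx), 0, sd_km)
  fy <- path[idx, 2] + stats::rnorm(length(idx), 0, sd_km)
  fll <- laea_inverse(fx, fy, config$center)
  fixes <- data.frame(seal_id = seal_id, timestamp = times[idx],
                      lon = fll$lon, lat = fll$lat, lc = lc,
                      stringsAsFactors = FALSE)

  truth <- structure(list(seal_id = seal_id, positions = positions,
                          schedule = NULL, true_budget = NULL),
                     class = "sim_truth")
  list(truth = truth, fixes = fixes)
}

# Exact IOU path over times t_hr (hours); both axes share parameters.
# With a domain raster, steps onto land (or off-grid) become velocity
# reversals: the position holds and both velocity components flip sign.
#' @keywords internal
sim_iou_path <- function(t_hr, beta, sigma, start_xy, v0, domain = NULL) {
  n <- length(t_hr)
  out <- matrix(0, n, 4)  # x, y, vx, vy
  out[1, ] <- c(start_xy, v0)
  if (n == 1) return(out)
  dts <- diff(t_hr)
  const_dt <- length(unique(round(dts, 10))) == 1
  st <- iou_step(beta, sigma, dts[1])
  L <- if (sigma > 0) t(chol(st$Q + diag(1e-14, 2))) else NULL
  at_sea <- function(x, y) {
    ij <- raster_index(domain, x, y)
    !is.na(ij[1, "i"]) && !domain$land[ij[1, "i"], ij[1, "j"]]
  }
  for (k in 2:n) {
    if (!const_dt) {
      st <- iou_step(beta, sigma, dts[k - 1])
      L <- if (sigma > 0) t(chol(st$Q + diag(1e-14, 2))) else NULL
    }
    zx <- if (is.null(L)) c(0, 0) else as.numeric(L %*% stats::rnorm(2))
    zy <- if (is.null(L)) c(0, 0) else as.numeric(L %*% stats::rnorm(2))
    sx <- st$T %*% out[k - 1, c(1, 3)] + zx
    sy <- st$T %*% out[k - 1, c(2, 4)] + zy
    if (!is.null(domain) && !at_sea(sx[1], sy[1])) {
      out[k, ] <- c(out[k - 1, 1], out[k - 1, 2],
                    -out[k - 1, 3], -out[k - 1, 4])
    } else {
      out[k, ] <- c(sx[1], sy[1], sx[2], sy[2])
    }
  }
  out
}
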