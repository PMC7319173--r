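# Configuration and shared helpers for the synthetic biologging generator.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic biologging generator.  Defaults describe
#' a plausible Arctic shelf deployment: a mostly low-quality Argos class mix
#' (class 1-3 fixes are a small minority), a median fix interval near half an
#' hour, a velocity autocorrelation time scale of one hour, and wet/dry sensor
#' hours drawn from a strongly bimodal mixture (dry mode on \[80, 100\]%, wet
#' mode on \[0, 25\]%).
#'
#' @param seed Integer master seed; every stream derives its own child seed
#'   from it, so a config is fully deterministic.
#' @param n_seals Number of simulated animals.
#' @param start_date,end_date `POSIXct` UTC bounds of the simulation; must be
#'   strictly ordered.
#' @param step_true True-path sampling step, minutes.  Fix times are drawn on
#'   this grid, so the true position at each fix is exact.
#' @param ou_beta Velocity autocorrelation parameter, 1/hr.
#' @param ou_sigma Velocity noise scale, km/hr^1.5; the stationary r.m.s.
#'   velocity per axis is `ou_sigma / sqrt(2 * ou_beta)`.
#' @param argos_class_probs Named probability vector over location classes
#'   `3,2,1,0,A,B,Z`; must sum to 1.
#' @param argos_class_sd_km Named per-class isotropic error SD (km).  Defaults
#'   follow the published Kalman-class error magnitudes for classes 3..B, and
#'   class Z is emitted as implausible outliers.
#' @param gap_mean_hr Mean fix interval, hours (geometric gaps on the true-path
#'   grid; the default yields a median interval of about 0.5 hr).
#' @param long_gap_prob,long_gap_mean_hr Occasional long transmission gaps:
#'   probability per fix of an added exponential gap with the given mean.
#' @param detect_floor_m Dive-detection floor of the tag, metres.  The tag
#'   firmware family this emulates reports several thresholds (1.0 m start/end
#'   detection, a 3 m nominal floor, 3.5 m histogram floor), so the floor is a
#'   parameter rather than a constant.
#' @param dry_modes List with elements `dry` and `wet`, each
#'   `c(shape1, shape2)` of a Beta draw; dry hours are `80 + 20*Beta`, wet
#'   hours `25*Beta`, giving percent-dry mass only on \[80,100\] and \[0,25\].
#' @param depth_dur `c(a, b, sd)` of the depth-duration law used for simulated
#'   dive durations, minutes: `a + b*log(depth_m) + N(0, sd)`.
#' @param surface_meanlog,surface_sdlog Log-normal parameters of intra-bout
#'   surface intervals, minutes (capped below 10 min).
#' @param rep_jitter Relative depth jitter within a repetitive bout (default
#'   +/-6% about the bout target, well inside the +/-15% bout criterion).
#' @param center Projection centre `c(lon, lat)` of the study area.
#' @param behavior_schedule Optional pre-built schedule `data.frame` (columns
#'   `seal_id`, `start`, `end`, `class`, `target_depth_m`); `NULL` generates
#'   one per seal.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_seals = 2L,
                       start_date = as.POSIXct("2016-07-15 00:00:00", tz = "UTC"),
                       end_date = as.POSIXct("2016-10-15 00:00:00", tz = "UTC"),
                       step_true = 15,
                       ou_beta = 1,
                       ou_sigma = 2,
                       argos_class_probs = c(`3` = 0.015, `2` = 0.025, `1` = 0.032,
                                             `0` = 0.100, A = 0.350, B = 0.450,
                                             Z = 0.028),
                       argos_class_sd_km = c(`3` = 0.25, `2` = 0.5, `1` = 1.5,
                                             `0` = 4, A = 8, B = 15, Z = 80),
                       gap_mean_hr = 0.75,
                       long_gap_prob = 0.02,
                       long_gap_mean_hr = 8,
                       detect_floor_m = 1.0,
                       dry_modes = list(dry = c(5, 1.5), wet = c(1.2, 5)),
                       depth_dur = c(a = -1.3, b = 1.7, sd = 0.5),
                       surface_meanlog = log(0.7),
                       surface_sdlog = 0.5,
                       rep_jitter = 0.06,
                       center = c(-156.8, 71.3),
                       behavior_schedule = NULL) {
  start_date <- as.POSIXct(start_date, tz = "UTC")
  end_date <- as.POSIXct(end_date, tz = "UTC")
  if (!(end_date > start_date)) stop("degenerate date range: end_date must be after start_date")
  classes <- c("3", "2", "1", "0", "A", "B", "Z")
  if (!setequal(names(argos_class_probs), classes))
    stop("argos_class_probs must be named over classes ", paste(classes, collapse = ","))
  if (abs(sum(argos_class_probs) - 1) > 1e-8)
    stop("argos_class_probs must sum to 1")
  if (any(argos_class_probs < 0)) stop("negative class probability")
  if (any(argos_class_sd_km < 0)) stop("negative class error SD")
  stopifnot(step_true > 0, ou_beta > 0, ou_sigma >= 0, gap_mean_hr > 0,
            detect_floor_m >= 0, rep_jitter >= 0, rep_jitter < 0.15)
  structure(
    list(seed = as.integer(seed), n_seals = as.integer(n_seals),
         start_date = start_date, end_date = end_date,
         step_true = step_true, ou_beta = ou_beta, ou_sigma = ou_sigma,
         argos_class_probs = argos_class_probs[classes],
         argos_class_sd_km = argos_class_sd_km[classes],
         gap_mean_hr = gap_mean_hr, long_gap_prob = long_gap_prob,
         long_gap_mean_hr = long_gap_mean_hr,
         detect_floor_m = detect_floor_m, dry_modes = dry_modes,
         depth_dur = depth_dur, surface_meanlog = surface_meanlog,
         surface_sdlog = surface_sdlog, rep_jitter = rep_jitter,
         center = center, behavior_schedule = behavior_schedule),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d seal(s), %s .. %s, seed %d\n", x$n_seals,
              format(x$start_date, "%Y-%m-%d"), format(x$end_date, "%Y-%m-%d"),
              x$seed))
  cat(sprintf("  OU beta %.3g /hr, sigma %.3g km/hr^1.5; mean fix gap %.3g hr\n",
              x$ou_beta, x$ou_sigma, x$gap_mean_hr))
  invisible(x)
}

# Deterministic child seed for a (seal, stream) pair, kept within 32-bit range.
#' @keywords internal
child_seed <- function(seed, seal = 0L, stream = 0L) {
  as.integer((abs(as.numeric(seed)) * 48271 + seal * 16807 + stream * 69621) %%
               2147483587)
}

#' Seal identifier labels for a simulation
#' @param config A [sim_config()].
#' @return Character vector of `n_seals` ids.
#' @export
sim_seal_ids <- function(config) sprintf("S%02d", seq_len(config$n_seals))

# Regular true-path time grid of a config.
#' @keywords internal
sim_times <- function(config) {
  seq(config$start_date, config$end_date, by = config$step_true * 60)
}

#' Look up the true position at arbitrary times
#'
#' Nearest-sample lookup on the true-path grid of a [simulate_track()] result.
#'
#' @param truth A `sim_truth` object.
#' @param at `POSIXct` vector of query times.
#' @return `data.frame` with `x`, `y`, `lon`, `lat` at each query time.
#' @export
truth_position_at <- function(truth, at) {
  pos <- truth$positions
  t0 <- pos$time[1]
  step <- as.numeric(difftime(pos$time[2], pos$time[1], units = "secs"))
  k <- round(as.numeric(difftime(at, t0, units = "secs")) / step) + 1
  k <- pmin(pmax(k, 1), nrow(pos))
  pos[k, c("x", "y", "lon", "lat")]
}
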