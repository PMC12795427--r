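# Trajectory metrics for the Morris water maze.
#
# All metrics weight each sample by the time to the next sample (the last
# sample carries the mean interval), so irregular frame times are handled
# consistently across latency, abidance and floating.

traj_check <- function(traj) {
  need <- c("t_s", "x_m", "y_m")
  if (length(setdiff(need, names(traj)))) {
    abort_field("traj", "needs columns t_s, x_m, y_m")
  }
  if (nrow(traj) == 0L) abort_field("traj", "empty trajectory")
  if (is.unsorted(traj$t_s, strictly = TRUE)) {
    abort_field("traj", "t_s must be strictly increasing")
  }
  invisible(traj)
}

sample_weights <- function(t) {
  if (length(t) == 1L) return(1)
  d <- diff(t)
  c(d, mean(d))
}

#' Latency to reach the platform
#'
#' Time of the first sample inside the platform disc; the trial cap if the
#' platform is never reached.
#'
#' @param traj Trajectory tibble (`t_s`, `x_m`, `y_m`).
#' @param geom A [pool_geometry()].
#' @param cap Trial cap in seconds.
#' @return Latency in seconds.
#' @export
latency <- function(traj, geom, cap = 60) {
  traj_check(traj)
  d2 <- (traj$x_m - geom$platform_center[1])^2 +
    (traj$y_m - geom$platform_center[2])^2
  hit <- which(d2 <= geom$platform_radius^2)
  if (length(hit)) traj$t_s[hit[1]] else cap
}

#' Distance traversed
#'
#' Sum of Euclidean segment lengths, by default truncated at the platform
#' latency (training-day convention); pass `truncate_at = NULL` for probe
#' trials.
#'
#' @inheritParams latency
#' @param truncate_at Optional time (s) after which segments are ignored.
#' @return Path length in metres (0 with a warning for < 2 samples).
#' @export
path_length <- function(traj, truncate_at = NULL) {
  traj_check(traj)
  if (nrow(traj) < 2L) {
    warning("fewer than 2 samples; path length 0")
    return(0)
  }
  keep <- if (is.null(truncate_at)) rep(TRUE, nrow(traj)) else traj$t_s <= truncate_at
  x <- traj$x_m[keep]; y <- traj$y_m[keep]
  if (length(x) < 2L) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Fraction of trial time spent floating
#'
#' Floating is near-immobility: maximal episodes in which the instantaneous
#' speed (central differences) stays below `speed_thresh` for at least
#' `min_dur` seconds. Returns the episode time as a percentage of trial
#' time.
#'
#' @inheritParams latency
#' @param speed_thresh Speed threshold in m/s.
#' @param min_dur Minimum episode duration in seconds.
#' @return Percent of trial time in [0, 100].
#' @export
floating_fraction <- function(traj, speed_thresh = 0.02, min_dur = 1) {
  traj_check(traj)
  n <- nrow(traj)
  if (n < 3L) return(0)
  sp <- numeric(n)
  sp[2:(n - 1)] <- sqrt((traj$x_m[3:n] - traj$x_m[1:(n - 2)])^2 +
                          (traj$y_m[3:n] - traj$y_m[1:(n - 2)])^2) /
    (traj$t_s[3:n] - traj$t_s[1:(n - 2)])
  sp[1] <- sp[2]; sp[n] <- sp[n - 1]
  slow <- sp < speed_thresh
  w <- sample_weights(traj$t_s)
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  t_float <- 0
  for (i in which(r$values)) {
    dur <- sum(w[starts[i]:ends[i]])
    if (dur >= min_dur) t_float <- t_float + dur
  }
  100 * t_float / sum(w)
}

#' Fraction of trial time in the wall zone (thigmotaxis)
#'
#' Percent of (time-weighted) samples farther from the pool center than
#' pool radius minus the wall-zone width.
#'
#' @inheritParams latency
#' @return Percent of trial time in [0, 100].
#' @export
thigmotaxis_fraction <- function(traj, geom) {
  traj_check(traj)
  r <- sqrt(traj$x_m^2 + traj$y_m^2)
  w <- sample_weights(traj$t_s)
  100 * sum(w[r > geom$pool_radius - geom$wall_width]) / sum(w)
}

#' Time share per pool quadrant (abidance)
#'
#' Time-weighted percentage of the trial spent in each compass quadrant
#' (half-open angular convention; shares sum to 100).
#'
#' @inheritParams latency
#' @return Named numeric of length 4 (`NE`, `NW`, `SW`, `SE`), percentages.
#' @export
quadrant_abidance <- function(traj, geom) {
  traj_check(traj)
  q <- point_quadrant(traj$x_m, traj$y_m)
  w <- sample_weights(traj$t_s)
  tot <- sum(w)
  vapply(c("NE", "NW", "SW", "SE"),
         function(lab) 100 * sum(w[q == lab]) / tot, numeric(1))
}

#' Number of target-zone crossings
#'
#' Entry events into the former platform footprint on the probe day:
#' outside-to-inside transitions, with a start inside the zone counting as
#' one entry.
#'
#' @inheritParams latency
#' @param zone_radius Radius of the target zone (default the platform
#'   radius).
#' @return Integer count.
#' @export
target_zone_crossings <- function(traj, geom, zone_radius = geom$platform_radius) {
  traj_check(traj)
  d2 <- (traj$x_m - geom$platform_center[1])^2 +
    (traj$y_m - geom$platform_center[2])^2
  inside <- d2 <= zone_radius^2
  sum(diff(c(FALSE, inside)) == 1L)
}

#' Trial-level metric table
#'
#' Computes all maze metrics for a set of labeled trajectories. Training
#' days report latency, distance (truncated at latency), floating and
#' thigmotaxis; the probe day (day 5) reports quadrant abidance and
#' target-zone crossings, with latency left `NA`.
#'
#' @param trajectories A list of trajectory tibbles.
#' @param labels Tibble with one row per trajectory: `animal`, `day`,
#'   `trial` (extra columns such as sex/genotype are carried through).
#' @param geom A [pool_geometry()].
#' @param schedule Start schedule used for validation (default
#'   [mwm_start_schedule()]).
#' @param cap Trial cap in seconds.
#' @param truncate_distance Truncate training-day distance at the latency
#'   (the configurable convention; default TRUE).
#' @return A tibble with one row per trial and columns for every metric.
#' @export
trial_table <- function(trajectories, labels, geom,
                        schedule = mwm_start_schedule(), cap = 60,
                        truncate_distance = TRUE) {
  if (length(trajectories) != nrow(labels)) {
    abort_field("labels", "one row per trajectory required")
  }
  if (length(setdiff(c("animal", "day", "trial"), names(labels)))) {
    abort_field("labels", "needs columns animal, day, trial")
  }
  known <- dplyr::semi_join(labels, schedule, by = c("day", "trial"))
  if (nrow(known) != nrow(labels)) {
    abort_field("labels", "day/trial combination not in the schedule")
  }
  purrr::map2(trajectories, seq_len(nrow(labels)), function(traj, i) {
    lab <- labels[i, ]
    probe <- lab$day == 5L
    if (probe) {
      ab <- quadrant_abidance(traj, geom)
      dplyr::bind_cols(lab, tibble(
        latency_s = NA_real_,
        distance_m = path_length(traj, truncate_at = NULL),
        floating_pct = floating_fraction(traj),
        thigmotaxis_pct = thigmotaxis_fraction(traj, geom),
        abidance_ne = ab[["NE"]], abidance_nw = ab[["NW"]],
        abidance_sw = ab[["SW"]], abidance_se = ab[["SE"]],
        crossings = target_zone_crossings(traj, geom)
      ))
    } else {
      lat <- latency(traj, geom, cap = cap)
      dplyr::bind_cols(lab, tibble(
        latency_s = lat,
        distance_m = path_length(
          traj, truncate_at = if (truncate_distance) lat else NULL),
        floating_pct = floating_fraction(traj),
        thigmotaxis_pct = thigmotaxis_fraction(traj, geom),
        abidance_ne = NA_real_, abidance_nw = NA_real_,
        abidance_sw = NA_real_, abidance_se = NA_real_,
        crossings = NA_integer_
      ))
    }
  }) |> dplyr::bind_rows()
}
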