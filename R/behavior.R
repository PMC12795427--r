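#' Configuration for the swim-path simulator
#'
#' Parameterizes the behavioral model generating Morris water maze swim
#' trajectories: a persistent random walk inside the pool disc with a
#' memory-dependent drift toward the platform, an optional wall attraction
#' (thigmotaxis), and explicit low-speed floating episodes. The drift weight
#' is logistic in ability x training day, so spatial memory expresses more
#' strongly in trained, able animals while remaining bounded.
#'
#' Training trials (days 1-4) end at platform contact or at the trial cap;
#' on the probe day (day 5) the platform is removed and the trial lasts the
#' full cap. Start positions follow the randomized schedule of the study
#' protocol ([mwm_start_schedule()]), entering at the wall of the scheduled
#' quadrant.
#'
#' @param geom Pool geometry from [pool_geometry()].
#' @param speed_mean,speed_sd Swim speed draw per trial, m/s.
#' @param bias_max Maximum platform-drift weight (0 disables memory).
#' @param bias_mid,bias_scale Midpoint and scale of the logistic mapping
#'   from ability x day to the drift weight.
#' @param thigmo_weight Outward wall-attraction weight (0 disables).
#' @param persistence Heading persistence of the walk (larger = straighter).
#' @param turn_sd SD of the isotropic heading noise per frame.
#' @param float_rate Floating episode starts per minute of swimming.
#' @param float_dur_mean Mean floating episode duration, seconds
#'   (exponential).
#' @param trial_cap Maximum trial duration, seconds.
#' @param fps Tracking frame rate, Hz.
#' @param schedule Start-position schedule tibble (day, trial, start
#'   quadrant); default [mwm_start_schedule()].
#' @param ability_support Allowed range for the ability argument of
#'   [generate_trajectory()].
#' @return A `behavior_config` list.
#' @export
behavior_config <- function(geom = pool_geometry(),
                            speed_mean = 0.20, speed_sd = 0.04,
                            bias_max = 0.9, bias_mid = 2.0, bias_scale = 1.2,
                            thigmo_weight = 0.15,
                            persistence = 8.0, turn_sd = 0.45,
                            float_rate = 0.3, float_dur_mean = 2.0,
                            trial_cap = 60, fps = 14,
                            schedule = mwm_start_schedule(),
                            ability_support = c(-4, 4)) {
  if (!inherits(geom, "pool_geometry")) abort_field("geom", "must be a pool_geometry")
  check_scalar_num(speed_mean, "speed_mean", lower = 0)
  check_scalar_num(speed_sd, "speed_sd", lower = 0)
  check_scalar_num(bias_max, "bias_max", lower = 0)
  check_scalar_num(thigmo_weight, "thigmo_weight", lower = 0)
  check_scalar_num(trial_cap, "trial_cap", lower = 1e-9)
  check_scalar_num(fps, "fps", lower = 1e-9)
  check_scalar_num(float_rate, "float_rate", lower = 0)
  structure(
    list(geom = geom, speed_mean = speed_mean, speed_sd = speed_sd,
         bias_max = bias_max, bias_mid = bias_mid, bias_scale = bias_scale,
         thigmo_weight = thigmo_weight, persistence = persistence,
         turn_sd = turn_sd, float_rate = float_rate,
         float_dur_mean = float_dur_mean, trial_cap = trial_cap, fps = fps,
         schedule = schedule, ability_support = ability_support),
    class = "behavior_config"
  )
}

#' Randomized start-position schedule
#'
#' The per-day, per-trial starting quadrants of the training protocol:
#' four training days of four trials each, and a single probe trial on day
#' 5 starting from SE (the platform sits in NW for all training trials).
#'
#' @return Tibble with columns `day`, `trial`, `start`.
#' @export
mwm_start_schedule <- function() {
  tibble(
    day = rep(1:5, times = c(4, 4, 4, 4, 1)),
    trial = c(rep(1:4, 4), 1L),
    start = c("NE", "SE", "SW", "SE",
              "SW", "NE", "SE", "SW",
              "SE", "SW", "NE", "SW",
              "NE", "SE", "SW", "NE",
              "SE")
  )
}

#' Simulate one swim trajectory
#'
#' Generates a timestamped swim path for one trial from the behavioral
#' model in [behavior_config()]. The animal starts at the wall of the
#' scheduled quadrant; each frame the heading is updated as a weighted sum
#' of the previous heading, a drift toward the platform (weight logistic in
#' ability x day), an outward wall attraction, and isotropic noise, then
#' the position advances at the drawn swim speed and is kept inside the
#' pool disc by reflection. Training trials stop at platform contact or at
#' the cap; day-5 trials last exactly the cap with the platform absent
#' (the remembered drift still applies, which is what probe-day abidance
#' measures).
#'
#' @param ability Latent memory ability (must lie in the configured
#'   support; 0 = average, higher = better).
#' @param day Training day 1-4 or probe day 5.
#' @param trial Trial index within the day (must exist in the schedule).
#' @param config A [behavior_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `t_s`, `x_m`, `y_m` and attributes `day`,
#'   `trial`, `fps`.
#' @export
generate_trajectory <- function(ability, day, trial = 1L,
                                config = behavior_config(), seed = NULL) {
  if (!inherits(config, "behavior_config")) {
    abort_field("config", "must be a behavior_config")
  }
  sup <- config$ability_support
  if (!is.finite(ability) || ability < sup[1] || ability > sup[2]) {
    abort_field("ability", sprintf("must lie in [%g, %g]", sup[1], sup[2]))
  }
  if (!day %in% 1:5) abort_field("day", "must be in 1..5")
  sched <- dplyr::filter(config$schedule, .data$day == !!day, .data$trial == !!trial)
  if (nrow(sched) != 1L) abort_field("trial", "day/trial not in the schedule")
  if (!is.null(seed)) {
    restore <- set_local_seed(seed)
    on.exit(restore(), add = TRUE)
  }

  geom <- config$geom
  dt <- 1 / config$fps
  n_max <- ceiling(config$trial_cap * config$fps)
  probe <- day == 5L

  # logistic drift weight in ability x day (probe day uses full training),
  # rescaled so zero or negative drive gives exactly zero platform drift
  drive <- ability * min(day, 4L)
  l0 <- stats::plogis(-config$bias_mid / config$bias_scale)
  l <- stats::plogis((drive - config$bias_mid) / config$bias_scale)
  w_mem <- config$bias_max * max(0, (l - l0) / (1 - l0))

  r_start <- geom$pool_radius * 0.96
  a0 <- quadrant_angle(sched$start)
  pos <- r_start * c(cos(a0), sin(a0))
  # release heading: uniform over the inward-facing half circle
  inward <- atan2(-pos[2], -pos[1])
  th0 <- inward + runif(1, -pi / 2, pi / 2)
  heading <- c(cos(th0), sin(th0))
  speed <- max(0.02, rnorm(1, config$speed_mean, config$speed_sd))

  p_float_start <- config$float_rate / 60 * dt
  floating_left <- 0

  xs <- numeric(n_max); ys <- numeric(n_max)
  n_used <- n_max
  for (k in seq_len(n_max)) {
    xs[k] <- pos[1]; ys[k] <- pos[2]
    if (!probe &&
        sum((pos - geom$platform_center)^2) <= geom$platform_radius^2) {
      n_used <- k
      break
    }
    if (floating_left > 0) {
      floating_left <- floating_left - dt
      step_speed <- 0.005
      dir <- heading
    } else {
      if (runif(1) < p_float_start) {
        floating_left <- rexp(1, rate = 1 / config$float_dur_mean)
      }
      u_plat <- geom$platform_center - pos
      np <- sqrt(sum(u_plat^2))
      u_plat <- if (np > 1e-9) u_plat / np else c(0, 0)
      rr <- sqrt(sum(pos^2))
      u_wall <- if (rr > 1e-9) pos / rr else c(0, 0)
      dir <- config$persistence * heading +
        w_mem * u_plat +
        config$thigmo_weight * u_wall +
        config$turn_sd * rnorm(2)
      nd <- sqrt(sum(dir^2))
      dir <- if (nd > 1e-9) dir / nd else heading
      step_speed <- speed
    }
    pos <- pos + step_speed * dt * dir
    rr <- sqrt(sum(pos^2))
    lim <- geom$pool_radius * 0.995
    if (rr > lim) {
      # reflect the heading at the wall and clamp the position to the disc
      nrm <- pos / rr
      dir <- dir - 2 * sum(dir * nrm) * nrm
      pos <- nrm * lim
    }
    heading <- dir
  }
  out <- tibble(
    t_s = (seq_len(n_used) - 1) * dt,
    x_m = xs[seq_len(n_used)],
    y_m = ys[seq_len(n_used)]
  )
  attr(out, "day") <- day
  attr(out, "trial") <- trial
  attr(out, "fps") <- config$fps
  out
}
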