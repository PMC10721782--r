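# Synthetic behavioral and physiological data: water-maze trajectories,
# object-exploration times, and thermocouple traces during a
# photobiomodulation session. Pure functions of (parameters, seed).

#' Simulate a water-maze swim trajectory
#'
#' Correlated random walk with drift toward the platform: at each step the
#' heading is blended toward the platform direction with per-second weight
#' `goal_bias` (compounded correctly over the sampling interval, so the
#' drift strength is independent of `dt`), plus angular noise scaled by
#' `(1 - heading_persistence)`. The path reflects at the arena wall and
#' stops at platform entry (sample strictly inside) or at the trial cap.
#'
#' @param arena List with `center` (x, y) and `radius` in cm.
#' @param platform List with `center` (x, y) and `radius` in cm; must lie
#'   inside the arena.
#' @param mean_speed Swim speed in cm/s (> 0).
#' @param heading_persistence In \[0, 1\]; 1 = no angular noise.
#' @param goal_bias In \[0, 1\]; 0 = undirected search, 1 = heading straight
#'   for the platform. Interpreted as the fraction of remaining angular
#'   error removed per second of swimming.
#' @param trial_cap_s Trial duration cap (s).
#' @param dt Sampling interval (s, > 0); 0.1 s mimics a 10 Hz tracker.
#' @param start Optional start position (x, y); default is on the wall
#'   opposite the platform.
#' @param seed RNG seed.
#' @return List with `trajectory` ([trajectory()]) and `truth` (records the
#'   platform entry time, `NA` if capped).
#' @export
gen_trajectory <- function(arena = list(center = c(0, 0), radius = 60),
                           platform = list(center = c(30, 0), radius = 5),
                           mean_speed = 18, heading_persistence = 0.8,
                           goal_bias = 0.3, trial_cap_s = 60, dt = 0.1,
                           start = NULL, seed = 1) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (mean_speed <= 0) stop("mean_speed must be > 0", call. = FALSE)
  pd <- sqrt(sum((platform$center - arena$center)^2))
  if (pd + platform$radius > arena$radius)
    stop("platform outside arena", call. = FALSE)
  if (is.null(start)) {
    away <- arena$center - platform$center
    away <- away / max(sqrt(sum(away^2)), 1e-12)
    start <- arena$center + away * arena$radius * 0.9
  }
  sigma_turn <- (1 - heading_persistence) * pi * sqrt(dt)
  bias_step <- if (goal_bias >= 1) 1 else 1 - (1 - goal_bias)^dt
  n_max <- ceiling(trial_cap_s / dt) + 1L

  path <- withr::with_seed(seed, {
    pos <- matrix(NA_real_, n_max, 2L)
    pos[1L, ] <- start
    goal0 <- platform$center - start
    theta <- atan2(goal0[2L], goal0[1L]) + rnorm(1L, 0, max(sigma_turn, 0.1))
    entry <- NA_real_
    i <- 1L
    while (i < n_max) {
      goal <- platform$center - pos[i, ]
      goal_ang <- atan2(goal[2L], goal[1L])
      blend <- (1 - bias_step) * c(cos(theta), sin(theta)) +
               bias_step * c(cos(goal_ang), sin(goal_ang))
      if (sum(blend^2) < 1e-12) blend <- c(cos(theta), sin(theta))
      theta <- atan2(blend[2L], blend[1L]) + rnorm(1L, 0, sigma_turn)
      p_new <- pos[i, ] + mean_speed * dt * c(cos(theta), sin(theta))
      rad <- sqrt(sum((p_new - arena$center)^2))
      if (rad > arena$radius) {             # reflect at the wall
        dir_out <- (p_new - arena$center) / rad
        p_new <- arena$center + dir_out * (2 * arena$radius - rad)
        inward <- atan2(arena$center[2L] - p_new[2L],
                        arena$center[1L] - p_new[1L])
        theta <- inward + rnorm(1L, 0, max(sigma_turn, 0.05))
      }
      i <- i + 1L
      pos[i, ] <- p_new
      dplat <- sqrt(sum((p_new - platform$center)^2))
      if (dplat < platform$radius) {
        entry <- (i - 1L) * dt
        break
      }
    }
    list(pos = pos[seq_len(i), , drop = FALSE], entry = entry)
  })
  n <- nrow(path$pos)
  traj <- trajectory(t_s = (seq_len(n) - 1L) * dt,
                     x_cm = path$pos[, 1L], y_cm = path$pos[, 2L],
                     arena = arena, platform = platform)
  truth <- synthetic_truth("gen_trajectory", seed, list(
    mean_speed = mean_speed, heading_persistence = heading_persistence,
    goal_bias = goal_bias, trial_cap_s = trial_cap_s, dt = dt,
    start = start, entry_time_s = path$entry,
    capped = is.na(path$entry)))
  list(trajectory = traj, truth = truth)
}

#' Simulate a novel-object exploration session
#'
#' The realized novel-object share is drawn from a Beta distribution with
#' mean `preference` and concentration `concentration` (`preference` 0 or 1
#' gives the degenerate point mass).
#'
#' @param preference Expected novel-object share in \[0, 1\]; 0.5 = chance.
#' @param total_time_s Total exploration time (> 0 s).
#' @param concentration Beta concentration (larger = less session-to-session
#'   spread).
#' @param seed RNG seed.
#' @return List with `record` ([exploration_record()]) and `truth`.
#' @export
gen_exploration <- function(preference = 0.5, total_time_s = 60,
                            concentration = 20, seed = 1) {
  if (preference < 0 || preference > 1)
    stop("preference must be in [0, 1]", call. = FALSE)
  if (total_time_s <= 0) stop("total_time_s must be > 0", call. = FALSE)
  p_real <- if (preference %in% c(0, 1)) {
    preference
  } else {
    withr::with_seed(seed, rbeta(1L, preference * concentration,
                                 (1 - preference) * concentration))
  }
  rec <- exploration_record(total_time_s * p_real, total_time_s * (1 - p_real))
  truth <- synthetic_truth("gen_exploration", seed, list(
    preference = preference, realized_share = p_real,
    total_time_s = total_time_s, concentration = concentration))
  list(record = rec, truth = truth)
}

#' Simulate a thermocouple trace during a photobiomodulation session
#'
#' First-order exponential approach to `baseline_C + rise_C` during
#' irradiation segments and decay back to baseline during pauses, sampled at
#' `dt_s`, plus Gaussian observation noise. A pre-session baseline lead of
#' `baseline_lead_s` seconds is prepended so baseline estimation has data.
#'
#' @param schedule A [pbm_schedule()].
#' @param baseline_C Resting cortical surface temperature.
#' @param rise_C Plateau temperature rise under irradiation.
#' @param time_constant_s First-order time constant (> 0 s).
#' @param noise_sd Observation noise SD in degC.
#' @param dt_s Sampling interval (s).
#' @param baseline_lead_s Pre-session baseline duration (s).
#' @param seed RNG seed.
#' @return List with `trace` (annotated [temperature_trace()]) and `truth`.
#' @export
gen_temperature_trace <- function(schedule = pbm_schedule(), baseline_C = 37,
                                  rise_C = 1.0, time_constant_s = 60,
                                  noise_sd = 0.02, dt_s = 1,
                                  baseline_lead_s = 120, seed = 1) {
  if (!is.finite(rise_C)) stop("rise must be finite", call. = FALSE)
  if (time_constant_s <= 0) stop("time constant must be > 0", call. = FALSE)
  seg <- schedule_segments_s(schedule, session_start_s = baseline_lead_s)
  total_s <- baseline_lead_s + protocol_duration(schedule) * 60
  t <- seq(0, total_s, by = dt_s)
  irr <- rep(FALSE, length(t))
  for (i in which(seg$kind == "irradiation"))
    irr <- irr | (t >= seg$start_s[i] & t < seg$end_s[i])
  target <- baseline_C + rise_C * irr
  temp <- numeric(length(t))
  temp[1L] <- baseline_C
  decay <- exp(-dt_s / time_constant_s)
  for (i in seq_along(t)[-1L])
    temp[i] <- target[i] + (temp[i - 1L] - target[i]) * decay
  if (noise_sd > 0)
    temp <- temp + withr::with_seed(seed, rnorm(length(t), 0, noise_sd))
  truth <- synthetic_truth("gen_temperature_trace", seed, list(
    baseline_C = baseline_C, rise_C = rise_C,
    time_constant_s = time_constant_s, noise_sd = noise_sd, dt_s = dt_s,
    baseline_lead_s = baseline_lead_s,
    fluence_J_cm2 = schedule$fluence_J_cm2))
  list(trace = temperature_trace(t, temp, segments = seg), truth = truth)
}
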