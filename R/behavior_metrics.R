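# Behavioral readouts: novel-object recognition index, water-maze escape
# latency, swim path length and mean speed.

#' Tracked swim trajectory in a circular arena
#'
#' @param t_s Strictly increasing sample times (seconds).
#' @param x_cm,y_cm Position samples (cm).
#' @param arena List with `center` (x, y) and `radius` (cm); all samples
#'   must lie within the arena radius plus 5% tolerance.
#' @param platform Optional list with `center` (x, y) and `radius` (cm); the
#'   escape-platform region of interest. In a probe trial (platform removed)
#'   this is the former platform location.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(t_s, x_cm, y_cm, arena, platform = NULL) {
  stopifnot(length(t_s) == length(x_cm), length(t_s) == length(y_cm))
  if (length(t_s) && any(diff(t_s) <= 0))
    stop("t must be strictly increasing", call. = FALSE)
  stopifnot(is.list(arena), length(arena$center) == 2L, arena$radius > 0)
  r <- sqrt((x_cm - arena$center[1L])^2 + (y_cm - arena$center[2L])^2)
  if (length(r) && max(r) > arena$radius * 1.05)
    stop("trajectory leaves the arena (beyond 5% tolerance)", call. = FALSE)
  if (!is.null(platform)) {
    stopifnot(length(platform$center) == 2L, platform$radius > 0)
    pd <- sqrt(sum((platform$center - arena$center)^2))
    if (pd + platform$radius > arena$radius)
      stop("platform outside arena", call. = FALSE)
  }
  structure(list(samples = data.frame(t_s = t_s, x_cm = x_cm, y_cm = y_cm),
                 arena = arena, platform = platform),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<trajectory> %d samples, %.1f s, arena r=%.1f cm%s\n",
              n, if (n) diff(range(x$samples$t_s)) else 0, x$arena$radius,
              if (is.null(x$platform)) "" else ", platform set"))
  invisible(x)
}

#' Exploration-time record of a novel-object recognition session
#'
#' @param t_novel_s,t_familiar_s Exploration time (s) of the novel and
#'   familiar object, both >= 0.
#' @return Object of class `exploration_record`.
#' @export
exploration_record <- function(t_novel_s, t_familiar_s) {
  if (t_novel_s < 0 || t_familiar_s < 0)
    stop("exploration times must be >= 0", call. = FALSE)
  structure(list(t_novel_s = t_novel_s, t_familiar_s = t_familiar_s),
            class = "exploration_record")
}

#' Recognition index
#'
#' `RI = T_novel / (T_novel + T_familiar)`; chance level 0.5.
#'
#' @param rec An [exploration_record()], or the novel-object time when
#'   `t_familiar_s` is given.
#' @param t_familiar_s Familiar-object time when `rec` is numeric.
#' @return Ratio in \[0, 1\].
#' @export
recognition_index <- function(rec, t_familiar_s = NULL) {
  if (is.numeric(rec) && !is.null(t_familiar_s))
    rec <- exploration_record(rec, t_familiar_s)
  stopifnot(inherits(rec, "exploration_record"))
  tot <- rec$t_novel_s + rec$t_familiar_s
  if (tot <= 0) stop("both exploration times are zero", call. = FALSE)
  rec$t_novel_s / tot
}

#' Escape latency of a water-maze trial
#'
#' Time from trial start to the first sample strictly inside the platform
#' region of interest. Entry is judged on sampled points (no interpolation
#' between samples), matching tracking-system output at >= 10 Hz. If the
#' animal never enters, the trial cap is returned and flagged.
#'
#' @param traj A [trajectory()] with a platform defined.
#' @param trial_cap_s Trial duration cap in seconds (trials last 1 min).
#' @return List with `latency_s` and logical `capped`.
#' @export
escape_latency <- function(traj, trial_cap_s = 60) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$platform)) stop("platform not defined", call. = FALSE)
  s <- traj$samples
  if (!nrow(s)) stop("empty trajectory", call. = FALSE)
  d <- sqrt((s$x_cm - traj$platform$center[1L])^2 +
            (s$y_cm - traj$platform$center[2L])^2)
  inside <- which(d < traj$platform$radius)
  if (length(inside)) {
    list(latency_s = s$t_s[inside[1L]] - s$t_s[1L], capped = FALSE)
  } else {
    list(latency_s = trial_cap_s, capped = TRUE)
  }
}

#' Swim path length
#'
#' Sum of Euclidean steps between consecutive samples (cm).
#'
#' @param traj A [trajectory()] with >= 2 samples.
#' @return Path length in cm.
#' @export
path_length <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  s <- traj$samples
  if (nrow(s) < 2L) stop("need >= 2 samples", call. = FALSE)
  sum(sqrt(diff(s$x_cm)^2 + diff(s$y_cm)^2))
}

#' Mean swim speed
#'
#' Path length divided by elapsed time (cm/s); uses the path, not the
#' displacement, so a closed loop has nonzero speed.
#'
#' @param traj A [trajectory()] with >= 2 samples.
#' @return Mean speed in cm/s.
#' @export
mean_speed <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  s <- traj$samples
  if (nrow(s) < 2L) stop("need >= 2 samples", call. = FALSE)
  dur <- s$t_s[nrow(s)] - s$t_s[1L]
  if (dur <= 0) stop("zero duration", call. = FALSE)
  path_length(traj) / dur
}
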