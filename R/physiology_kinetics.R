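# Photobiomodulation protocol arithmetic, thermocouple-trace summaries, and
# tracer (Evans blue) drainage time courses.

#' Photobiomodulation session schedule
#'
#' Ordered irradiation/pause segments plus dose geometry. The default is the
#' standard session: 17 min irradiation, 5 min pause, 17 min irradiation,
#' 5 min pause, 17 min irradiation (61 min in total).
#'
#' @param segments Data frame with columns `kind`
#'   (`"irradiation"`/`"pause"`) and `minutes` (> 0), or `NULL` for the
#'   default session.
#' @param fluence_J_cm2 Delivered fluence per session (free parameter;
#'   typical doses 16, 32, 64 J/cm^2).
#' @param spot_area_cm2 Irradiated spot area (> 0).
#' @return Object of class `pbm_schedule`.
#' @export
pbm_schedule <- function(segments = NULL, fluence_J_cm2 = 32,
                         spot_area_cm2 = 0.2) {
  if (is.null(segments)) {
    segments <- data.frame(
      kind = c("irradiation", "pause", "irradiation", "pause", "irradiation"),
      minutes = c(17, 5, 17, 5, 17))
  }
  segments <- as.data.frame(segments)
  stopifnot(all(c("kind", "minutes") %in% names(segments)))
  if (nrow(segments) && !all(segments$kind %in% c("irradiation", "pause")))
    stop("segment kind must be 'irradiation' or 'pause'", call. = FALSE)
  if (any(segments$minutes <= 0))
    stop("segment durations must be positive", call. = FALSE)
  if (spot_area_cm2 <= 0) stop("spot area must be > 0", call. = FALSE)
  structure(list(segments = segments, fluence_J_cm2 = fluence_J_cm2,
                 spot_area_cm2 = spot_area_cm2),
            class = "pbm_schedule")
}

#' Total session duration
#'
#' @param schedule A [pbm_schedule()] (an empty schedule sums to 0).
#' @return Total duration in minutes.
#' @export
protocol_duration <- function(schedule) {
  stopifnot(inherits(schedule, "pbm_schedule"))
  if (!nrow(schedule$segments)) return(0)
  sum(schedule$segments$minutes)
}

# segment boundaries in seconds, given the session start time
schedule_segments_s <- function(schedule, session_start_s = 0) {
  seg <- schedule$segments
  if (!nrow(seg)) {
    return(data.frame(kind = character(), start_s = numeric(),
                      end_s = numeric()))
  }
  ends <- session_start_s + cumsum(seg$minutes) * 60
  starts <- c(session_start_s, ends[-length(ends)])
  data.frame(kind = seg$kind, start_s = starts, end_s = ends)
}

#' Thermocouple temperature trace with session annotation
#'
#' @param t_s Strictly increasing sample times (s).
#' @param temp_C Temperatures in degrees C; values outside the \[20, 45\]
#'   physiological sanity band are rejected.
#' @param segments Data frame annotating the session: columns `kind`,
#'   `start_s`, `end_s` (seconds on the trace clock). May be `NULL` for an
#'   unannotated trace.
#' @return Object of class `temperature_trace`.
#' @export
temperature_trace <- function(t_s, temp_C, segments = NULL) {
  stopifnot(length(t_s) == length(temp_C), length(t_s) >= 1L)
  if (any(diff(t_s) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  if (min(temp_C) < 20 || max(temp_C) > 45)
    stop("temperatures outside the [20, 45] degC sanity band", call. = FALSE)
  if (!is.null(segments))
    stopifnot(all(c("kind", "start_s", "end_s") %in% names(segments)))
  structure(list(samples = data.frame(t_s = t_s, temp_C = temp_C),
                 segments = segments),
            class = "temperature_trace")
}

trace_baseline <- function(trace, baseline_window_s) {
  if (is.null(trace$segments) ||
      !any(trace$segments$kind == "irradiation"))
    stop("trace has no irradiation segments annotated", call. = FALSE)
  s0 <- min(trace$segments$start_s[trace$segments$kind == "irradiation"])
  s <- trace$samples
  in_win <- s$t_s >= s0 - baseline_window_s & s$t_s < s0
  if (sum(in_win) < 3L)
    stop("baseline window empty (needs >= 3 samples before first irradiation)",
         call. = FALSE)
  list(baseline_C = mean(s$temp_C[in_win]), session_start_s = s0)
}

#' Maximum temperature rise during a session
#'
#' Baseline is the mean temperature over the `baseline_window_s` seconds
#' preceding the first irradiation segment; the rise is the maximum of
#' (T - baseline) over the session (from first irradiation onward). A trace
#' that only cools gives a negative value (not clamped). Rises above +0.5
#' degC are flagged, the conventional threshold for irreversible cortical
#' thermal damage; the flag never modifies the data.
#'
#' @param trace An annotated [temperature_trace()].
#' @param baseline_window_s Baseline window length (s).
#' @param smoothing_window_s Optional centered moving-average window applied
#'   before taking the maximum; 0 (default) uses the raw samples. The raw
#'   maximum of a long noisy trace carries an extreme-value bias of several
#'   noise SDs, so a window of 10-30 s is recommended for sampled
#'   thermocouple data.
#' @return List with `rise_C`, `baseline_C` and logical `thermal_flag`.
#' @export
max_temperature_rise <- function(trace, baseline_window_s = 60,
                                 smoothing_window_s = 0) {
  stopifnot(inherits(trace, "temperature_trace"))
  bl <- trace_baseline(trace, baseline_window_s)
  s <- trace$samples
  temp <- s$temp_C
  if (smoothing_window_s > 0 && nrow(s) > 2L) {
    dt <- stats::median(diff(s$t_s))
    k <- max(1L, round(smoothing_window_s / dt))
    if (k > 1L) {
      sm <- as.numeric(stats::filter(temp, rep(1 / k, k), sides = 2))
      for (i in which(is.na(sm))) {     # truncated windows at the edges
        half <- floor(k / 2)
        w <- max(1L, i - half):min(length(temp), i + half)
        sm[i] <- mean(temp[w])
      }
      temp <- sm
    }
  }
  sess <- s$t_s >= bl$session_start_s
  if (!any(sess)) stop("no samples during session", call. = FALSE)
  rise <- max(temp[sess]) - bl$baseline_C
  list(rise_C = rise, baseline_C = bl$baseline_C, thermal_flag = rise > 0.5)
}

#' Mean temperature rise during irradiation
#'
#' Mean of (T - baseline) over samples inside irradiation segments; the
#' whole-session mean (irradiation plus pauses) is reported alongside since
#' either averaging convention is defensible.
#'
#' @param trace An annotated [temperature_trace()].
#' @param baseline_window_s Baseline window length (s).
#' @return List with `rise_C` (irradiation segments only),
#'   `session_rise_C` (whole session) and `baseline_C`.
#' @export
mean_temperature_rise <- function(trace, baseline_window_s = 60) {
  stopifnot(inherits(trace, "temperature_trace"))
  bl <- trace_baseline(trace, baseline_window_s)
  s <- trace$samples
  irr <- rep(FALSE, nrow(s))
  seg <- trace$segments
  for (i in which(seg$kind == "irradiation"))
    irr <- irr | (s$t_s >= seg$start_s[i] & s$t_s < seg$end_s[i])
  if (!any(irr)) stop("no samples inside irradiation segments", call. = FALSE)
  sess <- s$t_s >= bl$session_start_s & s$t_s < max(seg$end_s)
  list(rise_C = mean(s$temp_C[irr]) - bl$baseline_C,
       session_rise_C = mean(s$temp_C[sess]) - bl$baseline_C,
       baseline_C = bl$baseline_C)
}

#' Tracer intensity time course in a region of interest
#'
#' For each timepoint image: mean intensity inside `roi` minus mean inside
#' `background_roi`, clamped at 0 (background subtraction makes the series
#' invariant to adding a constant to the whole image). Optionally normalized
#' to the series maximum for cross-animal comparison.
#'
#' @param images List of [vessel_image()]s (or matrices) sharing one shape.
#' @param times_min Acquisition times in minutes, one per image.
#' @param roi,background_roi Non-empty [binary_mask()]s on the same grid.
#' @param normalize `"none"` (raw background-subtracted means, default) or
#'   `"max"`.
#' @return Data frame of class `intensity_series` with columns `t_min`,
#'   `roi_intensity`, `background_intensity`, `net_intensity`.
#' @export
roi_timecourse <- function(images, times_min, roi, background_roi,
                           normalize = c("none", "max")) {
  normalize <- match.arg(normalize)
  stopifnot(length(images) == length(times_min))
  if (any(diff(times_min) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  rm_ <- as_mask_array(roi); bm_ <- as_mask_array(background_roi)
  if (sum(rm_) == 0L || sum(bm_) == 0L) stop("empty ROI", call. = FALSE)
  px <- lapply(images, function(im)
    if (inherits(im, "vessel_image")) im$pixels else im)
  shapes <- vapply(px, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L ||
      !identical(dim(px[[1L]]), dim(rm_)) || !identical(dim(px[[1L]]), dim(bm_)))
    stop("image/ROI shape mismatch", call. = FALSE)
  roi_mean <- vapply(px, function(p) mean(p[rm_ == 1L]), 0)
  bg_mean <- vapply(px, function(p) mean(p[bm_ == 1L]), 0)
  net <- pmax(roi_mean - bg_mean, 0)
  if (normalize == "max" && max(net) > 0) net <- net / max(net)
  structure(data.frame(t_min = times_min, roi_intensity = roi_mean,
                       background_intensity = bg_mean, net_intensity = net),
            normalize = normalize,
            class = c("intensity_series", "data.frame"))
}
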