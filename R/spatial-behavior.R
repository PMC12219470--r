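#' Per-frame locomotion speed and session running speed
#'
#' Speed is the absolute central-difference gradient of the track-axis
#' position, converted from pixels to cm using the track length, times the
#' frame rate.  The session running speed is the 95th percentile of the
#' per-frame speed, a statistic robust to acceleration and deceleration
#' phases.
#'
#' @param traj A `duo_trajectory` (or data.frame with `x_px` and attributes
#'   `fps`, `track_length_cm`).
#' @return List with `speed` (cm/s per frame) and `running_speed` (cm/s).
#' @export
compute_speed <- function(traj) {
  assert_that(nrow(traj) >= 2, "insufficient frames: need at least 2")
  fps <- attr(traj, "fps")
  pos_cm <- track_cm(traj)
  grad <- position_gradient(pos_cm)
  speed <- abs(grad) * fps
  list(speed = speed,
       running_speed = unname(stats::quantile(speed, 0.95)))
}

# Track-axis position in cm, scaled from the pixel range to the track
# length (an animal covers the full track within a session).  A stationary
# trajectory (zero pixel range) maps to a constant position.
#' @keywords internal
#' @noRd
track_cm <- function(traj) {
  rng <- diff(range(traj$x_px))
  if (rng == 0) return(rep(0, nrow(traj)))
  (traj$x_px - min(traj$x_px)) * attr(traj, "track_length_cm") / rng
}

# Central-difference gradient with one-sided differences at the ends.
#' @keywords internal
#' @noRd
position_gradient <- function(x) {
  n <- length(x)
  g <- numeric(n)
  if (n >= 3) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  g[1] <- x[2] - x[1]
  g[n] <- x[n] - x[n - 1]
  g
}

#' Classify behaviour frames as idle / running left / running right
#'
#' A frame is idle when the (5-frame moving-average smoothed) speed is at
#' or below the threshold; otherwise the sign of the position gradient
#' along the track axis sets the direction.  "Right" means increasing
#' linearized position.
#'
#' @param traj A `duo_trajectory`.
#' @param threshold_cm_s Speed threshold; default 3 cm/s.
#' @param smooth_frames Moving-average window for the speed (odd integer).
#' @return Character vector per frame in `{"idle", "left", "right"}`.
#' @export
classify_behavior <- function(traj, threshold_cm_s = 3, smooth_frames = 5) {
  fps <- attr(traj, "fps")
  pos_cm <- track_cm(traj)
  grad <- position_gradient(pos_cm)
  speed <- abs(grad) * fps
  sm <- moving_average(speed, smooth_frames)
  lab <- rep("idle", nrow(traj))
  run <- sm > threshold_cm_s      # speed exactly at threshold -> idle
  lab[run & grad > 0] <- "right"
  lab[run & grad <= 0] <- "left"
  lab
}

#' @keywords internal
#' @noRd
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  # sum with unit weights, then divide: exact when x is constant
  out <- as.numeric(stats::filter(x, rep(1, w), sides = 2)) / w
  half <- floor(w / 2)
  n <- length(x)
  for (i in seq_len(min(half, n))) {
    out[i] <- mean(x[1:min(n, i + half)])
    out[n - i + 1] <- mean(x[max(1, n - i + 1 - half):n])
  }
  out
}

#' Linearize position with direction-specific mapping
#'
#' Projects position onto the track axis, rescales to `[0, 100)`
#' cm-equivalents, and offsets frames classified as running right by +100
#' so each running direction occupies its own half of the `[0, 200)` range.
#' Idle frames are `NA`.
#'
#' @param traj A `duo_trajectory`.
#' @param behavior Optional precomputed labels from [classify_behavior()].
#' @return Numeric vector per frame in `[0, 200)`, `NA` when idle.
#' @export
linearize_position <- function(traj, behavior = NULL) {
  if (is.null(behavior)) behavior <- classify_behavior(traj)
  lin <- track_cm(traj) / attr(traj, "track_length_cm") * 100
  lin <- pmin(lin, 100 - 1e-9)
  out <- rep(NA_real_, length(lin))
  out[behavior == "left"] <- lin[behavior == "left"]
  out[behavior == "right"] <- lin[behavior == "right"] + 100
  out
}

#' Detect linear-track trials
#'
#' A trial completes each time the animal enters the end zone (outer
#' `end_zone_cm` of the track) opposite to the previously visited end.
#' Frames between completions are assigned a running trial id.
#'
#' @param traj A `duo_trajectory`.
#' @param end_zone_cm End-zone depth; default 10 cm.
#' @return List with `trial_id` (integer per frame; the trial in progress,
#'   starting at 1) and `n_trials` (completed end-to-end visits).
#' @export
detect_trials <- function(traj, end_zone_cm = 10) {
  L <- attr(traj, "track_length_cm")
  pos <- track_cm(traj)
  in_low <- pos <= end_zone_cm
  in_high <- pos >= L - end_zone_cm
  last_end <- if (in_low[1]) "low" else if (in_high[1]) "high" else "none"
  n_trials <- 0L
  trial_id <- integer(length(pos))
  for (t in seq_along(pos)) {
    end_here <- if (in_low[t]) "low" else if (in_high[t]) "high" else "none"
    if (end_here != "none" && end_here != last_end && last_end != "none") {
      n_trials <- n_trials + 1L
    }
    if (end_here != "none") last_end <- end_here
    trial_id[t] <- n_trials + 1L
  }
  list(trial_id = trial_id, n_trials = n_trials)
}

#' Annotate a trajectory with speed, behaviour, linear position and trials
#'
#' Convenience wrapper running [compute_speed()], [classify_behavior()],
#' [linearize_position()] and [detect_trials()] and storing the results as
#' columns.
#'
#' @param traj A `duo_trajectory`.
#' @param speed_threshold_cm_s Idle threshold for behaviour labels.
#' @param end_zone_cm End-zone depth for trial detection.
#' @return The trajectory with added columns `speed`, `behavior`, `linpos`,
#'   `trial_id`, and attributes `running_speed`, `n_trials`.
#' @export
annotate_trajectory <- function(traj, speed_threshold_cm_s = 3,
                                end_zone_cm = 10) {
  sp <- compute_speed(traj)
  beh <- classify_behavior(traj, speed_threshold_cm_s)
  lin <- linearize_position(traj, beh)
  tr <- detect_trials(traj, end_zone_cm)
  traj$speed <- sp$speed
  traj$behavior <- beh
  traj$linpos <- lin
  traj$trial_id <- tr$trial_id
  attr(traj, "running_speed") <- sp$running_speed
  attr(traj, "n_trials") <- tr$n_trials
  traj
}
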