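#' Simulate a linear-track trajectory
#'
#' Generates a back-and-forth run on a linear track with pauses at both
#' ends, emulating an animal shuttling for rewards at the two track ends.
#' Within each traversal the speed is constant, drawn from
#' `N(run_speed_cm_s, run_speed_sd)`; pause durations are exponential with
#' mean `pause_mean_s`.  The x pixel coordinate is the track axis
#' (`px_per_cm` pixels per cm); y holds small camera noise.
#'
#' @param config A [duo_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `duo_trajectory`: a data.frame with columns `frame`, `x_px`,
#'   `y_px` and attributes `fps`, `track_length_cm`, `px_per_cm`, and
#'   `planted` (list with `lap_count`, the number of completed end-to-end
#'   traversals, and `run_speed_cm_s`).
#' @seealso [compute_speed()], [classify_behavior()], [linearize_position()]
#' @export
simulate_trajectory <- function(config, seed = config$seed) {
  assert_that(inherits(config, "duo_config"), "config must be a duo_config")
  assert_that(config$session_duration_s > 0 && config$fps > 0,
              "invalid config: non-positive duration or fps")
  n_frames <- round(config$session_duration_s * config$fps)
  L <- config$track_length_cm
  dt <- 1 / config$fps

  with_seed(derive_seed(seed, "trajectory"), {
    pos <- numeric(0)
    at <- 0          # current position, cm
    heading <- 1     # +1 toward L, -1 toward 0
    laps <- 0L
    while (length(pos) < n_frames) {
      # pause at the current end
      if (config$pause_mean_s > 0) {
        p_dur <- stats::rexp(1, 1 / config$pause_mean_s)
        n_p <- round(p_dur * config$fps)
        if (n_p > 0) pos <- c(pos, rep(at, n_p))
      }
      if (length(pos) >= n_frames) break
      # one traversal at constant speed
      v <- max(5, stats::rnorm(1, config$run_speed_cm_s, config$run_speed_sd))
      step <- v * dt * heading
      run <- seq(at + step, by = step,
                 length.out = ceiling(abs((ifelse(heading > 0, L, 0) - at) / step)))
      run <- pmin(pmax(run, 0), L)
      target <- if (heading > 0) L else 0
      # a lap counts only if the run reaches the far end inside the budget
      n_keep <- min(length(run), n_frames - length(pos))
      if (n_keep > 0 && any(run[seq_len(n_keep)] == target)) laps <- laps + 1L
      pos <- c(pos, run)
      at <- ifelse(heading > 0, L, 0)
      heading <- -heading
    }
    pos <- pos[seq_len(n_frames)]
    y <- config$fov_shape[1] / 2 + stats::rnorm(n_frames, 0, 0.5)
    traj <- data.frame(frame = seq_len(n_frames) - 1L,
                       x_px = pos * config$px_per_cm,
                       y_px = y)
    attr(traj, "fps") <- config$fps
    attr(traj, "track_length_cm") <- L
    attr(traj, "px_per_cm") <- config$px_per_cm
    attr(traj, "planted") <- list(lap_count = laps,
                                  run_speed_cm_s = config$run_speed_cm_s)
    class(traj) <- c("duo_trajectory", "data.frame")
    traj
  })
}

#' @export
print.duo_trajectory <- function(x, ...) {
  cat(sprintf("<duo_trajectory> %d frames @ %s fps, track %s cm\n",
              nrow(x), format(attr(x, "fps")),
              format(attr(x, "track_length_cm"))))
  invisible(x)
}
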