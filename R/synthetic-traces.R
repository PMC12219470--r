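#' Calcium indicator impulse response
#'
#' Difference-of-exponentials kernel `(1 - exp(-t/rise)) * exp(-t/decay)`
#' normalized to unit peak, sampled at the frame rate and truncated at five
#' decay constants.
#'
#' @param fps Frames per second.
#' @param rise_s,decay_s Time constants in seconds.
#' @return Numeric vector of kernel taps (first tap at lag 0).
#' @export
calcium_kernel <- function(fps, rise_s = 0.05, decay_s = 0.4) {
  t <- seq(0, 5 * decay_s, by = 1 / fps)
  h <- (1 - exp(-t / rise_s)) * exp(-t / decay_s)
  h / max(h)
}

# Causal convolution of an event train with a kernel.
#' @keywords internal
#' @noRd
convolve_events <- function(events, kernel) {
  out <- as.numeric(stats::filter(events, kernel,
                                  method = "convolution", sides = 1))
  # filter(sides = 1) leaves NA for the first length(kernel)-1 frames
  k <- length(kernel)
  for (t in seq_len(min(k - 1, length(events)))) {
    out[t] <- sum(events[t:1] * kernel[seq_len(t)])
  }
  out
}

#' Simulate dynamic- and static-channel traces for one session
#'
#' Active tuned cells emit Poisson events whose rate follows a Gaussian
#' tuning curve of track position, only while the animal runs in the cell's
#' preferred direction; untuned active cells emit homogeneous events;
#' inactive cells emit none.  Dynamic-channel fluorescence is the event
#' train convolved with the indicator kernel plus baseline and white noise.
#' The static-channel trace is a constant per-cell baseline plus a slow
#' sinusoidal drift, plus `crosstalk_alpha` times the dynamic-channel
#' fluorescence, plus white noise.
#'
#' @param truth A `duo_truth` from [simulate_population()].
#' @param traj A `duo_trajectory` for this session.
#' @param config The [duo_config()].
#' @param session Session index (1-based).
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `duo_session` list with elements `session`, `day`,
#'   `trajectory`, `events` (deconvolved-style event TraceSet, active cells
#'   only), `gcamp_fluor` (fluorescence TraceSet, active cells only),
#'   `static_traces` (TraceSet, all cells; attribute `baseline` holds the
#'   noise- and crosstalk-free baseline-plus-drift matrix),
#'   `footprints_gcamp` (active cells), `footprints_static` (all cells).
#'   Footprint lists carry an attribute `true_cell` mapping local index to
#'   ground-truth cell.
#' @export
simulate_session_traces <- function(truth, traj, config, session,
                                    seed = config$seed) {
  assert_that(inherits(truth, "duo_truth"), "truth must be a duo_truth")
  assert_that(session >= 1 && session <= ncol(truth$active_matrix),
              "session index out of range")
  n_frames <- nrow(traj)
  fps <- attr(traj, "fps")
  pos_cm <- traj$x_px / attr(traj, "px_per_cm")
  v <- c(0, diff(pos_cm)) * fps
  moving_right <- v > 3
  moving_left <- v < -3

  n <- nrow(truth$base_centroids)
  active <- truth$active_matrix[, session]
  kernel <- calcium_kernel(fps, config$kernel_rise_s, config$kernel_decay_s)

  events <- matrix(0, n, n_frames)
  fluor <- matrix(0, n, n_frames)
  for (cell in seq_len(n)) {
    sub_seed <- derive_seed(seed, "traces", session, cell)
    if (!active[cell]) next
    rate <- if (truth$tuned_mask[cell]) {
      on_dir <- if (truth$field_direction[cell] == "right") moving_right else moving_left
      center_s <- truth$field_centers_by_session[cell, session]
      bump <- exp(-(pos_cm - center_s)^2 / (2 * config$field_width_cm^2))
      config$base_rate_hz +
        (config$peak_rate_hz - config$base_rate_hz) * bump * on_dir
    } else {
      rep(config$untuned_rate_hz, n_frames)
    }
    ev <- with_seed(sub_seed, {
      counts <- stats::rpois(n_frames, rate / fps)
      amps <- stats::runif(n_frames, config$event_amp_range[1],
                           config$event_amp_range[2])
      counts * amps
    })
    events[cell, ] <- ev
    fluor[cell, ] <- convolve_events(ev, kernel)
  }

  noise_g <- if (config$noise_sd > 0)
    with_seed(derive_seed(seed, "gnoise", session),
              matrix(stats::rnorm(n * n_frames, 0, config$noise_sd), n, n_frames))
  else matrix(0, n, n_frames)
  gcamp_fluor <- 1 + fluor + noise_g   # unit baseline in the dynamic channel

  tt <- seq_len(n_frames) / fps
  phases <- with_seed(derive_seed(seed, "drift", session),
                      stats::runif(n, 0, 2 * pi))
  drift <- truth$static_baselines * config$static_drift_frac *
    sin(outer(phases, 2 * pi * tt / (n_frames / fps), function(p, w) w + p))
  baseline <- truth$static_baselines + drift
  noise_s <- if (config$noise_sd > 0)
    with_seed(derive_seed(seed, "snoise", session),
              matrix(stats::rnorm(n * n_frames, 0, config$noise_sd), n, n_frames))
  else matrix(0, n, n_frames)
  static <- baseline + truth$crosstalk_alpha * gcamp_fluor + noise_s

  act_idx <- which(active)
  ev_set <- trace_set(events[act_idx, , drop = FALSE], "deconvolved", fps)
  attr(ev_set, "true_cell") <- act_idx
  fl_set <- trace_set(gcamp_fluor[act_idx, , drop = FALSE], "denoised", fps)
  attr(fl_set, "true_cell") <- act_idx
  st_set <- trace_set(static, "raw-projected", fps)
  attr(st_set, "baseline") <- baseline
  attr(st_set, "true_cell") <- seq_len(n)

  structure(list(
    session = session,
    day = (session - 1) * config$session_interval_days,
    trajectory = traj,
    events = ev_set,
    gcamp_fluor = fl_set,
    static_traces = st_set,
    footprints_gcamp = truth_footprints(truth, config, session, "gcamp", act_idx),
    footprints_static = truth_footprints(truth, config, session, "static")
  ), class = "duo_session")
}

#' Temporal trace container
#'
#' @param values Numeric cells x frames matrix.
#' @param kind One of `"raw-projected"`, `"denoised"`, `"deconvolved"`.
#' @param fps Frames per second.
#' @return The matrix with class `duo_traces` and attributes `kind`, `fps`.
#' @export
trace_set <- function(values, kind = c("raw-projected", "denoised", "deconvolved"),
                      fps) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  assert_that(all(is.finite(values)), "traces must be finite")
  if (kind == "deconvolved")
    assert_that(all(values >= 0), "deconvolved traces must be non-negative")
  structure(values, kind = kind, fps = fps, class = c("duo_traces", "matrix"))
}

#' Render per-channel movies from footprints and traces
#'
#' Frame `t` is the sum over cells of `footprint * trace[cell, t]` plus
#' optional pixel noise.  Intended for small fields of view; memory grows as
#' `prod(fov_shape) * frames`.
#'
#' @param footprints List of `duo_footprint`.
#' @param traces Matrix (cells x frames) aligned with `footprints`.
#' @param noise_sd Pixel noise SD.
#' @param seed Seed for the pixel noise.
#' @return 3D array `(rows, cols, frames)`.
#' @export
render_movie <- function(footprints, traces, noise_sd = 0, seed = 1L) {
  assert_that(length(footprints) == nrow(traces),
              "one footprint per trace row required")
  fov <- footprints[[1]]$fov_shape
  n_frames <- ncol(traces)
  mov <- array(0, c(fov[1], fov[2], n_frames))
  for (i in seq_along(footprints)) {
    fp <- footprints[[i]]
    assert_that(all(fp$fov_shape == fov), "geometry error: FOV shapes differ")
    rows <- fp$origin[1] + seq_len(nrow(fp$weights)) - 1L
    cols <- fp$origin[2] + seq_len(ncol(fp$weights)) - 1L
    mov[rows, cols, ] <- mov[rows, cols, ] +
      outer(fp$weights, traces[i, ])
  }
  if (noise_sd > 0) {
    mov <- mov + with_seed(derive_seed(seed, "movie"),
                           array(stats::rnorm(length(mov), 0, noise_sd), dim(mov)))
  }
  mov
}

#' Render a static-channel summary image for one session
#'
#' The mean projection of the static movie equals the footprint-weighted
#' mean trace; rendering it directly avoids materializing the movie.
#'
#' @param session A `duo_session`.
#' @param noise_sd Pixel noise on the summary image (noise on a mean image
#'   is `noise_sd/sqrt(frames)`-scale; default 0.01).
#' @param seed Seed for the pixel noise.
#' @return 2D matrix of the field of view.
#' @export
render_static_summary <- function(session, noise_sd = 0.01, seed = 1L) {
  fov <- session$footprints_static[[1]]$fov_shape
  img <- matrix(0, fov[1], fov[2])
  mean_tr <- rowMeans(session$static_traces)
  for (i in seq_along(session$footprints_static)) {
    fp <- session$footprints_static[[i]]
    rows <- fp$origin[1] + seq_len(nrow(fp$weights)) - 1L
    cols <- fp$origin[2] + seq_len(ncol(fp$weights)) - 1L
    # footprint amplitude already carries the baseline level; scale the
    # weight map to unit peak before multiplying by the mean trace
    w <- fp$weights / max(fp$weights)
    img[rows, cols] <- img[rows, cols] + w * mean_tr[i]
  }
  if (noise_sd > 0) {
    img <- img + with_seed(derive_seed(seed, "summary", session$session),
                           matrix(stats::rnorm(length(img), 0, noise_sd),
                                  nrow(img), ncol(img)))
  }
  img
}

#' Simulate a full multi-session experiment
#'
#' One trajectory and one set of traces per session, sharing a single
#' ground truth.  Day indices run `0, interval, 2*interval, ...`.
#'
#' @param config A [duo_config()].
#' @return A `duo_experiment` list with `sessions` (list of `duo_session`),
#'   `truth` and `config`.
#' @export
simulate_experiment <- function(config) {
  truth <- simulate_population(config)
  sessions <- lapply(seq_len(config$n_sessions), function(s) {
    traj <- simulate_trajectory(config, seed = derive_seed(config$seed, "traj", s))
    simulate_session_traces(truth, traj, config, s)
  })
  structure(list(sessions = sessions, truth = truth, config = config),
            class = "duo_experiment")
}

#' @export
print.duo_session <- function(x, ...) {
  cat(sprintf("<duo_session> #%d (day %s): %d active / %d cells, %d frames\n",
              x$session, format(x$day), nrow(x$events),
              nrow(x$static_traces), ncol(x$static_traces)))
  invisible(x)
}

#' @export
print.duo_experiment <- function(x, ...) {
  cat(sprintf("<duo_experiment> %d sessions, %d cells\n",
              length(x$sessions), nrow(x$truth$base_centroids)))
  invisible(x)
}
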