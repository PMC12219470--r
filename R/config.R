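#' Experiment configuration for the synthetic dual-channel generator
#'
#' Bundles every tunable of the synthetic world into one validated object.
#' The defaults describe the reference in-vivo design this package targets:
#' seven 15-minute sessions at 30 frames/s recorded every other day
#' (spanning 13 calendar days), roughly 150 cells per channel in the field
#' of view, and a 1-m linear track.
#'
#' @param n_sessions Number of recording sessions (>= 1).
#' @param session_interval_days Days between consecutive sessions.
#' @param session_duration_s Session length in seconds.
#' @param fps Imaging frame rate, frames per second.
#' @param n_cells Number of ground-truth cells in the field of view.
#' @param fov_shape Field-of-view size in pixels, `c(height, width)`.
#' @param track_length_cm Linear track length in cm.
#' @param place_cell_fraction Fraction of cells given a planted place field.
#' @param field_width_cm Gaussian tuning-curve width (sigma) in cm.
#' @param activity_prob Per-session probability that a cell is active
#'   (GCaMP channel); the static marker is constitutive and unaffected.
#' @param activity_corr Session-to-session autocorrelation of the active
#'   state (first-order Markov persistence); 0 gives independent sessions,
#'   positive values make reactivation decay with time interval.
#' @param field_jitter_cm Per-session SD of the random walk of planted
#'   field centres (representational drift of the spatial code).
#' @param crosstalk_alpha Planted linear leak of dynamic-channel
#'   fluorescence into the static channel, dimensionless in `[0, 1)`.
#' @param fov_jitter_px Maximum rigid field-of-view translation per session
#'   (uniform in `[-j, j]` per axis).
#' @param noise_sd Additive white-noise SD on traces, fluorescence a.u.
#' @param seed Master seed; every stochastic stage derives a sub-seed.
#' @param run_speed_cm_s Mean running speed on the track.
#' @param run_speed_sd SD of the per-run speed draw.
#' @param pause_mean_s Mean pause duration at each track end (0 = no pause).
#' @param min_separation_px Minimum pairwise centroid separation.
#' @param footprint_sigma_px Gaussian footprint sigma, dynamic channel.
#' @param static_sigma_px Gaussian footprint sigma, static (nuclear) channel.
#' @param kernel_rise_s,kernel_decay_s Calcium-indicator kernel time
#'   constants (exponential rise / decay), seconds.
#' @param peak_rate_hz In-field event rate of a tuned cell.
#' @param base_rate_hz Out-of-field / off-direction event rate.
#' @param untuned_rate_hz Homogeneous event rate of untuned active cells.
#' @param static_baseline,static_baseline_sd Mean and SD of the per-cell
#'   static-channel baseline fluorescence.
#' @param static_drift_frac Amplitude of the slow sinusoidal drift of the
#'   static baseline, as a fraction of the baseline.
#' @param event_amp_range Uniform range of per-event amplitudes.
#' @param px_per_cm Pixel scale of the behaviour camera.
#'
#' @return An object of class `duo_config` (a validated named list).
#' @examples
#' cfg <- duo_config(n_sessions = 3, session_duration_s = 60, fps = 10,
#'                   n_cells = 20, fov_shape = c(80, 80))
#' cfg$n_sessions
#' @export
duo_config <- function(n_sessions = 7,
                       session_interval_days = 2,
                       session_duration_s = 900,
                       fps = 30,
                       n_cells = 150,
                       fov_shape = c(300, 300),
                       track_length_cm = 100,
                       place_cell_fraction = 0.4,
                       field_width_cm = 8,
                       activity_prob = 0.7,
                       activity_corr = 0.5,
                       field_jitter_cm = 2,
                       crosstalk_alpha = 0.05,
                       fov_jitter_px = 2,
                       noise_sd = 0.1,
                       seed = 1L,
                       run_speed_cm_s = 45,
                       run_speed_sd = 1,
                       pause_mean_s = 2,
                       min_separation_px = 10,
                       footprint_sigma_px = 3,
                       static_sigma_px = 2,
                       kernel_rise_s = 0.05,
                       kernel_decay_s = 0.4,
                       peak_rate_hz = 2,
                       base_rate_hz = 0.02,
                       untuned_rate_hz = 0.2,
                       static_baseline = 2,
                       static_baseline_sd = 0.2,
                       static_drift_frac = 0.02,
                       event_amp_range = c(0.5, 1.5),
                       px_per_cm = 4) {
  cfg <- list(
    n_sessions = as.integer(n_sessions),
    session_interval_days = session_interval_days,
    session_duration_s = session_duration_s,
    fps = fps,
    n_cells = as.integer(n_cells),
    fov_shape = as.integer(fov_shape),
    track_length_cm = track_length_cm,
    place_cell_fraction = place_cell_fraction,
    field_width_cm = field_width_cm,
    activity_prob = activity_prob,
    activity_corr = activity_corr,
    field_jitter_cm = field_jitter_cm,
    crosstalk_alpha = crosstalk_alpha,
    fov_jitter_px = fov_jitter_px,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    run_speed_cm_s = run_speed_cm_s,
    run_speed_sd = run_speed_sd,
    pause_mean_s = pause_mean_s,
    min_separation_px = min_separation_px,
    footprint_sigma_px = footprint_sigma_px,
    static_sigma_px = static_sigma_px,
    kernel_rise_s = kernel_rise_s,
    kernel_decay_s = kernel_decay_s,
    peak_rate_hz = peak_rate_hz,
    base_rate_hz = base_rate_hz,
    untuned_rate_hz = untuned_rate_hz,
    static_baseline = static_baseline,
    static_baseline_sd = static_baseline_sd,
    static_drift_frac = static_drift_frac,
    event_amp_range = event_amp_range,
    px_per_cm = px_per_cm
  )
  class(cfg) <- "duo_config"
  validate_config(cfg)
  cfg
}

#' Desk-scale demonstration configuration
#'
#' Same world as [duo_config()] but with 5-minute sessions at 15 frames/s so
#' the full pipeline runs end-to-end in minutes on one CPU.
#'
#' @param ... Overrides forwarded to [duo_config()].
#' @return A `duo_config`.
#' @export
duo_config_demo <- function(...) {
  duo_config(session_duration_s = 300, fps = 15, ...)
}

#' @keywords internal
#' @noRd
validate_config <- function(cfg) {
  assert_that(cfg$n_sessions >= 1L, "invalid config: n_sessions must be >= 1")
  assert_that(cfg$session_duration_s > 0 && cfg$fps > 0,
              "invalid config: session duration and fps must be positive")
  assert_that(cfg$n_cells >= 1L, "invalid config: n_cells must be >= 1")
  assert_that(length(cfg$fov_shape) == 2L && all(cfg$fov_shape > 0),
              "invalid config: fov_shape must be two positive integers")
  assert_that(cfg$track_length_cm > 0 && cfg$field_width_cm > 0 &&
                cfg$px_per_cm > 0,
              "invalid config: lengths must be positive")
  assert_that(cfg$place_cell_fraction >= 0 && cfg$place_cell_fraction <= 1,
              "invalid config: place_cell_fraction must be in [0, 1]")
  assert_that(cfg$activity_prob >= 0 && cfg$activity_prob <= 1,
              "invalid config: activity_prob must be in [0, 1]")
  assert_that(cfg$activity_corr >= 0 && cfg$activity_corr <= 1,
              "invalid config: activity_corr must be in [0, 1]")
  assert_that(cfg$field_jitter_cm >= 0,
              "invalid config: field_jitter_cm must be non-negative")
  assert_that(cfg$crosstalk_alpha >= 0 && cfg$crosstalk_alpha < 1,
              "invalid config: crosstalk_alpha must be in [0, 1)")
  assert_that(cfg$fov_jitter_px >= 0 && cfg$noise_sd >= 0,
              "invalid config: jitter and noise must be non-negative")
  invisible(cfg)
}

#' @export
print.duo_config <- function(x, ...) {
  cat("<duo_config>\n")
  cat(sprintf("  %d sessions every %s d; %ss at %s fps; %d cells in %dx%d px\n",
              x$n_sessions, format(x$session_interval_days),
              format(x$session_duration_s), format(x$fps), x$n_cells,
              x$fov_shape[1], x$fov_shape[2]))
  cat(sprintf("  track %s cm; place fraction %s; activity prob %s; crosstalk %s\n",
              format(x$track_length_cm), format(x$place_cell_fraction),
              format(x$activity_prob), format(x$crosstalk_alpha)))
  invisible(x)
}
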