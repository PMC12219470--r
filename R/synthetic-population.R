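#' Simulate the ground-truth cell population
#'
#' Samples cell body locations with a minimum pairwise separation, assigns
#' place-field tuning to a fraction of cells (field centre plus preferred
#' running direction), draws the per-session activity schedule for the
#' dynamic channel, and draws one rigid field-of-view translation per
#' session.
#'
#' @param config A [duo_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `duo_truth` list:
#'   \describe{
#'     \item{base_centroids}{n_cells x 2 matrix, jitter-free `(row, col)`.}
#'     \item{session_shifts}{n_sessions x 2 matrix of rigid shifts (px).}
#'     \item{tuned_mask}{logical per cell.}
#'     \item{field_centers_cm}{session-1 field centre on the track (NA if
#'       untuned).}
#'     \item{field_centers_by_session}{n_cells x n_sessions matrix of
#'       drifting field centres (random walk, SD `field_jitter_cm`/session).}
#'     \item{field_direction}{"left" or "right" (NA if untuned).}
#'     \item{active_matrix}{logical n_cells x n_sessions.}
#'     \item{static_baselines}{per-cell static-channel baseline level.}
#'     \item{crosstalk_alpha}{copied from the config.}
#'   }
#' @export
simulate_population <- function(config, seed = config$seed) {
  assert_that(inherits(config, "duo_config"), "config must be a duo_config")
  n <- config$n_cells
  fov <- config$fov_shape
  sep <- config$min_separation_px
  margin <- ceiling(3 * config$footprint_sigma_px + config$fov_jitter_px + 2)
  assert_that(fov[1] > 2 * margin && fov[2] > 2 * margin,
              "fov too small for footprint margin")
  # crude packing feasibility check before attempting rejection sampling
  capacity <- ((fov[1] - 2 * margin) / sep + 1) * ((fov[2] - 2 * margin) / sep + 1)
  if (n > 0.7 * capacity)
    stop("packing error: too many cells for the requested minimum separation",
         call. = FALSE)

  with_seed(derive_seed(seed, "population"), {
    pts <- matrix(NA_real_, n, 2)
    placed <- 0L
    attempts <- 0L
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > 200L * n)
        stop("packing error: could not place cells at the minimum separation",
             call. = FALSE)
      cand <- c(stats::runif(1, margin, fov[1] - margin),
                stats::runif(1, margin, fov[2] - margin))
      if (placed == 0L ||
          min(sqrt((pts[seq_len(placed), 1] - cand[1])^2 +
                     (pts[seq_len(placed), 2] - cand[2])^2)) >= sep) {
        placed <- placed + 1L
        pts[placed, ] <- cand
      }
    }

    tuned <- rep(FALSE, n)
    n_tuned <- round(config$place_cell_fraction * n)
    if (n_tuned > 0) tuned[sample.int(n, n_tuned)] <- TRUE
    centers <- rep(NA_real_, n)
    direction <- rep(NA_character_, n)
    centers[tuned] <- stats::runif(sum(tuned), 0.1 * config$track_length_cm,
                                   0.9 * config$track_length_cm)
    direction[tuned] <- sample(c("left", "right"), sum(tuned), replace = TRUE)

    shifts <- matrix(0, config$n_sessions, 2)
    if (config$fov_jitter_px > 0 && config$n_sessions > 1) {
      shifts[-1, ] <- stats::runif(2 * (config$n_sessions - 1),
                                   -config$fov_jitter_px, config$fov_jitter_px)
    }

    # per-cell activity substreams: adding cells does not reshuffle others.
    # active state is a stationary first-order Markov chain with marginal
    # activity_prob and one-step autocorrelation activity_corr, so the
    # expected reactivation rate decays with session separation
    k <- config$n_sessions
    p_act <- config$activity_prob
    r_act <- config$activity_corr
    active <- matrix(FALSE, n, k)
    for (cell in seq_len(n)) {
      active[cell, ] <- with_seed(derive_seed(seed, "activity", cell), {
        s <- logical(k)
        s[1] <- stats::runif(1) < p_act
        for (j in seq_len(k)[-1]) {
          pp <- if (s[j - 1]) p_act + r_act * (1 - p_act) else p_act * (1 - r_act)
          s[j] <- stats::runif(1) < pp
        }
        s
      })
    }

    # representational drift: field centres random-walk across sessions
    centers_by_session <- matrix(NA_real_, n, k)
    for (cell in seq_len(n)) {
      if (!tuned[cell]) next
      centers_by_session[cell, ] <- with_seed(
        derive_seed(seed, "fielddrift", cell), {
          steps <- c(0, stats::rnorm(k - 1, 0, config$field_jitter_cm))
          pmin(pmax(centers[cell] + cumsum(steps),
                    0.05 * config$track_length_cm),
               0.95 * config$track_length_cm)
        })
    }

    baselines <- pmax(0.5, stats::rnorm(n, config$static_baseline,
                                        config$static_baseline_sd))

    structure(list(base_centroids = pts,
                   session_shifts = shifts,
                   tuned_mask = tuned,
                   field_centers_cm = centers,
                   field_centers_by_session = centers_by_session,
                   field_direction = direction,
                   active_matrix = active,
                   static_baselines = baselines,
                   crosstalk_alpha = config$crosstalk_alpha),
              class = "duo_truth")
  })
}

#' Ground-truth centroids for one session (after jitter)
#' @param truth A `duo_truth`.
#' @param session Session index.
#' @return n_cells x 2 matrix of `(row, col)` centroids.
#' @export
session_centroids <- function(truth, session) {
  assert_that(session >= 1 && session <= nrow(truth$session_shifts),
              "session index out of range")
  sweep(truth$base_centroids, 2, truth$session_shifts[session, ], "+")
}

# Footprint lists for one session of the synthetic world.
#' @keywords internal
#' @noRd
truth_footprints <- function(truth, config, session, channel = c("gcamp", "static"),
                             cells = seq_len(nrow(truth$base_centroids))) {
  channel <- match.arg(channel)
  sigma <- if (channel == "gcamp") config$footprint_sigma_px else config$static_sigma_px
  ctr <- session_centroids(truth, session)
  fps <- lapply(seq_along(cells), function(i) {
    cell <- cells[i]
    amp <- if (channel == "static") truth$static_baselines[cell] else 1
    gaussian_footprint(i, ctr[cell, ], sigma, config$fov_shape, amplitude = amp)
  })
  attr(fps, "true_cell") <- cells
  fps
}
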