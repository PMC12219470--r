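#' Cosine-kernel density estimate on the linearized track
#'
#' Weighted kernel density with the cosine kernel
#' `K(u) = (pi/4) * cos(pi * u / 2)` for `|u| <= 1`, `u = (x - x_s) / bw`,
#' evaluated at the `n_bins` bin centres `0.5, 1.5, ..., n_bins - 0.5` and
#' normalized to sum to one.  The default bandwidth (half-support) is 5 cm
#' at 1 cm/bin.
#'
#' @param samples Positions in `[0, limits[2])`; `NA`s are dropped.
#' @param weights Optional non-negative sample weights (e.g. deconvolved
#'   event amplitudes).
#' @param bandwidth Kernel half-support in cm.
#' @param n_bins Number of spatial bins (default 200, i.e. 1 cm/bin over
#'   both running directions).
#' @param limits Range of the linearized coordinate.
#' @return Numeric density per bin, summing to 1.
#' @export
estimate_density <- function(samples, weights = NULL, bandwidth = 5,
                             n_bins = 200, limits = c(0, 200)) {
  keep <- !is.na(samples)
  samples <- samples[keep]
  if (!is.null(weights)) {
    weights <- weights[keep]
    assert_that(all(weights >= 0), "weights must be non-negative")
  } else {
    weights <- rep(1, length(samples))
  }
  pos <- samples[weights > 0]
  w <- weights[weights > 0]
  if (length(pos) == 0L)
    stop("empty-density error: no samples with positive weight", call. = FALSE)
  assert_that(all(pos >= limits[1] & pos < limits[2]),
              "samples must lie inside the track limits")
  centers <- seq(limits[1] + 0.5 * diff(limits) / n_bins, limits[2],
                 by = diff(limits) / n_bins)
  dens <- cosine_kde(pos, w, centers, bandwidth)
  tot <- sum(dens)
  if (tot <= 0) stop("empty-density error: zero total mass", call. = FALSE)
  dens / tot
}

# Kernel evaluation shared by estimate_density and the vectorized shuffle
# machinery.  Returns unnormalized density at `centers`.
#' @keywords internal
#' @noRd
cosine_kde <- function(pos, w, centers, bandwidth) {
  as.numeric(crossprod(cosine_kernel_matrix(pos, centers, bandwidth), w))
}

# T x B matrix of kernel weights; row t holds K((centers - pos[t]) / bw).
# NA positions give all-zero rows.
#' @keywords internal
#' @noRd
cosine_kernel_matrix <- function(pos, centers, bandwidth) {
  u <- outer(pos, centers, function(p, c) (c - p) / bandwidth)
  k <- (pi / 4) * cos(pi * u / 2)
  k[!is.finite(k) | abs(u) > 1] <- 0
  k[k < 0] <- 0
  k
}

#' Occupancy and firing rate map for one cell
#'
#' Occupancy is the kernel density of the linearized position over all
#' non-idle frames; spatial firing activity is the kernel density of the
#' positions at frames with events, weighted by the deconvolved amplitude.
#' Both sum to one over bins.  Bins with occupancy below `occupancy_floor`
#' are masked from the normalized map and downstream statistics.
#'
#' @param trace Deconvolved event trace for one cell (length = frames).
#' @param traj An annotated trajectory (see [annotate_trajectory()]).
#' @param bandwidth Kernel half-support, cm.
#' @param n_bins Number of bins over both directions.
#' @param occupancy_floor Minimum occupancy for a bin to be valid.
#' @param frames Optional logical/integer frame subset (e.g. odd trials).
#' @return A `duo_ratemap`: list with `occupancy`, `firing`, `normalized`
#'   (`firing/occupancy`, NA outside `valid`), `valid`, `lambda_bar`,
#'   `n_bins`, and `silent` (TRUE when the trace has no events in the
#'   usable frames).
#' @export
rate_map <- function(trace, traj, bandwidth = 5, n_bins = 200,
                     occupancy_floor = 1e-4, frames = NULL) {
  assert_that(length(trace) == nrow(traj),
              "trace and trajectory must share frame count")
  linpos <- traj$linpos
  if (is.null(linpos)) stop("trajectory must be annotated (linpos missing)")
  use <- !is.na(linpos)
  if (!is.null(frames)) {
    sel <- rep(FALSE, nrow(traj))
    sel[frames] <- TRUE
    use <- use & sel
  }
  if (!any(use)) stop("no-coverage error: no usable frames", call. = FALSE)
  occupancy <- estimate_density(linpos[use], bandwidth = bandwidth,
                                n_bins = n_bins)
  valid <- occupancy >= occupancy_floor
  ev <- trace[use]
  silent <- !any(ev > 0)
  if (silent) {
    firing <- rep(0, n_bins)
  } else {
    firing <- estimate_density(linpos[use], weights = ev,
                               bandwidth = bandwidth, n_bins = n_bins)
  }
  lambda_bar <- sum(occupancy[valid] * firing[valid]) /
    max(sum(occupancy[valid]), .Machine$double.eps)
  normalized <- rep(NA_real_, n_bins)
  normalized[valid] <- firing[valid] / occupancy[valid]
  structure(list(occupancy = occupancy, firing = firing,
                 normalized = normalized, valid = valid,
                 lambda_bar = lambda_bar, n_bins = n_bins, silent = silent),
            class = "duo_ratemap")
}

#' Skaggs-style spatial information
#'
#' `I = sum_i p_i * (lambda_i / lambda_bar) * log2(lambda_i / lambda_bar)`
#' over valid bins, with `lambda_bar` the occupancy-weighted mean firing
#' activity `sum_i p_i lambda_i` (occupancy renormalized over valid bins).
#' Bins with zero firing contribute zero.  The statistic is invariant to
#' uniform rescaling of the firing map and non-negative by Jensen's
#' inequality.
#'
#' @param firing A `duo_ratemap`, or a numeric firing-activity vector.
#' @param occupancy Occupancy probabilities (required when `firing` is a
#'   vector).
#' @param mean_mode `"occupancy"` (default; Skaggs convention) or a
#'   numeric value to use directly as `lambda_bar` (e.g. a temporal mean).
#' @return Spatial information in bits.
#' @export
spatial_information <- function(firing, occupancy = NULL,
                                mean_mode = "occupancy") {
  if (inherits(firing, "duo_ratemap")) {
    rm_ <- firing
    lam <- rm_$firing[rm_$valid]
    p <- rm_$occupancy[rm_$valid]
  } else {
    lam <- as.numeric(firing)
    p <- as.numeric(occupancy)
    assert_that(length(lam) == length(p),
                "firing and occupancy must have equal length")
  }
  assert_that(all(p >= 0) && all(lam >= 0),
              "occupancy and firing must be non-negative")
  p <- p / sum(p)
  lbar <- if (identical(mean_mode, "occupancy")) sum(p * lam) else as.numeric(mean_mode)
  if (lbar <= 0) stop("silent-cell error: mean firing activity is zero",
                      call. = FALSE)
  r <- lam / lbar
  terms <- ifelse(r > 0, p * r * log2(r), 0)
  sum(terms)
}

#' Occupancy-normalized rate map
#'
#' @param rm A `duo_ratemap`.
#' @return Numeric vector `firing/occupancy`, NA at masked bins.
#' @export
normalized_rate_map <- function(rm) {
  assert_that(inherits(rm, "duo_ratemap"), "rm must be a duo_ratemap")
  if (!any(rm$valid)) stop("no-coverage error: all bins masked", call. = FALSE)
  rm$normalized
}

#' @export
print.duo_ratemap <- function(x, ...) {
  cat(sprintf("<duo_ratemap> %d bins (%d valid), lambda_bar %.4g%s\n",
              x$n_bins, sum(x$valid), x$lambda_bar,
              if (x$silent) ", silent" else ""))
  invisible(x)
}
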