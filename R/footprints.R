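# Static-channel cell detection: local maxima on a smoothed summary image,
# footprints grown as round above-half-max regions.

#' Detection parameters for the static channel
#'
#' The source pipeline states the procedure (local maxima, round features)
#' but no numeric values; all parameters are exposed here with defaults.
#'
#' @param smoothing_sigma Gaussian smoothing sigma in pixels.
#' @param min_distance Minimum distance between accepted peaks, pixels.
#' @param intensity_threshold Absolute intensity threshold on the smoothed
#'   image, or `NULL` to use `threshold_quantile`.
#' @param threshold_quantile Quantile of the smoothed image used as the
#'   threshold when `intensity_threshold` is `NULL` (default 0.95).
#' @param radius_bounds `c(min, max)` equivalent radius in pixels.
#' @param roundness_min Minimum roundness `4*pi*area/perimeter^2`.
#' @return A `duo_detection_params` list.
#' @export
detection_params <- function(smoothing_sigma = 2, min_distance = 8,
                             intensity_threshold = NULL,
                             threshold_quantile = 0.95,
                             radius_bounds = c(1, 8), roundness_min = 0.6) {
  assert_that(min_distance >= 1, "min_distance must be >= 1")
  assert_that(radius_bounds[1] < radius_bounds[2],
              "radius_bounds must satisfy min < max")
  assert_that(roundness_min >= 0 && roundness_min <= 1,
              "roundness_min must be in [0, 1]")
  structure(list(smoothing_sigma = smoothing_sigma,
                 min_distance = min_distance,
                 intensity_threshold = intensity_threshold,
                 threshold_quantile = threshold_quantile,
                 radius_bounds = radius_bounds,
                 roundness_min = roundness_min),
            class = "duo_detection_params")
}

#' Separable Gaussian smoothing of an image
#'
#' Edge effects are corrected by normalizing with the smoothed indicator
#' image, so constant images stay constant.
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian sigma in pixels; `sigma <= 0` returns the input.
#' @return Smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(image, sigma) {
  if (sigma <= 0) return(image)
  half <- ceiling(3 * sigma)
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  sm1 <- function(m) {
    # convolve columns with k, zero padding
    out <- apply(m, 2, function(col) {
      as.numeric(stats::filter(c(rep(0, half), col, rep(0, half)), k,
                               sides = 2))[(half + 1):(half + length(col))]
    })
    matrix(out, nrow(m), ncol(m))
  }
  num <- t(sm1(t(sm1(image))))
  den <- t(sm1(t(sm1(matrix(1, nrow(image), ncol(image))))))
  num / den
}

#' Detect local maxima in a summary image
#'
#' Smooths the image, keeps pixels that are maximal in their 3x3
#' neighbourhood (plateaus keep the lexicographically smallest pixel) and
#' above the intensity threshold, then enforces the minimum pairwise
#' distance greedily in order of descending intensity.
#'
#' @param image 2D numeric matrix (finite values).
#' @param params A [detection_params()].
#' @return Integer matrix of `(row, col)` peaks sorted by descending
#'   smoothed intensity; zero rows when nothing qualifies.
#' @export
detect_local_maxima <- function(image, params = detection_params()) {
  assert_that(all(is.finite(image)), "image must be finite-valued")
  if (length(image) == 0L) return(matrix(integer(0), 0, 2))
  sm <- gaussian_smooth(image, params$smoothing_sigma)
  thr <- params$intensity_threshold %||%
    stats::quantile(sm, params$threshold_quantile, names = FALSE)

  nr <- nrow(sm); nc <- ncol(sm)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sm
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    if (dr < 0 || (dr == 0 && dc < 0)) {
      # tie with a lexicographically smaller neighbour disqualifies this
      # pixel, so plateaus keep their smallest coordinate
      is_max <- is_max & (sm > nb)
    } else {
      is_max <- is_max & (sm >= nb)
    }
  }
  is_max <- is_max & (sm > thr)
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(matrix(integer(0), 0, 2))
  vals <- sm[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d <- sqrt((cand[keep, 1] - cand[i, 1])^2 + (cand[keep, 2] - cand[i, 2])^2)
    if (all(d >= params$min_distance)) keep[i] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  dimnames(out) <- list(NULL, c("row", "col"))
  out
}

#' Grow a round footprint around a detected peak
#'
#' The footprint is the connected above-half-max region around the peak of
#' the smoothed image (half-max relative to the local annulus background).
#' The candidate is rejected when its equivalent radius
#' `sqrt(area / pi)` falls outside `radius_bounds` or its roundness
#' `4 * pi * area / perimeter^2` is below `roundness_min` (perimeter is the
#' Manhattan boundary length scaled by `pi/4`, which is exact for disks).
#' Weights are local-background-subtracted raw intensities inside the
#' region.
#'
#' @param image Raw 2D image.
#' @param peak `c(row, col)` of a local maximum (of the smoothed image).
#' @param params A [detection_params()].
#' @param smoothed Optional precomputed smoothed image.
#' @param cell_id Identifier for the resulting footprint.
#' @return A `duo_footprint`, or `NULL` when the candidate is rejected.
#' @export
grow_round_footprint <- function(image, peak, params = detection_params(),
                                 smoothed = NULL, cell_id = 1L) {
  nr <- nrow(image); nc <- ncol(image)
  assert_that(peak[1] >= 1 && peak[1] <= nr && peak[2] >= 1 && peak[2] <= nc,
              "peak must lie within the image")
  sm <- smoothed %||% gaussian_smooth(image, params$smoothing_sigma)
  # contract: peak must be a local maximum of the smoothed image
  r0 <- max(1, peak[1] - 1):min(nr, peak[1] + 1)
  c0 <- max(1, peak[2] - 1):min(nc, peak[2] + 1)
  assert_that(sm[peak[1], peak[2]] >= max(sm[r0, c0]),
              "contract violation: peak is not a local maximum")

  rmax <- params$radius_bounds[2]
  # the background annulus sits at 1.5 x rmax so an oversized blob cannot
  # serve as its own background and masquerade as a small footprint
  win <- ceiling(1.5 * rmax) + 4L
  rr <- max(1, peak[1] - win):min(nr, peak[1] + win)
  cc <- max(1, peak[2] - win):min(nc, peak[2] + win)
  sub_sm <- sm[rr, cc]
  sub_raw <- image[rr, cc]
  pr <- peak[1] - rr[1] + 1L
  pc <- peak[2] - cc[1] + 1L

  d <- sqrt(outer((seq_along(rr) - pr)^2, (seq_along(cc) - pc)^2, "+"))
  annulus <- d >= 1.5 * rmax + 1 & d <= 1.5 * rmax + 3
  bg_sm <- if (any(annulus)) stats::median(sub_sm[annulus]) else min(sub_sm)
  bg_raw <- if (any(annulus)) stats::median(sub_raw[annulus]) else min(sub_raw)

  half_max <- bg_sm + (sub_sm[pr, pc] - bg_sm) / 2
  region <- flood_fill(sub_sm >= half_max, pr, pc)
  area <- sum(region)
  eq_radius <- sqrt(area / pi)
  if (eq_radius < params$radius_bounds[1] || eq_radius > rmax) return(NULL)
  n_edges <- manhattan_perimeter(region)
  roundness <- 4 * pi * area / (n_edges * pi / 4)^2
  if (roundness < params$roundness_min) return(NULL)

  w <- (sub_raw - bg_raw) * region
  w[w < 0] <- 0
  if (!any(w > 0)) return(NULL)
  # trim to the bounding box of the region
  rows_in <- range(which(apply(region, 1, any)))
  cols_in <- range(which(apply(region, 2, any)))
  w <- w[rows_in[1]:rows_in[2], cols_in[1]:cols_in[2], drop = FALSE]
  fp <- footprint(cell_id, w,
                  c(rr[1] + rows_in[1] - 1L, cc[1] + cols_in[1] - 1L),
                  c(nr, nc))
  fp$roundness <- roundness
  fp$eq_radius <- eq_radius
  fp
}

# 4-connected flood fill from (r, c) within a logical mask.
#' @keywords internal
#' @noRd
flood_fill <- function(mask, r, c) {
  if (!mask[r, c]) return(matrix(FALSE, nrow(mask), ncol(mask)))
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  stack <- matrix(c(r, c), 1, 2)
  out[r, c] <- TRUE
  while (nrow(stack) > 0) {
    cur <- stack[nrow(stack), ]
    stack <- stack[-nrow(stack), , drop = FALSE]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      q <- cur + d
      if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
          mask[q[1], q[2]] && !out[q[1], q[2]]) {
        out[q[1], q[2]] <- TRUE
        stack <- rbind(stack, q)
      }
    }
  }
  out
}

# Number of exposed 4-neighbour edges of a logical region (Manhattan
# boundary length in pixel units).
#' @keywords internal
#' @noRd
manhattan_perimeter <- function(region) {
  nr <- nrow(region); nc <- ncol(region)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- region
  edges <- 0L
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- pad[(2 + d[1]):(nr + 1 + d[1]), (2 + d[2]):(nc + 1 + d[2])]
    edges <- edges + sum(region & !nb)
  }
  edges
}

#' Detect cells in a static-channel movie or summary image
#'
#' Composition of [detect_local_maxima()] and [grow_round_footprint()].
#' A 3D array input is first reduced to a summary image (mean projection
#' by default; the static signal makes mean and max equivalent up to
#' noise).
#'
#' @param x 2D summary image or 3D frame stack `(rows, cols, frames)`.
#' @param params A [detection_params()].
#' @param projection `"mean"` or `"max"` summary for stack input.
#' @return List of `duo_footprint`s with `cell_id` assigned in detection
#'   order.
#' @export
detect_cells <- function(x, params = detection_params(),
                         projection = c("mean", "max")) {
  projection <- match.arg(projection)
  img <- if (length(dim(x)) == 3L) {
    apply(x, c(1, 2), if (projection == "mean") mean else max)
  } else as.matrix(x)
  sm <- gaussian_smooth(img, params$smoothing_sigma)
  peaks <- detect_local_maxima(img, params)
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    fp <- grow_round_footprint(img, peaks[i, ], params, smoothed = sm,
                               cell_id = length(out) + 1L)
    if (!is.null(fp)) out[[length(out) + 1L]] <- fp
  }
  out
}
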