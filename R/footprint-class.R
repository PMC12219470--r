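#' Spatial footprint of one cell
#'
#' A footprint is a non-negative 2D weight map over the field of view.  To
#' keep memory proportional to cell size rather than FOV size, weights are
#' stored as a small patch plus the patch origin; [footprint_matrix()]
#' materializes the full map.
#'
#' @param cell_id Identifier (integer or character).
#' @param weights Numeric matrix of non-negative weights (the patch).
#' @param origin `c(row, col)` of the patch's top-left pixel in FOV
#'   coordinates (1-based).
#' @param fov_shape `c(height, width)` of the field of view.
#' @return A `duo_footprint` with fields `cell_id`, `weights`, `origin`,
#'   `fov_shape` and `centroid` (weight-weighted mean, FOV coordinates).
#' @export
footprint <- function(cell_id, weights, origin, fov_shape) {
  weights <- as.matrix(weights)
  assert_that(all(is.finite(weights)) && all(weights >= 0),
              "footprint weights must be finite and non-negative")
  assert_that(any(weights > 0), "footprint must have a positive weight")
  assert_that(origin[1] >= 1 && origin[2] >= 1 &&
                origin[1] + nrow(weights) - 1 <= fov_shape[1] &&
                origin[2] + ncol(weights) - 1 <= fov_shape[2],
              "footprint patch must lie inside the field of view")
  ctr <- patch_centroid(weights) + origin - 1
  structure(list(cell_id = cell_id, weights = weights,
                 origin = as.integer(origin),
                 fov_shape = as.integer(fov_shape),
                 centroid = ctr),
            class = "duo_footprint")
}

#' @keywords internal
#' @noRd
patch_centroid <- function(w) {
  tot <- sum(w)
  r <- sum(row(w) * w) / tot
  c <- sum(col(w) * w) / tot
  c(r, c)
}

#' Materialize a footprint as a full field-of-view matrix
#' @param fp A `duo_footprint`.
#' @return Numeric matrix of size `fov_shape`.
#' @export
footprint_matrix <- function(fp) {
  m <- matrix(0, fp$fov_shape[1], fp$fov_shape[2])
  rows <- fp$origin[1] + seq_len(nrow(fp$weights)) - 1L
  cols <- fp$origin[2] + seq_len(ncol(fp$weights)) - 1L
  m[rows, cols] <- fp$weights
  m
}

#' Extract centroids from a list of footprints
#' @param fps List of `duo_footprint` objects.
#' @return Numeric matrix with one `(row, col)` per footprint.
#' @export
footprint_centroids <- function(fps) {
  if (length(fps) == 0L) return(matrix(numeric(0), 0, 2))
  do.call(rbind, lapply(fps, function(f) f$centroid))
}

#' @export
print.duo_footprint <- function(x, ...) {
  cat(sprintf("<duo_footprint> cell %s, centroid (%.1f, %.1f), %dx%d patch\n",
              format(x$cell_id), x$centroid[1], x$centroid[2],
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

# Build a truncated isotropic Gaussian footprint centred at (r, c).
#' @keywords internal
#' @noRd
gaussian_footprint <- function(cell_id, center, sigma, fov_shape,
                               amplitude = 1, truncate = 3) {
  half <- ceiling(truncate * sigma)
  r0 <- max(1L, floor(center[1]) - half)
  r1 <- min(fov_shape[1], floor(center[1]) + half)
  c0 <- max(1L, floor(center[2]) - half)
  c1 <- min(fov_shape[2], floor(center[2]) + half)
  rr <- r0:r1
  cc <- c0:c1
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
  w <- amplitude * exp(-d2 / (2 * sigma^2))
  w[d2 > (truncate * sigma)^2] <- 0
  footprint(cell_id, w, c(r0, c0), fov_shape)
}
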