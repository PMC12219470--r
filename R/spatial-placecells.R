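# Place-cell classification: observed spatial information and stability
# versus circular-shuffle null distributions.

#' Precompute the spatial design of a session
#'
#' Builds the kernel-weight matrices and occupancy densities shared by
#' every cell of a session (full session, odd/even trials, first/second
#' half of trials).  Computing this once makes the 500-shuffle null test a
#' handful of matrix products per cell.
#'
#' @param traj An annotated trajectory ([annotate_trajectory()]).
#' @param bandwidth Kernel half-support, cm.
#' @param n_bins Number of spatial bins.
#' @param occupancy_floor Minimum occupancy for a valid bin.
#' @return A `duo_spatial_design` (list of kernel matrices, occupancy
#'   vectors and valid-bin masks).
#' @export
spatial_design <- function(traj, bandwidth = 5, n_bins = 200,
                           occupancy_floor = 1e-4) {
  assert_that(!is.null(traj$linpos) && !is.null(traj$trial_id),
              "trajectory must be annotated first")
  n_frames <- nrow(traj)
  centers <- seq(0.5 * 200 / n_bins, 200, by = 200 / n_bins)
  # the kernel has 2*bandwidth/binwidth nonzero bins per frame (~5% of 200):
  # sparse storage makes the 500-shuffle null a cheap sparse-dense product
  K <- Matrix::Matrix(cosine_kernel_matrix(traj$linpos, centers, bandwidth),
                      sparse = TRUE)

  n_trials <- max(traj$trial_id)
  # trials alternate running direction on a shuttle task, and the rate maps
  # are direction-split, so a raw odd/even-trial split would compare
  # disjoint spatial supports; pair consecutive trials into round trips so
  # both directions appear on both sides of the split
  lap <- ceiling(traj$trial_id / 2)
  odd <- lap %% 2 == 1
  first_half <- traj$trial_id <= ceiling(n_trials / 2)
  masks <- list(all = rep(TRUE, n_frames), odd = odd, even = !odd,
                half1 = first_half, half2 = !first_half)

  mk <- function(mask) {
    Km <- Matrix::Diagonal(x = as.numeric(mask)) %*% K
    occ_raw <- Matrix::colSums(Km)
    tot <- sum(occ_raw)
    if (tot <= 0) return(NULL)
    occ <- occ_raw / tot
    list(K = Km, occupancy = occ, valid = occ >= occupancy_floor)
  }
  parts <- lapply(masks, mk)
  structure(list(parts = parts, n_bins = n_bins, bandwidth = bandwidth,
                 occupancy_floor = occupancy_floor,
                 fps = attr(traj, "fps"), n_frames = n_frames,
                 n_trials = n_trials),
            class = "duo_spatial_design")
}

# Normalized firing density columns for a trace matrix W (frames x k).
#' @keywords internal
#' @noRd
firing_density <- function(part, W) {
  f <- as.matrix(Matrix::crossprod(part$K, W))   # bins x k
  tot <- colSums(f)
  tot[tot <= 0] <- NA
  sweep(f, 2, tot, "/")
}

# Columnwise Pearson correlation between two matrices over rows `rows`.
#' @keywords internal
#' @noRd
col_cors <- function(A, B, rows) {
  A <- A[rows, , drop = FALSE]
  B <- B[rows, , drop = FALSE]
  A <- sweep(A, 2, colMeans(A), "-")
  B <- sweep(B, 2, colMeans(B), "-")
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2) * colSums(B^2))
  out <- num / den
  out[!is.finite(out)] <- NA
  out
}

# Spatial information per column of a firing-density matrix.
#' @keywords internal
#' @noRd
si_columns <- function(part, F) {
  p <- part$occupancy[part$valid]
  p <- p / sum(p)
  lam <- F[part$valid, , drop = FALSE]
  lam <- sweep(lam, 2, colSums(lam), "/")   # renormalize over valid bins
  lbar <- colSums(lam * p)
  r <- sweep(lam, 2, lbar, "/")
  terms <- r * log2(r)
  terms[!is.finite(terms)] <- 0
  as.numeric(colSums(terms * p))
}

# Observed stability (mean of odd/even and half-split correlations) for a
# trace-column matrix W; returns a vector over columns.
#' @keywords internal
#' @noRd
stability_columns <- function(design, W) {
  p <- design$parts
  if (is.null(p$odd) || is.null(p$even) || is.null(p$half1) || is.null(p$half2))
    return(rep(NA_real_, ncol(W)))
  f_odd <- firing_density(p$odd, W)
  f_even <- firing_density(p$even, W)
  f_h1 <- firing_density(p$half1, W)
  f_h2 <- firing_density(p$half2, W)
  r1 <- col_cors(f_odd / p$odd$occupancy, f_even / p$even$occupancy,
                 p$odd$valid & p$even$valid)
  r2 <- col_cors(f_h1 / p$half1$occupancy, f_h2 / p$half2$occupancy,
                 p$half1$valid & p$half2$valid)
  rowMeans(cbind(r1, r2), na.rm = TRUE)
}

#' Within- or across-session spatial stability
#'
#' Within a session, stability is the mean Pearson correlation of the
#' occupancy-normalized rate maps across odd vs even trials and first vs
#' second half of trials (option `"both"`, the default, averages the two
#' splits).  Requires at least 4 trials.
#'
#' @param trace Deconvolved event trace for one cell.
#' @param traj An annotated trajectory.
#' @param split `"both"`, `"odd-even"`, or `"halves"`.
#' @param bandwidth,n_bins,occupancy_floor Passed to the rate maps.
#' @return Pearson correlation (numeric scalar, NA for silent splits).
#' @seealso [map_correlation()] for the across-session variant.
#' @export
session_stability <- function(trace, traj, split = c("both", "odd-even", "halves"),
                              bandwidth = 5, n_bins = 200,
                              occupancy_floor = 1e-4) {
  split <- match.arg(split)
  assert_that(max(traj$trial_id) >= 4,
              "need at least 4 trials for within-session stability")
  design <- spatial_design(traj, bandwidth, n_bins, occupancy_floor)
  W <- matrix(trace, ncol = 1)
  p <- design$parts
  pair_cor <- function(a, b) {
    fa <- firing_density(a, W); fb <- firing_density(b, W)
    rows <- a$valid & b$valid
    if (sum(rows) < 2)
      stop("insufficient-overlap error: fewer than 2 jointly valid bins",
           call. = FALSE)
    col_cors(fa / a$occupancy, fb / b$occupancy, rows)
  }
  oe <- pair_cor(p$odd, p$even)
  hh <- pair_cor(p$half1, p$half2)
  switch(split,
         "odd-even" = as.numeric(oe),
         "halves" = as.numeric(hh),
         "both" = mean(c(oe, hh), na.rm = TRUE))
}

#' Correlation of two normalized rate maps (across sessions)
#'
#' @param map_a,map_b Normalized rate maps (vectors with NA at masked
#'   bins), e.g. from [normalized_rate_map()].
#' @return Pearson correlation over jointly valid bins.
#' @export
map_correlation <- function(map_a, map_b) {
  rows <- is.finite(map_a) & is.finite(map_b)
  if (sum(rows) < 2)
    stop("insufficient-overlap error: fewer than 2 jointly valid bins",
         call. = FALSE)
  stats::cor(map_a[rows], map_b[rows])
}

#' Shuffle-based place-cell classification
#'
#' Builds null distributions of spatial information and stability by
#' circularly shifting the deconvolved trace (offsets uniform in
#' `[min_shift, T - min_shift]` frames, default 30 s) and recomputing both
#' statistics per shuffle.  A cell is a place cell when both observed
#' statistics exceed the given percentile of their null distributions.
#'
#' @param trace Deconvolved event trace for one cell.
#' @param traj An annotated trajectory (ignored when `design` is given
#'   together with its source trajectory).
#' @param n_shuffles Number of circular shuffles (default 500).
#' @param percentile Null percentile for both criteria (default 95).
#' @param seed Integer seed; identical seeds give identical nulls.
#' @param min_shift_s Minimum circular shift in seconds.
#' @param design Optional precomputed [spatial_design()] for the session.
#' @return A `duo_placecell` list: `spatial_information`, `stability`,
#'   `null_si`, `null_stability`, `si_p95`, `stab_p95`, `is_place_cell`,
#'   `silent`.
#' @export
place_cell_test <- function(trace, traj, n_shuffles = 500, percentile = 95,
                            seed = 1L, min_shift_s = 30, design = NULL) {
  if (is.null(design)) design <- spatial_design(traj)
  T_ <- design$n_frames
  assert_that(length(trace) == T_, "trace length must match the trajectory")
  min_shift <- round(min_shift_s * design$fps)
  assert_that(T_ > 2 * min_shift,
              "invalid-shift error: trace shorter than twice the minimum shift")

  all_part <- design$parts$all
  W0 <- matrix(trace, ncol = 1)
  f0 <- firing_density(all_part, W0)
  if (!any(trace > 0) || any(!is.finite(f0))) {
    return(structure(list(spatial_information = NA_real_, stability = NA_real_,
                          null_si = rep(NA_real_, n_shuffles),
                          null_stability = rep(NA_real_, n_shuffles),
                          si_p95 = NA_real_, stab_p95 = NA_real_,
                          is_place_cell = FALSE, silent = TRUE),
                     class = "duo_placecell"))
  }
  obs_si <- si_columns(all_part, f0)
  obs_stab <- stability_columns(design, W0)

  offsets <- with_seed(derive_seed(seed, "placecell"),
                       sample(seq.int(min_shift, T_ - min_shift),
                              n_shuffles, replace = TRUE))
  # shifted copies of a sparse event train, assembled in triplet form:
  # column s holds the trace circularly shifted forward by offsets[s]
  ev_idx <- which(trace > 0)
  rows <- outer(ev_idx - 1L, offsets, "+") %% T_ + 1L
  W <- Matrix::sparseMatrix(
    i = as.integer(rows),
    j = rep(seq_len(n_shuffles), each = length(ev_idx)),
    x = rep(trace[ev_idx], n_shuffles),
    dims = c(T_, n_shuffles))
  null_si <- si_columns(all_part, firing_density(all_part, W))
  null_stab <- stability_columns(design, W)

  q <- percentile / 100
  si_p <- stats::quantile(null_si, q, na.rm = TRUE, names = FALSE)
  st_p <- stats::quantile(null_stab, q, na.rm = TRUE, names = FALSE)
  structure(list(spatial_information = obs_si, stability = obs_stab,
                 null_si = null_si, null_stability = null_stab,
                 si_p95 = si_p, stab_p95 = st_p,
                 is_place_cell = isTRUE(obs_si > si_p && obs_stab > st_p),
                 silent = FALSE),
            class = "duo_placecell")
}

#' @export
print.duo_placecell <- function(x, ...) {
  cat(sprintf("<duo_placecell> SI %.3f (null p95 %.3f), stability %.3f (null p95 %.3f) -> %s\n",
              x$spatial_information, x$si_p95, x$stability, x$stab_p95,
              if (x$is_place_cell) "PLACE CELL" else "not a place cell"))
  invisible(x)
}
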