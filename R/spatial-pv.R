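#' Population-vector correlation between two sessions
#'
#' For each spatial bin the population vector (PV) is the across-cell
#' vector of normalized spatial firing activity.  The PV correlation of a
#' session pair is the mean over bins of the Pearson correlation between
#' the two sessions' PVs.  Cells inactive in a session are either assigned
#' an all-zero map (`"zero-fill"`) or dropped from both sessions
#' (`"intersect"`).
#'
#' @param maps_a,maps_b Matrices (cells x bins) of normalized rate maps,
#'   rows aligned to the same cell identities; rows of inactive cells may
#'   be all-NA.
#' @param mode `"zero-fill"` or `"intersect"`.
#' @param active_a,active_b Optional logical vectors marking the rows that
#'   correspond to active cells; defaults to rows with any finite value.
#' @return Mean Pearson correlation across bins (scalar).
#' @export
pv_correlation <- function(maps_a, maps_b, mode = c("zero-fill", "intersect"),
                           active_a = NULL, active_b = NULL) {
  mode <- match.arg(mode)
  maps_a <- as.matrix(maps_a)
  maps_b <- as.matrix(maps_b)
  assert_that(all(dim(maps_a) == dim(maps_b)),
              "maps must share dimensions (cells x bins)")
  if (is.null(active_a)) active_a <- apply(is.finite(maps_a), 1, any)
  if (is.null(active_b)) active_b <- apply(is.finite(maps_b), 1, any)

  if (mode == "zero-fill") {
    maps_a[!active_a, ] <- 0
    maps_b[!active_b, ] <- 0
    keep <- active_a | active_b
  } else {
    keep <- active_a & active_b
  }
  if (sum(keep) < 2)
    stop("insufficient-cells error: fewer than 2 cells in the PV",
         call. = FALSE)
  A <- maps_a[keep, , drop = FALSE]
  B <- maps_b[keep, , drop = FALSE]
  # bins where any retained cell has a masked value are dropped
  ok_bin <- apply(is.finite(A), 2, all) & apply(is.finite(B), 2, all)
  A <- A[, ok_bin, drop = FALSE]
  B <- B[, ok_bin, drop = FALSE]
  r <- col_cors(A, B, rep(TRUE, nrow(A)))
  mean(r, na.rm = TRUE)
}

#' Activity quantile of each cell within a session
#'
#' The quantile of a cell's temporal-mean activity relative to all cells in
#' the session: `(number of cells with strictly smaller mean + half the
#' other tied cells) / n`, giving values in `[0, 1)` and equal values for
#' tied cells.
#'
#' @param traces Matrix (cells x frames) of traces.
#' @return Numeric quantile per cell.
#' @export
activity_quantile <- function(traces) {
  traces <- as.matrix(traces)
  assert_that(nrow(traces) >= 2, "insufficient-cells error: need >= 2 cells")
  m <- rowMeans(traces)
  n <- length(m)
  vapply(m, function(v) (sum(m < v) + (sum(m == v) - 1) / 2) / n, numeric(1))
}
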