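# Longitudinal tracking statistics from boolean activity matrices.

#' Build the cells-by-sessions activity matrix from a registration map
#'
#' Entry `(cell, session)` is TRUE when the global identity has a member
#' in that session.  Cells never present are dropped (they are
#' undetectable); rows can optionally be restricted to a subset of global
#' ids (e.g. the stable dynamic-channel subset).
#'
#' @param map A `duo_regmap`.
#' @param subset Optional vector of global ids to keep.
#' @return A `duo_activity`: logical matrix with rownames = global ids,
#'   attribute `day_index`.
#' @export
build_activity_matrix <- function(map, subset = NULL) {
  assert_that(inherits(map, "duo_regmap"), "map must be a duo_regmap")
  asg <- map$assignments
  if (is.null(asg) || nrow(asg) == 0L)
    stop("empty-matrix error: registration map has no assignments",
         call. = FALSE)
  ids <- sort(unique(asg$global_id))
  if (!is.null(subset)) ids <- ids[ids %in% subset]
  if (length(ids) == 0L)
    stop("empty-matrix error: no cells after subsetting", call. = FALSE)
  m <- matrix(FALSE, length(ids), map$n_sessions,
              dimnames = list(ids, NULL))
  hit <- asg[asg$global_id %in% ids, ]
  m[cbind(match(hit$global_id, ids), hit$session)] <- TRUE
  activity_matrix(m, map$day_index)
}

#' Construct an activity matrix directly
#'
#' @param m Logical cells x sessions matrix; every row must have at least
#'   one TRUE entry.
#' @param day_index Day index per session (strictly increasing).
#' @return A `duo_activity`.
#' @export
activity_matrix <- function(m, day_index = seq_len(ncol(m)) - 1) {
  m <- as.matrix(m)
  storage.mode(m) <- "logical"
  assert_that(all(rowSums(m) >= 1),
              "every activity-matrix row needs at least one active session")
  assert_that(length(day_index) == ncol(m) &&
                (ncol(m) == 1 || all(diff(day_index) > 0)),
              "day_index must be strictly increasing, one per session")
  structure(m, day_index = day_index, class = c("duo_activity", "matrix"))
}

#' Per-session tracking probability p_m
#'
#' `p_m = (1/k) * sum_i N_mi / N_i`, where `N_i` is the number of cells
#' active in session `i` and `N_mi` the number of those cells whose total
#' active-session count is exactly `m`.  The vector over `m = 1..k` sums
#' to one for any activity matrix.
#'
#' @param am A `duo_activity`.
#' @param m Optional single session count; default returns the whole
#'   vector `p_1..p_k`.
#' @return Probability vector (or scalar when `m` is given).
#' @export
tracking_probability <- function(am, m = NULL) {
  k <- ncol(am)
  n_i <- colSums(am)
  if (any(n_i == 0))
    stop("zero-session error: a session has no active cells", call. = FALSE)
  row_m <- rowSums(am)
  p <- vapply(seq_len(k), function(mm) {
    n_mi <- colSums(am & (row_m == mm))
    mean(n_mi / n_i)
  }, numeric(1))
  names(p) <- paste0("p_", seq_len(k))
  if (is.null(m)) return(p)
  assert_that(m >= 1 && m <= k, "m must be in 1..k")
  unname(p[m])
}

#' Reactivation rate of a session pair
#'
#' `p_AB = 0.5 * (N_2/N_A + N_2/N_B)` with `N_2` the number of cells
#' active in both sessions: the `m = 2, k = 2` special case of
#' [tracking_probability()] restricted to the pair.
#'
#' @param am A `duo_activity`.
#' @param A,B Distinct session indices.
#' @return Probability in `[0, 1]`, symmetric in `(A, B)`.
#' @export
reactivation_rate <- function(am, A, B) {
  assert_that(A != B, "sessions must differ")
  k <- ncol(am)
  assert_that(A >= 1 && A <= k && B >= 1 && B <= k, "session out of range")
  n_a <- sum(am[, A]); n_b <- sum(am[, B])
  if (n_a == 0 || n_b == 0)
    stop("zero-session error: empty session", call. = FALSE)
  n2 <- sum(am[, A] & am[, B])
  0.5 * (n2 / n_a + n2 / n_b)
}

#' Proportion of cells per combination of active sessions
#'
#' @param am A `duo_activity`.
#' @return Named numeric vector; names are activity patterns such as
#'   `"1010101"`, values sum to one.
#' @export
combination_proportions <- function(am) {
  pat <- apply(unclass(am), 1, function(r) paste(as.integer(r), collapse = ""))
  tab <- table(pat)
  out <- as.numeric(tab) / nrow(am)
  names(out) <- names(tab)
  out
}

#' OLS slope of a metric against session-pair time interval
#'
#' @param interval Time interval in days per observation.
#' @param value Metric value per observation.
#' @return List with `slope`, `intercept`, `p_value` (two-sided t test of
#'   the slope), `se`, `n`.
#' @export
slope_vs_interval <- function(interval, value) {
  assert_that(length(interval) == length(value) && length(value) >= 3,
              "need at least 3 (interval, value) points")
  if (length(unique(interval)) < 2)
    stop("rank-deficient error: all intervals equal", call. = FALSE)
  fit <- stats::lm(value ~ interval)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["interval", "Estimate"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       p_value = unname(sm["interval", "Pr(>|t|)"]),
       se = unname(sm["interval", "Std. Error"]),
       n = length(value))
}

#' All session pairs of an activity matrix with their day intervals
#'
#' @param am A `duo_activity` (or anything with a `day_index` attribute
#'   and `k` columns).
#' @return data.frame with `A`, `B`, `interval_days`.
#' @export
session_pairs <- function(am) {
  k <- ncol(am)
  day <- attr(am, "day_index")
  out <- expand.grid(A = seq_len(k), B = seq_len(k))
  out <- out[out$A < out$B, ]
  out$interval_days <- abs(day[out$B] - day[out$A])
  rownames(out) <- NULL
  out
}
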