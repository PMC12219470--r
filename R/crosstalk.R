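# Channel cross-talk: footprint projection, per-cell linear coefficient,
# circular-shuffle null, and the expected ratio from emission spectra.

#' Project a movie onto spatial footprints
#'
#' `trace[c, t] = sum_px(w_c * frame_t) / sum_px(w_c)` — the
#' weight-normalized projection of raw pixel fluorescence onto each
#' footprint.
#'
#' @param movie 3D array `(rows, cols, frames)`.
#' @param footprints List of `duo_footprint` sharing the movie's FOV.
#' @return A `duo_traces` matrix (cells x frames), kind `"raw-projected"`.
#' @param fps Frame rate stored on the result.
#' @export
project_traces <- function(movie, footprints, fps = NA_real_) {
  assert_that(length(dim(movie)) == 3, "movie must be a 3D array")
  out <- matrix(0, length(footprints), dim(movie)[3])
  for (i in seq_along(footprints)) {
    fp <- footprints[[i]]
    assert_that(all(fp$fov_shape == dim(movie)[1:2]),
                "movie and footprints must share the FOV shape")
    tot <- sum(fp$weights)
    if (tot <= 0)
      stop("degenerate-footprint error: zero total weight", call. = FALSE)
    rows <- fp$origin[1] + seq_len(nrow(fp$weights)) - 1L
    cols <- fp$origin[2] + seq_len(ncol(fp$weights)) - 1L
    block <- movie[rows, cols, , drop = FALSE]
    out[i, ] <- apply(block, 3, function(f) sum(f * fp$weights)) / tot
  }
  trace_set(out, "raw-projected", fps)
}

#' Fit the cross-talk coefficient of one cell
#'
#' Ordinary least squares `static ~ intercept + beta * gcamp`; `beta` is
#' the fraction of dynamic-channel fluorescence dynamics leaking into the
#' static channel.
#'
#' @param gcamp,static Equal-length traces (>= 10 frames).
#' @return Slope `beta` (scalar).
#' @export
fit_crosstalk <- function(gcamp, static) {
  assert_that(length(gcamp) == length(static) && length(gcamp) >= 10,
              "traces must have equal length >= 10")
  vg <- stats::var(gcamp)
  if (!is.finite(vg) || vg == 0)
    stop("undefined-fit error: dynamic trace has zero variance",
         call. = FALSE)
  stats::cov(gcamp, static) / vg
}

#' Circular-shuffle null distribution of the cross-talk coefficient
#'
#' Each shuffle circularly shifts the static trace by a uniform random
#' offset in `[min_shift, T - min_shift]` frames and refits the
#' coefficient, breaking temporal alignment while preserving both
#' marginal distributions exactly.
#'
#' @param gcamp,static Equal-length traces.
#' @param n_shuffles Number of shuffles.
#' @param seed Integer seed (deterministic null per seed).
#' @param min_shift Minimum shift in frames; default 30 s at `fps`.
#' @param fps Frame rate used for the default `min_shift`.
#' @return Numeric vector of null coefficients, length `n_shuffles`.
#' @export
shuffled_null <- function(gcamp, static, n_shuffles = 100, seed = 1L,
                          min_shift = NULL, fps = 30) {
  T_ <- length(gcamp)
  min_shift <- min_shift %||% round(30 * fps)
  if (T_ <= 2 * min_shift)
    stop("invalid-shift error: trace shorter than twice the minimum shift",
         call. = FALSE)
  vg <- stats::var(gcamp)
  if (!is.finite(vg) || vg == 0)
    stop("undefined-fit error: dynamic trace has zero variance",
         call. = FALSE)
  offsets <- with_seed(derive_seed(seed, "ctnull"),
                       sample(seq.int(min_shift, T_ - min_shift),
                              n_shuffles, replace = TRUE))
  gc <- gcamp - mean(gcamp)
  sc <- static - mean(static)
  vapply(offsets, function(o) {
    sum(gc * circular_shift(sc, o)) / ((T_ - 1) * vg)
  }, numeric(1))
}

#' Estimate cross-talk for a set of registered cell pairs
#'
#' @param gcamp_traces,static_traces Matrices (cells x frames), rows
#'   aligned across channels.
#' @param n_shuffles Shuffles per cell for the null.
#' @param seed Master seed; per-cell sub-seeds are derived.
#' @param min_shift,fps Passed to [shuffled_null()].
#' @return A `duo_crosstalk`: `coefficients` (per cell), `null`
#'   (cells x shuffles matrix).
#' @export
crosstalk_estimate <- function(gcamp_traces, static_traces, n_shuffles = 100,
                               seed = 1L, min_shift = NULL, fps = 30) {
  gcamp_traces <- as.matrix(gcamp_traces)
  static_traces <- as.matrix(static_traces)
  assert_that(all(dim(gcamp_traces) == dim(static_traces)),
              "trace matrices must share dimensions")
  n <- nrow(gcamp_traces)
  beta <- numeric(n)
  null <- matrix(NA_real_, n, n_shuffles)
  for (i in seq_len(n)) {
    beta[i] <- fit_crosstalk(gcamp_traces[i, ], static_traces[i, ])
    null[i, ] <- shuffled_null(gcamp_traces[i, ], static_traces[i, ],
                               n_shuffles, seed = derive_seed(seed, "cell", i),
                               min_shift = min_shift, fps = fps)
  }
  structure(list(coefficients = beta, null = null),
            class = "duo_crosstalk")
}

#' Emission/transmission spectra container
#'
#' @param wavelength_nm Strictly increasing wavelength grid.
#' @param emission Relative emission intensity (>= 0, positive total).
#' @param transmission_green,transmission_red Filter transmission in
#'   `[0, 1]` on the same grid.
#' @return A `duo_spectra` list.
#' @export
spectra_set <- function(wavelength_nm, emission, transmission_green,
                        transmission_red) {
  n <- length(wavelength_nm)
  assert_that(n >= 2 && all(diff(wavelength_nm) > 0),
              "wavelength grid must be strictly increasing")
  assert_that(length(emission) == n && length(transmission_green) == n &&
                length(transmission_red) == n,
              "all curves must share the wavelength grid")
  assert_that(all(emission >= 0) && sum(emission) > 0,
              "emission must be non-negative with positive total")
  assert_that(all(transmission_green >= 0 & transmission_green <= 1) &&
                all(transmission_red >= 0 & transmission_red <= 1),
              "transmissions must lie in [0, 1]")
  structure(list(wavelength_nm = wavelength_nm, emission = emission,
                 transmission_green = transmission_green,
                 transmission_red = transmission_red),
            class = "duo_spectra")
}

#' Read spectra from two-column CSV files onto a common grid
#'
#' Each file needs columns `wavelength_nm` and `value`; curves are
#' linearly interpolated onto the union of all wavelength points (so sharp
#' filter edges are preserved), 0 outside their support.
#'
#' @param emission_csv,green_csv,red_csv File paths.
#' @return A `duo_spectra`.
#' @export
read_spectra <- function(emission_csv, green_csv, red_csv) {
  rd <- function(path) utils::read.csv(path)
  em <- rd(emission_csv); gr <- rd(green_csv); re <- rd(red_csv)
  grid <- sort(unique(c(em$wavelength_nm, gr$wavelength_nm, re$wavelength_nm)))
  interp <- function(d) {
    v <- stats::approx(d$wavelength_nm, d$value, xout = grid, rule = 1)$y
    v[is.na(v)] <- 0
    v
  }
  spectra_set(grid, interp(em), interp(gr), interp(re))
}

#' Expected cross-talk ratio from spectra
#'
#' The amount of dynamic-indicator emission passing the red (static
#' channel) filter divided by the amount passing the green (dynamic
#' channel) filter, both by trapezoidal integration over wavelength.
#'
#' @param spectra A `duo_spectra`.
#' @return Dimensionless ratio.
#' @export
expected_crosstalk_ratio <- function(spectra) {
  assert_that(inherits(spectra, "duo_spectra"), "need a duo_spectra")
  w <- spectra$wavelength_nm
  den <- trapz(w, spectra$emission * spectra$transmission_green)
  if (den <= 0)
    stop("degenerate-spectra error: no emission passes the green filter",
         call. = FALSE)
  trapz(w, spectra$emission * spectra$transmission_red) / den
}

#' Summary statistics and tests for a cross-talk estimate
#'
#' @param est A `duo_crosstalk` (>= 2 cells).
#' @param expected_ratio Optional expected ratio for the one-sample test.
#' @return List with observed and null means/SDs, `paired_t` (observed
#'   coefficient vs per-cell null mean) and, when `expected_ratio` is
#'   given, `one_sample_t` against it.
#' @export
summarize_crosstalk <- function(est, expected_ratio = NULL) {
  assert_that(inherits(est, "duo_crosstalk"), "need a duo_crosstalk")
  n <- length(est$coefficients)
  if (n < 2)
    stop("insufficient-data error: need at least 2 cells", call. = FALSE)
  null_cell_mean <- rowMeans(est$null)
  d <- est$coefficients - null_cell_mean
  paired <- if (stats::sd(d) == 0) {
    list(statistic = 0, p.value = 1)
  } else {
    t <- stats::t.test(est$coefficients, null_cell_mean, paired = TRUE)
    list(statistic = unname(t$statistic), p.value = t$p.value)
  }
  out <- list(observed_mean = mean(est$coefficients),
              observed_sd = stats::sd(est$coefficients),
              null_mean = mean(est$null),
              null_sd = stats::sd(as.numeric(est$null)),
              paired_t = paired)
  if (!is.null(expected_ratio)) {
    dev <- est$coefficients - expected_ratio
    out$one_sample_t <- if (stats::sd(dev) == 0) {
      list(statistic = 0, p.value = 1)
    } else {
      t <- stats::t.test(est$coefficients, mu = expected_ratio)
      list(statistic = unname(t$statistic), p.value = t$p.value)
    }
    out$expected_ratio <- expected_ratio
  }
  out
}
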