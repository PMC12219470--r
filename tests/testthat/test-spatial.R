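# Behaviour segmentation, KDE rate maps, spatial information, stability,
# place-cell classification and PV correlation.

make_traj <- function(x_px, fps = 10, track = 100) {
  tr <- data.frame(frame = seq_along(x_px) - 1, x_px = x_px,
                   y_px = rep(50, length(x_px)))
  attr(tr, "fps") <- fps
  attr(tr, "track_length_cm") <- track
  attr(tr, "px_per_cm") <- 4
  class(tr) <- c("duo_trajectory", "data.frame")
  tr
}

test_that("compute_speed handles constant motion and rest", {
  # 10 cm/s at 10 fps: 1 cm = 4 px per frame over the full track
  tr <- make_traj(seq(0, 400, by = 4))
  sp <- compute_speed(tr)
  expect_true(all(abs(sp$speed[2:100] - 10) < 0.01))
  expect_equal(sp$running_speed, 10, tolerance = 0.01)

  still <- make_traj(rep(200, 50))
  expect_true(all(compute_speed(still)$speed == 0))
  expect_error(compute_speed(make_traj(1)), "insufficient frames")
})

test_that("planted running speed is recovered at the 95th percentile", {
  cfg <- duo_config(n_sessions = 1, session_duration_s = 300, fps = 30,
                    n_cells = 5, fov_shape = c(100, 100),
                    run_speed_cm_s = 45)
  traj <- simulate_trajectory(cfg)
  rs <- compute_speed(traj)$running_speed
  expect_lt(abs(rs - 45) / 45, 0.05)
})

test_that("behaviour labels follow the 3 cm/s closed-boundary convention", {
  still <- make_traj(rep(100, 30))
  expect_true(all(classify_behavior(still) == "idle"))

  right <- make_traj(seq(0, 400, by = 2))  # 5 cm/s increasing
  lab <- classify_behavior(right)
  expect_true(all(lab[3:98] == "right"))

  # exactly at threshold -> idle (closed boundary).  All quantities are
  # exact binary fractions: 1.5 px/frame * (128 cm / 512 px) * 8 fps = 3
  border <- make_traj(c(seq(0, 511.5, by = 1.5), 512), fps = 8, track = 128)
  expect_true(all(classify_behavior(border) == "idle"))

  left <- make_traj(seq(400, 0, by = -2))
  expect_true(all(classify_behavior(left)[3:98] == "left"))
})

test_that("trial detection counts end-zone visits", {
  # two full back-and-forth laps starting from end A: 4 trials
  lap <- c(seq(0, 400, by = 4), seq(400, 0, by = -4))
  tr <- make_traj(rep(lap, 2))
  expect_equal(detect_trials(tr)$n_trials, 4)

  expect_equal(detect_trials(make_traj(rep(2, 40)))$n_trials, 0)

  cfg <- tiny_config(n_sessions = 1, session_duration_s = 120)
  traj <- simulate_trajectory(cfg)
  expect_equal(detect_trials(traj)$n_trials,
               attr(traj, "planted")$lap_count)
})

test_that("linearization is direction-split and invertible", {
  x <- c(seq(0, 400, by = 4), seq(400, 0, by = -4))
  tr <- make_traj(x)
  beh <- classify_behavior(tr)
  lin <- linearize_position(tr, beh)
  expect_true(all(is.na(lin) | (lin >= 0 & lin < 200)))
  expect_true(all(lin[beh == "left"] < 100))
  expect_true(all(lin[beh == "right"] >= 100))
  # position 0 running left -> 0; position 50 cm running right -> 150
  beh_l <- rep("left", length(x)); beh_r <- rep("right", length(x))
  expect_equal(linearize_position(tr, beh_l)[1], 0)
  i50 <- which(x == 200)[1]
  expect_equal(linearize_position(tr, beh_r)[i50], 150)
  # un-offsetting rightward frames recovers the raw linearization
  raw <- linearize_position(tr, beh_l)
  expect_equal(lin[beh == "right"] - 100, raw[beh == "right"])
})

test_that("cosine KDE has the stated support, normalization and invariances", {
  d <- estimate_density(100)
  expect_equal(sum(d), 1)
  expect_equal(sum(d > 0), 10)          # +-5 cm at 1 cm/bin
  sup <- which(d > 0)
  expect_equal(d[sup], rev(d[sup]), tolerance = 1e-12)  # symmetric

  # KDE consistency: for uniform samples the max/min bin ratio tends to 1
  set.seed(20)
  ratio_at <- function(n) {
    d2 <- estimate_density(runif(n, 0, 200))
    inner <- d2[10:190]                  # away from edge truncation
    max(inner) / min(inner)
  }
  r_small <- ratio_at(2000)
  r_big <- ratio_at(50000)
  expect_lt(r_big, r_small)
  expect_lt(r_big, 1.25)

  w <- runif(50, 0.1, 2)
  xs <- runif(50, 10, 190)
  expect_equal(estimate_density(xs, w), estimate_density(xs, 2 * w),
               tolerance = 1e-12)
  expect_error(estimate_density(numeric(0)), "empty-density")
  expect_error(estimate_density(c(10, 20), c(0, 0)), "empty-density")
})

test_that("spatial information reproduces hand-computed values", {
  expect_equal(spatial_information(c(2, 0), c(0.5, 0.5)), 1.0)
  expect_equal(spatial_information(c(4, 0), c(0.25, 0.75)), 2.0)
  expect_equal(spatial_information(rep(3, 10), rep(0.1, 10)), 0)
  expect_error(spatial_information(c(0, 0), c(0.5, 0.5)), "silent-cell")
})

test_that("spatial information is non-negative and scale-invariant", {
  set.seed(21)
  for (rep in 1:200) {
    p <- runif(20); p <- p / sum(p)
    lam <- runif(20) * rbinom(20, 1, 0.8)
    if (sum(lam) == 0) next
    si <- spatial_information(lam, p)
    expect_gte(si, -1e-12)
    expect_equal(spatial_information(lam * 7.3, p), si, tolerance = 1e-9)
  }
})

test_that("normalized rate maps mask empty bins and find planted fields", {
  p <- c(0.5, 0.5, 0)
  lam <- c(0.4, 0.4, 0.2)
  rm_ <- structure(list(occupancy = p, firing = lam,
                        normalized = c(0.8, 0.8, NA),
                        valid = c(TRUE, TRUE, FALSE),
                        lambda_bar = 0.4, n_bins = 3, silent = FALSE),
                   class = "duo_ratemap")
  nm <- normalized_rate_map(rm_)
  expect_true(is.na(nm[3]))
  expect_equal(nm[1:2], c(0.8, 0.8))

  # well-sampled fields (10 min, 4 Hz in-field) localize to within 3 cm
  w <- small_session(n_cells = 10, duration = 600, place_fraction = 1,
                     seed = 31, noise_sd = 0, peak_rate_hz = 4)
  tc <- attr(w$ses$events, "true_cell")
  hits <- 0; tried <- 0
  for (i in seq_along(tc)) {
    rmap <- rate_map(w$ses$events[i, ], w$traj)
    if (rmap$silent) next
    tried <- tried + 1
    offset <- if (w$pop$field_direction[tc[i]] == "right") 100 else 0
    center <- w$pop$field_centers_by_session[tc[i], 1] + offset
    peak_bin <- which.max(rmap$normalized) - 0.5
    if (abs(peak_bin - center) <= 3) hits <- hits + 1
  }
  expect_gte(hits / tried, 0.8)
})

test_that("map correlation and within-session stability behave", {
  m <- c(NA, 1, 2, 3, 4, NA)
  expect_equal(map_correlation(m, m), 1)
  a <- c(1, 2, 3, 4)
  b <- c(4, 3, 2, 1)
  expect_equal(map_correlation(a, b), cor(a, b))
  expect_lt(map_correlation(a, b), 0)
  expect_error(map_correlation(c(1, NA), c(NA, 1)), "insufficient-overlap")

  w <- small_session(n_cells = 8, duration = 300, place_fraction = 1,
                     seed = 32, noise_sd = 0)
  r <- session_stability(w$ses$events[1, ], w$traj)
  expect_true(is.finite(r))
  expect_gt(r, 0.2)   # a strong planted field is split-stable
})

test_that("untuned cells have stability centred near zero", {
  w <- small_session(n_cells = 30, duration = 300, place_fraction = 0,
                     seed = 33)
  rs <- vapply(seq_len(nrow(w$ses$events)), function(i)
    session_stability(w$ses$events[i, ], w$traj), numeric(1))
  expect_lt(abs(mean(rs, na.rm = TRUE)), 0.15)
})

test_that("place_cell_test is deterministic and flags silent traces", {
  w <- small_session(n_cells = 6, duration = 120, place_fraction = 1,
                     seed = 34)
  a <- place_cell_test(w$ses$events[1, ], w$traj, n_shuffles = 60, seed = 5)
  b <- place_cell_test(w$ses$events[1, ], w$traj, n_shuffles = 60, seed = 5)
  expect_identical(a, b)

  z <- place_cell_test(rep(0, nrow(w$traj)), w$traj, n_shuffles = 10, seed = 1)
  expect_true(z$silent)
  expect_false(z$is_place_cell)
})

test_that("circular trace shuffles preserve total event mass", {
  w <- small_session(n_cells = 4, duration = 120, place_fraction = 1,
                     seed = 35)
  tr <- w$ses$events[1, ]
  sh <- duoscope:::circular_shift(tr, 321)
  expect_equal(sum(sh), sum(tr))
  expect_equal(sort(sh[sh > 0]), sort(tr[tr > 0]))
})

test_that("pv_correlation: self-pairs, permutations and drift ordering", {
  set.seed(22)
  maps <- matrix(abs(rnorm(20 * 200)), 20, 200)
  expect_equal(pv_correlation(maps, maps, "zero-fill"), 1)
  expect_equal(pv_correlation(maps, maps, "intersect"), 1)

  perm <- sample(20)
  got <- pv_correlation(maps, maps[perm, ], "intersect")
  # brute-force per-bin Pearson on the permuted matrix
  brute <- mean(vapply(1:200, function(b) cor(maps[, b], maps[perm, b]),
                       numeric(1)))
  expect_equal(got, brute, tolerance = 1e-12)

  # synthetic drift: session B = noisy maps with half the cells inactive
  drift_pv <- function(noise) {
    maps_b <- maps + matrix(abs(rnorm(20 * 200, 0, noise)), 20, 200)
    act_b <- rep(c(TRUE, FALSE), 10)
    zf <- pv_correlation(maps, maps_b, "zero-fill",
                         active_b = act_b)
    it <- pv_correlation(maps, maps_b, "intersect",
                         active_b = act_b)
    c(zf = zf, it = it)
  }
  lo <- drift_pv(0.5); hi <- drift_pv(2)
  expect_lte(lo[["zf"]], lo[["it"]])
  expect_lte(hi[["zf"]], hi[["it"]])
  expect_lt(hi[["zf"]], lo[["zf"]])
  expect_lt(hi[["it"]], lo[["it"]])

  expect_error(pv_correlation(maps[1:2, ], maps[1:2, ], "intersect",
                              active_a = c(TRUE, FALSE)),
               "insufficient-cells")
})

test_that("activity quantiles use strict-rank-with-midrank-ties", {
  tr <- rbind(rep(1, 5), rep(2, 5), rep(3, 5), rep(4, 5))
  expect_equal(activity_quantile(tr), c(0, 0.25, 0.5, 0.75))

  ties <- rbind(rep(2, 4), rep(2, 4), rep(2, 4))
  q <- activity_quantile(ties)
  expect_true(all(q == q[1]))

  set.seed(23)
  m <- matrix(rnorm(60), 12, 5)
  q2 <- activity_quantile(m)
  mu <- rowMeans(m)
  brute <- vapply(mu, function(v)
    (sum(mu < v) + (sum(mu == v) - 1) / 2) / length(mu), numeric(1))
  expect_equal(q2, brute)
  expect_error(activity_quantile(m[1, , drop = FALSE]), "insufficient-cells")
})

test_that("occupancy and firing densities sum to one over bins", {
  w <- small_session(n_cells = 5, duration = 120, place_fraction = 1,
                     seed = 36)
  for (i in 1:3) {
    rmap <- rate_map(w$ses$events[i, ], w$traj)
    expect_equal(sum(rmap$occupancy), 1, tolerance = 1e-9)
    if (!rmap$silent) expect_equal(sum(rmap$firing), 1, tolerance = 1e-9)
  }
})
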