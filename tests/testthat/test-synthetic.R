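# Synthetic data generator: trajectories, population, traces, movies.

test_that("simulate_trajectory is deterministic and respects the config", {
  cfg <- tiny_config()
  a <- simulate_trajectory(cfg, seed = 11)
  b <- simulate_trajectory(cfg, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, simulate_trajectory(cfg, seed = 12)))
  expect_equal(nrow(a), round(cfg$session_duration_s * cfg$fps))
  expect_error(simulate_trajectory(duo_config(session_duration_s = -1)),
               "invalid config")
})

test_that("zero-pause constant-speed trajectory runs at the planted speed", {
  cfg <- tiny_config(pause_mean_s = 0, run_speed_sd = 0, run_speed_cm_s = 40)
  traj <- simulate_trajectory(cfg)
  sp <- compute_speed(traj)$speed
  # all frames are run frames; central differences at turnarounds dip, so
  # check the bulk of the distribution
  expect_gt(mean(abs(sp - 40) < 1), 0.9)
})

test_that("planted lap count matches an independent threshold-crossing scan", {
  cfg <- tiny_config(session_duration_s = 120)
  traj <- simulate_trajectory(cfg)
  pos_cm <- traj$x_px / attr(traj, "px_per_cm")
  L <- attr(traj, "track_length_cm")
  # independent scan: count arrivals at the opposite end
  state <- if (pos_cm[1] < L / 2) "low" else "high"
  laps <- 0L
  for (p in pos_cm) {
    if (state == "low" && p >= L - 0.25) { laps <- laps + 1L; state <- "high" }
    else if (state == "high" && p <= 0.25) { laps <- laps + 1L; state <- "low" }
  }
  expect_equal(attr(traj, "planted")$lap_count, laps)
})

test_that("simulate_population honours tuning fraction, jitter and separation", {
  cfg0 <- tiny_config(place_cell_fraction = 0)
  expect_false(any(simulate_population(cfg0)$tuned_mask))

  cfg1 <- tiny_config(fov_jitter_px = 0)
  pop1 <- simulate_population(cfg1)
  expect_equal(session_centroids(pop1, 1), session_centroids(pop1, 3))

  pop <- simulate_population(tiny_config())
  d <- as.matrix(dist(pop$base_centroids))
  diag(d) <- Inf
  expect_gte(min(d), 10)

  expect_error(simulate_population(duo_config(n_cells = 5000)),
               "packing error")
})

test_that("per-cell seed streams are stable when cells are added", {
  p20 <- simulate_population(tiny_config(n_cells = 20, fov_jitter_px = 0))
  p10 <- simulate_population(tiny_config(n_cells = 10, fov_jitter_px = 0))
  expect_equal(p20$active_matrix[1:10, ], p10$active_matrix)
})

test_that("session traces obey the cross-talk construction exactly", {
  w <- small_session(n_cells = 8, duration = 30, seed = 3,
                     crosstalk_alpha = 0, noise_sd = 0, static_drift_frac = 0)
  st <- unclass(w$ses$static_traces)
  expect_true(all(abs(st - st[, 1]) < 1e-12))  # constant per cell

  w2 <- small_session(n_cells = 8, duration = 30, seed = 3,
                      crosstalk_alpha = 0.05, noise_sd = 0)
  st2 <- unclass(w2$ses$static_traces)
  base <- attr(w2$ses$static_traces, "baseline")
  g_all <- matrix(0, 8, ncol(st2))
  g_all[attr(w2$ses$gcamp_fluor, "true_cell"), ] <- unclass(w2$ses$gcamp_fluor)
  inactive <- setdiff(1:8, attr(w2$ses$gcamp_fluor, "true_cell"))
  g_all[inactive, ] <- 1   # inactive cells sit at the unit baseline
  expect_equal(st2 - base, 0.05 * g_all, tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(simulate_session_traces(w$pop, w$traj, w$cfg, 99),
               "session index")
})

test_that("tuned cells fire around their planted field centre", {
  w <- small_session(n_cells = 12, duration = 300, place_fraction = 1,
                     seed = 9, noise_sd = 0)
  tc <- attr(w$ses$events, "true_cell")
  lin <- w$ses$trajectory$linpos
  for (i in seq_along(tc)) {
    cell <- tc[i]
    ev <- w$ses$events[i, ]
    # recompute from emitted events on the direction-specific linearized
    # axis: a "left" field lives in [0,100), a "right" field in [100,200)
    offset <- if (w$pop$field_direction[cell] == "right") 100 else 0
    sel <- !is.na(lin) & lin >= offset & lin < offset + 100 & ev > 0
    if (sum(ev[sel]) == 0) next
    center <- w$pop$field_centers_by_session[cell, 1] + offset
    m <- sum(lin[sel] * ev[sel]) / sum(ev[sel])
    expect_lt(abs(m - center), w$cfg$field_width_cm)
  }
})

test_that("simulate_experiment yields the 13-day schedule and activity stats", {
  cfg <- tiny_config(n_sessions = 7, session_interval_days = 2,
                     session_duration_s = 10)
  ex <- simulate_experiment(cfg)
  days <- vapply(ex$sessions, `[[`, numeric(1), "day")
  expect_equal(days, c(0, 2, 4, 6, 8, 10, 12))
  expect_equal(diff(range(days)) + 1, 13)   # spans 13 calendar days

  cfg1 <- tiny_config(activity_prob = 1, session_duration_s = 10)
  expect_true(all(simulate_experiment(cfg1)$truth$active_matrix))

  cfg06 <- duo_config(n_sessions = 5, session_duration_s = 10, fps = 10,
                      n_cells = 500, fov_shape = c(400, 400),
                      activity_prob = 0.6)
  act <- simulate_population(cfg06)$active_matrix
  frac <- colMeans(act)
  sd3 <- 3 * sqrt(0.6 * 0.4 / 500)
  expect_true(all(abs(frac - 0.6) <= sd3))
})

test_that("movies round-trip traces through footprint projection", {
  fov <- c(40, 40)
  fp1 <- footprint(1, matrix(c(0, 1, 0, 1, 4, 1, 0, 1, 0), 3, 3), c(10, 10), fov)
  fp2 <- footprint(2, matrix(1, 3, 3), c(25, 25), fov)
  tr <- rbind(sin(1:50) + 2, cos(1:50) + 2)
  mov <- render_movie(list(fp1, fp2), tr)
  back <- project_traces(mov, list(fp1, fp2), fps = 10)
  # weight-normalized projection recovers traces up to sum(w^2)/sum(w)
  gains <- vapply(list(fp1, fp2),
                  function(f) sum(f$weights^2) / sum(f$weights), numeric(1))
  expect_equal(unclass(back), tr * gains, ignore_attr = TRUE,
               tolerance = 1e-12)

  expect_true(all(render_movie(list(fp1), matrix(0, 1, 5)) == 0))

  mov1 <- render_movie(list(fp1), matrix(1, 1, 3))
  peak <- which(mov1[, , 1] == max(mov1[, , 1]), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(11, 11))  # centroid of the cross patch
})

test_that("experiment generation is fully reproducible per seed", {
  cfg <- tiny_config(session_duration_s = 20)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$truth, e2$truth)
  expect_identical(e1$sessions[[2]]$events, e2$sessions[[2]]$events)
  expect_identical(e1$sessions[[3]]$static_traces, e2$sessions[[3]]$static_traces)
})
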