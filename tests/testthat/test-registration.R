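# Centroid-distance registration: mutual-NN matching, cross-session
# chaining, and propagation of the static-channel map.

test_that("match_centroids handles identity, disjoint and empty inputs", {
  pts <- cbind(c(10, 20, 30), c(10, 25, 5))
  mm <- match_centroids(pts, pts, max_dist = 5)
  expect_equal(mm$pairs$index_a, mm$pairs$index_b)
  expect_equal(mm$pairs$dist, rep(0, 3))

  far <- pts + 100   # every cross-distance far exceeds 2 * max_dist
  expect_equal(nrow(match_centroids(pts, far, max_dist = 5)$pairs), 0)

  e <- match_centroids(matrix(numeric(0), 0, 2), pts, 5)
  expect_equal(nrow(e$pairs), 0)
  expect_equal(e$unmatched_b, 1:3)
})

test_that("matching recovers planted correspondence under jitter", {
  cfg <- duo_config(n_cells = 100, fov_shape = c(250, 250))
  pop <- simulate_population(cfg)
  a <- pop$base_centroids
  with_jitter <- function(j, seed) {
    set.seed(seed)
    a + matrix(runif(200, -j, j), ncol = 2)
  }
  b <- with_jitter(2, 1)
  mm <- match_centroids(a, b, max_dist = 5)
  correct <- mean(mm$pairs$index_a == mm$pairs$index_b) *
    nrow(mm$pairs) / nrow(a)
  expect_gte(correct, 0.99)

  # accuracy is non-increasing in jitter magnitude
  acc <- vapply(c(0, 1, 2, 4), function(j) {
    m <- match_centroids(a, with_jitter(j, 2), max_dist = 5)
    sum(m$pairs$index_a == m$pairs$index_b) / nrow(a)
  }, numeric(1))
  expect_true(all(diff(acc) <= 1e-9))
})

test_that("matching is permutation-invariant and symmetric", {
  set.seed(3)
  a <- cbind(runif(30, 10, 90), runif(30, 10, 90))
  b <- a + matrix(runif(60, -1, 1), ncol = 2)
  mm <- match_centroids(a, b, 5)

  perm <- sample(30)
  mp <- match_centroids(a[perm, ], b, 5)
  got <- sort(paste(perm[mp$pairs$index_a], mp$pairs$index_b))
  expect_equal(got, sort(paste(mm$pairs$index_a, mm$pairs$index_b)))

  sw <- match_centroids(b, a, 5)
  expect_equal(sort(paste(sw$pairs$index_b, sw$pairs$index_a)),
               sort(paste(mm$pairs$index_a, mm$pairs$index_b)))
})

test_that("cross-session registration chains identities correctly", {
  pts <- cbind(c(10, 30, 50), c(10, 30, 50))
  map <- register_cross_session(list(pts, pts, pts), 5)
  am <- build_activity_matrix(map)
  expect_true(all(am))
  expect_equal(nrow(am), 3)

  # cell 2 missing in session 2 only
  map2 <- register_cross_session(list(pts, pts[-2, , drop = FALSE], pts), 5)
  am2 <- build_activity_matrix(map2)
  expect_equal(unname(rowSums(am2)), c(3, 2, 3))
  expect_equal(unname(which(!am2[2, ])), 2L)

  expect_error(register_cross_session(list(pts, pts), 5, day_index = c(2, 2)),
               "strictly increasing")
})

test_that("7-session synthetic registration recovers planted identities", {
  cfg <- duo_config(session_duration_s = 10)  # 150 cells, jitter 2 px
  pop <- simulate_population(cfg)
  cents <- lapply(1:7, function(s) session_centroids(pop, s))
  map <- register_cross_session(cents, 5, day_index = seq(0, 12, 2))
  # local index equals ground-truth cell here, so a correctly tracked
  # identity keeps one local index across its sessions
  consistent <- vapply(split(map$assignments$local_index,
                             map$assignments$global_id),
                       function(v) length(unique(v)) == 1, logical(1))
  expect_gte(sum(consistent & table(map$assignments$global_id) == 7) /
               cfg$n_cells, 0.95)
})

test_that("propagation lets dynamic cells inherit static identities", {
  pts <- cbind(c(10, 30, 50, 70), c(10, 30, 50, 70))
  smap <- register_cross_session(list(pts, pts, pts), 5)
  # dynamic channel: cell 4 active in sessions 1 and 3 only; all dynamic
  # centroids coincide with the static ones
  gc <- list(pts, pts[1:3, ], pts)
  cc <- lapply(gc, function(g) register_cross_channel(g, pts, 5))
  gmap <- propagate_gcamp_map(smap, cc)
  am <- build_activity_matrix(gmap)
  expect_equal(unname(rowSums(am)), c(3, 3, 3, 2))
  expect_equal(attr(gmap, "stable_ids"), 1:4)

  # no static detections -> nothing propagated
  none <- lapply(gc, function(g)
    register_cross_channel(g, matrix(numeric(0), 0, 2), 5))
  expect_true(all(vapply(none, function(m) nrow(m$pairs) == 0, logical(1))))
})

test_that("propagated map matches ground truth on a synthetic experiment", {
  cfg <- tiny_config(n_sessions = 4, session_duration_s = 10, n_cells = 30,
                     fov_shape = c(150, 150))
  ex <- simulate_experiment(cfg)
  det <- lapply(ex$sessions, function(s)
    detect_cells(render_static_summary(s)))
  smap <- register_cross_session(det, 5)
  cc <- lapply(seq_len(4), function(s)
    register_cross_channel(ex$sessions[[s]]$footprints_gcamp, det[[s]], 5))
  gmap <- propagate_gcamp_map(smap, cc)
  am <- build_activity_matrix(gmap)
  # with constitutive static landmarks every global id is stable
  expect_equal(length(attr(gmap, "stable_ids")), smap$n_global)
  # activity matrix equals the ground-truth schedule for tracked cells
  truth_rows <- ex$truth$active_matrix[rowSums(ex$truth$active_matrix) > 0, ]
  expect_equal(sort(unname(rowSums(am))), sort(unname(rowSums(truth_rows))))
  expect_equal(unname(colSums(am)), unname(colSums(truth_rows)))
})

test_that("one-to-one invariants hold on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- cbind(runif(40, 0, 100), runif(40, 0, 100))
    b <- cbind(runif(35, 0, 100), runif(35, 0, 100))
    mm <- match_centroids(a, b, 8)
    expect_false(anyDuplicated(mm$pairs$index_a) > 0)
    expect_false(anyDuplicated(mm$pairs$index_b) > 0)
    expect_true(all(mm$pairs$dist <= 8))
  }
})
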