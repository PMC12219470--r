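# Shared fixtures: small worlds that keep individual tests fast.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_sessions = 3, session_duration_s = 60, fps = 10,
         n_cells = 20, fov_shape = c(100, 100)),
    list(...))
  do.call(duo_config, args)
}

# A single-session world with annotated trajectory, used by spatial tests.
small_session <- function(n_cells = 20, duration = 120, fps = 10,
                          place_fraction = 0.5, seed = 42, ...) {
  cfg <- duo_config(n_sessions = 1, session_duration_s = duration, fps = fps,
                    n_cells = n_cells, fov_shape = c(120, 120),
                    place_cell_fraction = place_fraction, activity_prob = 1,
                    seed = seed, ...)
  pop <- simulate_population(cfg)
  traj <- annotate_trajectory(simulate_trajectory(cfg))
  ses <- simulate_session_traces(pop, traj, cfg, 1)
  list(cfg = cfg, pop = pop, traj = traj, ses = ses)
}

# Activity matrix straight from a logical matrix literal.
am_of <- function(rows, day_index = NULL) {
  m <- do.call(rbind, rows)
  if (is.null(day_index)) day_index <- seq_len(ncol(m)) - 1
  activity_matrix(m, day_index)
}

# Independent oracle for the per-session tracking probability: explicit
# per-cell, per-session accumulation of 1/(k * N_i).
tracking_oracle <- function(m) {
  k <- ncol(m)
  n_i <- colSums(m)
  p <- numeric(k)
  for (cell in seq_len(nrow(m))) {
    rs <- sum(m[cell, ])
    for (i in seq_len(k)) {
      if (m[cell, i]) p[rs] <- p[rs] + 1 / (k * n_i[i])
    }
  }
  p
}

# Brute-force local-maximum scan used as detection oracle: a pixel is a
# peak when strictly greater than every pixel within `radius`.
bruteforce_peaks <- function(img, radius = 1, threshold = -Inf) {
  nr <- nrow(img); nc <- ncol(img)
  out <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (img[r, c] <= threshold) next
    rr <- max(1, r - radius):min(nr, r + radius)
    cc <- max(1, c - radius):min(nc, c + radius)
    nb <- img[rr, cc]
    nb[which(rr == r), which(cc == c)] <- -Inf
    if (img[r, c] > max(nb)) out <- rbind(out, c(r, c))
  }
  out
}

# Planted-blob image: isotropic Gaussians at given centres.
blob_image <- function(centers, fov = c(60, 60), sigma = 2, amp = 1) {
  img <- matrix(0, fov[1], fov[2])
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(fov[1]) - centers[i, 1])^2,
                (seq_len(fov[2]) - centers[i, 2])^2, "+")
    img <- img + amp * exp(-d2 / (2 * sigma^2))
  }
  img
}
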