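# Centroid-distance cell registration: across channels within a session
# and across sessions through a running reference.

#' Match two centroid sets by mutual nearest neighbours
#'
#' Pairs are mutual nearest neighbours with distance at most `max_dist`,
#' reported in ascending distance order (ties broken by lower index pair).
#' Mutual-nearest-neighbour pairs are one-to-one by construction;
#' swapping the inputs swaps pair columns only.
#'
#' @param centroids_a,centroids_b Numeric matrices, one `(row, col)` per
#'   cell.
#' @param max_dist Maximum pairing distance in pixels (> 0).
#' @return A `duo_matches` list: `pairs` (data.frame `index_a`, `index_b`,
#'   `dist`), `unmatched_a`, `unmatched_b`.
#' @export
match_centroids <- function(centroids_a, centroids_b, max_dist = 5) {
  assert_that(max_dist > 0, "max_dist must be positive")
  centroids_a <- as_centroid_matrix(centroids_a)
  centroids_b <- as_centroid_matrix(centroids_b)
  na <- nrow(centroids_a); nb <- nrow(centroids_b)
  empty <- data.frame(index_a = integer(0), index_b = integer(0),
                      dist = numeric(0))
  if (na == 0L || nb == 0L) {
    return(structure(list(pairs = empty, unmatched_a = seq_len(na),
                          unmatched_b = seq_len(nb)), class = "duo_matches"))
  }
  d <- sqrt(outer(centroids_a[, 1], centroids_b[, 1], "-")^2 +
              outer(centroids_a[, 2], centroids_b[, 2], "-")^2)
  nn_b <- apply(d, 1, which.min)            # best b for each a
  nn_a <- apply(d, 2, which.min)            # best a for each b
  a_idx <- seq_len(na)
  mutual <- nn_a[nn_b[a_idx]] == a_idx &
    d[cbind(a_idx, nn_b[a_idx])] <= max_dist
  pairs <- data.frame(index_a = a_idx[mutual],
                      index_b = nn_b[a_idx][mutual],
                      dist = d[cbind(a_idx[mutual], nn_b[a_idx][mutual])])
  ord <- order(pairs$dist, pairs$index_a, pairs$index_b)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(seq_len(na), pairs$index_a),
                 unmatched_b = setdiff(seq_len(nb), pairs$index_b)),
            class = "duo_matches")
}

#' @keywords internal
#' @noRd
as_centroid_matrix <- function(x) {
  if (is.list(x) && length(x) > 0 && inherits(x[[1]], "duo_footprint"))
    return(footprint_centroids(x))
  if (is.list(x) && length(x) == 0L) return(matrix(numeric(0), 0, 2))
  x <- as.matrix(x)
  assert_that(ncol(x) == 2, "centroids must be an n x 2 matrix")
  x
}

#' Register dynamic-channel cells to static-channel cells within a session
#'
#' @param gcamp_fps,static_fps Footprint lists (or centroid matrices).
#' @param max_dist Maximum centroid distance in pixels.
#' @return A `duo_matches` with `index_a` indexing the dynamic channel and
#'   `index_b` the static channel.
#' @export
register_cross_channel <- function(gcamp_fps, static_fps, max_dist = 5) {
  match_centroids(gcamp_fps, static_fps, max_dist)
}

#' Register cells across sessions against a running reference
#'
#' The first session seeds the reference.  Each later session is matched
#' to the reference by [match_centroids()]; matched reference centroids
#' are updated to the running mean of their members, unmatched session
#' cells open new global identities, and unmatched reference cells are
#' simply absent from that session.
#'
#' @param footprints_by_session List (one element per session) of
#'   footprint lists or centroid matrices.
#' @param max_dist Maximum centroid distance in pixels.
#' @param day_index Optional day index per session (defaults to
#'   `0, 1, 2, ...`); must be strictly increasing.
#' @param channel Channel label stored in the map.
#' @return A `duo_regmap`: `assignments` data.frame (`global_id`,
#'   `session`, `channel`, `local_index`), `n_sessions`, `day_index`,
#'   `n_global`.
#' @export
register_cross_session <- function(footprints_by_session, max_dist = 5,
                                   day_index = NULL, channel = "static") {
  k <- length(footprints_by_session)
  assert_that(k >= 1, "need at least one session")
  fov_shapes <- lapply(footprints_by_session, function(fps) {
    if (is.list(fps) && length(fps) > 0 && inherits(fps[[1]], "duo_footprint"))
      fps[[1]]$fov_shape else NULL
  })
  fov_shapes <- fov_shapes[!vapply(fov_shapes, is.null, logical(1))]
  if (length(fov_shapes) > 1) {
    assert_that(all(vapply(fov_shapes, function(s)
      all(s == fov_shapes[[1]]), logical(1))),
      "shape error: field-of-view shapes differ across sessions")
  }
  day_index <- day_index %||% (seq_len(k) - 1)
  assert_that(all(diff(day_index) > 0) || k == 1,
              "day indices must be strictly increasing")

  cents <- lapply(footprints_by_session, as_centroid_matrix)
  ref <- cents[[1]]
  ref_count <- rep(1L, nrow(ref))
  asg <- data.frame(global_id = seq_len(nrow(ref)),
                    session = rep(1L, nrow(ref)),
                    channel = channel,
                    local_index = seq_len(nrow(ref)))
  for (s in seq_len(k)[-1]) {
    cur <- cents[[s]]
    mm <- match_centroids(ref, cur, max_dist)
    if (nrow(mm$pairs) > 0) {
      gi <- mm$pairs$index_a
      li <- mm$pairs$index_b
      asg <- rbind(asg, data.frame(global_id = gi, session = s,
                                   channel = channel, local_index = li))
      ref[gi, ] <- (ref[gi, , drop = FALSE] * ref_count[gi] +
                      cur[li, , drop = FALSE]) / (ref_count[gi] + 1)
      ref_count[gi] <- ref_count[gi] + 1L
    }
    if (length(mm$unmatched_b) > 0) {
      new_ids <- nrow(ref) + seq_along(mm$unmatched_b)
      asg <- rbind(asg, data.frame(global_id = new_ids, session = s,
                                   channel = channel,
                                   local_index = mm$unmatched_b))
      ref <- rbind(ref, cur[mm$unmatched_b, , drop = FALSE])
      ref_count <- c(ref_count, rep(1L, length(mm$unmatched_b)))
    }
  }
  rownames(asg) <- NULL
  structure(list(assignments = asg, n_sessions = k, day_index = day_index,
                 n_global = nrow(ref), channel = channel),
            class = "duo_regmap")
}

#' Propagate a static-channel cross-session map to the dynamic channel
#'
#' Each dynamic-channel cell inherits the global identity of its
#' cross-channel static partner; cells without a static partner are
#' excluded.  The "stable" subset consists of global identities whose
#' static landmark is present in every session.
#'
#' @param static_map A `duo_regmap` for the static channel.
#' @param cross_channel List of `duo_matches` per session (`index_a` =
#'   dynamic local index, `index_b` = static local index).
#' @return A `duo_regmap` for the dynamic channel with attribute
#'   `stable_ids` (global ids tracked in all sessions in the static
#'   channel).
#' @export
propagate_gcamp_map <- function(static_map, cross_channel) {
  assert_that(inherits(static_map, "duo_regmap"), "static_map must be a duo_regmap")
  assert_that(length(cross_channel) == static_map$n_sessions,
              "one cross-channel matching per session required")
  sasg <- static_map$assignments
  rows <- list()
  for (s in seq_len(static_map$n_sessions)) {
    mm <- cross_channel[[s]]
    ses <- sasg[sasg$session == s, ]
    lut <- stats::setNames(ses$global_id, ses$local_index)
    p <- mm$pairs
    gid <- lut[as.character(p$index_b)]
    keep <- !is.na(gid)
    gid <- gid[keep]
    if (anyDuplicated(gid))
      stop("conflict error: two dynamic cells inherit one global id",
           call. = FALSE)
    if (any(keep)) {
      rows[[s]] <- data.frame(global_id = as.integer(gid), session = s,
                              channel = "gcamp",
                              local_index = p$index_a[keep])
    }
  }
  asg <- do.call(rbind, rows)
  rownames(asg) <- NULL
  per_session <- table(factor(sasg$global_id, levels = seq_len(static_map$n_global)))
  stable_ids <- as.integer(names(per_session)[per_session == static_map$n_sessions])
  out <- structure(list(assignments = asg, n_sessions = static_map$n_sessions,
                        day_index = static_map$day_index,
                        n_global = static_map$n_global, channel = "gcamp"),
                   class = "duo_regmap")
  attr(out, "stable_ids") <- stable_ids
  out
}

#' @export
print.duo_regmap <- function(x, ...) {
  cat(sprintf("<duo_regmap> %s channel: %d global ids over %d sessions (%d assignments)\n",
              x$channel, x$n_global, x$n_sessions, nrow(x$assignments)))
  invisible(x)
}

#' @export
print.duo_matches <- function(x, ...) {
  cat(sprintf("<duo_matches> %d pairs (%d/%d unmatched)\n",
              nrow(x$pairs), length(x$unmatched_a), length(x$unmatched_b)))
  invisible(x)
}
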