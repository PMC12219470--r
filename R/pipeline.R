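# End-to-end orchestration: simulate -> detect -> register -> crosstalk ->
# tracking -> spatial/drift, with a self-describing run manifest.

#' Run the full synthetic-data analysis pipeline
#'
#' Executes every stage in dependency order on a simulated experiment and
#' writes plain-text results plus a manifest with per-file checksums.
#' Identical config and seed give byte-identical outputs.
#'
#' @param config A [duo_config()] (see [duo_config_demo()] for a
#'   desk-scale run).
#' @param out_dir Output directory (created if missing).
#' @param n_shuffles Place-cell shuffles per cell (default 500).
#' @param crosstalk_shuffles Shuffles per cell for the cross-talk null.
#' @param detection A [detection_params()] for the static channel.
#' @param max_dist Registration centroid-distance threshold, px.
#' @return The run manifest (invisibly), also written as
#'   `manifest.json`.
#' @export
run_full_analysis <- function(config = duo_config_demo(), out_dir,
                              n_shuffles = 500, crosstalk_shuffles = 100,
                              detection = detection_params(),
                              max_dist = 5) {
  assert_that(inherits(config, "duo_config"), "config must be a duo_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # circular-shuffle shift floor: 30 s, capped for very short sessions
  min_shift_s <- min(30, config$session_duration_s / 4)
  log_lines <- character(0)
  stamp <- function(stage) {
    log_lines <<- c(log_lines, sprintf("stage=%s elapsed=%.1fs", stage,
                                       proc.time()[["elapsed"]] - t0))
  }
  t0 <- proc.time()[["elapsed"]]

  ## -- simulate ---------------------------------------------------------
  exp <- simulate_experiment(config)
  for (s in seq_along(exp$sessions)) {
    exp$sessions[[s]]$trajectory <- annotate_trajectory(exp$sessions[[s]]$trajectory)
  }
  day_index <- vapply(exp$sessions, `[[`, numeric(1), "day")
  stamp("simulate")

  ## -- detect static cells ---------------------------------------------
  detected <- lapply(exp$sessions, function(ses) {
    detect_cells(render_static_summary(ses, seed = config$seed), detection)
  })
  stamp("detect")

  ## -- registration -----------------------------------------------------
  static_map <- register_cross_session(detected, max_dist, day_index,
                                       channel = "static")
  cross_channel <- lapply(seq_along(exp$sessions), function(s) {
    register_cross_channel(exp$sessions[[s]]$footprints_gcamp, detected[[s]],
                           max_dist)
  })
  gcamp_map <- propagate_gcamp_map(static_map, cross_channel)
  gcamp_only_map <- register_cross_session(
    lapply(exp$sessions, `[[`, "footprints_gcamp"), max_dist, day_index,
    channel = "gcamp")
  stable_ids <- attr(gcamp_map, "stable_ids")
  stamp("register")

  ## -- crosstalk ---------------------------------------------------------
  # registered pairs: dynamic cell <-> its static partner; the synthetic
  # static trace of the same ground-truth cell stands in for projecting
  # the (unmaterialized) static movie onto the matched footprint
  g_rows <- list(); s_rows <- list()
  for (s in seq_along(exp$sessions)) {
    ses <- exp$sessions[[s]]
    p <- cross_channel[[s]]$pairs
    if (nrow(p) == 0) next
    true_cells <- attr(ses$gcamp_fluor, "true_cell")[p$index_a]
    g_rows[[s]] <- ses$gcamp_fluor[p$index_a, , drop = FALSE]
    s_rows[[s]] <- ses$static_traces[true_cells, , drop = FALSE]
  }
  ct <- crosstalk_estimate(do.call(rbind, g_rows), do.call(rbind, s_rows),
                           n_shuffles = crosstalk_shuffles,
                           seed = config$seed, fps = config$fps,
                           min_shift = round(min_shift_s * config$fps))
  ct_summary <- summarize_crosstalk(ct)
  stamp("crosstalk")

  ## -- tracking ----------------------------------------------------------
  am_static <- build_activity_matrix(static_map)
  am_gcamp <- build_activity_matrix(gcamp_only_map)
  am_stable <- build_activity_matrix(gcamp_map, subset = stable_ids)
  tracking_tab <- rbind(
    data.frame(criterion = "dtomato", m = seq_len(config$n_sessions),
               p = tracking_probability(am_static)),
    data.frame(criterion = "gcamp", m = seq_len(config$n_sessions),
               p = tracking_probability(am_gcamp)),
    data.frame(criterion = "stable_gcamp", m = seq_len(config$n_sessions),
               p = tracking_probability(am_stable)))
  stamp("tracking")

  ## -- spatial: place cells and rate maps -------------------------------
  pc_flags <- list()       # per session: named logical by gcamp local idx
  maps <- list()           # per session: list local idx -> normalized map
  for (s in seq_along(exp$sessions)) {
    ses <- exp$sessions[[s]]
    design <- spatial_design(ses$trajectory)
    n_loc <- nrow(ses$events)
    flags <- logical(n_loc)
    mlist <- vector("list", n_loc)
    for (i in seq_len(n_loc)) {
      pc <- place_cell_test(ses$events[i, ], ses$trajectory,
                            n_shuffles = n_shuffles,
                            seed = derive_seed(config$seed, "pc", s, i),
                            min_shift_s = min_shift_s, design = design)
      flags[i] <- pc$is_place_cell
      rmap <- try(rate_map(ses$events[i, ], ses$trajectory), silent = TRUE)
      mlist[[i]] <- if (inherits(rmap, "try-error") || rmap$silent)
        NULL else rmap$normalized
    }
    pc_flags[[s]] <- flags
    maps[[s]] <- mlist
  }
  stamp("placecells")

  ## -- drift: reactivation and PV correlation vs interval ----------------
  lookup <- function(map) {
    a <- map$assignments
    lapply(seq_len(map$n_sessions), function(s) {
      ss <- a[a$session == s, ]
      stats::setNames(ss$local_index, ss$global_id)
    })
  }
  lut_g <- lookup(gcamp_only_map)   # all-GCaMP identities
  lut_p <- lookup(gcamp_map)        # dTomato-propagated identities

  place_ids <- function(lut, s) {
    loc <- lut[[s]]
    as.integer(names(loc)[pc_flags[[s]][loc]])
  }
  maps_for <- function(lut, s, ids) {
    loc <- lut[[s]]
    out <- matrix(NA_real_, length(ids), 200)
    for (j in seq_along(ids)) {
      li <- loc[as.character(ids[j])]
      if (!is.na(li) && !is.null(maps[[s]][[li]]))
        out[j, ] <- maps[[s]][[li]]
    }
    out
  }
  pairs <- session_pairs(am_gcamp)
  drift_rows <- list()
  for (r in seq_len(nrow(pairs))) {
    A <- pairs$A[r]; B <- pairs$B[r]; iv <- pairs$interval_days[r]
    add <- function(metric, criterion, value) {
      drift_rows[[length(drift_rows) + 1L]] <<-
        data.frame(A = A, B = B, interval_days = iv, metric = metric,
                   criterion = criterion, value = value)
    }
    # reactivation over place cells (union of the pair)
    for (cr in c("gcamp", "stable_gcamp")) {
      lut <- if (cr == "gcamp") lut_g else lut_p
      am <- if (cr == "gcamp") am_gcamp else am_stable
      ids <- union(place_ids(lut, A), place_ids(lut, B))
      if (cr == "stable_gcamp") ids <- intersect(ids, stable_ids)
      ids <- ids[as.character(ids) %in% rownames(am)]
      if (length(ids) >= 2) {
        sub <- am[as.character(ids), , drop = FALSE]
        n_a <- sum(sub[, A]); n_b <- sum(sub[, B])
        if (n_a > 0 && n_b > 0) {
          n2 <- sum(sub[, A] & sub[, B])
          add("reactivation", cr, 0.5 * (n2 / n_a + n2 / n_b))
        }
      }
    }
    # PV correlation under the three inclusion criteria
    pv_try <- function(ids, lut, mode, criterion) {
      if (length(ids) < 2) return(invisible(NULL))
      ma <- maps_for(lut, A, ids)
      mb <- maps_for(lut, B, ids)
      v <- try(pv_correlation(ma, mb, mode), silent = TRUE)
      if (!inherits(v, "try-error") && is.finite(v)) add("pv", criterion, v)
    }
    ids_g <- union(place_ids(lut_g, A), place_ids(lut_g, B))
    ids_p <- intersect(union(place_ids(lut_p, A), place_ids(lut_p, B)),
                       stable_ids)
    pv_try(ids_g, lut_g, "zero-fill", "gcamp")
    pv_try(ids_p, lut_p, "zero-fill", "stable_gcamp")
    pv_try(ids_g, lut_g, "intersect", "always_active")
  }
  drift_tab <- do.call(rbind, drift_rows)
  slopes <- list()
  for (metric in unique(drift_tab$metric)) {
    for (cr in unique(drift_tab$criterion[drift_tab$metric == metric])) {
      sub <- drift_tab[drift_tab$metric == metric & drift_tab$criterion == cr, ]
      if (nrow(sub) >= 3 && length(unique(sub$interval_days)) >= 2) {
        slopes[[paste(metric, cr, sep = "_")]] <-
          slope_vs_interval(sub$interval_days, sub$value)
      }
    }
  }
  stamp("drift")

  ## -- write results -----------------------------------------------------
  wcsv <- function(d, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(d, path, row.names = FALSE)
    path
  }
  pc_tab <- do.call(rbind, lapply(seq_along(pc_flags), function(s)
    data.frame(session = s, local_index = seq_along(pc_flags[[s]]),
               is_place_cell = pc_flags[[s]])))
  files <- c(
    wcsv(tracking_tab, "tracking_probability.csv"),
    wcsv(drift_tab, "drift.csv"),
    wcsv(pc_tab, "place_cells.csv"),
    wcsv(data.frame(cell = seq_along(ct$coefficients),
                    beta = ct$coefficients,
                    null_mean = rowMeans(ct$null)), "crosstalk.csv")
  )
  res_json <- file.path(out_dir, "results.json")
  jsonlite::write_json(list(
    crosstalk = list(observed_mean = ct_summary$observed_mean,
                     null_mean = ct_summary$null_mean,
                     paired_t_p = ct_summary$paired_t$p.value),
    slopes = slopes,
    n_detected_static = vapply(detected, length, integer(1)),
    n_global_static = static_map$n_global,
    n_stable = length(stable_ids)
  ), res_json, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  files <- c(files, res_json)

  manifest <- list(
    package_version = as.character(utils::packageVersion("duoscope")),
    config = unclass(config),
    seed = config$seed,
    n_shuffles = n_shuffles,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))),
    log = log_lines
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(manifest)
}

#' Build report tables (and optional plots) from a results directory
#'
#' Aggregates stage outputs into per-figure tables: tracking probability
#' per criterion, mean reactivation and PV correlation per time interval.
#' Missing stage outputs produce an explicit gap note instead of an error.
#'
#' @param results_dir Directory written by [run_full_analysis()].
#' @param plots Also render PDF figures (default FALSE; the tables are the
#'   canonical, byte-stable output).
#' @return Character vector of files written (invisibly).
#' @export
make_report <- function(results_dir, plots = FALSE) {
  rep_dir <- file.path(results_dir, "report")
  dir.create(rep_dir, showWarnings = FALSE)
  notes <- character(0)
  written <- character(0)
  rd <- function(name) {
    p <- file.path(results_dir, name)
    if (!file.exists(p)) { notes <<- c(notes, paste("missing:", name)); NULL }
    else utils::read.csv(p)
  }
  tr <- rd("tracking_probability.csv")
  if (!is.null(tr)) {
    p <- file.path(rep_dir, "fig_tracking.csv")
    utils::write.csv(tr, p, row.names = FALSE)
    written <- c(written, p)
  }
  dr <- rd("drift.csv")
  if (!is.null(dr) && nrow(dr) > 0) {
    agg <- stats::aggregate(value ~ metric + criterion + interval_days, dr, mean)
    agg <- agg[order(agg$metric, agg$criterion, agg$interval_days), ]
    p <- file.path(rep_dir, "fig_drift_vs_interval.csv")
    utils::write.csv(agg, p, row.names = FALSE)
    written <- c(written, p)
    if (plots) {
      pdf_path <- file.path(rep_dir, "fig_drift_vs_interval.pdf")
      grDevices::pdf(pdf_path, width = 6, height = 4)
      for (metric in unique(agg$metric)) {
        sub <- agg[agg$metric == metric, ]
        plot(NULL, xlim = range(sub$interval_days), ylim = range(sub$value),
             xlab = "interval (days)", ylab = metric,
             main = paste(metric, "vs time interval"))
        crs <- unique(sub$criterion)
        for (i in seq_along(crs)) {
          s2 <- sub[sub$criterion == crs[i], ]
          graphics::lines(s2$interval_days, s2$value, col = i, type = "b")
        }
        graphics::legend("topright", legend = crs, col = seq_along(crs), lty = 1)
      }
      grDevices::dev.off()
      written <- c(written, pdf_path)
    }
  } else if (is.null(dr) || nrow(dr) == 0) {
    notes <- c(notes, "missing panel: drift vs interval (no tracking results)")
  }
  notes_path <- file.path(rep_dir, "report_notes.txt")
  writeLines(if (length(notes)) notes else "complete", notes_path)
  invisible(c(written, notes_path))
}

#' Path to a bundled synthetic spectra stand-in
#'
#' The package bundles a *synthetic* approximation of a GCaMP-like
#' emission spectrum and idealized 525/50 (green) and 630/75 (red)
#' band-pass filter curves; these are constructed stand-ins, not measured
#' vendor curves.
#'
#' @param which `"emission"`, `"green"` or `"red"`.
#' @return File path of the CSV.
#' @export
synthetic_spectra_path <- function(which = c("emission", "green", "red")) {
  which <- match.arg(which)
  f <- switch(which,
              emission = "gcamp_emission_synthetic.csv",
              green = "filter_green_525-50_synthetic.csv",
              red = "filter_red_630-75_synthetic.csv")
  system.file("extdata", f, package = "duoscope", mustWork = TRUE)
}
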