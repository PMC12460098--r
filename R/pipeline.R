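#' Run the full avoidance-analysis pipeline on one synthetic trial
#'
#' Simulates a sonar stream under a treatment schedule, builds the
#' trimmed before/during/after CFP triplet for every stimulus event,
#' segments each CFP, measures the avoidance distance, and (optionally)
#' runs the permutational ANOVA on the assembled measurement table.
#' Stage failures (empty windows, invalid-category images) are logged
#' with their event id and the run continues; a run yielding zero valid
#' measurements fails.
#'
#' @param config A [sonar_config()].
#' @param params A [school_params()]; per-level displacement factors go
#'   in its `displacement_factor` named vector.
#' @param schedule A [make_schedule()] result.
#' @param trim Seconds trimmed at each phase boundary (default 5).
#' @param seg A [seg_params()] for the classical backend.
#' @param backend Segmentation backend, `"classical"` or `"dl"`.
#' @param model Trained `segmenter_model` when `backend = "dl"`.
#' @param metres_per_pixel Raster scale; defaults to the range
#'   resolution.
#' @param meta Named list of trial-level labels attached to every
#'   measurement (e.g. `pen = "A"`, `depth = 8`).
#' @param run_stats Run [permanova()] on the measurement table.
#' @param n_perm,seed Permutations for the statistics and the master
#'   seed for the whole run (simulation + permutation).
#' @param out_dir Optional output directory; when given, the
#'   measurement table, ANOVA tables and a JSON run manifest are
#'   written there.
#' @return List with `schedule`, `truth`, `measurements` (tidy data
#'   frame: replicate, pen, depth, level, phase, category, censored,
#'   distance_m, n_frames), `stats`, `pairwise`, `log`, `config`,
#'   `params`.
#' @export
run_pipeline <- function(config = sonar_config(),
                         params = school_params(),
                         schedule = make_schedule("stim", 3, seed = 1),
                         trim = 5, seg = seg_params(),
                         backend = c("classical", "dl"), model = NULL,
                         metres_per_pixel = config$range_resolution,
                         meta = list(), run_stats = TRUE, n_perm = 999,
                         seed = 1, out_dir = NULL) {
  backend <- match.arg(backend)
  sim <- simulate_frames(params, schedule, config, seed = seed)
  rep_counter <- stats::setNames(rep(0L, length(unique(schedule$level))),
                                 unique(schedule$level))
  rows <- list(); log <- list()
  for (i in seq_len(nrow(schedule))) {
    lev <- schedule$level[i]
    rep_counter[lev] <- rep_counter[lev] + 1L
    w <- phase_windows(schedule$onset[i], schedule$duration[i], trim)
    for (p in seq_len(nrow(w))) {
      ev_meta <- c(list(phase = w$phase[p], level = lev,
                        replicate = rep_counter[lev]), meta)
      row <- tryCatch({
        cfp <- accumulate_cfp(sim$frames, w[p, ], metres_per_pixel,
                              meta = ev_meta)
        mask <- segment(cfp, backend, seg, model)
        m <- avoidance_distance(mask)
        m$n_frames <- cfp$n_frames
        m
      }, pensonar_empty_window = function(e) e,
         pensonar_not_measurable = function(e) e)
      if (inherits(row, "condition")) {
        log[[length(log) + 1L]] <- data.frame(
          event = i, level = lev, replicate = rep_counter[lev],
          phase = w$phase[p], status = "excluded",
          note = conditionMessage(row), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- row
        log[[length(log) + 1L]] <- data.frame(
          event = i, level = lev, replicate = rep_counter[lev],
          phase = w$phase[p], status = row$category,
          note = sprintf("distance %.3f m", row$distance_m),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    stop("run produced zero valid measurements")
  measurements <- do.call(rbind, rows)
  measurements$phase <- factor(measurements$phase,
                               levels = c("before", "during", "after"))
  log <- do.call(rbind, log)

  stats_res <- NULL; pw <- NULL
  if (run_stats) {
    f <- if (length(unique(measurements$level)) > 1)
      distance_m ~ phase * level else distance_m ~ phase
    stats_res <- permanova(f, measurements, n_perm = n_perm,
                           seed = seed + 1L)
    pw <- tryCatch(
      pairwise_permanova(distance_m ~ phase, measurements,
                         n_perm = n_perm, seed = seed + 2L),
      error = function(e) NULL)
  }
  out <- list(schedule = schedule, truth = sim$truth,
              measurements = measurements, stats = stats_res,
              pairwise = pw, log = log, config = config, params = params)
  if (!is.null(out_dir)) write_run(out, out_dir, seed)
  out
}

# Write the run's tables and manifest under out_dir.
write_run <- function(run, out_dir, seed) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
  utils::write.csv(run$measurements,
                   file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(run$log, file.path(out_dir, "run_log.csv"),
                   row.names = FALSE)
  utils::write.csv(run$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  if (!is.null(run$stats))
    utils::write.csv(run$stats$aov.tab,
                     file.path(out_dir, "permanova.csv"),
                     row.names = FALSE)
  if (!is.null(run$pairwise))
    utils::write.csv(run$pairwise,
                     file.path(out_dir, "pairwise.csv"),
                     row.names = FALSE)
  manifest <- list(
    package = "pensonar",
    version = as.character(utils::packageVersion("pensonar")),
    seed = seed,
    config = unclass(run$config),
    params = unclass(run$params),
    n_events = nrow(run$schedule))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Build a miniature deterministic test dataset
#'
#' Generates a desk-size trial (reduced sonar geometry, 2 levels x 2
#' replicates, shortened protocol) plus one CFP image of each
#' segmentation category, for use by tests and examples.  Deterministic
#' for a fixed seed.
#'
#' @param seed Integer seed.
#' @param dir Optional directory; when given, the schedule, ground truth
#'   and per-category CFP summaries are written as plain-text files.
#' @return List with `config`, `params`, `schedule`, `frames`, `truth`,
#'   and `cfp` (named list with one `cfp_image` per category:
#'   `pattern`, `out_of_range`, `invalid`).
#' @export
make_fixtures <- function(seed = 1, dir = NULL) {
  config <- sonar_config(n_bearings = 120L, n_range_bins = 50L,
                         range_resolution = 0.1, scan_period = 5,
                         exclusion_radius = 0.5)
  params <- school_params(n_agents = 60L, baseline_radius = 1.5,
                          radial_spread = 0.3,
                          displacement_factor = c(stim = 0.4, ctrl = 0))
  schedule <- make_schedule(c("stim", "ctrl"), repetitions = 2,
                            duration = 30, break_duration = 60,
                            order = "sequential", seed = seed)
  sim <- simulate_frames(params, schedule, config, seed = seed)
  w <- phase_windows(schedule$onset[1], schedule$duration[1], trim = 5)
  cfp_pattern <- accumulate_cfp(sim$frames, w[1, ],
                                meta = list(level = "stim"))
  empty <- simulate_frames(school_params(n_agents = 0L,
                                         baseline_radius = 1.5),
                           schedule, config, seed = seed + 1L)
  cfp_oor <- accumulate_cfp(empty$frames, w[1, ])
  inv <- make_invalid_frames(config, burst_level = 5, n_frames = 4,
                             seed = seed + 2L,
                             t_start = w$start[1])
  cfp_inv <- accumulate_cfp(inv, w[1, ])
  out <- list(config = config, params = params, schedule = schedule,
              frames = sim$frames, truth = sim$truth,
              cfp = list(pattern = cfp_pattern, out_of_range = cfp_oor,
                         invalid = cfp_inv))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(as.data.frame(schedule),
                     file.path(dir, "schedule.csv"), row.names = FALSE)
    utils::write.csv(sim$truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  out
}
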