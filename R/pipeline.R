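#' Read / write target tracks as CSV
#'
#' Columns `frame,label,x_px,y_px,radius_px,detected[,visible]`.
#' @param path File path.
#' @return A [target_track()] for the reader.
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$detected <- as.logical(df$detected)
  if ("visible" %in% names(df)) df$visible <- as.logical(df$visible)
  target_track(df)
}

#' @rdname read_track_csv
#' @param track A [target_track()].
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

default_config <- function() {
  list(participant = "p01", device = "tobii2",
       condition = "seated_chinrest", mode = "simulate",
       filter_window_s = 0.30, track_smooth_frames = 5,
       scenario = list(), out_dir = NULL)
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (!cfg$condition %in% c("seated_chinrest", "seated_free", "walking"))
    stop("unknown condition '", cfg$condition, "' in config", call. = FALSE)
  if (!cfg$device %in% c("tobii2", "tobii3"))
    stop("unknown device '", cfg$device, "' in config", call. = FALSE)
  cfg
}

pipeline_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the evaluation pipeline
#'
#' Executes preprocess -> (target acquisition) -> segment -> metrics for
#' one session and returns the per-interval results table plus report
#' artifacts. Inputs come either from a simulated session
#' (`mode: simulate`, the scenario built from the config and `seed`) or
#' from files (`mode: files`, with `gaze_path`, `track_path`,
#' `schedule_path`). The output is a pure function of (inputs, config,
#' seed).
#'
#' @param config Path to a YAML file or a named list. Recognized fields:
#'   `participant`, `device`, `condition`, `mode`, `filter_window_s`,
#'   `track_smooth_frames`, `scenario` (overrides for
#'   [synthetic_scenario()]), `gaze_path`, `track_path`, `schedule_path`,
#'   `out_dir`.
#' @param seed Integer seed for the simulated mode.
#' @param verbose Log each stage with counts.
#' @return List of class `pipeline_result`: `results` (one row per
#'   interval plus one aggregate row), `intervals`, `frames`, `track`,
#'   `heatmap`, `truth` (simulated mode only). When `out_dir` is set,
#'   `results.csv` and `heatmap.csv` are written there.
#' @export
run_pipeline <- function(config, seed = 1L, verbose = TRUE) {
  cfg <- load_config(config)
  if (cfg$mode == "simulate") {
    sc_args <- utils::modifyList(
      list(condition = cfg$condition, device = cfg$device, seed = seed),
      cfg$scenario)
    scenario <- do.call(synthetic_scenario, sc_args)
    ses <- simulate_session(scenario)
    rec <- ses$recording; track <- ses$track; schedule <- ses$schedule
    truth <- ses$truth
    pipeline_log(verbose, "simulate", "%d samples, %d track rows",
                 nrow(rec$samples), nrow(track))
  } else if (cfg$mode == "files") {
    rec <- read_gaze_export(cfg$gaze_path, device = cfg$device)
    track <- read_track_csv(cfg$track_path)
    schedule <- read_schedule(cfg$schedule_path)
    truth <- NULL
    pipeline_log(verbose, "load", "%d samples, %d track rows",
                 nrow(rec$samples), nrow(track))
  } else stop("unknown mode '", cfg$mode, "'", call. = FALSE)
  cam <- rec$camera

  filtered <- filter_recording(rec, cfg$filter_window_s)
  frames <- frame_average(filtered)
  frames_raw <- frame_average(rec)
  pipeline_log(verbose, "preprocess",
               "%d frames, missing %.2f%% raw / %.2f%% filtered",
               nrow(frames), missing_fraction(frames_raw),
               missing_fraction(frames))

  track <- smooth_track(track, cfg$track_smooth_frames)
  intervals <- if (cfg$condition == "walking")
    walking_intervals(track, frame_rate_hz = cam$frame_rate_hz)
  else seated_intervals(schedule)
  pipeline_log(verbose, "segment", "%d interval(s)", nrow(intervals))

  res <- do.call(rbind, lapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    r <- interval_accuracy(frames, track, cam, iv)
    r$speed_deg_s <- target_speed(track, cam, iv)
    r$interval <- i
    r
  }))
  agg <- data.frame(
    label = "all", start_t = min(res$start_t), end_t = max(res$end_t),
    accuracy_deg = mean(res$accuracy_deg[res$valid]),
    accuracy_median_deg = mean(res$accuracy_median_deg[res$valid]),
    bias_deg = mean(res$bias_deg[res$valid]),
    n_frames_valid = sum(res$n_frames_valid),
    missing_pct = mean(res$missing_pct),
    valid = any(res$valid),
    precision_rms_s2s_deg = mean(res$precision_rms_s2s_deg[res$valid]),
    precision_sd_deg = mean(res$precision_sd_deg[res$valid]),
    speed_deg_s = mean(res$speed_deg_s[res$valid]),
    interval = NA_integer_)
  results <- rbind(res, agg)
  results <- cbind(data.frame(participant = cfg$participant,
                              device = cfg$device,
                              condition = cfg$condition), results)
  pipeline_log(verbose, "metrics",
               "aggregate accuracy %.2f deg over %d interval(s)",
               agg$accuracy_deg, nrow(res))

  tpts <- do.call(rbind, lapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    f_idx <- interval_frames(iv, cam$frame_rate_hz)
    tr <- track[track$label == iv$label & track$frame %in% f_idx &
                  track$detected, c("x_px", "y_px")]
    tr
  }))
  hm <- if (nrow(tpts))
    heatmap_from_points(tpts$x_px, tpts$y_px, cam) else NULL

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(cfg$out_dir, "results.csv"),
                     row.names = FALSE)
    if (!is.null(hm))
      write_heatmap_csv(hm, file.path(cfg$out_dir, "heatmap.csv"))
    pipeline_log(verbose, "report", "artifacts written to %s", cfg$out_dir)
  }
  structure(list(results = results, intervals = intervals,
                 frames = frames, track = track, heatmap = hm,
                 truth = truth),
            class = "pipeline_result")
}

cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    out[[key]] <- args[i + 1]
    i <- i + 2
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic session's gaze export,
#' schedule and track to `--out`), `detect` (localize targets in a frame
#' directory and write the track), `evaluate` (run the full pipeline),
#' `report` (summarize one or more results tables across participants).
#' Each takes `--config`, `--seed`, `--out` and `--log-level`
#' (`info`/`quiet`). Invoke via `Rscript -e 'gazeqc::gazeqc_cli()' ...`
#' or the installed `exec/gazeqc` script.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the subcommand's main artifact.
#' @export
gazeqc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: gazeqc <simulate|detect|evaluate|report>",
                          call. = FALSE)
  cmd <- args[1]
  opts <- cli_args(args[-1])
  seed <- as.integer(opts$seed %||% 1)
  verbose <- (opts$`log-level` %||% "info") != "quiet"
  out <- opts$out
  cfg <- if (!is.null(opts$config)) load_config(opts$config)
         else load_config(list())
  switch(cmd,
    simulate = {
      stopifnot(!is.null(out))
      sc_args <- utils::modifyList(
        list(condition = cfg$condition, device = cfg$device, seed = seed),
        cfg$scenario)
      ses <- simulate_session(do.call(synthetic_scenario, sc_args))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_gaze_export(ses$recording, file.path(out, "gaze.csv"))
      write_schedule(ses$schedule, file.path(out, "schedule.csv"))
      write_track_csv(ses$track, file.path(out, "track.csv"))
      pipeline_log(verbose, "simulate", "session written to %s", out)
      invisible(ses)
    },
    detect = {
      stopifnot(!is.null(cfg$frames_dir), !is.null(out))
      src <- read_frames(cfg$frames_dir)
      rows <- lapply(seq_len(src$n), function(i) {
        if (cfg$condition == "walking") {
          img <- src$frame(i)
          prior <- tryCatch(carpet_vanishing_point(img),
                            error = function(e) NULL)
          if (is.null(prior))
            data.frame(frame = src$index[i], label = "bullseye",
                       x_px = NA_real_, y_px = NA_real_,
                       radius_px = NA_real_, detected = FALSE)
          else locate_bullseye(img, prior, frame_index = src$index[i])
        } else {
          out_i <- detect_dots(src$frame(i), frame_index = src$index[i])
          out_i$radius_px <- NA_real_
          out_i
        }
      })
      track <- target_track(do.call(rbind, rows))
      write_track_csv(track, out)
      pipeline_log(verbose, "detect", "%d frames -> %s", src$n, out)
      invisible(track)
    },
    evaluate = {
      if (!is.null(out)) cfg$out_dir <- out
      invisible(run_pipeline(cfg, seed = seed, verbose = verbose))
    },
    report = {
      stopifnot(!is.null(cfg$results_paths), !is.null(out))
      res <- do.call(rbind, lapply(cfg$results_paths, utils::read.csv))
      res <- res[!is.na(res$interval), , drop = FALSE]
      summ <- condition_summary(res)
      utils::write.csv(summ, out, row.names = FALSE)
      pipeline_log(verbose, "report", "summary written to %s", out)
      invisible(summ)
    },
    stop("unknown subcommand '", cmd, "'", call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
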