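# End-to-end orchestration: video -> tracks -> traces -> events -> kinetics
# -> potential-of-death series -> chains, with every artifact written as CSV
# next to a serialized run configuration and a checksummed MANIFEST, so a
# rerun on identical inputs and configuration is byte-identical.

#' Pipeline run configuration
#'
#' @param red_path,green_path Channel inputs for [read_stack()]; leave `NULL`
#'   when passing in-memory stacks to [run_pipeline()].
#' @param calibration A [calibration()].
#' @param tracking A [tracking_config()].
#' @param roi A [roi_geometry()].
#' @param t_lag_hours Apoptosis-rate window, hours (10 for accuracy
#'   benchmarking, 4 to resolve kinetics).
#' @param t_tilde_hours Cumulative-map window, hours; 16 h captures the vast
#'   majority of chain-of-death durations.
#' @param window_um,stride_um Sliding-window side and stride for the
#'   potential of death (stride defaults to the side: non-overlapping
#'   tiling).
#' @param aggregate Per-frame window aggregate, `"mean"` or `"max"`.
#' @param se_radius_px Wake structuring-element radius; `NULL` derives it
#'   from the average detected cell radius via [wake_radius()].
#' @param chain_radius_factor,chain_t_lag_hours Chain-growing parameters.
#' @param output_dir Where [run_pipeline()] writes artifacts; `NULL` skips
#'   writing.
#' @param seed Seed recorded with the run.
#' @return A `run_config` list.
#' @export
run_config <- function(red_path = NULL, green_path = NULL,
                       calibration = apoptomap::calibration(),
                       tracking = tracking_config(), roi = roi_geometry(),
                       t_lag_hours = 10, t_tilde_hours = 16,
                       window_um = 283, stride_um = NULL,
                       aggregate = "mean", se_radius_px = NULL,
                       chain_radius_factor = 10, chain_t_lag_hours = NULL,
                       output_dir = NULL, seed = 1) {
  if (t_lag_hours <= 0 || t_tilde_hours <= 0)
    abort("t_lag_hours and t_tilde_hours must be positive.",
          class = "apoptomap_config_error")
  structure(list(red_path = red_path, green_path = green_path,
                 calibration = calibration, tracking = tracking, roi = roi,
                 t_lag_hours = t_lag_hours, t_tilde_hours = t_tilde_hours,
                 window_um = window_um, stride_um = stride_um,
                 aggregate = aggregate, se_radius_px = se_radius_px,
                 chain_radius_factor = chain_radius_factor,
                 chain_t_lag_hours = chain_t_lag_hours %||% t_lag_hours,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full apoptosis-mapping pipeline
#'
#' @param cfg A [run_config()].
#' @param red,green Optional in-memory [frame_stack()]s overriding the
#'   configured paths.
#' @return An `apoptomap_run` object: list of tibbles `tracks`, `traces`,
#'   `events`, `kinetics`, `survival`, `pdeath`, `chains`, plus `threshold`,
#'   `avg_radius`, `se_radius_px`, `dims` and the `cfg`. If
#'   `cfg$output_dir` is set, all tables plus `run_config.json` and a
#'   checksummed `MANIFEST.csv` are written there.
#' @export
run_pipeline <- function(cfg = run_config(), red = NULL, green = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(red) && is.null(cfg$red_path))
    abort("No red channel: set `red_path` or pass `red`.",
          class = "apoptomap_config_error")
  if (is.null(green) && is.null(cfg$green_path))
    abort("No green channel: set `green_path` or pass `green`.",
          class = "apoptomap_config_error")
  cal <- cfg$calibration
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)),
            class = "apoptomap_stage_error", parent = e)
    })
  }
  red <- red %||% stage("read", read_stack(cfg$red_path, "red", cal))
  green <- green %||% stage("read", read_stack(cfg$green_path, "green", cal))
  if (!all(dim(red) == dim(green)))
    abort("Red and green stacks have different dimensions.",
          class = "apoptomap_format_error")
  dims <- dim(red)

  detections <- stage("detect", detect_stack(red, cfg$tracking))
  tracks <- stage("track",
                  link_tracks(detections, cfg$tracking, n_frames_total = dims[3]))
  avg_radius <- if (nrow(tracks) > 0L) mean(tracks$radius) else NA_real_
  traces <- stage("trace", extract_traces(tracks, green, cfg$roi, avg_radius))
  th <- stage("threshold", estimate_threshold(traces))
  events <- stage("events", call_death_times(traces, tracks, th))

  t_lag <- hours_to_frames(cfg$t_lag_hours, cal)
  kinetics <- stage("kinetics",
                    apoptosis_rate(events, tracks, t_lag, dims[3], cal))
  survival <- stage("survival",
                    overall_survival(events, tracks, dims[3], cal))

  se_r <- cfg$se_radius_px %||% wake_radius(avg_radius)
  t_tilde <- hours_to_frames(cfg$t_tilde_hours, cal)
  pdeath <- stage("pdeath", {
    if (t_tilde >= dims[3]) abort("t_tilde_hours spans the whole video.")
    md <- build_seed_video(events, dims)
    m <- propagate_wake(md, se_r)
    mc <- cumulative_map(m, t_tilde)
    windowed_pdeath(mc, cal, cfg$window_um, cfg$stride_um, cfg$aggregate)
  })
  chains <- stage("chains",
                  chain_of_death(events, cfg$chain_t_lag_hours, cal,
                                 cfg$chain_radius_factor))

  run <- structure(list(tracks = tracks, traces = traces, events = events,
                        kinetics = kinetics, survival = survival,
                        pdeath = pdeath, chains = chains,
                        threshold = th, avg_radius = avg_radius,
                        se_radius_px = se_r, dims = dims, cfg = cfg),
                   class = "apoptomap_run")
  if (!is.null(cfg$output_dir)) write_run(run, cfg$output_dir)
  run
}

#' @export
print.apoptomap_run <- function(x, ...) {
  cat(sprintf(paste0("<apoptomap_run: %d tracks, %d death events, th = %.3g, ",
                     "%d x %d x %d>\n"),
              dplyr::n_distinct(x$tracks$track_id), nrow(x$events),
              x$threshold, x$dims[1], x$dims[2], x$dims[3]))
  invisible(x)
}

#' Write run artifacts to a directory
#'
#' @param run An `apoptomap_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    tracks = run$tracks, traces = run$traces, events = run$events,
    kinetics = run$kinetics, survival = run$survival,
    pdeath = dplyr::select(run$pdeath, -dplyr::any_of("windows")),
    chains = dplyr::mutate(run$chains, member_ids = purrr::map_chr(
      .data$member_ids, paste, collapse = ";")))
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p)
    paths <- c(paths, p)
  }
  cfg_json <- file.path(dir, "run_config.json")
  jsonlite::write_json(serialize_config(run), cfg_json,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, cfg_json)
  manifest <- tibble(file = basename(paths),
                     md5 = unname(tools::md5sum(paths)))
  readr::write_csv(manifest, file.path(dir, "MANIFEST.csv"))
  invisible(dir)
}

serialize_config <- function(run) {
  cfg <- run$cfg
  list(red_path = cfg$red_path, green_path = cfg$green_path,
       pixel_size_um = cfg$calibration$pixel_size_um,
       frame_interval_h = cfg$calibration$frame_interval_h,
       tracking = unclass(cfg$tracking), roi = unclass(cfg$roi),
       t_lag_hours = cfg$t_lag_hours, t_tilde_hours = cfg$t_tilde_hours,
       window_um = cfg$window_um, stride_um = cfg$stride_um,
       aggregate = cfg$aggregate, se_radius_px = run$se_radius_px,
       chain_radius_factor = cfg$chain_radius_factor,
       chain_t_lag_hours = cfg$chain_t_lag_hours, seed = cfg$seed,
       threshold = run$threshold, avg_radius = run$avg_radius,
       dims = run$dims)
}

#' Statistic-only potential-of-death computation from an event table
#'
#' Skips tracking entirely: rasterizes a supplied event table, propagates
#' wakes, and evaluates the windowed potential of death. This is the entry
#' point for externally produced death events.
#'
#' @param events Event tibble (`x`, `y`, `radius`, `death_frame`).
#' @param dims `c(D1, D2, T)` of the underlying field.
#' @param cal A [calibration()].
#' @param t_tilde_hours Cumulative-window length, hours.
#' @param se_radius_px Wake erosion radius; defaults to
#'   [wake_radius()] of the mean event radius.
#' @param ... Passed to [windowed_pdeath()] (`window_um`, `stride_um`,
#'   `aggregate`).
#' @return The [windowed_pdeath()] tibble.
#' @export
pdeath_from_events <- function(events, dims, cal = calibration(),
                               t_tilde_hours = 16, se_radius_px = NULL, ...) {
  se_r <- se_radius_px %||% wake_radius(mean(events$radius))
  md <- build_seed_video(events, dims)
  m <- propagate_wake(md, se_r)
  mc <- cumulative_map(m, hours_to_frames(t_tilde_hours, cal))
  windowed_pdeath(mc, cal, ...)
}
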