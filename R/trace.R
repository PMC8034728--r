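# Caspase-reporter signal extraction. For every track point a square ROI is
# centered on the detected cell position in the green channel; the foreground
# is the detected cell disk and the background is the annulus between the
# cell disk and a neighborhood circle of radius `bg_radius_factor` times the
# experiment-average cell radius, both clipped to the ROI and the frame. The
# per-track trace is the background-normalized contrast
#   mu(t) = (mu_fg - mu_bg) / mu_bg  -  min over the track of the same ratio,
# so every trace has minimum exactly 0 and apoptosis onset appears as a jump.

#' ROI geometry for trace extraction
#'
#' @param roi_side_px Square ROI edge in px; must be odd so it can be
#'   centered on the cell. The default 31 px corresponds to roughly 20 um at
#'   a 5x objective.
#' @param bg_radius_factor The neighborhood circle radius as a multiple of
#'   the experiment-average detected cell radius.
#' @param epsilon_bg Backgrounds below `epsilon_bg * max(green)` are treated
#'   as unmeasurable: such frames are dropped from the ratio and filled by
#'   linear interpolation from neighboring frames.
#' @return A `roi_geometry` list.
#' @export
roi_geometry <- function(roi_side_px = 31, bg_radius_factor = 2.0,
                         epsilon_bg = 1e-6) {
  roi_side_px <- as.integer(roi_side_px)
  if (roi_side_px %% 2L == 0L)
    abort("roi_side_px must be odd.", class = "apoptomap_config_error")
  if (bg_radius_factor <= 1)
    abort("bg_radius_factor must exceed 1 (annulus must be non-empty).",
          class = "apoptomap_config_error")
  structure(list(roi_side_px = roi_side_px, bg_radius_factor = bg_radius_factor,
                 epsilon_bg = epsilon_bg),
            class = "roi_geometry")
}

#' Extract normalized caspase-reporter traces for all tracks
#'
#' @param tracks Tibble from [link_tracks()].
#' @param green Green-channel [frame_stack()].
#' @param geom A [roi_geometry()].
#' @param avg_radius Experiment-average cell radius (px); defaults to the
#'   mean detected radius over all track points.
#' @return A tibble with one row per track point: `track_id`, `frame`,
#'   `mu_fg`, `mu_bg`, `ratio`, `mu`, `bg_flagged`. Within each track,
#'   `min(mu) == 0` exactly.
#' @export
extract_traces <- function(tracks, green, geom = roi_geometry(),
                           avg_radius = NULL) {
  stopifnot(inherits(green, "frame_stack"))
  if (nrow(tracks) == 0L)
    return(tibble(track_id = integer(), frame = integer(), mu_fg = numeric(),
                  mu_bg = numeric(), ratio = numeric(), mu = numeric(),
                  bg_flagged = logical()))
  if (max(tracks$frame) > n_frames(green))
    abort("Track frames exceed the green stack duration.",
          class = "apoptomap_validation_error")
  avg_radius <- avg_radius %||% mean(tracks$radius)
  bg_radius <- geom$bg_radius_factor * avg_radius
  if (bg_radius > geom$roi_side_px / 2)
    warn("Neighborhood circle exceeds the ROI; background clipped to the ROI.")
  eps <- geom$epsilon_bg * max(green)
  half <- (geom$roi_side_px - 1L) %/% 2L
  D1 <- dim(green)[1]; D2 <- dim(green)[2]

  one_point <- function(x, y, radius, frame) {
    cx <- as.integer(round(x)); cy <- as.integer(round(y))
    xs <- max(1L, cx - half):min(D2, cx + half)
    ys <- max(1L, cy - half):min(D1, cy + half)
    roi <- green[ys, xs, frame, drop = TRUE]
    d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
    fg <- d2 <= radius^2
    bg <- d2 > radius^2 & d2 <= bg_radius^2
    mu_fg <- if (any(fg)) mean(roi[fg]) else NA_real_
    mu_bg <- if (any(bg)) mean(roi[bg]) else NA_real_
    c(mu_fg, mu_bg)
  }

  res <- dplyr::mutate(
    as_tibble(tracks)[c("track_id", "frame", "x", "y", "radius")],
    fgbg = purrr::pmap(list(.data$x, .data$y, .data$radius, .data$frame),
                       one_point),
    mu_fg = purrr::map_dbl(.data$fgbg, 1),
    mu_bg = purrr::map_dbl(.data$fgbg, 2),
    fgbg = NULL, x = NULL, y = NULL, radius = NULL)

  res <- dplyr::group_modify(
    dplyr::group_by(res, .data$track_id),
    function(df, key) normalize_trace(df, eps))
  dplyr::ungroup(res)
}

# per-track Eq-3 style normalization with epsilon-floored backgrounds
normalize_trace <- function(df, eps) {
  df <- dplyr::arrange(df, .data$frame)
  bad <- is.na(df$mu_bg) | df$mu_bg < eps | is.na(df$mu_fg)
  ratio <- ifelse(bad, NA_real_, (df$mu_fg - df$mu_bg) / df$mu_bg)
  if (all(is.na(ratio))) {
    ratio <- rep(0, nrow(df))                 # no measurable background at all
  } else if (anyNA(ratio)) {
    ok <- which(!is.na(ratio))
    ratio <- approx(df$frame[ok], ratio[ok], xout = df$frame, rule = 2)$y
  }
  df$ratio <- ratio
  df$mu <- ratio - min(ratio)
  df$bg_flagged <- bad
  df
}

#' Pooled Otsu threshold over all traces of a video
#'
#' Pools every `mu` sample of every track into one multiset and returns its
#' [otsu_threshold()]; one threshold per video separates basal from
#' apoptotic reporter levels.
#'
#' @param traces Tibble from [extract_traces()].
#' @return Scalar threshold `th`.
#' @export
estimate_threshold <- function(traces) {
  otsu_threshold(traces$mu)
}

#' Call per-track apoptosis times by first threshold crossing
#'
#' A track dies at the first frame where its normalized trace exceeds `th`;
#' the call is definitive even if the trace later falls back below the
#' threshold (reporter bleaching). Tracks never exceeding `th` yield no
#' event.
#'
#' @param traces Tibble from [extract_traces()].
#' @param tracks Tibble from [link_tracks()] (supplies position and radius at
#'   death).
#' @param th Threshold from [estimate_threshold()].
#' @return Event tibble: `track_id`, `x`, `y`, `radius`, `death_frame`.
#' @export
call_death_times <- function(traces, tracks, th) {
  if (!is.finite(th))
    abort("`th` must be finite.", class = "apoptomap_config_error")
  deaths <- dplyr::summarise(
    dplyr::group_by(traces, .data$track_id),
    death_frame = {
      over <- .data$frame[.data$mu > th]
      if (length(over) > 0L) min(over) else NA_integer_
    },
    .groups = "drop")
  deaths <- dplyr::filter(deaths, !is.na(.data$death_frame))
  ev <- dplyr::inner_join(deaths, as_tibble(tracks),
                          by = c("track_id", death_frame = "frame"))
  out <- dplyr::transmute(ev, track_id = .data$track_id, x = .data$x,
                          y = .data$y, radius = .data$radius,
                          death_frame = as.integer(.data$death_frame))
  dplyr::arrange(out, .data$death_frame, .data$track_id)
}
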