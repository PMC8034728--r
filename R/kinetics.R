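# Time-centric apoptosis counting. For each frame t:
#   N_ap(t)    events with death frame in the closed trailing window
#              [t - T_LAG, t]
#   N_track(t) tracks existing at t whose death has not yet been called
#   N_avg(t)   mean of N_track over [t - T_LAG, t]
#   O(t)       100 * N_ap / N_avg, the apoptosis rate (% per T_LAG window)
#   N_avg2(t)  mean of N_track over {t-1, t, t+1} (truncated at the ends)
#   OS(t)      100 * N_avg2(t) / reference, reference = mean N_track over the
#              first three frames ("overall survival")

# per-frame living-track counts shared by both kinetics
living_counts <- function(tracks, events, n_frames_total) {
  spans <- track_spans(tracks)
  spans <- dplyr::left_join(spans, events[c("track_id", "death_frame")],
                            by = "track_id")
  vapply(seq_len(n_frames_total), function(t) {
    sum(spans$t_start <= t & spans$t_end >= t &
          (is.na(spans$death_frame) | spans$death_frame > t))
  }, numeric(1))
}

#' Apoptosis-rate kinetics
#'
#' @param events Event tibble from [call_death_times()].
#' @param tracks Tibble from [link_tracks()].
#' @param t_lag_frames Trailing-window length `T_LAG` in frames (>= 1).
#' @param n_frames_total Total video duration in frames.
#' @param cal A [calibration()] used to report hours.
#' @param truncate_edges If `TRUE` (default) the rate is reported only from
#'   `t = T_LAG + 1` onward, where the trailing window is complete; earlier
#'   frames get `NA`.
#' @return Tibble: `frame`, `hours`, `n_ap`, `n_track`, `n_avg`,
#'   `apoptosis_rate_pct`. Frames whose window holds no living tracks
#'   (`n_avg == 0`) have `NA` rate.
#' @export
apoptosis_rate <- function(events, tracks, t_lag_frames,
                           n_frames_total = max(tracks$frame),
                           cal = calibration(), truncate_edges = TRUE) {
  t_lag_frames <- as.integer(t_lag_frames)
  if (t_lag_frames < 1L)
    abort("t_lag_frames must be >= 1.", class = "apoptomap_config_error")
  tt <- seq_len(n_frames_total)
  n_track <- living_counts(tracks, events, n_frames_total)
  n_ap <- vapply(tt, function(t) {
    lo <- t - t_lag_frames
    sum(events$death_frame >= lo & events$death_frame <= t, na.rm = TRUE)
  }, numeric(1))
  n_avg <- vapply(tt, function(t) {
    mean(n_track[max(1L, t - t_lag_frames):t])
  }, numeric(1))
  rate <- ifelse(n_avg > 0, 100 * n_ap / n_avg, NA_real_)
  if (truncate_edges) rate[tt <= t_lag_frames] <- NA_real_
  tibble(frame = tt, hours = frames_to_hours(tt, cal),
         n_ap = n_ap, n_track = n_track, n_avg = n_avg,
         apoptosis_rate_pct = rate)
}

#' Overall-survival kinetics
#'
#' @inheritParams apoptosis_rate
#' @return Tibble: `frame`, `hours`, `n_track`, `n_avg2`, `survival_pct`.
#' @export
overall_survival <- function(events, tracks,
                             n_frames_total = max(tracks$frame),
                             cal = calibration()) {
  if (n_frames_total < 3L)
    abort("Overall survival needs at least 3 frames.",
          class = "apoptomap_config_error")
  tt <- seq_len(n_frames_total)
  n_track <- living_counts(tracks, events, n_frames_total)
  n_avg2 <- vapply(tt, function(t) {
    mean(n_track[max(1L, t - 1L):min(n_frames_total, t + 1L)])
  }, numeric(1))
  reference <- mean(n_track[1:3])
  if (reference == 0)
    abort("No living tracks in the first three frames; survival undefined.",
          class = "apoptomap_degenerate_error")
  tibble(frame = tt, hours = frames_to_hours(tt, cal),
         n_track = n_track, n_avg2 = n_avg2,
         survival_pct = 100 * n_avg2 / reference)
}
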