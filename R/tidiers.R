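# broom-style accessors for the pipeline result object.

#' Tidy an apoptomap run into its per-event table
#'
#' @param x An `apoptomap_run`.
#' @param ... Unused.
#' @return The event tibble (`track_id`, `x`, `y`, `radius`, `death_frame`)
#'   with death times also in hours.
#' @method tidy apoptomap_run
#' @export
tidy.apoptomap_run <- function(x, ...) {
  cal <- x$cfg$calibration
  dplyr::mutate(x$events,
                death_hours = frames_to_hours(.data$death_frame, cal))
}

#' One-row summary of an apoptomap run
#'
#' @param x An `apoptomap_run`.
#' @param ... Unused.
#' @return A one-row tibble: track and event counts, the pooled reporter
#'   threshold, mean detected radius, final overall survival, mean
#'   apoptosis rate, and mean potential of death.
#' @method glance apoptomap_run
#' @export
glance.apoptomap_run <- function(x, ...) {
  tibble(n_tracks = dplyr::n_distinct(x$tracks$track_id),
         n_events = nrow(x$events),
         threshold = x$threshold,
         avg_radius_px = x$avg_radius,
         se_radius_px = x$se_radius_px,
         mean_apoptosis_rate_pct =
           mean(x$kinetics$apoptosis_rate_pct, na.rm = TRUE),
         final_survival_pct = tail(x$survival$survival_pct, 1L),
         mean_pdeath = mean(x$pdeath$pdeath),
         mean_induction_interval_h =
           if (nrow(x$chains) > 0L) mean(x$chains$induction_interval_h)
           else NA_real_)
}
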