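# Chains of death. Every death event seeds a chain: starting from the seed,
# any event inside the circular zone of radius `radius_factor` times the
# seed's radius, centered on the seed's death position, joins the chain if
# its death time is within `t_lag` of the latest chain member. The chain's
# total duration (last member minus seed, in hours) is the seed's induction
# interval; the distribution of induction intervals over an experiment is
# what calibrates the cumulative-map window T_tilde.

#' Grow chains of death and compute induction intervals
#'
#' @param events Event tibble (`track_id`, `x`, `y`, `radius`,
#'   `death_frame`); rows without a death frame are ignored. Every event
#'   seeds its own chain, including events already absorbed into an earlier
#'   chain.
#' @param t_lag_h Maximum time gap between consecutive chain members, hours.
#' @param cal A [calibration()].
#' @param radius_factor Capture radius as a multiple of the seed's radius at
#'   death (default 10).
#' @return Tibble: `seed_id`, `n_members`, `member_ids` (list-column),
#'   `induction_interval_h`.
#' @export
chain_of_death <- function(events, t_lag_h, cal = calibration(),
                           radius_factor = 10) {
  ev <- dplyr::filter(as_tibble(events), !is.na(.data$death_frame))
  ev <- dplyr::arrange(ev, .data$death_frame, .data$track_id)
  if (nrow(ev) == 0L)
    return(tibble(seed_id = integer(), n_members = integer(),
                  member_ids = list(), induction_interval_h = numeric()))
  t_lag_frames <- t_lag_h / cal$frame_interval_h
  purrr::map_dfr(seq_len(nrow(ev)), function(s) {
    seed <- ev[s, ]
    capture <- radius_factor * seed$radius
    in_zone <- which(
      (ev$x - seed$x)^2 + (ev$y - seed$y)^2 <= capture^2 &
        ev$death_frame >= seed$death_frame)
    cand <- ev[in_zone, ]
    cand <- cand[order(cand$death_frame), ]
    # walk forward: each member must fall within t_lag of the latest member
    members <- seed$track_id
    t_last <- seed$death_frame
    for (k in seq_len(nrow(cand))) {
      if (cand$track_id[k] == seed$track_id) next
      if (cand$death_frame[k] - t_last <= t_lag_frames) {
        members <- c(members, cand$track_id[k])
        t_last <- cand$death_frame[k]
      } else break
    }
    tibble(seed_id = seed$track_id, n_members = length(members),
           member_ids = list(members),
           induction_interval_h =
             frames_to_hours(t_last - seed$death_frame, cal))
  })
}
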