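# Frame-to-frame track linking. Matching between the active tracks and the
# detections of the next frame minimizes total squared displacement subject
# to a gating distance; unmatched detections are track births, tracks missed
# for more than `max_gap_frames` consecutive frames terminate, and bridged
# gaps are filled by linear interpolation of position and radius.

#' Match two point sets by gated optimal assignment
#'
#' Augments the rectangular problem with per-point "no match" alternatives at
#' cost `gate^2`, so a pair is linked exactly when its squared displacement is
#' below the gate and linking lowers the total cost.
#'
#' @param prev,curr Data frames with `x`, `y` columns.
#' @param gate Gating distance (px); pairs farther apart are never linked.
#' @return List with `pairs` (two-column matrix of row indices into `prev`
#'   and `curr`) and `cost` (total squared displacement of the linked pairs
#'   plus `gate^2` per unmatched point).
#' @export
match_frames <- function(prev, curr, gate) {
  n <- nrow(prev); m <- nrow(curr)
  if (n == 0L || m == 0L)
    return(list(pairs = matrix(integer(), 0, 2), cost = (n + m) * gate^2))
  d2 <- outer(prev$x, curr$x, `-`)^2 + outer(prev$y, curr$y, `-`)^2
  d2[d2 > gate^2] <- Inf
  size <- n + m
  C <- matrix(0, size, size)               # bottom-right block: dummy-dummy, 0
  C[seq_len(n), seq_len(m)] <- d2
  C[seq_len(n), m + seq_len(n)] <- Inf
  C[cbind(seq_len(n), m + seq_len(n))] <- gate^2
  C[n + seq_len(m), seq_len(m)] <- Inf
  C[cbind(n + seq_len(m), seq_len(m))] <- gate^2
  sol <- solve_assignment(C)
  i <- seq_len(n)
  j <- sol$match[i]
  linked <- j <= m & is.finite(d2[cbind(i, pmin(j, m))])
  pairs <- cbind(i[linked], j[linked])
  cost <- sum(d2[pairs]) + gate^2 * ((n - nrow(pairs)) + (m - nrow(pairs)))
  list(pairs = pairs, cost = cost)
}

#' Link per-frame detections into cell tracks
#'
#' @param detections Tibble from [detect_stack()]: `frame`, `x`, `y`,
#'   `radius` (extra columns are ignored).
#' @param cfg A [tracking_config()].
#' @param n_frames_total Total number of frames; defaults to the largest
#'   frame index present.
#' @return A tibble of track points: `track_id`, `frame`, `x`, `y`, `radius`,
#'   `interpolated` (TRUE on gap-filled frames). Each track covers a
#'   contiguous frame range.
#' @export
link_tracks <- function(detections, cfg = tracking_config(),
                        n_frames_total = NULL) {
  detections <- as_tibble(detections)
  if (nrow(detections) == 0L)
    return(tibble(track_id = integer(), frame = integer(), x = numeric(),
                  y = numeric(), radius = numeric(), interpolated = logical()))
  n_frames_total <- n_frames_total %||% max(detections$frame)
  by_frame <- split(detections, factor(detections$frame,
                                       levels = seq_len(n_frames_total)))
  # active-track state
  state <- tibble(track_id = integer(), x = numeric(), y = numeric(),
                  radius = numeric(), last_seen = integer())
  next_id <- 1L
  out <- vector("list", n_frames_total)
  for (t in seq_len(n_frames_total)) {
    det <- by_frame[[t]]
    alive <- state[t - state$last_seen <= cfg$max_gap_frames + 1L, , drop = FALSE]
    mt <- match_frames(alive, det, cfg$gating_px)
    rows <- list()
    if (nrow(mt$pairs) > 0L) {
      for (k in seq_len(nrow(mt$pairs))) {
        tr <- alive[mt$pairs[k, 1], ]
        dd <- det[mt$pairs[k, 2], ]
        gap <- t - tr$last_seen - 1L
        if (gap > 0L) {                      # linearly interpolate the dropout
          f <- seq_len(gap) / (gap + 1L)
          rows[[length(rows) + 1L]] <- tibble(
            track_id = tr$track_id, frame = tr$last_seen + seq_len(gap),
            x = tr$x + f * (dd$x - tr$x), y = tr$y + f * (dd$y - tr$y),
            radius = tr$radius + f * (dd$radius - tr$radius),
            interpolated = TRUE)
        }
        rows[[length(rows) + 1L]] <- tibble(
          track_id = tr$track_id, frame = t, x = dd$x, y = dd$y,
          radius = dd$radius, interpolated = FALSE)
        state[state$track_id == tr$track_id,
              c("x", "y", "radius", "last_seen")] <-
          list(dd$x, dd$y, dd$radius, t)
      }
    }
    # births: unmatched detections start new tracks
    unmatched_det <- setdiff(seq_len(nrow(det)), mt$pairs[, 2])
    for (k in unmatched_det) {
      dd <- det[k, ]
      rows[[length(rows) + 1L]] <- tibble(
        track_id = next_id, frame = t, x = dd$x, y = dd$y,
        radius = dd$radius, interpolated = FALSE)
      state <- dplyr::bind_rows(state, tibble(
        track_id = next_id, x = dd$x, y = dd$y, radius = dd$radius,
        last_seen = t))
      next_id <- next_id + 1L
    }
    # terminations happen implicitly once last_seen falls out of the window
    out[[t]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$track_id, .data$frame)
}

#' Per-track frame ranges
#' @param tracks Tibble from [link_tracks()].
#' @return Tibble `track_id`, `t_start`, `t_end`, `n_frames`.
#' @export
track_spans <- function(tracks) {
  if (nrow(tracks) == 0L)
    return(tibble(track_id = integer(), t_start = integer(),
                  t_end = integer(), n_frames = integer()))
  dplyr::summarise(dplyr::group_by(tracks, .data$track_id),
                   t_start = min(.data$frame), t_end = max(.data$frame),
                   n_frames = dplyr::n(), .groups = "drop")
}
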