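# Spatiotemporal death map. Each called death seeds a binary disk at its
# death frame; the map M then evolves by
#   M(.,.,t) = erode(M(.,.,t-1), disk(r)) + MD(.,.,t),     M(.,.,1) = MD(.,.,1)
# where erode is grayscale morphological erosion (min over the disk
# structuring element, background 0 outside the frame). Each death therefore
# leaves a "wake" whose radius shrinks by r per frame: a disk of radius r0
# survives ceiling(r0 / r) frames, so r = r0/3 gives a three-hour wake at
# hourly sampling. The cumulative map sums squared wake intensities over a
# forward window of T_tilde frames.

#' Rasterize death events into a binary seed video
#'
#' @param events Event tibble (`x`, `y`, `radius`, `death_frame`); rows with
#'   `NA` death frames are ignored.
#' @param dims `c(D1, D2, T)` of the output video.
#' @return A `D1 x D2 x T` binary (0/1) array; overlapping same-frame disks
#'   are unioned, so the seed video never exceeds 1.
#' @export
build_seed_video <- function(events, dims) {
  stopifnot(length(dims) == 3L)
  md <- array(0, dim = dims)
  events <- events[!is.na(events$death_frame), , drop = FALSE]
  if (nrow(events) > 0L &&
      (any(events$x < 1 | events$x > dims[2] | events$y < 1 | events$y > dims[1]) ||
       any(events$death_frame < 1 | events$death_frame > dims[3])))
    abort("Events fall outside the video dimensions.",
          class = "apoptomap_validation_error")
  for (k in seq_len(nrow(events))) {
    off <- disk_offsets(events$radius[k])
    ys <- round(events$y[k]) + off$dy
    xs <- round(events$x[k]) + off$dx
    ok <- ys >= 1 & ys <= dims[1] & xs >= 1 & xs <= dims[2]
    md[cbind(ys[ok], xs[ok], events$death_frame[k])] <- 1
  }
  md
}

#' Grayscale erosion of a frame by a disk structuring element
#'
#' Minimum filter over the disk `{(dx, dy): dx^2 + dy^2 <= r^2}`; pixels
#' outside the frame count as 0, so the operator is anti-extensive on
#' non-negative frames with zero background.
#'
#' @param frame Numeric matrix.
#' @param r Structuring-element radius (px, > 0).
#' @return Eroded matrix of the same dimensions.
#' @export
erode_gray <- function(frame, r) {
  if (r <= 0) abort("Structuring-element radius must be positive.",
                    class = "apoptomap_config_error")
  off <- disk_offsets(r)
  nr <- nrow(frame); nc <- ncol(frame)
  out <- NULL
  for (k in seq_len(nrow(off))) {
    sh <- shift_zero(frame, off$dy[k], off$dx[k])
    out <- if (is.null(out)) sh else pmin(out, sh)
  }
  out
}

# frame translated by (dr, dc), zero-filled: out[i,j] = frame[i+dr, j+dc]
shift_zero <- function(frame, dr, dc) {
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(0, nr, nc)
  ri <- max(1L, 1L - dr):min(nr, nr - dr)
  ci <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(ri) > 0L && length(ci) > 0L)
    out[ri, ci] <- frame[ri + dr, ci + dc]
  out
}

#' Propagate death wakes through a seed video
#'
#' @param md Binary seed video from [build_seed_video()].
#' @param r Structuring-element radius (px). Choose the experiment-average
#'   cell radius divided by 3 (see [wake_radius()]) so each wake survives at
#'   least three hourly frames.
#' @return Grayscale wake video `M`, same dimensions as `md`. Values can
#'   exceed 1 where a fresh death lands on a surviving wake.
#' @export
propagate_wake <- function(md, r) {
  if (r <= 0) abort("Structuring-element radius must be positive.",
                    class = "apoptomap_config_error")
  m <- array(0, dim = dim(md))
  m[, , 1] <- md[, , 1]
  for (t in seq_len(dim(md)[3])[-1]) {
    m[, , t] <- erode_gray(m[, , t - 1, drop = TRUE], r) + md[, , t, drop = TRUE]
  }
  m
}

#' Default structuring-element radius from the average cell radius
#'
#' One third of the experiment-average detected cell radius, rounded up;
#' with hourly frames this makes an average-sized death wake last at least
#' three hours.
#'
#' @param avg_cell_radius_px Average detected cell radius (px).
#' @return Integer radius in px (at least 1).
#' @export
wake_radius <- function(avg_cell_radius_px) {
  max(1L, as.integer(ceiling(avg_cell_radius_px / 3)))
}

#' Cumulative death map over a forward temporal window
#'
#' `MC(x, y, t) = sum over t' in [t, t + t_tilde] of M(x, y, t')^2`,
#' defined for `t` in `1 .. T - t_tilde`.
#'
#' @param m Wake video from [propagate_wake()].
#' @param t_tilde_frames Window length in frames (>= 0, < T).
#' @return A `D1 x D2 x (T - t_tilde)` array.
#' @export
cumulative_map <- function(m, t_tilde_frames) {
  t_tilde_frames <- as.integer(t_tilde_frames)
  T_ <- dim(m)[3]
  if (t_tilde_frames < 0L || t_tilde_frames >= T_)
    abort("t_tilde_frames must be in [0, T).", class = "apoptomap_config_error")
  m2 <- m^2
  cs <- array(0, dim = dim(m) + c(0, 0, 1))           # prefix sums over frames
  for (t in seq_len(T_)) cs[, , t + 1] <- cs[, , t] + m2[, , t]
  n_out <- T_ - t_tilde_frames
  mc <- array(0, dim = c(dim(m)[1:2], n_out))
  for (t in seq_len(n_out)) mc[, , t] <- cs[, , t + t_tilde_frames + 1] - cs[, , t]
  mc
}
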