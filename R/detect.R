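# Per-frame cell localization: Otsu binarization of the red channel followed
# by a circular Hough transform (CHT) over an imposed radius range. The
# accumulator for radius r is the FFT convolution of the mask's edge image
# with a one-pixel-wide ring kernel of radius r, normalized by ring size, so
# a peak value of 1 means the full circle perimeter is present.

#' Tracking configuration
#'
#' @param radius_min_px,radius_max_px Admissible cell radius range imposed on
#'   the circular Hough transform (px).
#' @param gating_px Maximum per-frame displacement for track linking (px).
#'   Default `3 * radius_max_px`: cancer cells embedded in a collagen gel move
#'   slowly relative to hourly sampling.
#' @param max_gap_frames Longest detection dropout bridged by a track; gaps
#'   are filled by linear interpolation of position and radius.
#' @param min_votes Minimum fraction of the circle perimeter that must be
#'   present in the edge image for a Hough peak to count as a cell.
#' @return A `tracking_config` list.
#' @export
tracking_config <- function(radius_min_px = 4, radius_max_px = 8,
                            gating_px = 3 * radius_max_px,
                            max_gap_frames = 2, min_votes = 0.35) {
  if (radius_min_px > radius_max_px)
    abort("radius_min_px must be <= radius_max_px.", class = "apoptomap_config_error")
  if (gating_px <= 0)
    abort("gating_px must be positive.", class = "apoptomap_config_error")
  structure(list(radius_min_px = as.integer(round(radius_min_px)),
                 radius_max_px = as.integer(round(radius_max_px)),
                 gating_px = gating_px,
                 max_gap_frames = as.integer(max_gap_frames),
                 min_votes = min_votes),
            class = "tracking_config")
}

#' Binarize a fluorescence frame by Otsu thresholding
#'
#' @param frame Numeric matrix (one frame of the red channel).
#' @return Logical matrix, `TRUE` on foreground (`intensity > threshold`).
#' @export
binarize_frame <- function(frame) {
  frame > otsu_threshold(as.vector(frame))
}

# odd-sized kernel holding a one-pixel ring of radius r, normalized to sum 1
ring_kernel <- function(r) {
  side <- 2L * (r + 1L) + 1L
  c0 <- r + 2L
  d <- sqrt(outer((seq_len(side) - c0)^2, (seq_len(side) - c0)^2, `+`))
  k <- (d >= r - 0.5 & d < r + 0.5) * 1
  k / sum(k)
}

# pixel offsets of the filled disk {x^2 + y^2 <= r^2}
disk_offsets <- function(r) {
  s <- seq(-floor(r), floor(r))
  g <- expand.grid(dy = s, dx = s)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

#' Detect circular cells in one frame (circular Hough transform)
#'
#' Runs the CHT on the edge pixels of the Otsu-binarized frame (or of a
#' supplied logical mask), scanning integer radii in the configured range.
#' Accumulator peaks above `min_votes` are kept and non-maximum-suppressed
#' with minimum separation `radius_min_px`, so two detections can never fall
#' closer than the smallest admissible radius.
#'
#' @param frame Numeric matrix or logical mask.
#' @param cfg A [tracking_config()].
#' @return A tibble of detections: `x`, `y` (px, 1-based centers), `radius`
#'   (px), `votes` (perimeter fraction). Zero rows when nothing is found.
#' @export
detect_cells <- function(frame, cfg = tracking_config()) {
  mask <- if (is.logical(frame)) frame else binarize_frame(frame)
  empty <- tibble(x = numeric(), y = numeric(), radius = numeric(),
                  votes = numeric())
  if (!any(mask)) return(empty)
  edges <- mask_edges(mask)
  if (!any(edges)) return(empty)
  radii <- seq(cfg$radius_min_px, cfg$radius_max_px)
  edge_img <- edges * 1
  acc_best <- matrix(-Inf, nrow(mask), ncol(mask))
  rad_best <- matrix(radii[1], nrow(mask), ncol(mask))
  for (r in radii) {
    acc <- EBImage::filter2(edge_img, ring_kernel(r), boundary = 0)
    upd <- acc > acc_best
    acc_best[upd] <- acc[upd]
    rad_best[upd] <- r
  }
  # candidate centers must themselves lie on the binarized foreground: a
  # genuine cell center is inside its own disk
  cand <- which(acc_best >= cfg$min_votes & mask, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  det <- tibble(x = as.numeric(cand[, 2]), y = as.numeric(cand[, 1]),
                radius = rad_best[cand], votes = acc_best[cand])
  nms_detections(det, min_sep = cfg$radius_min_px)
}

# edge pixels: foreground with at least one 4-neighbor of background
mask_edges <- function(mask) {
  pad <- function(shift_r, shift_c) {
    m <- matrix(FALSE, nrow(mask), ncol(mask))
    src_r <- seq_len(nrow(mask)) - shift_r
    src_c <- seq_len(ncol(mask)) - shift_c
    ok_r <- src_r >= 1 & src_r <= nrow(mask)
    ok_c <- src_c >= 1 & src_c <= ncol(mask)
    m[ok_r, ok_c] <- mask[src_r[ok_r], src_c[ok_c]]
    m
  }
  interior <- pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1) & mask
  mask & !interior
}

# greedy non-maximum suppression by descending vote count
nms_detections <- function(det, min_sep) {
  det <- det[order(-det$votes), , drop = FALSE]
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    kept <- which(keep)
    d2 <- (det$x[kept] - det$x[i])^2 + (det$y[kept] - det$y[i])^2
    keep[i] <- all(d2 > min_sep^2)
  }
  out <- det[keep, , drop = FALSE]
  out[order(out$y, out$x), , drop = FALSE]
}

#' Detect cells on every frame of a red-channel stack
#'
#' @param stack A red-channel [frame_stack()].
#' @param cfg A [tracking_config()].
#' @return A tibble with columns `frame`, `x`, `y`, `radius`, `votes`.
#' @export
detect_stack <- function(stack, cfg = tracking_config()) {
  purrr::map_dfr(seq_len(n_frames(stack)), function(t) {
    det <- detect_cells(get_frame(stack, t), cfg)
    if (nrow(det) > 0L) dplyr::mutate(det, frame = t, .before = 1) else NULL
  })
}
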