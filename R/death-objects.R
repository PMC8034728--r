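# Death objects and the potential of death induction. The non-zero support
# of a cumulative-map frame decomposes into 8-connected objects; for objects
# s_i with mean map value m_i and boundary centroids c_i, the potential is
#
#   P(t) = 1 / (2 |S|) * sum over unordered pairs (i, j) of
#          (m_i + m_j) / dbar(i, j)
#
# with dbar the Euclidean distance between boundary centroids divided by the
# largest dimension of the evaluated region. P is 0 with fewer than two
# objects, grows with wake intensity and with spatial crowding of deaths, and
# is evaluated inside sliding windows (283 um by default) to localize the
# statistic and increase its per-frame sample size.

# 8-connected labeling of the non-zero support of a matrix (igraph
# components over the pixel adjacency graph)
label_components_8 <- function(frame) {
  nz <- which(frame != 0)
  lab <- matrix(0L, nrow(frame), ncol(frame))
  if (length(nz) == 0L) return(lab)
  nr <- nrow(frame)
  idx <- seq_along(nz)
  pos <- integer(length(frame)); pos[nz] <- idx
  r <- ((nz - 1L) %% nr) + 1L
  cc <- ((nz - 1L) %/% nr) + 1L
  edges <- list()
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(frame)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    has <- pos[nb] > 0L
    edges[[length(edges) + 1L]] <- rbind(idx[ok][has], pos[nb][has])
  }
  em <- do.call(cbind, edges)
  g <- igraph::graph_from_edgelist(t(em), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(nz) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[nz] <- comp
  lab
}

#' Extract death objects from one cumulative-map frame
#'
#' Connected components of the non-zero support under 8-connectivity, with
#' the per-object mean map value and the boundary centroid (mean coordinate
#' of the object pixels having at least one 4-neighbor outside the object).
#'
#' @param mc_frame Numeric matrix (one frame of the cumulative map).
#' @return Tibble: `object_id`, `n_pixels`, `mean_mc`, `cx`, `cy`, and a
#'   `pixels` list-column of `(y, x)` index matrices.
#' @export
extract_objects <- function(mc_frame) {
  lab <- label_components_8(mc_frame)
  n_obj <- max(lab)
  if (n_obj == 0L)
    return(tibble(object_id = integer(), n_pixels = integer(),
                  mean_mc = numeric(), cx = numeric(), cy = numeric(),
                  pixels = list()))
  purrr::map_dfr(seq_len(n_obj), function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    inside <- lab == i
    bnd <- boundary_pixels(inside, px)
    tibble(object_id = i, n_pixels = nrow(px),
           mean_mc = mean(mc_frame[px]),
           cx = mean(bnd[, 2]), cy = mean(bnd[, 1]),
           pixels = list(px))
  })
}

# pixels of `px` (rows y, cols x) with a 4-neighbor outside the object;
# isolated pixels and full-interior degenerate cases fall back to all pixels
boundary_pixels <- function(inside, px) {
  nr <- nrow(inside); nc <- ncol(inside)
  on_bnd <- vapply(seq_len(nrow(px)), function(k) {
    y <- px[k, 1]; x <- px[k, 2]
    y == 1L || y == nr || x == 1L || x == nc ||
      !inside[y - 1L, x] || !inside[y + 1L, x] ||
      !inside[y, x - 1L] || !inside[y, x + 1L]
  }, logical(1))
  if (!any(on_bnd)) px else px[on_bnd, , drop = FALSE]
}

#' Potential of death induction of one object set
#'
#' @param objects Tibble from [extract_objects()].
#' @param frame_dims `c(D1, D2)` of the region the objects were extracted
#'   from; pairwise distances are normalized by `max(frame_dims)`.
#' @return Non-negative scalar; 0 when fewer than two objects exist. Pairs
#'   with coincident centroids are skipped with a warning.
#' @export
potential_of_death <- function(objects, frame_dims) {
  n <- nrow(objects)
  if (n < 2L) return(0)
  norm <- max(frame_dims)
  total <- 0
  skipped <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt((objects$cx[i] - objects$cx[j])^2 +
              (objects$cy[i] - objects$cy[j])^2) / norm
    if (d == 0) { skipped <- skipped + 1L; next }
    total <- total + (objects$mean_mc[i] + objects$mean_mc[j]) / d
  }
  if (skipped > 0L)
    warn(sprintf("Skipped %d object pair(s) with coincident centroids.", skipped))
  total / (2 * n)
}

#' Sliding-window potential-of-death series
#'
#' Evaluates [potential_of_death()] inside square windows tiled across each
#' cumulative-map frame (stride defaults to one window side; the last
#' row/column of windows is anchored to the frame edge so the field is fully
#' covered). Objects are re-extracted inside each window, and the distance
#' normalization uses the window side.
#'
#' @param mc Cumulative map from [cumulative_map()].
#' @param cal A [calibration()].
#' @param window_um Window side in micrometres (default 283).
#' @param stride_um Window stride; defaults to `window_um` (tiling).
#' @param aggregate Per-frame summary over windows holding at least one
#'   object: `"mean"` (default) or `"max"`.
#' @return Tibble: `frame`, `hours`, `pdeath` (aggregate), `pdeath_max`,
#'   `n_windows` (windows holding >= 1 object), plus a `windows` list-column
#'   of per-window tibbles (`wx`, `wy`, `n_objects`, `pdeath`).
#' @export
windowed_pdeath <- function(mc, cal = calibration(), window_um = 283,
                            stride_um = NULL, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  dims <- dim(mc)
  side <- as.integer(round(um_to_px(window_um, cal)))
  if (side < 8L)
    abort("Window is below 8 px; check the calibration.",
          class = "apoptomap_config_error")
  if (side > max(dims[1:2])) {
    warn("Window exceeds the frame; evaluating the whole frame once.")
    side <- max(dims[1:2])
  }
  stride <- if (is.null(stride_um)) side
            else max(1L, as.integer(round(um_to_px(stride_um, cal))))
  starts <- function(extent) {
    if (side >= extent) return(1L)
    s <- seq(1L, extent - side + 1L, by = stride)
    if (tail(s, 1L) != extent - side + 1L) s <- c(s, extent - side + 1L)
    s
  }
  sy <- starts(dims[1]); sx <- starts(dims[2])
  grid <- expand.grid(wy = sy, wx = sx)

  per_frame <- purrr::map_dfr(seq_len(dims[3]), function(t) {
    fr <- mc[, , t, drop = TRUE]
    wins <- purrr::pmap_dfr(grid, function(wy, wx) {
      sub <- fr[wy:min(dims[1], wy + side - 1L),
                wx:min(dims[2], wx + side - 1L), drop = FALSE]
      obj <- extract_objects(sub)
      tibble(wx = wx, wy = wy, n_objects = nrow(obj),
             pdeath = potential_of_death(obj, dim(sub)))
    })
    occupied <- wins[wins$n_objects >= 1L, , drop = FALSE]
    agg <- if (nrow(occupied) == 0L) 0
           else if (aggregate == "mean") mean(occupied$pdeath)
           else max(occupied$pdeath)
    tibble(frame = t, hours = frames_to_hours(t, cal), pdeath = agg,
           pdeath_max = if (nrow(occupied) == 0L) 0 else max(occupied$pdeath),
           n_windows = nrow(occupied), windows = list(wins))
  })
  per_frame
}
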