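# Ground-truthed simulator. Emulates the imaging model the pipeline assumes:
# red-prestained disk-shaped cells drifting slowly in a dark field, a green
# caspase reporter that ramps up at each cell's death and persists, additive
# Gaussian noise, and configurable death processes (explicit schedule,
# constant hazard, or contagion where a death transiently raises the hazard
# of its neighbors). Rendering and event generation are split so that
# point-pattern statistics can be simulated at scale without rasterizing
# video.

#' Simulation configuration
#'
#' Defaults emulate a sparse tumor-on-chip field imaged hourly: a 512 x 512
#' view with ~100 cells of radius ~6 px over 48 frames, cell peak intensity
#' well above 5 noise SDs.
#'
#' @param dims `c(D1, D2, T)`.
#' @param n_cells Number of cells.
#' @param cell_radius_px `c(mean, sd)` of cell radii in px.
#' @param drift_px_per_frame SD of the per-frame Brownian step.
#' @param red_peak,green_peak,background_mean,noise_sd Intensity units.
#' @param death_schedule `NULL`, an explicit event data frame
#'   (`x`, `y`, `t`, `radius`: those cells die at the stated frames), or a
#'   hazard model: `list(type = "constant", rate = h)` with per-frame death
#'   probability `h`, or `list(type = "contagion", base_rate =, boost_rate =,
#'   capture_radius_px =, lag_frames =, n_index =, index_frame =)` where a
#'   cell's hazard switches to `boost_rate` while any death younger than
#'   `lag_frames` lies within the capture radius, and `n_index` randomly
#'   chosen cells die unconditionally at `index_frame` (index deaths seeding
#'   the propagation, as when a cytotoxic stimulus first takes effect;
#'   both default to 0).
#' @param spatial_mode `list(type = "random")` or
#'   `list(type = "clustered", k =, spread =)` for initial cell placement.
#' @param green_rise_frames Frames over which the reporter ramps to its peak.
#' @param seed RNG seed, recorded in every output.
#' @param calibration A [calibration()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(dims = c(512, 512, 48), n_cells = 100,
                       cell_radius_px = c(6, 1), drift_px_per_frame = 0.4,
                       red_peak = 180, green_peak = 180,
                       background_mean = 20, noise_sd = 5,
                       death_schedule = list(type = "constant", rate = 0.005),
                       spatial_mode = list(type = "random"),
                       green_rise_frames = 2, seed = 1,
                       calibration = apoptomap::calibration()) {
  stopifnot(length(dims) == 3L, all(dims >= 1))
  if (is.list(death_schedule) && !is.data.frame(death_schedule)) {
    rates <- unlist(death_schedule[names(death_schedule) %in%
                                     c("rate", "base_rate", "boost_rate")])
    if (any(rates < 0 | rates > 1))
      abort("Hazard rates must lie in [0, 1].", class = "apoptomap_config_error")
  }
  structure(list(dims = as.integer(dims), n_cells = as.integer(n_cells),
                 cell_radius_px = cell_radius_px,
                 drift_px_per_frame = drift_px_per_frame,
                 red_peak = red_peak, green_peak = green_peak,
                 background_mean = background_mean, noise_sd = noise_sd,
                 death_schedule = death_schedule, spatial_mode = spatial_mode,
                 green_rise_frames = as.integer(green_rise_frames),
                 seed = as.integer(seed), calibration = calibration),
            class = "sim_config")
}

# initial cell placement, kept a margin away from the borders
place_cells <- function(cfg, margin) {
  D1 <- cfg$dims[1]; D2 <- cfg$dims[2]; n <- cfg$n_cells
  mode <- cfg$spatial_mode
  if (identical(mode$type, "clustered")) {
    centers <- tibble(cx = runif(mode$k, margin, D2 - margin),
                      cy = runif(mode$k, margin, D1 - margin))
    pick <- sample.int(mode$k, n, replace = TRUE)
    x <- pmin(pmax(centers$cx[pick] + rnorm(n, 0, mode$spread), margin), D2 - margin)
    y <- pmin(pmax(centers$cy[pick] + rnorm(n, 0, mode$spread), margin), D1 - margin)
  } else {
    x <- runif(n, margin, D2 - margin)
    y <- runif(n, margin, D1 - margin)
  }
  tibble(cell_id = seq_len(n), x = x, y = y)
}

#' Simulate cell trajectories and death times without rendering
#'
#' The abstract half of the simulator: Brownian trajectories (frozen at
#' death) and death frames drawn from the configured schedule or hazard
#' model.
#'
#' @param cfg A [sim_config()].
#' @return List with `trajectories` (tibble `cell_id`, `frame`, `x`, `y`,
#'   `radius`, `alive`), `deaths` (tibble `cell_id`, `x`, `y`, `radius`,
#'   `death_frame`, positions at death; `NA`-free), and `cfg`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  D1 <- cfg$dims[1]; D2 <- cfg$dims[2]; T_ <- cfg$dims[3]
  sched <- cfg$death_schedule
  explicit <- is.data.frame(sched)
  if (explicit) {
    sched <- as_tibble(sched)
    if (any(sched$x < 1 | sched$x > D2 | sched$y < 1 | sched$y > D1 |
              sched$t < 1 | sched$t > T_))
      abort("Scheduled events fall outside the video dimensions.",
            class = "apoptomap_config_error")
    cfg$n_cells <- nrow(sched)
  }
  n <- cfg$n_cells
  radius <- pmax(2, rnorm(n, cfg$cell_radius_px[1], cfg$cell_radius_px[2]))
  margin <- max(radius) + 2
  cells <- if (explicit) tibble(cell_id = seq_len(n), x = sched$x, y = sched$y)
           else place_cells(cfg, margin)
  if (explicit) radius <- sched$radius

  x <- matrix(NA_real_, n, T_); y <- matrix(NA_real_, n, T_)
  x[, 1] <- cells$x; y[, 1] <- cells$y
  death <- rep(NA_integer_, n)
  if (explicit) death <- as.integer(sched$t)
  index_cells <- integer()
  if (!explicit && identical(sched$type, "contagion") &&
      (sched$n_index %||% 0L) > 0L)
    index_cells <- sample.int(n, sched$n_index)

  hazard_at <- function(t) {
    if (explicit || is.null(sched)) return(rep(0, n))
    if (identical(sched$type, "constant")) return(rep(sched$rate, n))
    # contagion: boosted hazard near recent deaths
    h <- rep(sched$base_rate, n)
    recent <- which(!is.na(death) & death < t & death >= t - sched$lag_frames)
    if (length(recent) > 0L) {
      for (k in recent) {
        near <- (x[, t - 1] - x[k, death[k]])^2 + (y[, t - 1] - y[k, death[k]])^2 <=
          sched$capture_radius_px^2
        h[near] <- sched$boost_rate
      }
    }
    h
  }

  for (t in seq_len(T_)) {
    if (t > 1L) {
      alive <- is.na(death) | death >= t
      step_x <- rnorm(n, 0, cfg$drift_px_per_frame)
      step_y <- rnorm(n, 0, cfg$drift_px_per_frame)
      x[, t] <- ifelse(alive, pmin(pmax(x[, t - 1] + step_x, margin), D2 - margin),
                       x[, t - 1])
      y[, t] <- ifelse(alive, pmin(pmax(y[, t - 1] + step_y, margin), D1 - margin),
                       y[, t - 1])
      if (!explicit) {
        h <- hazard_at(t)
        dies <- is.na(death) & rbinom(n, 1, h) == 1L
        death[dies] <- t
        if (length(index_cells) > 0L && t == (sched$index_frame %||% 0L))
          death[index_cells[is.na(death[index_cells])]] <- t
      }
    } else if (!explicit) {
      # no deaths on the first frame: the reporter needs a pre-death baseline
    }
  }

  traj <- tibble(cell_id = rep(seq_len(n), T_),
                 frame = rep(seq_len(T_), each = n),
                 x = as.vector(x), y = as.vector(y),
                 radius = rep(radius, T_))
  traj$alive <- is.na(death[traj$cell_id]) | traj$frame < death[traj$cell_id]
  dd <- which(!is.na(death))
  deaths <- tibble(cell_id = dd,
                   x = x[cbind(dd, death[dd])], y = y[cbind(dd, death[dd])],
                   radius = radius[dd], death_frame = death[dd])
  list(trajectories = traj, deaths = deaths, cfg = cfg)
}

# additive rendering of one smoothed disk into a frame matrix
add_disk <- function(frame, cx, cy, r, peak, edge_sigma = 1) {
  D1 <- nrow(frame); D2 <- ncol(frame)
  ext <- ceiling(r + 3 * edge_sigma)
  ys <- max(1L, floor(cy - ext)):min(D1, ceiling(cy + ext))
  xs <- max(1L, floor(cx - ext)):min(D2, ceiling(cx + ext))
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  frame[ys, xs] <- frame[ys, xs] + peak * stats::pnorm((r - d) / edge_sigma)
  frame
}

#' Simulate a two-channel ground-truthed video
#'
#' Renders the cohort from [simulate_cohort()]: red channel shows every cell
#' (the pre-stain persists after death); green shows each dead cell's disk
#' ramping from 0 to `green_peak` over `green_rise_frames` frames and
#' persisting. Gaussian noise on a constant background is added to both
#' channels and frames are rounded to integer intensities, so a fixed seed
#' reproduces the stacks bit-exactly.
#'
#' @param cfg A [sim_config()].
#' @return List with `red` and `green` [frame_stack()]s, `truth`
#'   (the cohort trajectories), `deaths` (true events), and `cfg`.
#' @export
simulate_video <- function(cfg = sim_config()) {
  cohort <- simulate_cohort(cfg)
  D1 <- cfg$dims[1]; D2 <- cfg$dims[2]; T_ <- cfg$dims[3]
  red <- array(0, dim = cfg$dims); green <- array(0, dim = cfg$dims)
  traj <- cohort$trajectories
  death_of <- rep(NA_integer_, cfg$n_cells)
  death_of[cohort$deaths$cell_id] <- cohort$deaths$death_frame
  for (t in seq_len(T_)) {
    fr_r <- matrix(0, D1, D2); fr_g <- matrix(0, D1, D2)
    pts <- traj[traj$frame == t, ]
    for (k in seq_len(nrow(pts))) {
      fr_r <- add_disk(fr_r, pts$x[k], pts$y[k], pts$radius[k], cfg$red_peak)
      df <- death_of[pts$cell_id[k]]
      if (!is.na(df) && t >= df) {
        ramp <- min(1, (t - df + 1) / max(1L, cfg$green_rise_frames))
        fr_g <- add_disk(fr_g, pts$x[k], pts$y[k], pts$radius[k],
                         ramp * cfg$green_peak)
      }
    }
    npx <- D1 * D2
    red[, , t] <- pmax(0, round(fr_r + cfg$background_mean +
                                  rnorm(npx, 0, cfg$noise_sd)))
    green[, , t] <- pmax(0, round(fr_g + cfg$background_mean +
                                    rnorm(npx, 0, cfg$noise_sd)))
  }
  list(red = frame_stack(red, "red", cfg$calibration),
       green = frame_stack(green, "green", cfg$calibration),
       truth = cohort$trajectories, deaths = cohort$deaths, cfg = cfg)
}

#' Simulate an abstract spatial death pattern
#'
#' Event tables for point-pattern statistics: positions are uniform
#' (`"random"`) or drawn around `k` cluster centers (`"clustered"`), and
#' death frames follow a constant rate (uniform over the recording) or match
#' the per-frame counts of a reference event set.
#'
#' @param n_events Number of events (ignored when `match_counts_to` is
#'   given).
#' @param mode `"random"` or `"clustered"`.
#' @param dims `c(D1, D2, T)`.
#' @param radius Event radius in px (recycled).
#' @param k,spread Cluster count and SD of positions around each center
#'   (clustered mode).
#' @param match_counts_to Optional reference event table; the output then
#'   reproduces its per-frame event counts with fresh positions.
#' @param seed Optional RNG seed.
#' @return Event tibble: `track_id`, `x`, `y`, `radius`, `death_frame`.
#' @export
simulate_death_pattern <- function(n_events, mode = c("random", "clustered"),
                                   dims = c(512, 512, 48), radius = 6,
                                   k = 3, spread = 10,
                                   match_counts_to = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  D1 <- dims[1]; D2 <- dims[2]; T_ <- dims[3]
  frames <- if (!is.null(match_counts_to)) {
    sort(match_counts_to$death_frame[!is.na(match_counts_to$death_frame)])
  } else if (n_events > 0L) {
    sort(sample.int(T_, n_events, replace = TRUE))
  } else integer()
  n <- length(frames)
  if (n == 0L)
    return(tibble(track_id = integer(), x = numeric(), y = numeric(),
                  radius = numeric(), death_frame = integer()))
  margin <- max(radius) + 1
  if (mode == "clustered") {
    centers <- tibble(cx = runif(k, margin, D2 - margin),
                      cy = runif(k, margin, D1 - margin))
    pick <- sample.int(k, n, replace = TRUE)
    x <- pmin(pmax(centers$cx[pick] + rnorm(n, 0, spread), 1), D2)
    y <- pmin(pmax(centers$cy[pick] + rnorm(n, 0, spread), 1), D1)
  } else {
    x <- runif(n, margin, D2 - margin)
    y <- runif(n, margin, D1 - margin)
  }
  tibble(track_id = seq_len(n), x = x, y = y,
         radius = rep_len(radius, n), death_frame = as.integer(frames))
}

#' Three-death demonstration scenario
#'
#' A minimal event pattern for tracing the potential of death induction by
#' hand: three deaths at 2 h, 9 h and 11 h on a 120 x 120 field, the first
#' far from the later, closely spaced pair, analyzed with a 6-frame
#' cumulative window. While only one wake exists the potential is zero; it
#' rises when the second and third deaths enter the window and falls once
#' the early wakes fade out of it.
#'
#' @return List with `events` (3-row event tibble), `dims`, and the matching
#'   mapping parameters `t_tilde_frames = 6` and `se_radius_px = 3`
#'   (one third of the 9 px event radius).
#' @export
three_death_demo <- function() {
  events <- tibble(track_id = 1:3,
                   x = c(30, 62, 78), y = c(95, 42, 30),
                   radius = 9, death_frame = c(2L, 9L, 11L))
  list(events = events, dims = c(120L, 120L, 20L),
       t_tilde_frames = 6L, se_radius_px = 3L)
}

#' Canonical death-pattern study conditions
#'
#' The frozen simulation conditions used throughout the package to contrast
#' transmissible and random death: a 200 x 200 px field (2 um/px) with 250
#' cells followed for 48 hourly frames, under either a constant per-frame
#' death hazard of 0.4%/h or a contagion process (base hazard 0.02%/h,
#' boosted to 1.5%/h while any death younger than 10 frames lies within
#' 40 px). The contagion parameters put the propagation in its growth phase
#' for the whole recording, emulating a cytotoxic response that intensifies
#' with time; the matching map parameters use a 6 h cumulative window so the
#' potential-of-death series stays long relative to the recording.
#'
#' @return Named list: `dims`, `n_cells`, `calibration`, `constant` and
#'   `contagion` (death-schedule lists for [sim_config()]), and map
#'   parameters `t_tilde_hours`, `se_radius_px`, `window_um`.
#' @export
death_pattern_conditions <- function() {
  list(dims = c(200L, 200L, 48L), n_cells = 250L,
       calibration = calibration(pixel_size_um = 2, frame_interval_h = 1),
       constant = list(type = "constant", rate = 0.004),
       contagion = list(type = "contagion", base_rate = 0.0002,
                        boost_rate = 0.015, capture_radius_px = 40,
                        lag_frames = 10),
       t_tilde_hours = 6, se_radius_px = 2, window_um = 283)
}
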