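# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# moderate ground-truthed video shared by trace/kinetics/pipeline tests
shared_sim <- function() {
  cached("sim", simulate_video(sim_config(
    dims = c(256, 256, 20), n_cells = 30, seed = 7,
    death_schedule = list(type = "constant", rate = 0.02))))
}

# full tracking + trace + event pass over the shared video
shared_run <- function() {
  cached("run", {
    sim <- shared_sim()
    run_pipeline(run_config(calibration = sim$cfg$calibration,
                            t_tilde_hours = 6, window_um = 150,
                            seed = sim$cfg$seed),
                 red = sim$red, green = sim$green)
  })
}

# frame with hard disks of given centers/radii/value on a constant background
disk_frame <- function(side, xs, ys, rs, value = 200, background = 10) {
  fr <- matrix(background, side, side)
  for (k in seq_along(xs)) {
    d2 <- outer((seq_len(side) - ys[k])^2, (seq_len(side) - xs[k])^2, `+`)
    fr[d2 <= rs[k]^2] <- value
  }
  fr
}

# minimal trace/track pair for kinetics tests: `mus` is a list of per-track
# mu vectors, all starting at frame 1
toy_traces <- function(mus) {
  purrr::imap_dfr(mus, function(mu, i) {
    tibble::tibble(track_id = as.integer(i), frame = seq_along(mu),
                   mu_fg = mu, mu_bg = 1, ratio = mu, mu = mu,
                   bg_flagged = FALSE)
  })
}

toy_tracks <- function(mus, x = 50, y = 50, radius = 5) {
  purrr::imap_dfr(mus, function(mu, i) {
    tibble::tibble(track_id = as.integer(i), frame = seq_along(mu),
                   x = x + i, y = y + i, radius = radius,
                   interpolated = FALSE)
  })
}
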