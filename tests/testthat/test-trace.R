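uniform_stack <- function(value, side = 64, T_ = 3) {
  frame_stack(array(value, c(side, side, T_)), "green")
}

one_track <- function(x, y, frames = 1:3, radius = 5) {
  tibble::tibble(track_id = 1L, frame = frames, x = x, y = y,
                 radius = radius, interpolated = FALSE)
}

test_that("a uniform green field gives an identically zero trace", {
  tr <- one_track(32, 32)
  res <- extract_traces(tr, uniform_stack(50), roi_geometry(31, 2), avg_radius = 5)
  expect_equal(res$mu_fg, rep(50, 3))
  expect_equal(res$mu_bg, rep(50, 3))
  expect_equal(res$mu, rep(0, 3))
})

test_that("the normalized trace is the background contrast minus its minimum", {
  # frame 1: fg disk at 30 over bg 10 -> ratio 2; frame 2: uniform 10 -> 0
  side <- 64
  px <- array(10, c(side, side, 2))
  d2 <- outer((1:side - 32)^2, (1:side - 32)^2, `+`)
  fr1 <- matrix(10, side, side); fr1[d2 <= 25] <- 30
  px[, , 1] <- fr1
  tr <- one_track(32, 32, frames = 1:2)
  res <- extract_traces(tr, frame_stack(px, "green"), roi_geometry(31, 2),
                        avg_radius = 5)
  expect_equal(res$mu_fg, c(30, 10))
  expect_equal(res$mu_bg, c(10, 10))
  expect_equal(res$ratio, c(2, 0))
  expect_equal(res$mu, c(2, 0))
})

test_that("ROIs clipped at the frame border still normalize to zero minimum", {
  tr <- one_track(3, 3)                    # ROI mostly outside the frame
  res <- extract_traces(tr, uniform_stack(40), roi_geometry(31, 2), avg_radius = 5)
  expect_equal(nrow(res), 3L)
  expect_false(anyNA(res$mu))
  expect_equal(min(res$mu), 0)
})

test_that("every trace of a simulated video has minimum exactly zero", {
  run <- shared_run()
  mins <- dplyr::summarise(dplyr::group_by(run$traces, track_id),
                           m = min(mu), .groups = "drop")
  expect_true(all(mins$m == 0))
})

test_that("unmeasurable backgrounds are flagged and interpolated, not fatal", {
  side <- 64
  px <- array(20, c(side, side, 3))
  px[, , 2] <- 0                           # dark frame: background below floor
  d2 <- outer((1:side - 32)^2, (1:side - 32)^2, `+`)
  fr3 <- matrix(20, side, side); fr3[d2 <= 25] <- 60
  px[, , 3] <- fr3
  tr <- one_track(32, 32)
  res <- extract_traces(tr, frame_stack(px, "green"), roi_geometry(31, 2),
                        avg_radius = 5)
  expect_true(res$bg_flagged[2])
  expect_false(anyNA(res$mu))
  expect_equal(res$ratio[2], mean(res$ratio[c(1, 3)]))   # linear fill
})

test_that("death calls fire at the first crossing and only there", {
  mus <- list(c(0, 0, 0.1, 0.9, 1.2), rep(0, 5))
  traces <- toy_traces(mus)
  tracks <- toy_tracks(mus)
  ev <- call_death_times(traces, tracks, th = 0.6)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$track_id, 1L)
  expect_equal(ev$death_frame, 4L)
  # a dip back below the threshold does not retract the call
  mus2 <- list(c(0, 1.5, 0.2, 1.8, 0))
  ev2 <- call_death_times(toy_traces(mus2), toy_tracks(mus2), th = 1)
  expect_equal(ev2$death_frame, 2L)
})

test_that("programmed deaths are recovered from the shared simulated video", {
  sim <- shared_sim()
  run <- shared_run()
  ev <- run$events
  td <- sim$deaths
  hit <- vapply(seq_len(nrow(td)), function(i) {
    d <- sqrt((ev$x - td$x[i])^2 + (ev$y - td$y[i])^2)
    any(d <= 5 & abs(ev$death_frame - td$death_frame[i]) <= 1)
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
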