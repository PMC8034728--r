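make_det <- function(frame, x, y, radius = 5) {
  tibble::tibble(frame = frame, x = x, y = y, radius = radius, votes = 1)
}

test_that("a stationary detection yields one full-length track", {
  det <- make_det(1:10, x = rep(20, 10), y = rep(30, 10))
  tr <- link_tracks(det, tracking_config(4, 8))
  expect_equal(dplyr::n_distinct(tr$track_id), 1L)
  expect_equal(nrow(tr), 10L)
  expect_equal(tr$frame, 1:10)
})

test_that("crossing cells are linked by the globally optimal assignment", {
  # two cells swap x positions at 2 px/frame; straight-line continuation is
  # the minimum-total-cost linking at every step
  frames <- 1:11
  a_x <- seq(20, 40, by = 2); b_x <- seq(40, 20, by = -2)
  det <- dplyr::bind_rows(make_det(frames, a_x, y = 50),
                          make_det(frames, b_x, y = 52))
  cfg <- tracking_config(4, 8, gating_px = 8)
  tr <- link_tracks(det, cfg)
  expect_equal(dplyr::n_distinct(tr$track_id), 2L)
  # per-step linking cost equals the brute-force minimum over both pairings
  for (t in 2:11) {
    prev <- det[det$frame == t - 1, ]
    curr <- det[det$frame == t, ]
    got <- match_frames(prev, curr, cfg$gating_px)
    expect_equal(got$cost, brute_matching_cost(prev, curr, cfg$gating_px))
  }
  # each track continues its own straight line through the crossing
  tr1 <- tr[tr$track_id == tr$track_id[tr$frame == 1 & tr$x == 20], ]
  expect_equal(tr1$x, a_x)
})

test_that("late detections start new tracks at their first frame", {
  det <- dplyr::bind_rows(make_det(1:10, rep(20, 10), rep(20, 10)),
                          make_det(5:10, rep(80, 6), rep(80, 6)))
  tr <- link_tracks(det, tracking_config(4, 8))
  spans <- track_spans(tr)
  expect_equal(sort(spans$t_start), c(1L, 5L))
})

test_that("short dropouts are bridged with linear interpolation", {
  det <- make_det(c(1:4, 7:10), x = c(10, 12, 14, 16, 22, 24, 26, 28),
                  y = rep(40, 8))
  tr <- link_tracks(det, tracking_config(4, 8, max_gap_frames = 2))
  expect_equal(dplyr::n_distinct(tr$track_id), 1L)
  expect_equal(tr$frame, 1:10)
  expect_equal(tr$x[tr$frame %in% 5:6], c(18, 20))
  expect_true(all(tr$interpolated[tr$frame %in% 5:6]))
  # a longer dropout splits the track
  det2 <- make_det(c(1:3, 8:10), x = rep(10, 6), y = rep(40, 6))
  tr2 <- link_tracks(det2, tracking_config(4, 8, max_gap_frames = 2))
  expect_equal(dplyr::n_distinct(tr2$track_id), 2L)
})

test_that("track counts are conserved frame to frame", {
  set.seed(77)
  sim <- shared_sim()
  run <- shared_run()
  tr <- run$tracks
  spans <- track_spans(tr)
  for (t in 2:19) {
    alive_t <- sum(spans$t_start <= t & spans$t_end >= t)
    alive_prev <- sum(spans$t_start <= t - 1 & spans$t_end >= t - 1)
    born <- sum(spans$t_start == t)
    died <- sum(spans$t_end == t - 1)
    expect_equal(alive_t, alive_prev - died + born)
  }
})
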