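test_that("the apoptosis rate is the event count over the average living count", {
  # 100 tracks over 30 frames; 5 deaths inside the window ending at t = 20
  mus <- c(replicate(100, rep(0, 30), simplify = FALSE))
  tracks <- toy_tracks(mus)
  events <- tibble::tibble(track_id = 1:5, x = 1, y = 1, radius = 5,
                           death_frame = c(12L, 14L, 15L, 18L, 20L))
  kin <- apoptosis_rate(events, tracks, t_lag_frames = 10, n_frames_total = 30)
  expect_equal(kin$n_ap[kin$frame == 20], 5)
  # living counts step down at each death; N_avg stays near 100
  expect_equal(kin$n_track[kin$frame == 11], 100)
  expect_equal(kin$n_track[kin$frame == 30], 95)
  row20 <- kin[kin$frame == 20, ]
  expect_equal(row20$apoptosis_rate_pct, 100 * 5 / row20$n_avg)
  expect_true(all(is.na(kin$apoptosis_rate_pct[kin$frame <= 10])))

  none <- apoptosis_rate(events[0, ], tracks, 10, 30)
  expect_true(all(none$apoptosis_rate_pct[none$frame > 10] == 0))
})

test_that("overall survival is the smoothed living count over the start reference", {
  mus <- c(replicate(100, rep(0, 10), simplify = FALSE))
  tracks <- toy_tracks(mus)
  no_events <- tibble::tibble(track_id = integer(), x = numeric(),
                              y = numeric(), radius = numeric(),
                              death_frame = integer())
  os <- overall_survival(no_events, tracks, 10)
  expect_equal(os$survival_pct, rep(100, 10))

  # half the cohort dies at frame 4: the tail settles at 50%
  events <- tibble::tibble(track_id = 1:50, x = 1, y = 1, radius = 5,
                           death_frame = rep(4L, 50))
  os2 <- overall_survival(events, tracks, 10)
  expect_equal(os2$survival_pct[os2$frame >= 5], rep(50, 6))
  expect_equal(os2$n_avg2[1], 100)
  expect_error(overall_survival(no_events, tracks[0, ], 10),
               class = "apoptomap_degenerate_error")
})

test_that("dead plus living tracks account exactly for the tracks present", {
  run <- shared_run()
  spans <- track_spans(run$tracks)
  kin <- run$kinetics
  ev <- dplyr::left_join(run$events, spans, by = "track_id")
  for (t in unique(kin$frame)) {
    existing <- sum(spans$t_start <= t & spans$t_end >= t)
    dead_present <- sum(ev$death_frame <= t & ev$t_start <= t & ev$t_end >= t)
    expect_equal(kin$n_track[kin$frame == t] + dead_present, existing)
    # and the global inequality: every counted death ever seen is a track
    expect_lte(sum(run$events$death_frame <= t), nrow(spans))
  }
})

test_that("survival on the shared video matches the programmed kill fraction", {
  sim <- shared_sim()
  run <- shared_run()
  killed <- nrow(sim$deaths)
  expected <- 100 * (30 - killed) / 30
  final <- tail(run$survival$survival_pct, 1)
  expect_lt(abs(final - expected), 12)     # counting error on 30 cells
})
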