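test_that("object extraction uses 8-connectivity", {
  fr <- matrix(0, 10, 10)
  fr[3, 3] <- 1; fr[4, 4] <- 1              # touching diagonally
  expect_equal(nrow(extract_objects(fr)), 1L)

  fr2 <- matrix(0, 20, 20)
  fr2[3:5, 3:5] <- 1; fr2[3:5, 9:11] <- 2   # gap of 3 zero columns
  obj <- extract_objects(fr2)
  expect_equal(nrow(obj), 2L)
  expect_equal(sort(obj$mean_mc), c(1, 2))

  expect_equal(nrow(extract_objects(matrix(0, 8, 8))), 0L)
})

test_that("labeling agrees with flood fill on random sparse frames", {
  set.seed(31)
  for (i in 1:20) {
    fr <- random_object_frame(30, 6)
    got <- apoptomap:::label_components_8(fr)
    ref <- brute_components8(fr)
    expect_equal(max(got), max(ref))
    # same partition: each got-label maps to exactly one ref-label
    if (max(got) > 0) {
      tab <- table(got[got > 0], ref[ref > 0])
      expect_true(all(rowSums(tab > 0) == 1))
      expect_true(all(colSums(tab > 0) == 1))
    }
  }
})

test_that("the potential matches its closed form on a two-object frame", {
  # 3x3 squares of value 2 and 4; boundary centroids 100 px apart on a
  # 100x100 frame, so the normalized distance is exactly 1
  fr <- matrix(0, 100, 100)
  fr[9:11, 9:11] <- 2
  fr[89:91, 69:71] <- 4
  obj <- extract_objects(fr)
  expect_equal(nrow(obj), 2L)
  expect_equal(potential_of_death(obj, c(100, 100)), (2 + 4) / 4)
  # one object alone has no pairs
  expect_equal(potential_of_death(obj[1, ], c(100, 100)), 0)
})

test_that("the potential is invariant to rigid translation", {
  fr <- matrix(0, 60, 60)
  fr[5:7, 5:7] <- 1.5; fr[20:23, 30:34] <- 3
  moved <- matrix(0, 60, 60)
  moved[25:27, 15:17] <- 1.5; moved[40:43, 40:44] <- 3
  p1 <- potential_of_death(extract_objects(fr), c(60, 60))
  p2 <- potential_of_death(extract_objects(moved), c(60, 60))
  expect_equal(p1, p2)
  expect_gt(p1, 0)
})

test_that("doubling all pairwise distances halves the potential", {
  near <- matrix(0, 200, 200)
  near[10:12, 10:12] <- 2; near[10:12, 40:42] <- 3; near[40:42, 10:12] <- 5
  far <- matrix(0, 200, 200)
  far[10:12, 10:12] <- 2; far[10:12, 70:72] <- 3; far[70:72, 10:12] <- 5
  p_near <- potential_of_death(extract_objects(near), c(200, 200))
  p_far <- potential_of_death(extract_objects(far), c(200, 200))
  expect_equal(p_far, p_near / 2)
})

test_that("the object pipeline agrees with pixel-level brute force", {
  set.seed(53)
  for (i in 1:50) {
    fr <- random_object_frame(40, 5)
    got <- potential_of_death(extract_objects(fr), dim(fr))
    expect_equal(got, brute_pdeath(fr), tolerance = 1e-12)
  }
})

test_that("windowed evaluation reduces to the single busy window", {
  cal <- calibration(pixel_size_um = 2, frame_interval_h = 1)
  # all events inside one 141x141 px window of a 200x200 field
  ev <- tibble::tibble(track_id = 1:3, x = c(30, 60, 45), y = c(30, 60, 80),
                       radius = 5, death_frame = c(2L, 3L, 4L))
  pd <- pdeath_from_events(ev, c(200, 200, 12), cal, t_tilde_hours = 4,
                           se_radius_px = 2, window_um = 283)
  busy <- pd$windows[[4]]
  occupied <- busy[busy$n_objects > 0, ]
  expect_equal(pd$pdeath[4], mean(occupied$pdeath))
  expect_true(all(pd$pdeath >= 0))

  empty <- pdeath_from_events(ev[0, ], c(200, 200, 12), cal,
                              t_tilde_hours = 4, se_radius_px = 2)
  expect_true(all(empty$pdeath == 0))
})

test_that("coincident centroids are skipped with a warning, not infinite", {
  obj <- tibble::tibble(object_id = 1:2, n_pixels = c(4L, 4L),
                        mean_mc = c(1, 2), cx = c(10, 10), cy = c(5, 5),
                        pixels = list(NULL, NULL))
  expect_warning(p <- potential_of_death(obj, c(50, 50)), "coincident")
  expect_equal(p, 0)
})
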