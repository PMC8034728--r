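one_event <- function(x, y, radius, frame) {
  tibble::tibble(track_id = 1L, x = x, y = y, radius = radius,
                 death_frame = as.integer(frame))
}

test_that("seed videos rasterize death disks at the right frame only", {
  ev <- one_event(50, 40, 6, 3)
  md <- build_seed_video(ev, c(80, 80, 5))
  expect_equal(sum(md[, , -3]), 0)
  area <- sum(md[, , 3])
  expect_lt(abs(area - pi * 36), 12)        # rasterization tolerance
  expect_equal(max(md), 1)

  expect_equal(sum(build_seed_video(ev[0, ], c(40, 40, 4))), 0)

  both <- dplyr::bind_rows(one_event(30, 30, 6, 2), one_event(33, 30, 6, 2))
  md2 <- build_seed_video(both, c(60, 60, 3))
  expect_equal(max(md2), 1)                 # union, not sum

  expect_error(build_seed_video(one_event(99, 10, 5, 1), c(50, 50, 3)),
               class = "apoptomap_validation_error")
})

test_that("grayscale erosion is a disk minimum filter (loop oracle)", {
  # direct per-pixel minimum over the disk, out-of-frame treated as background
  loop_erode <- function(fr, r) {
    out <- fr
    for (y in seq_len(nrow(fr))) for (x in seq_len(ncol(fr))) {
      lo <- Inf
      for (dy in -r:r) for (dx in -r:r) {
        if (dx^2 + dy^2 > r^2) next
        yy <- y + dy; xx <- x + dx
        v <- if (yy < 1 || yy > nrow(fr) || xx < 1 || xx > ncol(fr)) 0
             else fr[yy, xx]
        if (v < lo) lo <- v
      }
      out[y, x] <- lo
    }
    out
  }
  set.seed(99)
  for (r in c(1, 2, 3)) {
    fr <- matrix(runif(30 * 30, 0, 2), 30, 30)
    fr[fr < 1.2] <- 0                       # zero background, sparse support
    got <- erode_gray(fr, r)
    expect_equal(got, loop_erode(fr, r), tolerance = 1e-12)
    expect_true(all(got <= fr))             # anti-extensive
  }
})

test_that("wakes obey the radius-vanishing law", {
  # support lasts between ceiling(r0/r) and ceiling(r0/r) + 1 frames
  cases <- list(c(30, 10), c(9, 3), c(12, 3), c(6, 3), c(15, 5))
  for (cs in cases) {
    r0 <- cs[1]; r <- cs[2]
    dims <- c(2 * r0 + 21, 2 * r0 + 21, ceiling(r0 / r) + 4)
    md <- build_seed_video(one_event(r0 + 10, r0 + 10, r0, 1), dims)
    m <- propagate_wake(md, r)
    alive <- which(apply(m, 3, function(f) any(f > 0)))
    expect_equal(min(alive), 1L)
    expect_gte(length(alive), ceiling(r0 / r))
    expect_lte(length(alive), ceiling(r0 / r) + 1)
    expect_true(all(diff(alive) == 1))      # contiguous support
  }
  # a cell-radius/3 structuring element keeps the wake up for >= 3 frames
  md <- build_seed_video(one_event(30, 30, 9, 1), c(60, 60, 8))
  m <- propagate_wake(md, 3)
  expect_gte(sum(apply(m, 3, function(f) any(f > 0))), 3)
})

test_that("an empty seed video propagates to an empty wake video", {
  md <- array(0, c(30, 30, 6))
  expect_equal(sum(propagate_wake(md, 3)), 0)
  expect_error(propagate_wake(md, 0), class = "apoptomap_config_error")
})

test_that("each wake frame is dominated by its eroded predecessor plus seeds", {
  set.seed(12)
  ev <- simulate_death_pattern(6, "random", dims = c(70, 70, 10), radius = 5,
                               seed = 12)
  md <- build_seed_video(ev, c(70, 70, 10))
  m <- propagate_wake(md, 2)
  for (t in 2:10) {
    er <- erode_gray(m[, , t - 1], 2)
    expect_true(all(er <= m[, , t - 1]))                    # anti-extensive
    expect_equal(m[, , t], er + md[, , t])                  # the recursion
  }
})

test_that("the cumulative map is the windowed sum of squared wakes", {
  m <- array(0, c(20, 20, 10))
  m[5, 5, ] <- 1                            # constant unit pixel
  m[8, 9, 4] <- 3                           # one bright flash at frame 4
  mc <- cumulative_map(m, 6)
  expect_equal(dim(mc)[3], 4L)
  expect_equal(mc[5, 5, 1], 7)              # inclusive window: T_tilde + 1 ones
  expect_equal(mc[8, 9, 1], 9)              # 3^2, frame 4 is inside [1, 7]
  # direct-summation oracle at every retained frame
  for (t in 1:4) {
    direct <- apply(m[, , t:(t + 6)]^2, c(1, 2), sum)
    expect_equal(mc[, , t], direct)
  }
  expect_equal(sum(cumulative_map(array(0, c(5, 5, 4)), 2)), 0)
  expect_error(cumulative_map(m, 10), class = "apoptomap_config_error")
})
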