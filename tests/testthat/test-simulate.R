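test_that("a fixed seed reproduces the stacks bit-exactly", {
  cfg <- sim_config(dims = c(64, 64, 4), n_cells = 5, seed = 13)
  a <- simulate_video(cfg)
  b <- simulate_video(cfg)
  expect_identical(as.vector(a$red), as.vector(b$red))
  expect_identical(as.vector(a$green), as.vector(b$green))
  expect_identical(a$deaths, b$deaths)
  expect_true(all(a$red == round(a$red)))   # integer intensities
})

test_that("without deaths the green channel stays at background", {
  cfg <- sim_config(dims = c(64, 64, 4), n_cells = 5, seed = 13,
                    death_schedule = NULL)
  sim <- simulate_video(cfg)
  expect_equal(nrow(sim$deaths), 0L)
  expect_lt(max(sim$green), cfg$background_mean + 5 * cfg$noise_sd)
})

test_that("the reporter turns on at the programmed death and not before", {
  sched <- tibble::tibble(x = 32, y = 32, t = 10L, radius = 6)
  cfg <- sim_config(dims = c(64, 64, 14), death_schedule = sched, seed = 3,
                    green_rise_frames = 2)
  sim <- simulate_video(cfg)
  sig <- vapply(1:14, function(t) sim$green[32, 32, t], numeric(1))
  expect_true(all(sig[1:9] < cfg$background_mean + 5 * cfg$noise_sd))
  expect_true(all(sig[11:14] > cfg$background_mean + 10 * cfg$noise_sd))
  expect_error(simulate_cohort(sim_config(
    dims = c(64, 64, 14),
    death_schedule = tibble::tibble(x = 99, y = 32, t = 2L, radius = 5))),
    class = "apoptomap_config_error")
})

test_that("death patterns respect counts, frames and spatial mode", {
  expect_equal(nrow(simulate_death_pattern(0, "random", c(50, 50, 10))), 0L)

  ref <- simulate_death_pattern(40, "random", c(200, 200, 30), seed = 9)
  matched <- simulate_death_pattern(0, "clustered", c(200, 200, 30),
                                    match_counts_to = ref, seed = 10)
  expect_equal(table(matched$death_frame), table(ref$death_frame))
  expect_false(isTRUE(all.equal(matched$x, ref$x)))

  # clustered patterns sit closer together than random ones
  nn_mean <- function(ev) {
    d <- as.matrix(dist(cbind(ev$x, ev$y))); diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  set.seed(70)
  nn <- vapply(1:20, function(i) {
    cl <- simulate_death_pattern(25, "clustered", c(200, 200, 30), k = 3,
                                 spread = 16, seed = 70 + i)
    rn <- simulate_death_pattern(25, "random", c(200, 200, 30),
                                 seed = 170 + i)
    nn_mean(cl) < nn_mean(rn)
  }, logical(1))
  expect_gte(mean(nn), 0.95)
})

test_that("hazard rates outside [0, 1] are rejected", {
  expect_error(sim_config(death_schedule = list(type = "constant", rate = 1.5)),
               class = "apoptomap_config_error")
})
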