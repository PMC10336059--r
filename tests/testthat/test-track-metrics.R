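arena <- arena_config(500, 500, c(0, 200, 60, 300),
                      object_point = c(250, 480),
                      conspecific_point = c(490, 250))

test_that("time outside the refuge counts detected seconds", {
  expect_equal(time_outside_refuge(bt_track(integer(0), numeric(0),
                                            numeric(0), 3600)), 0)
  full <- bt_track(0:3599, runif(3600, 100, 400), runif(3600, 0, 100), 3600)
  expect_equal(time_outside_refuge(full), 3600)
  tr <- random_track(137, duration = 500, seed = 3)
  expect_equal(time_outside_refuge(tr), 137)
})

test_that("minimum distance imputes only fully undetected tracks", {
  empty <- bt_track(integer(0), numeric(0), numeric(0), 3600)
  expect_equal(min_distance_to_point(empty, c(250, 480), 250), 250)
  expect_equal(min_distance_to_point(empty, c(490, 250), 350), 350)
  at_point <- bt_track(0L, 250, 480, 3600)
  expect_equal(min_distance_to_point(at_point, c(250, 480), 250), 0)
})

test_that("interaction radius comparison is closed at the boundary", {
  k <- 7
  tr <- bt_track(0:(k - 1), rep(250, k), rep(480, k), 3600)
  expect_equal(interaction_time(tr, c(250, 480), 100), k)
  off <- bt_track(0:9, rep(250 + 100.5, 10), rep(480, 10), 3600)
  expect_equal(interaction_time(off, c(250, 480), 100), 0)
  on_edge <- bt_track(0L, 350, 480, 3600)
  expect_equal(interaction_time(on_edge, c(250, 480), 100), 1)
})

test_that("total distance sums consecutive Euclidean steps", {
  tr <- bt_track(c(0L, 1L, 2L), c(0, 3, 6), c(0, 4, 8), 10)
  expect_equal(total_distance(tr), 10)
  single <- bt_track(0L, 5, 5, 10)
  expect_equal(total_distance(single), 0)
  # gap-spanning pairs still count unless split_gaps
  gap <- bt_track(c(0L, 5L), c(0, 3), c(0, 4), 10)
  expect_equal(total_distance(gap), 5)
  expect_equal(total_distance(gap, split_gaps = TRUE), 0)
})

test_that("square path turns by a right angle at each corner", {
  tr <- bt_track(0:3, c(0, 1, 1, 0), c(0, 0, 1, 1), 10)
  expect_equal(turning_angles(tr), c(pi / 2, pi / 2))
  line <- bt_track(0:3, 0:3, rep(0, 4), 10)
  expect_equal(turning_angles(line), c(0, 0))
})

test_that("turning angles skip zero-length displacements", {
  tr <- bt_track(0:3, c(0, 1, 1, 2), c(0, 0, 0, 1), 10)
  expect_equal(turning_angles(tr), pi / 4)
  expect_error(turning_angles(bt_track(0:1, c(0, 1), c(0, 0), 10)),
               class = "bt_insufficient_data")
})

test_that("metrics agree with brute-force per-row oracles", {
  point <- c(250, 480)
  for (seed in 1:25) {
    tr <- random_track(n = sample(20:200, 1), duration = 400, seed = seed)
    expect_equal(min_distance_to_point(tr, point, 250),
                 oracle_min_distance(tr, point))
    expect_equal(interaction_time(tr, point, 100),
                 oracle_interaction(tr, point, 100))
    expect_equal(total_distance(tr), oracle_total_distance(tr))
    expect_equal(turning_angles(tr), oracle_turning_angles(tr))
  }
})

test_that("total distance is invariant under rigid motions", {
  tr <- random_track(80, duration = 200, seed = 9)
  th <- 0.7; dx <- 120; dy <- -45
  xr <- cos(th) * tr$x_px - sin(th) * tr$y_px + dx
  yr <- sin(th) * tr$x_px + cos(th) * tr$y_px + dy
  moved <- bt_track(tr$t_s, xr, yr, attr(tr, "duration_s"))
  expect_equal(total_distance(moved), total_distance(tr), tolerance = 1e-10)
  expect_equal(turning_angles(moved), turning_angles(tr), tolerance = 1e-10)
})

test_that("metric-set dispatch follows the test protocol", {
  empty <- bt_track(integer(0), numeric(0), numeric(0), 3600,
                    test = "exploration")
  ms <- compute_metricset(empty, arena, "exploration")
  expect_equal(ms$time_outside_s, 0)
  expect_equal(ms$min_distance_px, 250)
  expect_equal(ms$interaction_time_s, 0)

  soc <- bt_track(0:49, rep(490, 50), rep(250, 50), 3600,
                  test = "sociability")
  ms2 <- compute_metricset(soc, arena, "sociability")
  expect_equal(ms2$interaction_time_s, ms2$time_outside_s)
  # sociability imputation is 350 px
  empty_soc <- bt_track(integer(0), numeric(0), numeric(0), 3600)
  expect_equal(compute_metricset(empty_soc, arena,
                                 "sociability")$min_distance_px, 350)

  sparse <- random_track(19, duration = 7200, seed = 2, test = "activity")
  ms3 <- compute_metricset(sparse, arena, "activity")
  expect_true(ms3$insufficient)
  expect_true(is.na(ms3$area95_px2))

  expect_error(compute_metricset(empty, arena, "grooming"), "unknown test")
})

test_that("metric invariants hold on simulated tracks", {
  mv <- movement_config(duration_s = 600, p_exit_refuge = 0.3)
  for (seed in 1:5) {
    tr <- simulate_trajectory(arena, mv, seed = seed, test = "exploration")
    ms <- compute_metricset(tr, arena, "exploration")
    expect_lte(ms$interaction_time_s, ms$time_outside_s)
    expect_lte(ms$time_outside_s, attr(tr, "duration_s"))
    expect_gte(ms$min_distance_px, 0)
  }
})

test_that("pixel-centimetre calibration matches the arena scale", {
  expect_equal(px_to_cm(16.7), 1)
  expect_equal(round(px_to_cm(33), 2), 1.98)
  expect_lt(abs(px_to_cm(250) - 15), 0.05)
  expect_lt(abs(px_to_cm(100) - 6), 0.05)
  expect_error(px_to_cm(10, px_per_cm = 0), "positive")
})
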