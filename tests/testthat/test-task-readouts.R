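# closed-form geometry: spider on the left plank at (-2.3, 2.15)

test_that("search-task minimum distance matches the layout geometry", {
  s <- make_test_session(fishing_pos = c(0, 0.3))
  # stationary at (0, 0.3); spider plank center at (-2.3, 2.15)
  want <- sqrt(2.3^2 + (2.15 - 0.3)^2)
  expect_equal(fishing_min_distance(s, "spider"), want, tolerance = 1e-9)
  # symmetric stimuli, centered participant: readout difference is zero
  expect_equal(fishing_readout(s), 0, tolerance = 1e-9)
})

test_that("hugging the turtle plank gives a positive readout; mirrored
           layouts negate it", {
  path <- function(t) cbind(rep(2.2, length(t)), rep(2.15, length(t)))
  s <- make_test_session(fishing_pos = path)   # spider left, turtle right
  expect_gt(fishing_readout(s), 4)
  s2 <- make_test_session(
    fishing_pos = function(t) cbind(rep(-2.2, length(t)),
                                    rep(2.15, length(t))),
    layout = scene_layout(spider_side_fishing = "right"))
  expect_equal(fishing_readout(s2), fishing_readout(s), tolerance = 1e-9)
  s3 <- make_test_session(fishing_pos = path,
                          layout = scene_layout(spider_side_fishing = "right"))
  expect_equal(fishing_readout(s3), -fishing_readout(s), tolerance = 1e-9)
})

test_that("track not covering the analysis window errors", {
  s <- make_test_session()
  short <- s$tracks$pelvis$samples
  short <- short[short$t < 100, ]
  s$tracks$pelvis <- motion_track(short$t, short$x, short$y, short$z,
                                  yaw = short$yaw, sensor_id = "pelvis")
  expect_error(fishing_min_distance(s, "spider"), "window")
})

test_that("orientation angle is 0 facing, 90 perpendicular, 180 back", {
  # participant on the spider half at (-1, 2.15); spider at (-2.3, 2.15)
  # facing the spider means facing -x, i.e. yaw +90 (CCW from +z)
  at <- function(yaw) make_test_session(
    fishing_pos = c(-1, 2.15), fishing_yaw = yaw)
  expect_equal(fishing_orientation(at(90), "spider"), 0, tolerance = 1e-6)
  expect_equal(fishing_orientation(at(-90), "spider"), 180, tolerance = 1e-6)
  expect_equal(fishing_orientation(at(0), "spider"), 90, tolerance = 1e-6)
  expect_equal(fishing_orientation(at(180), "spider"), 90, tolerance = 1e-6)
})

test_that("a half never entered yields a flagged missing orientation", {
  s <- make_test_session(fishing_pos = c(1.5, 2))  # right half only
  ang <- fishing_orientation(s, "spider")          # spider is left
  expect_true(is.na(ang))
  expect_true(isTRUE(attr(ang, "excluded")))
  expect_false(is.na(fishing_orientation(s, "turtle")))
})

test_that("glance difference counts merged glances inside the window", {
  fs <- data.frame(label = c("spider", "spider", "spider", "turtle"),
                   start = c(20, 30, 40, 50), end = c(21, 31, 41, 51))
  s <- make_test_session(focus_spec = fs)
  expect_equal(fishing_glance_difference(s), 2)
  s0 <- make_test_session()
  expect_equal(fishing_glance_difference(s0), 0)
  # focus before the wait ends is outside the analysis window
  fs2 <- data.frame(label = "spider", start = c(2, 20), end = c(3, 21))
  expect_equal(fishing_glance_difference(make_test_session(focus_spec = fs2)),
               1)
})

test_that("side occupancy partitions the window and drives physiology", {
  s <- make_test_session(fishing_pos = c(1.5, 2))  # turtle half throughout
  occ <- side_occupancy(s)
  expect_equal(nrow(occ$left), 0)
  expect_equal(sum(occ$right[, 2] - occ$right[, 1]), 120, tolerance = 1e-6)
  phys <- fishing_side_physiology(s)
  expect_true(is.na(phys$rr[["spider"]]))
  expect_equal(phys$rr[["turtle"]], 0.8, tolerance = 1e-9)

  # crossing participant: both halves occupied, constant rr both sides
  cross <- function(t) cbind(1.5 * sin(2 * pi * t / 40), rep(2, length(t)))
  s2 <- make_test_session(fishing_pos = cross)
  occ2 <- side_occupancy(s2)
  expect_equal(sum(occ2$left[, 2] - occ2$left[, 1]) +
                 sum(occ2$right[, 2] - occ2$right[, 1]), 120, tolerance = 1e-6)
  phys2 <- fishing_side_physiology(s2)
  expect_equal(unname(phys2$rr), c(0.8, 0.8), tolerance = 1e-9)
})

test_that("path side classification reads the first gate crossing", {
  lay <- scene_layout()
  straight <- function(xg) {
    t <- seq(0, 10, by = 0.05)
    z <- 0.25 + t / 10 * 3.45
    x <- xg * sin(pi * (z - 0.25) / 3.45)
    motion_track(t, x, rep(1, length(t)), z, sensor_id = "pelvis")
  }
  expect_equal(classify_path_side(straight(-0.8), c(0, 10), lay), "left")
  expect_equal(classify_path_side(straight(0.8), c(0, 10), lay), "right")

  # zig-zag: crosses the gate at x > 0 first, then wanders left
  t <- seq(0, 10, by = 0.05)
  z <- 0.25 + t / 10 * 3.45
  x <- ifelse(z < 2.5, 0.5, -0.9)
  zig <- motion_track(t, x, rep(1, length(t)), z, sensor_id = "pelvis")
  expect_equal(classify_path_side(zig, c(0, 10), lay), "right")

  # never crossing the gate line
  low <- motion_track(t, x, rep(1, length(t)), rep(1, length(t)),
                      sensor_id = "pelvis")
  expect_error(classify_path_side(low, c(0, 10), lay), "never crossed")
})

test_that("avoidance score attains +14/-14 for pure policies under both
           counterbalance schedules", {
  for (first in c("left", "right")) {
    lay <- scene_layout(spider_side_path_first = first)
    turtle_sides <- ifelse(lay$animal_swap_schedule == "left", "right",
                           "left")[rep(1:5, each = 2)]
    spider_sides <- lay$animal_swap_schedule[rep(1:5, each = 2)]
    expect_equal(avoidance_score(path_segment_choices(turtle_sides, lay)), 14)
    expect_equal(avoidance_score(path_segment_choices(spider_sides, lay)), -14)
    # the alternative sign convention flips the anchor
    expect_equal(avoidance_score(path_segment_choices(turtle_sides, lay),
                                 sign_convention = "avoid_negative"), -14)
  }
})

test_that("weight table: spider both legs of trial 1, near side after", {
  lay <- scene_layout(spider_side_path_first = "left")
  near <- c("center", "right", "left", "far_right", "far_left")
  near_side <- c(NA, "right", "left", "right", "left")
  sides <- c("left", "left",                    # spider side, weight 1 each
             near_side[rep(2:5, each = 2)])     # cost-0 near sides
  ch <- path_segment_choices(sides, lay)
  expect_equal(avoidance_score(ch), -2)
  expect_equal(ch$weight[1:2], c(1L, 1L))
  expect_true(all(ch$weight[3:10] == 0L))
})

test_that("segment weights follow the 0/1/2/4 cost-of-avoidance table", {
  expect_equal(segment_weight("left", "center"), 1L)
  expect_equal(segment_weight("right", "right"), 0L)
  expect_equal(segment_weight("left", "right"), 2L)
  expect_equal(segment_weight("right", "far_left"), 4L)
  expect_equal(segment_weight("left", "far_left"), 0L)
  expect_error(avoidance_score(path_segment_choices(rep("left", 10),
                                                    scene_layout())[-1, ]),
               "10 segments")
  expect_error(path_segment_choices(rep("left", 9), scene_layout()), "10")
})

test_that("sessions yield the ten segments their trajectories encode", {
  sides <- c("right", "right", "left", "right", "left",
             "left", "right", "right", "left", "left")
  s <- make_test_session(chosen_sides = sides)
  ch <- session_path_choices(s)
  expect_equal(nrow(ch), 10)
  expect_equal(ch$chosen_side, sides)
  expect_equal(path_choice_readout(s),
               avoidance_score(path_segment_choices(sides, s$layout)))
})

test_that("time to touch and the truncated first-presentation difference", {
  s <- make_test_session(touch_times = c(3.2, 2, 5, 4))  # spider first
  expect_equal(touch_time(s, 1), 3.2, tolerance = 1e-9)
  expect_equal(touch_readout(s), 1.2, tolerance = 1e-9)

  s2 <- make_test_session(touch_times = c(212, 2, 5, 4))
  expect_equal(touch_readout(s2), 20)

  # equal times give zero; a slower turtle gives an uncapped negative value
  expect_equal(touch_readout(make_test_session(touch_times = c(2, 2, 3, 3))),
               0, tolerance = 1e-9)
  expect_equal(touch_readout(make_test_session(touch_times = c(2, 30, 3, 3))),
               -28, tolerance = 1e-9)

  # turtle-first counterbalance swaps the roles
  s3 <- make_test_session(touch_times = c(3, 10, 5, 4),
                          layout = scene_layout(first_touch_stimulus =
                                                  "turtle"))
  expect_equal(touch_readout(s3), 7, tolerance = 1e-9)

  s4 <- make_test_session()
  s4$events <- s4$events[s4$events$kind != "stimulus_touch", ]
  expect_error(touch_time(s4, 1), "missing event")
})

test_that("constant-speed approaches split into three equal thirds that sum
           to the time to touch", {
  s <- make_test_session(touch_times = c(6, 6, 6, 6))
  td <- thirds_durations(s, 1)
  expect_equal(td, rep(2, 3), tolerance = 0.1)
  expect_equal(sum(td), touch_time(s, 1), tolerance = 1e-6)

  # a walk that stalls near the stimulus loads the last third
  s2 <- make_test_session(touch_times = c(12, 6, 6, 6))
  tr1 <- s2$tracks$pelvis$samples
  cd <- 260; touch <- 272
  sel <- tr1$t >= cd & tr1$t <= touch
  frac <- (tr1$t[sel] - cd) / 12
  tr1$z[sel] <- 3.8 * pmin(1, frac * 3 / 1.2)^0.25 *
    ifelse(frac < 0.1, frac / 0.1, 1)
  tr1$z[sel][frac > 0.9] <- 3.8
  s2$tracks$pelvis <- motion_track(tr1$t, tr1$x, tr1$y, tr1$z, yaw = tr1$yaw,
                                   sensor_id = "pelvis")
  td2 <- thirds_durations(s2, 1)
  expect_equal(sum(td2), 12, tolerance = 1e-6)
  expect_gt(td2[3], td2[1])
})

test_that("hand acceleration changes: smooth reach small, tremor capped", {
  s <- make_test_session(touch_times = c(8, 8, 8, 8),
                         hand_jitter = c(0.05, 0, 0, 0))
  noisy <- trial_accel_changes(s, 1)
  smooth <- trial_accel_changes(s, 2)
  expect_equal(noisy, 100)    # white-jitter trial saturates the cap
  expect_lt(smooth, 40)
  raw <- count_acceleration_sign_changes(resample_hand_track(
    s$tracks$right_hand$samples[s$tracks$right_hand$samples$t >= 260 &
                                  s$tracks$right_hand$samples$t <= 268, ]))
  expect_gt(raw, 100)
  expect_equal(truncate_value(raw, 100), 100)
})

test_that("pre-touch windows: constant RR recovered, closed eyes excluded", {
  s <- make_test_session(rr_const = 0.9)
  pw <- pre_touch_windows(s, 1)
  expect_equal(pw$rr, 0.9, tolerance = 1e-9)
  expect_false(pw$closed_eyes)

  # eye closed across the whole 0.5 s pupil window of trial 1's touch
  touch1 <- s$events$t[s$events$task == "touch_enemy" &
                         s$events$kind == "stimulus_touch"][1]
  s2 <- make_test_session(rr_const = 0.9,
                          blink_windows = matrix(c(touch1 - 0.6, touch1),
                                                 1, 2))
  pw2 <- pre_touch_windows(s2, 1)
  expect_true(is.na(pw2$pupil))
  expect_true(pw2$closed_eyes)
  expect_equal(pw2$rr, 0.9, tolerance = 1e-9)
})

test_that("readout rows satisfy their invariants on constructed sessions", {
  s <- make_test_session(touch_times = c(25, 2, 5, 4),
                         hand_jitter = c(0.05, 0, 0, 0.05))
  ro <- compute_readouts(list(s))
  expect_equal(nrow(ro), 1)
  expect_true(validate_readouts(ro))
  expect_equal(ro$touch_time_diff, 20)
  expect_equal(ro$accel_spider1, 100)
})
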