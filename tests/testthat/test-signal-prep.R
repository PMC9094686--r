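test_that("pupil outlier flagging matches the sliding-window definition", {
  v <- rep(3, 200)
  v[77] <- 9
  out <- flag_pupil_outliers(v)
  expect_true(is.na(out[77]))
  expect_equal(sum(is.na(out)), 1)

  ramp <- seq(1, 5, length.out = 300)
  expect_false(anyNA(flag_pupil_outliers(ramp)))

  # all-equal windows have zero MAD; the strict inequality flags nothing
  expect_false(anyNA(flag_pupil_outliers(rep(2.5, 150))))

  expect_error(flag_pupil_outliers(numeric(0)), "empty")
  expect_error(flag_pupil_outliers(rnorm(10)), "window/2")
})

test_that("outlier flagging equals the brute-force oracle on noisy series", {
  set.seed(1)
  for (rep_i in 1:10) {
    v <- rnorm(400, 3.5, 0.1)
    v[sample(400, 8)] <- v[sample(400, 8)] + sample(c(-2, 2), 8, TRUE)
    v[sample(400, 12)] <- NA
    out <- flag_pupil_outliers(v, window = 100, k = 3)
    want <- oracle_outlier_flags(v, 100, 3)
    expect_identical(is.na(out) & !is.na(v), want)
  }
})

test_that("interpolation fills gaps linearly and resamples by nearest", {
  rs <- interpolate_and_resample(c(0, 0.01, 0.02), c(1, NA, 3), rate = 100)
  expect_equal(rs$values, c(1, 2, 3))

  # nearest-neighbour: grid point at ~9.09 ms is closer to the 5 ms sample
  rs2 <- interpolate_and_resample(c(0, 0.005, 0.020), c(1, 2, 3), rate = 110)
  expect_equal(rs2$values[2], 2)

  # already-regular input is unchanged
  t <- (0:219) / 110
  v <- sin(t * 3)
  rs3 <- interpolate_and_resample(t, v, rate = 110)
  expect_equal(rs3$values, v, tolerance = 1e-12)

  # leading/trailing missing take the nearest valid value
  rs4 <- interpolate_and_resample((0:4) / 10, c(NA, 2, 4, NA, NA), rate = 10)
  expect_equal(rs4$values, c(2, 2, 4, 4, 4))

  expect_error(interpolate_and_resample(c(0, 1), c(NA, 2)), "two non-missing")
})

test_that("unit rescaling maps onto [0, 1] with the degenerate rule", {
  expect_equal(rescale_unit(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(rescale_unit(rep(7, 5)), rep(0, 5))
  set.seed(2)
  for (i in 1:20) {
    v <- rnorm(50)
    r <- rescale_unit(v)
    expect_equal(range(r), c(0, 1))
  }
})

test_that("pupil preprocessing chain yields a complete unit-range series", {
  t <- seq(0, 20, by = 1 / 110)
  n <- length(t)
  set.seed(3)
  pup <- 3.5 + 0.3 * sin(t) + rnorm(n, 0, 0.02)
  pup[500:540] <- NA                       # blink
  pup[1000] <- 7                           # artifact spike
  valid <- !is.na(pup)
  g <- gaze_stream(t, rep("", n), pup, pup, valid, valid)
  rs <- preprocess_pupil(g, "right")
  expect_false(anyNA(rs$values))
  expect_equal(rs$rate, 110)
  expect_gte(min(rs$values), 0)
  expect_lte(max(rs$values), 1)

  # constant input: degenerate rescale gives all zeros
  g2 <- gaze_stream(t, rep("", n), rep(3, n), rep(3, n))
  expect_true(all(preprocess_pupil(g2, "left")$values == 0))

  # rescaling is monotone: a dilation ramp keeps its ordering
  g3 <- gaze_stream(t, rep("", n), 3 + t / 20, 3 + t / 20)
  v <- preprocess_pupil(g3, "right")$values
  expect_true(all(diff(v) >= 0))
})

test_that("glance segmentation merges only sub-200 ms interruptions", {
  t <- seq(0, 3, by = 0.01)
  mk <- function(gap) {
    f <- rep("", length(t))
    f[t < 1] <- "spider"
    f[t >= 1 + gap & t < 2] <- "spider"
    gaze_stream(t, f, rep(3, length(t)), rep(3, length(t)))
  }
  expect_equal(segment_glances(mk(0.15), "spider")$count, 1)
  expect_equal(segment_glances(mk(0.25), "spider")$count, 2)
  expect_equal(segment_glances(mk(0.15), "turtle")$count, 0)

  gs <- segment_glances(mk(0.25), "spider")
  expect_equal(gs$total_duration, interval_sum <- sum(gs$intervals[, 2] -
                                                        gs$intervals[, 1]))
  # merging is idempotent
  expect_equal(merge_glance_intervals(gs$intervals, 0.2), gs$intervals)
})

test_that("glance counts equal the brute-force merge oracle", {
  set.seed(4)
  t <- seq(0, 10, by = 1 / 110)
  for (i in 1:100) {
    on <- runif(length(t)) < 0.4
    # runs persist: smooth with a random run structure
    on <- rep(sample(c(TRUE, FALSE), 40, TRUE),
              times = diff(c(0, sort(sample(length(t) - 1, 39)),
                             length(t))))
    f <- ifelse(on, "spider", "")
    g <- gaze_stream(t, f, rep(3, length(t)), rep(3, length(t)))
    expect_equal(segment_glances(g, "spider")$count,
                 oracle_glance_count(t, on, 0.2))
  }
})

test_that("spline resampling reproduces knots and closed forms", {
  t10 <- seq(0, 2, by = 0.1)
  tk <- motion_track(t10, t10 * 2, t10 * 0, 3 - t10, sensor_id = "right_hand")
  rt <- resample_hand_track(tk, rate = 10)
  expect_equal(rt$x, t10 * 2, tolerance = 1e-9)

  set.seed(5)
  ti <- sort(runif(40, 0, 2))
  ti[1] <- 0
  lin <- motion_track(ti, 1 + 2 * ti, 0.5 - ti, 3 * ti,
                      sensor_id = "right_hand")
  rl <- resample_hand_track(lin, rate = 10)
  expect_equal(rl$x, 1 + 2 * rl$t, tolerance = 1e-9)
  expect_equal(rl$y, 0.5 - rl$t, tolerance = 1e-9)

  ts <- seq(0, 2, by = 1 / 60)
  sine <- motion_track(ts, sin(2 * pi * ts), ts * 0, ts * 0 + 1,
                       sensor_id = "right_hand")
  rs <- resample_hand_track(sine, rate = 10)
  expect_equal(rs$x, sin(2 * pi * rs$t), tolerance = 1e-4)

  expect_error(resample_hand_track(
    motion_track(c(0, 1, 2), 1:3, 1:3, 1:3, sensor_id = "right_hand")),
    "4 samples")
})

test_that("acceleration sign changes: closed forms, oracle, invariances", {
  t <- seq(0, 5, by = 0.1)
  straight <- list(t = t, x = 2 * t, y = rep(1, length(t)), z = 3 - t)
  class(straight) <- "regular_track"
  expect_equal(count_acceleration_sign_changes(straight), 0)

  set.seed(6)
  for (i in 1:20) {
    x <- sin(2 * pi * runif(1, 0.3, 0.8) * t) + rnorm(length(t), 0, 0.05)
    y <- cos(2 * pi * runif(1, 0.3, 0.8) * t) + rnorm(length(t), 0, 0.05)
    z <- 0.3 * t + rnorm(length(t), 0, 0.05)
    rt <- structure(list(t = t, x = x, y = y, z = z),
                    class = "regular_track")
    want <- oracle_accel_count(x, y, z)
    expect_equal(count_acceleration_sign_changes(rt), want)
    # rigid translation
    rt2 <- structure(list(t = t, x = x + 5, y = y - 2, z = z + 0.7),
                     class = "regular_track")
    expect_equal(count_acceleration_sign_changes(rt2), want)
    # time reversal
    rt3 <- structure(list(t = t, x = rev(x), y = rev(y), z = rev(z)),
                     class = "regular_track")
    expect_equal(count_acceleration_sign_changes(rt3), want)
  }
})

test_that("truncation caps the printed worked examples and is idempotent", {
  expect_equal(truncate_value(212, 20), 20)
  expect_equal(truncate_value(739, 100), 100)
  expect_equal(truncate_value(5, 20), 5)
  expect_equal(truncate_value(c(21, 22, 30, 39, 70, 212), 20), rep(20, 6))
  v <- seq(-5, 150, by = 7)
  expect_true(all(diff(truncate_value(v, 100)) >= 0))
  expect_equal(truncate_value(truncate_value(v, 100), 100),
               truncate_value(v, 100))
  expect_error(truncate_value(5, -1))
})

test_that("windowed RR means follow the 250 Hz step-function rendering", {
  rr <- rr_series(seq(0, 60, by = 0.8), rep(0.8, 76))
  expect_equal(mean_rr_in_windows(rr, c(3.3, 7.1)), 0.8)

  rr2 <- rr_series(c(0, 0.5), c(0.8, 1.0))
  expect_equal(mean_rr_in_windows(rr2, c(0, 1)), 0.9)

  expect_true(is.na(mean_rr_in_windows(rr_series(c(10, 11), c(0.8, 0.8)),
                                       c(0, 5))))
  expect_error(mean_rr_in_windows(rr, matrix(numeric(0), ncol = 2)), "empty")
  expect_error(mean_rr_in_windows(rr, c(5, 5)), "degenerate")
})
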