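#' Flag pupil outliers against a moving median
#'
#' A value is marked missing iff it deviates from the moving median of its
#' centered window by more than `k` scaled median absolute deviations
#' (scaled MAD = 1.4826 x MAD, the consistency constant for a normal SD).
#' The window covers `window` samples (shrunk at the series edges); already
#' missing values stay missing and are skipped when forming the window
#' statistics. The inequality is strict, so an all-equal window (MAD 0)
#' flags nothing.
#'
#' @param values numeric vector of pupil diameters (may contain `NA`).
#' @param window window size in samples (default 100).
#' @param k deviation multiplier (default 3).
#' @return `values` with outliers replaced by `NA`.
#' @export
flag_pupil_outliers <- function(values, window = 100, k = 3) {
  n <- length(values)
  if (n == 0) stop("empty series")
  if (n < window / 2)
    stop(sprintf("need at least window/2 = %g samples, got %d", window / 2, n))
  mm <- .cpp_moving_median_mad(as.numeric(values), as.integer(window))
  smad <- 1.4826 * mm[, 2]
  dev <- abs(values - mm[, 1])
  out <- values
  out[!is.na(dev) & !is.na(smad) & dev > k * smad] <- NA_real_
  out
}

#' Linearly interpolate missing values and resample to a regular grid
#'
#' Internal missing runs are linearly interpolated in time; leading and
#' trailing missing values take the nearest valid value. The completed
#' irregular series is then transferred onto the regular grid
#' `t0 + i/rate` (spanning the input's time range) by nearest-neighbour
#' lookup.
#'
#' @param t timestamps in seconds (strictly increasing).
#' @param values numeric values, `NA` allowed.
#' @param rate output rate in Hz (default 110).
#' @param t0 grid origin (defaults to the first timestamp).
#' @return A `regular_series`: list with `t0`, `rate`, `values`.
#' @export
interpolate_and_resample <- function(t, values, rate = 110, t0 = NULL) {
  stopifnot(length(t) == length(values))
  assert_increasing(t, "series")
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least two non-missing samples")
  # linear fill inside, nearest valid at the edges (rule = 2)
  filled <- approx(t[ok], values[ok], xout = t, method = "linear",
                   rule = 2)$y
  t0 <- t0 %||% t[1]
  m <- floor((t[length(t)] - t0) * rate + 1e-9) + 1L
  grid <- t0 + (seq_len(m) - 1L) / rate
  # nearest-neighbour lookup into the completed irregular series
  idx <- findInterval(grid, t, all.inside = TRUE)
  use_next <- (grid - t[idx]) > (t[pmin(idx + 1L, length(t))] - grid)
  idx[use_next] <- pmin(idx[use_next] + 1L, length(t))
  regular_series(t0, rate, filled[idx])
}

#' Construct a regular series
#'
#' @param t0 time of the first sample (seconds).
#' @param rate sampling rate in Hz (> 0).
#' @param values numeric values.
#' @return An object of class `regular_series`.
#' @export
regular_series <- function(t0, rate, values) {
  stopifnot(is_scalar_number(rate), rate > 0)
  structure(list(t0 = t0, rate = rate, values = as.numeric(values)),
            class = "regular_series")
}

#' Grid timestamps of a regular series
#' @param series a `regular_series`.
#' @return numeric vector of sample times.
#' @export
series_times <- function(series) {
  series$t0 + (seq_along(series$values) - 1L) / series$rate
}

#' Rescale a series to the unit interval
#'
#' Maps values to `(v - min)/(max - min)`. A degenerate series with
#' `max == min` maps to all zeros.
#'
#' @param series a `regular_series` or numeric vector.
#' @return same shape as the input, rescaled into `[0, 1]`.
#' @export
rescale_unit <- function(series) {
  v <- if (inherits(series, "regular_series")) series$values else series
  if (length(v) == 0) stop("empty series")
  rng <- range(v, na.rm = TRUE)
  out <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else
    rep(0, length(v))
  if (inherits(series, "regular_series")) {
    series$values <- out
    series
  } else out
}

#' Preprocess a pupil stream
#'
#' The full pupillometry chain for one eye: moving-median MAD outlier
#' removal ([flag_pupil_outliers()]), linear interpolation of missing runs
#' (outliers and closed eyes) plus resampling to a regular grid
#' ([interpolate_and_resample()]), and rescaling to the unit interval
#' ([rescale_unit()]). Rescaling is applied to the segment handed in, i.e.
#' per task segment when callers slice the stream per task.
#'
#' @param gaze a [gaze_stream()].
#' @param eye `"right"` or `"left"`.
#' @param window,k outlier-window parameters, see [flag_pupil_outliers()].
#' @param rate output rate in Hz (default 110).
#' @return A `regular_series` in `[0, 1]` with no missing values.
#' @export
preprocess_pupil <- function(gaze, eye = c("right", "left"), window = 100,
                             k = 3, rate = 110) {
  eye <- match.arg(eye)
  stopifnot(inherits(gaze, "gaze_stream"))
  s <- gaze$samples
  if (nrow(s) == 0) stop("empty gaze stream")
  v <- if (eye == "right") s$pupil_right else s$pupil_left
  v <- flag_pupil_outliers(v, window = window, k = k)
  rescale_unit(interpolate_and_resample(s$t, v, rate = rate))
}

#' Segment glances at a target object
#'
#' A glance is a maximal run of gaze focus on `target`, after merging
#' consecutive runs separated by interruptions strictly shorter than
#' `max_gap` (default 200 ms), which are treated as continuous viewing.
#' Each sample is taken to cover the interval up to the next sample (the
#' last sample covers one median inter-sample step).
#'
#' @param gaze a [gaze_stream()].
#' @param target focused-object label of interest.
#' @param max_gap merge threshold in seconds (default 0.2).
#' @param window optional `c(start, end)` restriction in seconds.
#' @return A `glance_set`: list with `target`, `intervals` (matrix of
#'   `[start, end)` pairs), `count`, `total_duration`.
#' @export
segment_glances <- function(gaze, target, max_gap = 0.2, window = NULL) {
  stopifnot(inherits(gaze, "gaze_stream"))
  s <- gaze$samples
  if (!is.null(window)) s <- s[s$t >= window[1] & s$t < window[2], ]
  if (nrow(s) == 0) return(glance_set(target, interval_matrix(numeric(), numeric())))
  on <- !is.na(s$focus) & s$focus == target
  if (!any(on)) return(glance_set(target, interval_matrix(numeric(), numeric())))
  dt_med <- if (nrow(s) >= 2) median(diff(s$t)) else 0
  r <- rle(on)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  ti <- s$t
  run_start <- ti[starts_idx[r$values]]
  last_idx <- ends_idx[r$values]
  run_end <- ifelse(last_idx < nrow(s), ti[pmin(last_idx + 1L, nrow(s))],
                    ti[last_idx] + dt_med)
  iv <- merge_glance_intervals(interval_matrix(run_start, run_end), max_gap)
  glance_set(target, iv)
}

#' Merge glance intervals across short gaps
#'
#' Merges sorted disjoint `[start, end)` intervals whenever the gap between
#' consecutive intervals is strictly smaller than `max_gap`. Idempotent.
#'
#' @param intervals two-column matrix of sorted disjoint intervals.
#' @param max_gap merge threshold in seconds.
#' @return merged interval matrix.
#' @export
merge_glance_intervals <- function(intervals, max_gap = 0.2) {
  if (is.null(intervals) || nrow(intervals) <= 1) return(intervals)
  out <- intervals[1, , drop = FALSE]
  for (i in 2:nrow(intervals)) {
    gap <- intervals[i, 1] - out[nrow(out), 2]
    if (gap < max_gap) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], intervals[i, 2])
    } else {
      out <- rbind(out, intervals[i, , drop = FALSE])
    }
  }
  out
}

glance_set <- function(target, intervals) {
  structure(list(target = target, intervals = intervals,
                 count = nrow(intervals),
                 total_duration = interval_total(intervals)),
            class = "glance_set")
}

#' @export
print.glance_set <- function(x, ...) {
  cat(sprintf("<glance_set> target '%s': %d glance(s), %.3f s total\n",
              x$target, x$count, x$total_duration))
  invisible(x)
}

#' Resample a hand track to a regular grid by cubic splines
#'
#' Each coordinate is independently interpolated with a cubic spline
#' (through all irregular samples) and evaluated on the regular grid
#' spanning the track's time range.
#'
#' @param track a [motion_track()] (or data frame with `t,x,y,z`).
#' @param rate output rate in Hz (default 10).
#' @return A `regular_track`: list with `t`, `x`, `y`, `z`.
#' @export
resample_hand_track <- function(track, rate = 10) {
  s <- if (inherits(track, "motion_track")) track$samples else track
  if (nrow(s) < 4) stop("need at least 4 samples for cubic spline resampling")
  grid <- seq(s$t[1], s$t[nrow(s)], by = 1 / rate)
  out <- list(t = grid)
  for (cc in c("x", "y", "z"))
    out[[cc]] <- spline(s$t, s[[cc]], xout = grid, method = "fmm")$y
  structure(out, class = "regular_track")
}

#' Count acceleration sign changes of a resampled 3D track
#'
#' Takes the second finite difference of each coordinate on the regular
#' grid and counts strict sign changes (zeros are ignored), summed over the
#' three axes. Invariant to rigid translation and to time reversal of the
#' trajectory.
#'
#' @param regular_positions a `regular_track` from [resample_hand_track()].
#' @param tol second differences below this magnitude (meters) count as
#'   zero; guards against floating-point residue on exactly straight paths.
#' @return integer count.
#' @export
count_acceleration_sign_changes <- function(regular_positions, tol = 1e-9) {
  rp <- regular_positions
  if (length(rp$t) < 4) stop("need at least 4 grid samples")
  total <- 0L
  for (cc in c("x", "y", "z")) {
    a <- diff(rp[[cc]], differences = 2)
    s <- sign(a)
    s[abs(a) < tol] <- 0
    s <- s[s != 0]
    if (length(s) >= 2) total <- total + sum(s[-1] != s[-length(s)])
  }
  total
}

#' Truncate a value at a cap
#'
#' `min(value, cap)`, elementwise; monotone and idempotent. Used for the
#' 20 s cap on approach-time differences and the cap of 100 on hand
#' acceleration changes.
#'
#' @param value numeric vector.
#' @param cap positive cap.
#' @return capped values.
#' @examples
#' truncate_value(212, 20)  # 20
#' truncate_value(5, 20)    # 5
#' @export
truncate_value <- function(value, cap) {
  stopifnot(is_scalar_number(cap), cap > 0)
  pmin(value, cap)
}

#' Mean RR interval over a union of time windows
#'
#' The RR series is rendered as a step function (each beat's RR value holds
#' until the next beat; the last value holds afterwards) sampled at `rate`
#' (default 250 Hz, the storage rate of the RR time series), and the
#' arithmetic mean of the samples falling inside the union of `[start, end)`
#' windows is returned. Samples before the first beat are undefined; if no
#' defined sample falls inside the windows the result is `NA`.
#'
#' @param rr an [rr_series()].
#' @param windows two-column matrix (or length-2 vector) of window
#'   `(start, end)` pairs in seconds.
#' @param rate rendering rate in Hz (default 250).
#' @return mean RR in seconds, or `NA` if no sample falls inside.
#' @export
mean_rr_in_windows <- function(rr, windows, rate = 250) {
  stopifnot(inherits(rr, "rr_series"))
  if (is.null(dim(windows))) windows <- matrix(windows, ncol = 2, byrow = TRUE)
  if (nrow(windows) == 0) stop("empty window set")
  if (any(windows[, 2] <= windows[, 1])) stop("degenerate window (end <= start)")
  s <- rr$samples
  if (nrow(s) == 0) return(NA_real_)
  vals <- unlist(lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    m <- floor((w[2] - w[1]) * rate - 1e-9) + 1L
    tt <- w[1] + (seq_len(m) - 1L) / rate
    tt <- tt[tt < w[2]]
    idx <- findInterval(tt, s$t)
    v <- rep(NA_real_, length(tt))
    v[idx >= 1] <- s$rr[idx[idx >= 1]]
    v
  }))
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}
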