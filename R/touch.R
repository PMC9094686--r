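#' Trial table of the approach task
#'
#' @param session a `vr_session`.
#' @return data frame with one row per trial: `trial`, `stimulus`,
#'   `occurrence` (1st or 2nd presentation of that animal), `countdown_end`,
#'   `touch`.
#' @export
touch_trials <- function(session) {
  ev <- session$events
  ev <- ev[ev$task == "touch_enemy", ]
  trials <- sort(unique(ev$trial[ev$trial > 0]))
  rows <- lapply(trials, function(tr) {
    sub <- ev[ev$trial == tr, ]
    cd <- sub$t[sub$kind == "countdown_end"]
    to <- sub$t[sub$kind == "stimulus_touch"]
    st <- sub$stimulus[sub$kind == "stimulus_touch"]
    data.frame(trial = tr,
               stimulus = if (length(st)) st[1] else NA_character_,
               countdown_end = if (length(cd)) cd[1] else NA_real_,
               touch = if (length(to)) to[1] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$occurrence <- stats::ave(seq_len(nrow(out)), out$stimulus,
                               FUN = seq_along)
  out
}

#' Time to touch for one approach trial
#'
#' Time from the end of the 10 s countdown to the touch of the animal.
#'
#' @param session a `vr_session`.
#' @param trial trial index (1..4).
#' @return nonnegative time in seconds.
#' @export
touch_time <- function(session, trial) {
  cd <- event_time(session, "touch_enemy", "countdown_end", trial)
  to <- event_time(session, "touch_enemy", "stimulus_touch", trial)
  if (to < cd) stop(sprintf("trial %d: touch precedes countdown end", trial))
  to - cd
}

#' Approach-task readout: first-spider minus first-turtle time to touch
#'
#' The difference of the time to touch between the first spider trial and
#' the first turtle trial, truncated at `cap` (20 s) on the upper side
#' only. Positive values mean the spider took longer to touch.
#'
#' @inheritParams touch_time
#' @param cap upper truncation in seconds (default 20).
#' @return readout in seconds.
#' @export
touch_readout <- function(session, cap = 20) {
  tt <- touch_trials(session)
  first_of <- function(st) {
    tr <- tt$trial[tt$stimulus == st & tt$occurrence == 1]
    if (length(tr) == 0) stop(sprintf("no %s trial in approach task", st))
    tr[1]
  }
  truncate_value(touch_time(session, first_of("spider")) -
                   touch_time(session, first_of("turtle")), cap)
}

#' Time spent in each third of the approach path
#'
#' The start-to-table axis is split into three equal-length bands by
#' projecting the pelvis position onto that axis; the time between
#' countdown end and touch spent in each band is returned. Projections are
#' clipped to `[0, 1]`, so the durations always sum to the trial's time to
#' touch.
#'
#' @inheritParams touch_time
#' @return numeric vector `c(first, middle, last)` in seconds.
#' @export
thirds_durations <- function(session, trial) {
  cd <- event_time(session, "touch_enemy", "countdown_end", trial)
  to <- event_time(session, "touch_enemy", "stimulus_touch", trial)
  s <- get_track(session, "pelvis")$samples
  s <- s[s$t >= cd & s$t <= to, ]
  if (nrow(s) < 2) stop("pelvis track does not cover the approach window")
  a <- session$layout$start_position[c(1, 3)]
  b <- session$layout$table_position[c(1, 3)]
  u <- b - a
  L2 <- sum(u^2)
  p <- clamp(((s$x - a[1]) * u[1] + (s$z - a[2]) * u[2]) / L2, 0, 1)
  band <- findInterval(p, c(1 / 3, 2 / 3)) + 1L  # 1, 2, 3
  # each sample covers up to the next; the last sample covers up to touch
  dts <- c(diff(s$t), to - s$t[nrow(s)])
  out <- c(0, 0, 0)
  for (bd in 1:3) out[bd] <- sum(dts[band == bd])
  # time between countdown end and the first sample counts to its band
  out[band[1]] <- out[band[1]] + (s$t[1] - cd)
  out
}

#' Hand acceleration sign changes in one approach trial
#'
#' The right-hand track between countdown end and touch is resampled to a
#' regular 10 Hz grid with cubic splines, the sign changes of the second
#' finite difference are counted over the three axes, and the count is
#' truncated at `cap` (default 100).
#'
#' @inheritParams touch_time
#' @param rate resampling rate in Hz.
#' @param cap truncation cap.
#' @return integer count (capped).
#' @export
trial_accel_changes <- function(session, trial, rate = 10, cap = 100) {
  cd <- event_time(session, "touch_enemy", "countdown_end", trial)
  to <- event_time(session, "touch_enemy", "stimulus_touch", trial)
  s <- get_track(session, "right_hand")$samples
  s <- s[s$t >= cd & s$t <= to, ]
  if (nrow(s) < 4) stop("right-hand track does not cover the approach window")
  truncate_value(count_acceleration_sign_changes(resample_hand_track(s, rate)),
                 cap)
}

#' Pre-touch pupil and RR means for one approach trial
#'
#' Mean preprocessed pupil size of the chosen eye in the 0.5 s before the
#' stimulus is touched and mean RR interval in the last second before the
#' touch. If the eye was closed (no valid raw pupil sample) throughout the
#' pupil window, the pupil mean is `NA` and `closed_eyes` is flagged -- the
#' participant-level exclusion used in the group analysis. A missing RR
#' result is likewise flagged.
#'
#' @inheritParams touch_time
#' @param pupil_window pupil window length in seconds (default 0.5).
#' @param rr_window RR window length in seconds (default 1).
#' @param eye eye used for the pupil series (default right).
#' @param pupil_series optionally, a precomputed preprocessed pupil series
#'   covering the approach task (to avoid recomputation across trials).
#' @return list with `pupil`, `rr`, `closed_eyes`, `rr_missing`.
#' @export
pre_touch_windows <- function(session, trial, pupil_window = 0.5,
                              rr_window = 1, eye = "right",
                              pupil_series = NULL) {
  to <- event_time(session, "touch_enemy", "stimulus_touch", trial)
  pupil <- NA_real_
  closed <- FALSE
  if (!is.null(session$gaze)) {
    g <- session$gaze$samples
    raw_in <- g$t >= to - pupil_window & g$t < to
    valid <- if (eye == "right") g$valid_right else g$valid_left
    closed <- !any(raw_in & valid)
    if (!closed) {
      if (is.null(pupil_series))
        pupil_series <- touch_pupil_series(session, eye = eye)
      tt <- series_times(pupil_series)
      inside <- tt >= to - pupil_window & tt < to
      if (any(inside)) pupil <- mean(pupil_series$values[inside])
    }
  }
  rr <- NA_real_
  if (!is.null(session$rr))
    rr <- mean_rr_in_windows(session$rr, c(to - rr_window, to))
  list(pupil = pupil, rr = rr, closed_eyes = closed,
       rr_missing = is.na(rr))
}

#' Preprocessed pupil series over the approach-task segment
#'
#' @inheritParams pre_touch_windows
#' @return a `regular_series` in `[0, 1]` (see [preprocess_pupil()]).
#' @export
touch_pupil_series <- function(session, eye = "right") {
  if (is.null(session$gaze)) stop("gaze stream absent")
  ev <- session$events
  ev <- ev[ev$task == "touch_enemy", ]
  if (nrow(ev) == 0) stop("no approach-task events")
  w <- range(ev$t)
  g <- session$gaze$samples
  keep <- g$t >= w[1] & g$t <= w[2] + 1
  gseg <- gaze_stream(g$t[keep], g$focus[keep], g$pupil_left[keep],
                      g$pupil_right[keep], g$valid_left[keep],
                      g$valid_right[keep], session$gaze$nominal_rate)
  preprocess_pupil(gseg, eye = eye)
}
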