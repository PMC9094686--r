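#' Analysis window of the search task
#'
#' The task starts with a 10 s wait; the analysis window is the 120 s of
#' active search that follow, i.e. `[countdown_end, countdown_end + 120)`.
#'
#' @param session a `vr_session`.
#' @param duration window length in seconds (default 120).
#' @return `c(start, end)` in session seconds.
#' @export
fishing_window <- function(session, duration = 120) {
  t0 <- event_time(session, "fishing", "countdown_end")
  c(t0, t0 + duration)
}

pelvis_in_window <- function(session, window) {
  s <- get_track(session, "pelvis")$samples
  if (s$t[1] > window[1] + 1e-6 || s$t[nrow(s)] < window[2] - 1e-6)
    stop("pelvis track does not cover the analysis window")
  s[s$t >= window[1] & s$t < window[2], ]
}

#' Minimum horizontal distance to a stimulus in the search task
#'
#' Minimum over the 120 s analysis window of the horizontal (x, z) distance
#' between the pelvis and the stimulus position on its plank.
#'
#' @param session a `vr_session`.
#' @param stimulus `"spider"` or `"turtle"`.
#' @param duration analysis-window length in seconds.
#' @return distance in meters.
#' @export
fishing_min_distance <- function(session, stimulus, duration = 120) {
  w <- fishing_window(session, duration)
  s <- pelvis_in_window(session, w)
  p <- stimulus_position(session$layout, "fishing", 1, stimulus)
  min(sqrt((s$x - p[1])^2 + (s$z - p[3])^2))
}

#' Search-task readout: spider minus turtle minimum distance
#'
#' Positive values mean the participant stayed farther from the spider than
#' from the turtle.
#'
#' @inheritParams fishing_min_distance
#' @return difference in meters.
#' @export
fishing_readout <- function(session, duration = 120) {
  fishing_min_distance(session, "spider", duration) -
    fishing_min_distance(session, "turtle", duration)
}

#' Glance counts and their spider-minus-turtle difference
#'
#' Glances are segmented with [segment_glances()] (200 ms gap merging)
#' within the 120 s search window.
#'
#' @inheritParams fishing_min_distance
#' @param max_gap merge threshold in seconds.
#' @return list with `spider`, `turtle` (the two `glance_set`s) and `diff`
#'   (spider count minus turtle count).
#' @export
fishing_glances <- function(session, max_gap = 0.2, duration = 120) {
  if (is.null(session$gaze)) stop("gaze stream absent")
  w <- fishing_window(session, duration)
  sp <- segment_glances(session$gaze, "spider", max_gap = max_gap, window = w)
  tu <- segment_glances(session$gaze, "turtle", max_gap = max_gap, window = w)
  list(spider = sp, turtle = tu, diff = sp$count - tu$count)
}

#' @rdname fishing_glances
#' @return `fishing_glance_difference()`: integer count difference.
#' @export
fishing_glance_difference <- function(session, max_gap = 0.2, duration = 120) {
  fishing_glances(session, max_gap, duration)$diff
}

#' Side occupancy of the pelvis during the search window
#'
#' Splits the analysis window into maximal intervals during which the
#' pelvis is on the left (`x < 0`) or right (`x >= 0`) half of the field.
#' The intervals partition the window: boundaries are placed halfway
#' between samples of different sides.
#'
#' @inheritParams fishing_min_distance
#' @return list with interval matrices `left` and `right`.
#' @export
side_occupancy <- function(session, duration = 120) {
  w <- fishing_window(session, duration)
  s <- pelvis_in_window(session, w)
  side <- ifelse(s$x < 0, "left", "right")
  r <- rle(side)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  k <- length(r$values)
  # boundary between runs = midpoint between the adjacent samples
  bounds <- c(w[1],
              if (k > 1) (s$t[ends_idx[-k]] + s$t[starts_idx[-1]]) / 2,
              w[2])
  out <- list(left = NULL, right = NULL)
  for (side_name in c("left", "right")) {
    sel <- r$values == side_name
    out[[side_name]] <- interval_matrix(bounds[-(k + 1)][sel], bounds[-1][sel])
  }
  out
}

side_of_stimulus <- function(layout, task, trial, stimulus) {
  if (stimulus_position(layout, task, trial, stimulus)[1] < 0) "left" else "right"
}

#' Mean pelvis-to-stimulus orientation angle per stimulus side
#'
#' Per-sample angle between the pelvis forward vector (from yaw; 0 deg =
#' facing +z, counter-clockwise positive viewed from above) and the
#' horizontal vector from the pelvis to the stimulus, averaged over the
#' samples spent on that stimulus' half of the field. An angle of 0 means
#' the hips face the stimulus frontally, 180 means the back is turned to
#' it. If the participant never entered that half, the result is `NA` with
#' attribute `excluded = TRUE` (the never-entered-the-spider-side exclusion
#' used for group analyses).
#'
#' @inheritParams fishing_min_distance
#' @return mean angle in degrees in `[0, 180]`, or `NA` (excluded).
#' @export
fishing_orientation <- function(session, stimulus, duration = 120) {
  w <- fishing_window(session, duration)
  s <- pelvis_in_window(session, w)
  if (!"yaw" %in% names(s)) stop("pelvis yaw absent")
  p <- stimulus_position(session$layout, "fishing", 1, stimulus)
  on_side <- if (p[1] < 0) s$x < 0 else s$x >= 0
  if (!any(on_side)) {
    out <- NA_real_
    attr(out, "excluded") <- TRUE
    return(out)
  }
  s <- s[on_side, ]
  th <- s$yaw * pi / 180
  fwd <- cbind(-sin(th), cos(th))
  to <- cbind(p[1] - s$x, p[3] - s$z)
  nrm <- sqrt(rowSums(to^2))
  nrm[nrm < 1e-9] <- 1e-9
  cosang <- clamp(rowSums(fwd * to) / nrm, -1, 1)
  mean(acos(cosang) * 180 / pi)
}

#' Per-side physiology during the search task
#'
#' Mean RR interval and mean preprocessed pupil size per stimulus side,
#' each defined as the mean over the time spent on the pelvic half of the
#' field holding the corresponding stimulus. RR means use the 250 Hz
#' step-function rendering ([mean_rr_in_windows()]); pupil means average
#' the preprocessed unit-interval series ([preprocess_pupil()], computed
#' over the search-task segment) across the same occupancy intervals.
#' A side never occupied yields `NA` for that side.
#'
#' @inheritParams fishing_min_distance
#' @param eye eye used for the pupil series.
#' @return list with named vectors `rr` and `pupil` (elements `spider`,
#'   `turtle`, seconds and unit interval respectively).
#' @export
fishing_side_physiology <- function(session, eye = "right", duration = 120) {
  occ <- side_occupancy(session, duration)
  spider_side <- side_of_stimulus(session$layout, "fishing", 1, "spider")
  sides <- c(spider = spider_side,
             turtle = if (spider_side == "left") "right" else "left")
  rr_out <- pupil_out <- c(spider = NA_real_, turtle = NA_real_)
  pupil_series <- NULL
  if (!is.null(session$gaze)) {
    w <- fishing_window(session, duration)
    g <- session$gaze
    keep <- g$samples$t >= w[1] - 10 & g$samples$t < w[2]
    gseg <- gaze_stream(g$samples$t[keep], g$samples$focus[keep],
                        g$samples$pupil_left[keep], g$samples$pupil_right[keep],
                        g$samples$valid_left[keep], g$samples$valid_right[keep],
                        g$nominal_rate)
    pupil_series <- try(preprocess_pupil(gseg, eye = eye), silent = TRUE)
    if (inherits(pupil_series, "try-error")) pupil_series <- NULL
  }
  for (st in names(sides)) {
    iv <- occ[[sides[[st]]]]
    if (is.null(iv) || nrow(iv) == 0) next
    if (!is.null(session$rr))
      rr_out[[st]] <- mean_rr_in_windows(session$rr, iv)
    if (!is.null(pupil_series)) {
      tt <- series_times(pupil_series)
      inside <- in_intervals(tt, iv)
      if (any(inside)) pupil_out[[st]] <- mean(pupil_series$values[inside])
    }
  }
  list(rr = rr_out, pupil = pupil_out)
}
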