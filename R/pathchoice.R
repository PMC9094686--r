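#' Per-segment weight of the forced-choice cost-of-avoidance table
#'
#' The book's lateral position makes one of the two paths around the
#' central table shorter. Taking a path is weighted exponentially by its
#' cost: 0 for the shorter path (the book's near side), 1 for either path
#' when the book is centered, 2 for the shorter detour (far side of a
#' slightly offset book), and 4 for the longer detour (far side of a far
#' offset book).
#'
#' @param chosen_side `"left"` or `"right"`.
#' @param book_offset one of `center`, `right`, `left`, `far_right`,
#'   `far_left`.
#' @return integer weight in `{0, 1, 2, 4}`.
#' @export
segment_weight <- function(chosen_side, book_offset) {
  chosen_side <- match.arg(chosen_side, c("left", "right"))
  book_offset <- match.arg(book_offset, c("center", "right", "left",
                                          "far_right", "far_left"))
  if (book_offset == "center") return(1L)
  near <- if (book_offset %in% c("right", "far_right")) "right" else "left"
  if (chosen_side == near) return(0L)
  if (book_offset %in% c("right", "left")) 2L else 4L
}

#' Build the ten scored path segments from chosen sides
#'
#' Five trials with separately evaluated outward and return journeys give
#' ten segments. Each segment carries the cost weight of the chosen side
#' ([segment_weight()]) and a signed contribution: positive when the chosen
#' side is the turtle's (the spider was avoided), negative when it is the
#' spider's.
#'
#' @param chosen_sides character vector of 10 sides in trial order
#'   (trial 1 outward, trial 1 return, trial 2 outward, ...).
#' @param layout a [scene_layout()] providing book offsets and the
#'   animal-swap schedule.
#' @return data frame with one row per segment: `trial`, `leg`,
#'   `chosen_side`, `spider_side`, `book_offset`, `weight`,
#'   `signed_contribution`.
#' @export
path_segment_choices <- function(chosen_sides, layout) {
  if (length(chosen_sides) != 10)
    stop("exactly 10 chosen sides required (5 trials x outward/return)")
  trial <- rep(1:5, each = 2)
  leg <- rep(c("outward", "return"), 5)
  spider_side <- layout$animal_swap_schedule[trial]
  book_offset <- layout$book_offsets[trial]
  weight <- mapply(segment_weight, chosen_sides, book_offset)
  signed <- ifelse(chosen_sides == spider_side, -weight, weight)
  data.frame(trial = trial, leg = leg,
             chosen_side = as.character(chosen_sides),
             spider_side = spider_side, book_offset = book_offset,
             weight = as.integer(weight),
             signed_contribution = as.integer(signed),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cost-weighted avoidance score over ten path segments
#'
#' Sum of the signed contributions of the ten forced-choice segments;
#' guaranteed in `[-14, 14]`. +14 means the spider was avoided on every
#' leg, -14 that the spider side was taken on every leg. The default sign
#' convention anchors positive scores to avoidance; `"avoid_negative"`
#' flips it.
#'
#' @param choices data frame from [path_segment_choices()] (or
#'   [session_path_choices()]).
#' @param sign_convention `"avoid_positive"` (default) or
#'   `"avoid_negative"`.
#' @return integer score in `[-14, 14]`.
#' @export
avoidance_score <- function(choices,
                            sign_convention = c("avoid_positive",
                                                "avoid_negative")) {
  sign_convention <- match.arg(sign_convention)
  if (nrow(choices) != 10) stop("avoidance score needs exactly 10 segments")
  if (!all(sort(unique(choices$trial)) == 1:5) ||
      !all(table(choices$trial) == 2))
    stop("segments must cover trials 1..5 with outward and return legs")
  s <- sum(choices$signed_contribution)
  if (sign_convention == "avoid_negative") s <- -s
  if (abs(s) > 14) stop("internal error: score outside [-14, 14]")
  as.integer(s)
}

#' Classify the side taken in one forced-choice leg
#'
#' The side is read off at the first crossing of the gate line (the central
#' table's z midline) within the leg's time window: left if the pelvis x
#' coordinate at the crossing is negative, right otherwise. Re-crossings
#' later in the leg do not reclassify.
#'
#' @param track pelvis [motion_track()].
#' @param window `c(start, end)` of the leg in seconds.
#' @param layout a [scene_layout()] (supplies `choice_gate_z`).
#' @return `"left"` or `"right"`.
#' @export
classify_path_side <- function(track, window, layout) {
  s <- track$samples
  s <- s[s$t >= window[1] & s$t <= window[2], ]
  if (nrow(s) < 2) stop("gate never crossed: track does not cover the leg")
  gate <- layout$choice_gate_z
  dz <- s$z - gate
  cross <- which(dz[-length(dz)] * dz[-1] <= 0 &
                   (dz[-length(dz)] != 0 | dz[-1] != 0))
  if (length(cross) == 0) stop("gate never crossed in this leg")
  i <- cross[1]
  # interpolate x at the crossing
  frac <- if (dz[i + 1] == dz[i]) 0 else -dz[i] / (dz[i + 1] - dz[i])
  x_at <- s$x[i] + frac * (s$x[i + 1] - s$x[i])
  if (x_at < 0) "left" else "right"
}

#' Extract the ten scored path segments from a session
#'
#' For each forced-choice trial the window between `trial_start` and
#' `trial_end` is split at the time of maximum pelvis z (the far end of the
#' room, where the book is exchanged) into the outward and return legs;
#' each leg is classified with [classify_path_side()].
#'
#' @param session a `vr_session`.
#' @return data frame as from [path_segment_choices()].
#' @export
session_path_choices <- function(session) {
  track <- get_track(session, "pelvis")
  sides <- character(0)
  for (tr in 1:5) {
    t0 <- event_time(session, "path_choice", "trial_start", tr)
    t1 <- event_time(session, "path_choice", "trial_end", tr)
    s <- track$samples
    s <- s[s$t >= t0 & s$t <= t1, ]
    if (nrow(s) < 3) stop(sprintf("pelvis track does not cover trial %d", tr))
    t_split <- s$t[which.max(s$z)]
    sub <- structure(list(sensor_id = "pelvis", samples = s),
                     class = "motion_track")
    sides <- c(sides,
               classify_path_side(sub, c(t0, t_split), session$layout),
               classify_path_side(sub, c(t_split, t1), session$layout))
  }
  path_segment_choices(sides, session$layout)
}

#' Forced-choice readout of a session
#'
#' @inheritParams session_path_choices
#' @inheritParams avoidance_score
#' @return integer avoidance score in `[-14, 14]`.
#' @export
path_choice_readout <- function(session,
                                sign_convention = "avoid_positive") {
  avoidance_score(session_path_choices(session), sign_convention)
}
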