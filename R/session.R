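#' Scene layout of the virtual field
#'
#' Geometry shared by the three behavioral tasks. The coordinate frame is in
#' meters: `x` spans the field width (`x` in `[-width/2, width/2]`), `z` the
#' depth (`z` in `[0, depth]`), `y` is up, and the origin sits at the
#' midpoint of the starting long side. Side membership ("left"/"right") is
#' therefore a sign test on `x`.
#'
#' @param field_width,field_depth field footprint in meters.
#' @param spider_side_fishing side ("left"/"right") of the spider plank in
#'   the search task; the turtle takes the opposite plank.
#' @param spider_side_path_first spider side in the first forced-choice
#'   trial. Animal sides swap after trials 1 and 3, so the per-trial spider
#'   sides are `first, other, other, first, first`.
#' @param first_touch_stimulus animal presented in the first approach trial;
#'   the four trials alternate.
#' @param start_position 3D start point (meters).
#' @param table_position 3D point of the approach-task table top (the table
#'   stands at a height of 1.1 m).
#' @param choice_gate_z z coordinate (m) of the midline of the central table
#'   in the forced-choice task; the chosen side of a path segment is read off
#'   at the crossing of this gate line.
#' @param book_offsets lateral book positions for forced-choice trials 1..5.
#'   The canonical schedule is `center, right, left, far_right, far_left`.
#' @return An object of class `scene_layout`.
#' @export
scene_layout <- function(field_width = 4.6, field_depth = 4.3,
                         spider_side_fishing = c("left", "right"),
                         spider_side_path_first = c("left", "right"),
                         first_touch_stimulus = c("spider", "turtle"),
                         start_position = c(0, 0, 0),
                         table_position = c(0, 1.1, 3.8),
                         choice_gate_z = 2.15,
                         book_offsets = c("center", "right", "left",
                                          "far_right", "far_left")) {
  spider_side_fishing <- match.arg(spider_side_fishing)
  spider_side_path_first <- match.arg(spider_side_path_first)
  first_touch_stimulus <- match.arg(first_touch_stimulus)
  hw <- field_width / 2
  side_x <- function(side) if (side == "left") -1 else 1

  # search task: animals centered on the left/right planks
  fx <- side_x(spider_side_fishing)
  fishing <- list(`1` = list(
    spider = c(fx * hw, 0.85, field_depth / 2),
    turtle = c(-fx * hw, 0.85, field_depth / 2)
  ))

  # forced choice: sides swap after trials 1 and 3
  first <- spider_side_path_first
  other <- if (first == "left") "right" else "left"
  swap_schedule <- c(first, other, other, first, first)
  path_choice <- lapply(seq_len(5), function(tr) {
    sx <- side_x(swap_schedule[tr])
    list(spider = c(sx * 1.6, 0.9, choice_gate_z),
         turtle = c(-sx * 1.6, 0.9, choice_gate_z))
  })
  names(path_choice) <- as.character(1:5)

  # approach task: one animal per trial on the table top
  touch_order <- if (first_touch_stimulus == "spider")
    c("spider", "turtle", "spider", "turtle") else
    c("turtle", "spider", "turtle", "spider")
  touch <- lapply(seq_len(4), function(tr) {
    p <- list()
    p[[touch_order[tr]]] <- c(table_position[1], table_position[2] + 0.1,
                              table_position[3])
    p
  })
  names(touch) <- as.character(1:4)

  out <- structure(list(
    field_width = field_width, field_depth = field_depth,
    stimulus_positions = list(fishing = fishing, path_choice = path_choice,
                              touch_enemy = touch),
    start_position = as.numeric(start_position),
    table_position = as.numeric(table_position),
    table_height = 1.1,
    choice_gate_z = choice_gate_z,
    book_offsets = as.character(book_offsets),
    animal_swap_schedule = swap_schedule,
    touch_order = touch_order
  ), class = "scene_layout")
  validate_scene_layout(out)
  out
}

#' Validate a scene layout
#'
#' Checks the geometric invariants: strictly positive field dimensions, all
#' stimulus/start/table points inside the footprint, the canonical book
#' schedule, and the animal-swap pattern (swap after trials 1 and 3, both
#' animals on opposite sides within a block).
#'
#' @param layout a `scene_layout`.
#' @return `layout`, invisibly; errors on violation.
#' @export
validate_scene_layout <- function(layout) {
  stopifnot(inherits(layout, "scene_layout"))
  if (!is_scalar_number(layout$field_width) || layout$field_width <= 0 ||
      !is_scalar_number(layout$field_depth) || layout$field_depth <= 0)
    stop("field dimensions must be strictly positive")
  hw <- layout$field_width / 2
  inside <- function(p) {
    length(p) == 3 && all(is.finite(p)) &&
      p[1] >= -hw && p[1] <= hw && p[3] >= 0 && p[3] <= layout$field_depth
  }
  if (!inside(layout$start_position)) stop("start_position outside field")
  if (!inside(layout$table_position)) stop("table_position outside field")
  for (task in names(layout$stimulus_positions))
    for (tr in names(layout$stimulus_positions[[task]]))
      for (an in names(layout$stimulus_positions[[task]][[tr]]))
        if (!inside(layout$stimulus_positions[[task]][[tr]][[an]]))
          stop(sprintf("stimulus position outside field (%s trial %s %s)",
                       task, tr, an))
  canonical <- c("center", "right", "left", "far_right", "far_left")
  if (!identical(layout$book_offsets, canonical))
    stop("book_offsets for trials 1..5 must be exactly ",
         paste(canonical, collapse = ", "))
  s <- layout$animal_swap_schedule
  if (length(s) != 5 || s[1] == s[2] || s[2] != s[3] || s[3] == s[4] ||
      s[4] != s[5])
    stop("animal sides must swap after trial 1 and after trial 3")
  for (tr in 1:5) {
    pos <- layout$stimulus_positions$path_choice[[tr]]
    if (sign(pos$spider[1]) == sign(pos$turtle[1]))
      stop("both animals must sit on opposite sides within a block")
  }
  invisible(layout)
}

#' Irregular 3D motion track of one body sensor
#'
#' @param t timestamps in seconds (strictly increasing, session timebase).
#' @param x,y,z positions in meters.
#' @param yaw optional heading in degrees; 0 faces +z, increasing
#'   counter-clockwise viewed from above.
#' @param sensor_id one of `"head"`, `"pelvis"`, `"right_hand"`.
#' @return An object of class `motion_track`.
#' @export
motion_track <- function(t, x, y, z, yaw = NULL,
                         sensor_id = c("pelvis", "head", "right_hand")) {
  sensor_id <- match.arg(sensor_id)
  n <- length(t)
  if (n < 2) stop("motion track needs at least 2 samples")
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("motion track positions must be finite")
  assert_increasing(t, sprintf("motion track '%s'", sensor_id))
  samples <- data.frame(t = as.numeric(t), x = as.numeric(x),
                        y = as.numeric(y), z = as.numeric(z))
  if (!is.null(yaw)) {
    stopifnot(length(yaw) == n)
    samples$yaw <- as.numeric(yaw)
  }
  structure(list(sensor_id = sensor_id, samples = samples),
            class = "motion_track")
}

#' Gaze and pupil stream
#'
#' Eye-tracker samples at a nominal rate of about 110 Hz. Samples flagged
#' invalid carry missing pupil values (enforced on construction).
#'
#' @param t timestamps in seconds, strictly increasing.
#' @param focus focused-object label per sample (`NA` or `""` = none).
#' @param pupil_left,pupil_right pupil diameters (arbitrary units).
#' @param valid_left,valid_right logical validity flags.
#' @param nominal_rate nominal sampling rate in Hz.
#' @return An object of class `gaze_stream`.
#' @export
gaze_stream <- function(t, focus, pupil_left, pupil_right,
                        valid_left = !is.na(pupil_left),
                        valid_right = !is.na(pupil_right),
                        nominal_rate = 110) {
  n <- length(t)
  stopifnot(length(focus) == n, length(pupil_left) == n,
            length(pupil_right) == n)
  assert_increasing(t, "gaze stream")
  pupil_left[!valid_left] <- NA_real_
  pupil_right[!valid_right] <- NA_real_
  structure(list(
    samples = data.frame(t = as.numeric(t), focus = as.character(focus),
                         pupil_left = as.numeric(pupil_left),
                         pupil_right = as.numeric(pupil_right),
                         valid_left = as.logical(valid_left),
                         valid_right = as.logical(valid_right),
                         stringsAsFactors = FALSE),
    nominal_rate = nominal_rate
  ), class = "gaze_stream")
}

#' RR-interval series
#'
#' Inter-beat intervals (seconds) at the time of each beat. Intervals
#' outside the physiological range (0.25, 3.0) s are dropped during
#' validation; the number removed is kept in the `n_dropped` attribute.
#'
#' @param t beat timestamps in seconds, strictly increasing.
#' @param rr RR interval in seconds at each beat.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(t, rr) {
  stopifnot(length(t) == length(rr))
  keep <- is.finite(rr) & rr > 0.25 & rr < 3.0
  n_dropped <- sum(!keep)
  t <- as.numeric(t)[keep]
  rr <- as.numeric(rr)[keep]
  assert_increasing(t, "rr series")
  structure(list(samples = data.frame(t = t, rr = rr)),
            n_dropped = n_dropped, class = "rr_series")
}

.event_kinds <- c("task_start", "trial_start", "countdown_end",
                  "stimulus_touch", "trial_end", "task_end", "side_entry")
.tasks <- c("fishing", "path_choice", "touch_enemy")

#' Task-event log
#'
#' @param t event times in seconds (non-decreasing).
#' @param kind event kind; one of `task_start`, `trial_start`,
#'   `countdown_end`, `stimulus_touch`, `trial_end`, `task_end`,
#'   `side_entry`.
#' @param task task label (`fishing`, `path_choice`, `touch_enemy`).
#' @param trial 1-based trial index.
#' @param stimulus stimulus label (`spider`, `turtle`, `none`).
#' @return An object of class `task_events` (a data frame).
#' @export
task_events <- function(t, kind, task, trial, stimulus = "none") {
  n <- length(t)
  df <- data.frame(t = as.numeric(t), kind = as.character(kind),
                   task = as.character(task), trial = as.integer(trial),
                   stimulus = as.character(stimulus),
                   stringsAsFactors = FALSE)
  if (n && is.unsorted(df$t)) stop("task events must be ordered in time")
  if (n && !all(df$kind %in% .event_kinds))
    stop("unknown event kind: ",
         paste(setdiff(unique(df$kind), .event_kinds), collapse = ", "))
  if (n && !all(df$task %in% .tasks))
    stop("unknown task label: ",
         paste(setdiff(unique(df$task), .tasks), collapse = ", "))
  # a countdown must end before its trial's touch
  for (tr in unique(df$trial[df$task == "touch_enemy"])) {
    sub <- df[df$task == "touch_enemy" & df$trial == tr, ]
    cd <- sub$t[sub$kind == "countdown_end"]
    to <- sub$t[sub$kind == "stimulus_touch"]
    if (length(cd) && length(to) && to[1] < cd[1])
      stop(sprintf("trial %d: stimulus_touch precedes countdown_end", tr))
  }
  class(df) <- c("task_events", "data.frame")
  df
}

#' Derive the fear group from FSQ score and phobia diagnosis
#'
#' Group partition used throughout: participants with a positive clinical
#' spider-phobia diagnosis are `phobic`; of the rest, those with an FSQ
#' (Fear of Spiders Questionnaire) total greater than eight are `fearful`
#' and those at eight or below are `non_fearful`.
#'
#' @param fsq_total FSQ total score (non-negative).
#' @param cidi_phobia logical; clinical spider-phobia diagnosis.
#' @return `"phobic"`, `"fearful"`, or `"non_fearful"`.
#' @examples
#' derive_group(100, TRUE)   # "phobic"
#' derive_group(9, FALSE)    # "fearful"
#' derive_group(8, FALSE)    # "non_fearful"
#' @export
derive_group <- function(fsq_total, cidi_phobia) {
  if (!is_scalar_number(fsq_total) || fsq_total < 0)
    stop("fsq_total must be a non-negative number")
  stopifnot(is.logical(cidi_phobia), length(cidi_phobia) == 1L)
  if (isTRUE(cidi_phobia)) return("phobic")
  if (fsq_total > 8) "fearful" else "non_fearful"
}

#' One participant's VR session
#'
#' The atomic input of the pipeline: raw sensor streams, the event log, the
#' scene layout, and participant metadata.
#'
#' @param participant_id character id.
#' @param group `"phobic"`, `"fearful"`, or `"non_fearful"`.
#' @param questionnaire_scales named numeric vector of scale totals; an
#'   `fsq` entry is mandatory.
#' @param valence_ratings named numeric vector with `spider` and `turtle`
#'   valence ratings (ordinal).
#' @param tracks named list of [motion_track()]s (names = sensor ids).
#' @param gaze a [gaze_stream()] or `NULL`.
#' @param rr an [rr_series()] or `NULL`.
#' @param events a [task_events()] log.
#' @param layout a [scene_layout()].
#' @param validate run [validate_session()] on the result.
#' @return An object of class `vr_session`.
#' @export
vr_session <- function(participant_id, group, questionnaire_scales,
                       valence_ratings, tracks, gaze = NULL, rr = NULL,
                       events, layout, validate = TRUE) {
  s <- structure(list(
    participant_id = as.character(participant_id),
    group = match.arg(group, c("phobic", "fearful", "non_fearful")),
    questionnaire_scales = questionnaire_scales,
    valence_ratings = valence_ratings,
    tracks = tracks, gaze = gaze, rr = rr,
    events = events, layout = layout
  ), class = "vr_session")
  if (validate) validate_session(s)
  s
}

#' Validate a session's invariants
#'
#' Checks FSQ/group consistency (`non_fearful` requires FSQ <= 8, `fearful`
#' requires FSQ > 8), presence and validity of the three sensor tracks for a
#' complete session, stream monotonicity, and the layout invariants.
#'
#' @param session a `vr_session`.
#' @param complete require all three sensor tracks (default `TRUE`).
#' @return `session`, invisibly; errors on violation.
#' @export
validate_session <- function(session, complete = TRUE) {
  stopifnot(inherits(session, "vr_session"))
  fsq <- session$questionnaire_scales[["fsq"]]
  if (is.null(fsq) || !is.finite(fsq)) stop("questionnaire_scales must include 'fsq'")
  if (session$group == "non_fearful" && fsq > 8)
    stop("group 'non_fearful' inconsistent with FSQ > 8")
  if (session$group == "fearful" && fsq <= 8)
    stop("group 'fearful' inconsistent with FSQ <= 8")
  if (complete) {
    need <- c("head", "pelvis", "right_hand")
    if (!all(need %in% names(session$tracks)))
      stop("complete session requires tracks: ",
           paste(setdiff(need, names(session$tracks)), collapse = ", "))
  }
  for (tk in session$tracks) {
    stopifnot(inherits(tk, "motion_track"))
    assert_increasing(tk$samples$t, sprintf("track '%s'", tk$sensor_id))
  }
  if (!is.null(session$gaze)) assert_increasing(session$gaze$samples$t, "gaze")
  if (!is.null(session$rr)) assert_increasing(session$rr$samples$t, "rr")
  validate_scene_layout(session$layout)
  invisible(session)
}

#' @export
print.vr_session <- function(x, ...) {
  cat(sprintf("<vr_session> participant %s (%s), FSQ %s\n", x$participant_id,
              x$group, format(x$questionnaire_scales[["fsq"]])))
  cat(sprintf("  tracks: %s\n", paste(names(x$tracks), collapse = ", ")))
  cat(sprintf("  gaze: %s samples; rr: %s beats; events: %d\n",
              if (is.null(x$gaze)) "none" else nrow(x$gaze$samples),
              if (is.null(x$rr)) "none" else nrow(x$rr$samples),
              nrow(x$events)))
  invisible(x)
}

# ---- on-disk container -----------------------------------------------------

layout_to_list <- function(layout) unclass(layout)

layout_from_list <- function(l) {
  # jsonlite gives nested lists; coerce the numeric leaves back
  num <- function(x) as.numeric(unlist(x))
  sp <- lapply(l$stimulus_positions, function(task)
    lapply(task, function(tr) lapply(tr, num)))
  structure(list(
    field_width = num(l$field_width), field_depth = num(l$field_depth),
    stimulus_positions = sp,
    start_position = num(l$start_position),
    table_position = num(l$table_position),
    table_height = num(l$table_height),
    choice_gate_z = num(l$choice_gate_z),
    book_offsets = as.character(unlist(l$book_offsets)),
    animal_swap_schedule = as.character(unlist(l$animal_swap_schedule)),
    touch_order = as.character(unlist(l$touch_order))
  ), class = "scene_layout")
}

#' Write a session container to disk
#'
#' The container is a directory of UTF-8 CSVs plus one JSON metadata file:
#' `meta.json`, `motion.csv` (`t,sensor,x,y,z[,yaw]`), `gaze.csv`, `rr.csv`,
#' `events.csv`. Missing values are written as empty fields. The yaw column
#' is omitted when no track carries yaw.
#'
#' @param session a validated `vr_session`.
#' @param container_path directory to create/overwrite.
#' @return `container_path`, invisibly.
#' @seealso [load_session()]
#' @export
write_session <- function(session, container_path) {
  validate_session(session, complete = FALSE)
  ok <- dir.exists(container_path) || dir.create(container_path, recursive = TRUE)
  if (!ok) stop("cannot create container directory: ", container_path)

  meta <- list(participant_id = session$participant_id,
               group = session$group,
               questionnaire_scales = as.list(session$questionnaire_scales),
               valence_ratings = as.list(session$valence_ratings),
               layout = layout_to_list(session$layout))
  jsonlite::write_json(meta, file.path(container_path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  any_yaw <- any(vapply(session$tracks, function(tk)
    "yaw" %in% names(tk$samples), logical(1)))
  motion <- do.call(rbind, lapply(session$tracks, function(tk) {
    df <- tk$samples
    df$sensor <- tk$sensor_id
    if (any_yaw && !"yaw" %in% names(df)) df$yaw <- NA_real_
    cols <- c("t", "sensor", "x", "y", "z", if (any_yaw) "yaw")
    df[, cols]
  }))
  motion <- motion[order(motion$t, motion$sensor), ]
  write.csv(motion, file.path(container_path, "motion.csv"),
            row.names = FALSE, na = "")

  gz <- if (is.null(session$gaze))
    data.frame(t = numeric(), focus = character(), pupil_l = numeric(),
               pupil_r = numeric(), valid_l = logical(), valid_r = logical())
  else with(session$gaze$samples,
            data.frame(t = t, focus = focus, pupil_l = pupil_left,
                       pupil_r = pupil_right, valid_l = valid_left,
                       valid_r = valid_right))
  write.csv(gz, file.path(container_path, "gaze.csv"), row.names = FALSE, na = "")

  rrdf <- if (is.null(session$rr)) data.frame(t = numeric(), rr = numeric())
          else session$rr$samples
  write.csv(rrdf, file.path(container_path, "rr.csv"), row.names = FALSE, na = "")

  ev <- as.data.frame(session$events)
  write.csv(ev, file.path(container_path, "events.csv"), row.names = FALSE, na = "")
  invisible(container_path)
}

#' Load a session container from disk
#'
#' Inverse of [write_session()]: `load_session(write_session(s, p))`
#' reproduces `s` up to numeric round-off (below 1e-9). Validates all
#' session invariants on load.
#'
#' @param container_path directory written by [write_session()].
#' @return A validated `vr_session`.
#' @export
load_session <- function(container_path) {
  need <- c(meta = "meta.json", motion = "motion.csv", gaze = "gaze.csv",
            rr = "rr.csv", events = "events.csv")
  for (nm in names(need)) {
    f <- file.path(container_path, need[[nm]])
    if (!file.exists(f))
      stop(sprintf("%s stream absent (missing file %s)", nm, need[[nm]]))
  }
  meta <- jsonlite::read_json(file.path(container_path, "meta.json"))
  layout <- layout_from_list(meta$layout)

  motion <- read.csv(file.path(container_path, "motion.csv"),
                     stringsAsFactors = FALSE)
  tracks <- list()
  for (sid in unique(motion$sensor)) {
    sub <- motion[motion$sensor == sid, ]
    sub <- sub[order(sub$t), ]
    yaw <- if ("yaw" %in% names(sub) && any(is.finite(sub$yaw))) sub$yaw else NULL
    tracks[[sid]] <- motion_track(sub$t, sub$x, sub$y, sub$z, yaw = yaw,
                                  sensor_id = sid)
  }

  gz <- read.csv(file.path(container_path, "gaze.csv"),
                 stringsAsFactors = FALSE,
                 colClasses = c(focus = "character"))
  gaze <- if (nrow(gz) == 0) NULL else
    gaze_stream(gz$t, gz$focus, gz$pupil_l, gz$pupil_r,
                as.logical(gz$valid_l), as.logical(gz$valid_r))

  rrdf <- read.csv(file.path(container_path, "rr.csv"))
  rr <- if (nrow(rrdf) == 0) NULL else rr_series(rrdf$t, rrdf$rr)

  ev <- read.csv(file.path(container_path, "events.csv"),
                 stringsAsFactors = FALSE)
  events <- task_events(ev$t, ev$kind, ev$task, ev$trial, ev$stimulus)

  qs <- unlist(meta$questionnaire_scales)
  vr <- unlist(meta$valence_ratings)
  s <- vr_session(meta$participant_id, meta$group, qs, vr, tracks, gaze, rr,
                  events, layout, validate = FALSE)
  # mirror write_session: partial sessions (e.g. a single track) round-trip
  validate_session(s, complete = FALSE)
  s
}

# accessors used across modules
get_track <- function(session, sensor_id) {
  tk <- session$tracks[[sensor_id]]
  if (is.null(tk)) stop(sprintf("track '%s' absent from session", sensor_id))
  tk
}

#' Look up a stimulus position in the layout
#'
#' @param layout a [scene_layout()].
#' @param task task label (`fishing`, `path_choice`, `touch_enemy`).
#' @param trial trial index.
#' @param stimulus `"spider"` or `"turtle"`.
#' @return 3D point in meters.
#' @export
stimulus_position <- function(layout, task, trial, stimulus) {
  p <- layout$stimulus_positions[[task]][[as.character(trial)]][[stimulus]]
  if (is.null(p)) stop(sprintf("no %s position for %s trial %d",
                               stimulus, task, trial))
  p
}

event_time <- function(session, task, kind, trial = NULL) {
  ev <- session$events
  sel <- ev$task == task & ev$kind == kind
  if (!is.null(trial)) sel <- sel & ev$trial == trial
  t <- ev$t[sel]
  if (length(t) == 0)
    stop(sprintf("missing event %s for task %s%s", kind, task,
                 if (is.null(trial)) "" else sprintf(" trial %d", trial)))
  t[1]
}
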