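#' Per-participant readout row
#'
#' Computes every behavioral and physiological readout of one session:
#' the search-task minimum-distance, glance, and orientation differences
#' with per-side physiology; the forced-choice avoidance score; the
#' approach-task time-to-touch difference (truncated at 20 s), path-thirds
#' durations, hand acceleration-change counts (truncated at 100), and
#' pre-touch pupil/RR means; plus exclusion flags.
#'
#' @param session a `vr_session`.
#' @param include character subset of
#'   `c("fishing", "path_choice", "touch", "physiology")`.
#' @param touch_cap,accel_cap truncation caps (20 s / 100).
#' @param glance_gap glance merge threshold in seconds.
#' @param detail compute the within-task detail analyses (path thirds,
#'   acceleration changes, pre-touch windows); turn off when only the three
#'   primary readouts are needed.
#' @return one-row data frame.
#' @export
session_readouts <- function(session,
                             include = c("fishing", "path_choice", "touch",
                                         "physiology"),
                             touch_cap = 20, accel_cap = 100,
                             glance_gap = 0.2, detail = TRUE) {
  row <- list(participant_id = session$participant_id,
              group = session$group,
              fsq = session$questionnaire_scales[["fsq"]])
  for (sc in setdiff(names(session$questionnaire_scales), "fsq"))
    row[[paste0("scale_", sc)]] <- session$questionnaire_scales[[sc]]
  row$valence_spider <- session$valence_ratings[["spider"]]
  row$valence_turtle <- session$valence_ratings[["turtle"]]
  row$valence_diff <- row$valence_turtle - row$valence_spider

  has_gaze <- !is.null(session$gaze)
  has_rr <- !is.null(session$rr)

  if ("fishing" %in% include) {
    row$fishing_min_dist_spider <- fishing_min_distance(session, "spider")
    row$fishing_min_dist_turtle <- fishing_min_distance(session, "turtle")
    row$fishing_min_dist_diff <- row$fishing_min_dist_spider -
      row$fishing_min_dist_turtle
    ang_sp <- fishing_orientation(session, "spider")
    ang_tu <- fishing_orientation(session, "turtle")
    row$fishing_angle_spider <- as.numeric(ang_sp)
    row$fishing_angle_turtle <- as.numeric(ang_tu)
    row$fishing_angle_diff <- as.numeric(ang_sp) - as.numeric(ang_tu)
    row$excl_never_entered_spider_side <- isTRUE(attr(ang_sp, "excluded"))
    if (has_gaze) {
      gl <- fishing_glances(session, max_gap = glance_gap)
      row$fishing_glances_spider <- gl$spider$count
      row$fishing_glances_turtle <- gl$turtle$count
      row$fishing_glance_diff <- gl$diff
    }
    if ("physiology" %in% include && (has_gaze || has_rr)) {
      phys <- fishing_side_physiology(session)
      row$fishing_rr_spider_side <- phys$rr[["spider"]]
      row$fishing_rr_turtle_side <- phys$rr[["turtle"]]
      row$fishing_pupil_spider_side <- phys$pupil[["spider"]]
      row$fishing_pupil_turtle_side <- phys$pupil[["turtle"]]
    }
  }

  if ("path_choice" %in% include)
    row$path_choice_score <- path_choice_readout(session)

  if ("touch" %in% include) {
    tt <- touch_trials(session)
    row$touch_time_diff <- touch_readout(session, cap = touch_cap)
    pupil_series <- if ("physiology" %in% include && has_gaze)
      tryCatch(touch_pupil_series(session), error = function(e) NULL)
    else NULL
    closed_any <- FALSE
    rr_missing_any <- FALSE
    for (i in seq_len(nrow(tt))) {
      key <- paste0(tt$stimulus[i], tt$occurrence[i])
      row[[paste0("touch_time_", key)]] <- touch_time(session, tt$trial[i])
      if (!detail) next
      td <- thirds_durations(session, tt$trial[i])
      for (b in 1:3) row[[paste0("thirds_", key, "_", b)]] <- td[b]
      row[[paste0("accel_", key)]] <-
        trial_accel_changes(session, tt$trial[i], cap = accel_cap)
      if ("physiology" %in% include && (has_gaze || has_rr)) {
        pw <- pre_touch_windows(session, tt$trial[i],
                                pupil_series = pupil_series)
        row[[paste0("pretouch_pupil_", key)]] <- pw$pupil
        row[[paste0("pretouch_rr_", key)]] <- pw$rr
        closed_any <- closed_any || pw$closed_eyes
        rr_missing_any <- rr_missing_any || pw$rr_missing
      }
    }
    if ("physiology" %in% include && (has_gaze || has_rr)) {
      row$excl_closed_eyes <- closed_any
      row$excl_missing_rr <- rr_missing_any
    }
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Readout table for a list of sessions
#'
#' @param sessions list of `vr_session` objects.
#' @inheritParams session_readouts
#' @param on_error `"stop"` or `"skip"` (skip malformed sessions with a
#'   warning; an attribute `skipped` records their ids and reasons).
#' @return data frame with one row per (valid) session.
#' @export
compute_readouts <- function(sessions,
                             include = c("fishing", "path_choice", "touch",
                                         "physiology"),
                             touch_cap = 20, accel_cap = 100,
                             glance_gap = 0.2, on_error = c("stop", "skip"),
                             detail = TRUE) {
  on_error <- match.arg(on_error)
  rows <- list()
  skipped <- list()
  for (s in sessions) {
    r <- if (on_error == "skip") {
      tryCatch(session_readouts(s, include, touch_cap, accel_cap, glance_gap,
                                detail),
               error = function(e) e)
    } else session_readouts(s, include, touch_cap, accel_cap, glance_gap,
                            detail)
    if (inherits(r, "error")) {
      skipped[[s$participant_id]] <- conditionMessage(r)
      warning(sprintf("session %s skipped: %s", s$participant_id,
                      conditionMessage(r)), call. = FALSE)
    } else rows[[length(rows) + 1]] <- r
  }
  if (length(rows) == 0) stop("all sessions malformed; no readouts computed")
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    miss <- setdiff(cols, names(r))
    if (length(miss)) r[miss] <- NA
    r[, cols, drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Check the invariants of a readout table
#'
#' Asserts the readout-row contracts: the avoidance score lies in
#' `[-14, 14]`, the approach readout respects the 20 s cap, the
#' acceleration counts respect the cap of 100, and pre-touch pupil means
#' lie in `[0, 1]`.
#'
#' @param readouts data frame from [compute_readouts()].
#' @return `TRUE`, invisibly; errors on violation.
#' @export
validate_readouts <- function(readouts) {
  ok <- function(x, test) all(test(x[!is.na(x)]))
  if (!is.null(readouts$path_choice_score) &&
      !ok(readouts$path_choice_score, function(v) v >= -14 & v <= 14))
    stop("path_choice_score outside [-14, 14]")
  if (!is.null(readouts$touch_time_diff) &&
      !ok(readouts$touch_time_diff, function(v) v <= 20))
    stop("touch_time_diff above the 20 s cap")
  for (cc in grep("^accel_", names(readouts), value = TRUE))
    if (!ok(readouts[[cc]], function(v) v <= 100))
      stop("acceleration count above the cap of 100")
  for (cc in grep("^pretouch_pupil_", names(readouts), value = TRUE))
    if (!ok(readouts[[cc]], function(v) v >= 0 & v <= 1))
      stop("pre-touch pupil mean outside [0, 1]")
  invisible(TRUE)
}

#' Write/read the readout table
#'
#' CSV with one column per readout field; logical exclusion flags are
#' written as 0/1.
#'
#' @param readouts data frame from [compute_readouts()].
#' @param path file path (`readouts.csv`).
#' @return `path` (write) / the table (read).
#' @export
write_readouts <- function(readouts, path) {
  out <- readouts
  for (cc in names(out)) if (is.logical(out[[cc]])) out[[cc]] <- as.integer(out[[cc]])
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_readouts
#' @export
read_readouts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (cc in grep("^excl_", names(df), value = TRUE)) df[[cc]] <- df[[cc]] == 1
  df
}
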