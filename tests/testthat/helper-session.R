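# Deterministic constructed sessions with closed-form readouts.
#
# Timeline: fishing [0, 135] (wait ends at 10, window [10, 130]),
# path choice: trial tr in [140 + 20 (tr-1), +16], touch task from 250 on
# (10 s countdown per trial, touch at countdown_end + touch_times[tr]).

make_test_session <- function(fishing_pos = c(0, 0.3),
                              fishing_yaw = 0,
                              chosen_sides = rep("right", 10),
                              touch_times = c(3, 3, 3, 3),
                              layout = scene_layout(),
                              focus_spec = NULL,
                              pupil_fun = function(t) rep(3.5, length(t)),
                              blink_windows = NULL,
                              rr_const = 0.8,
                              hand_jitter = rep(0, 4),
                              touch_walk_from = 0,
                              rate = 30,
                              group = "non_fearful", fsq = 5) {
  dt <- 1 / rate

  # --- fishing segment: constant position (or function of t)
  t_f <- seq(0, 135, by = dt)
  if (is.function(fishing_pos)) {
    fp <- fishing_pos(t_f)
    fx <- fp[, 1]; fz <- fp[, 2]
  } else {
    fx <- rep(fishing_pos[1], length(t_f))
    fz <- rep(fishing_pos[2], length(t_f))
  }
  fyaw <- rep(fishing_yaw, length(t_f))[seq_along(t_f)]

  # --- path choice: parametric legs through the chosen gate sides
  t_p <- c(); px <- c(); pz <- c()
  ev <- list(data.frame(t = c(0, 0, 10, 130, 135),
                        kind = c("task_start", "trial_start",
                                 "countdown_end", "trial_end", "task_end"),
                        task = "fishing", trial = c(0, 1, 1, 1, 0),
                        stimulus = "none"))
  ev[[2]] <- data.frame(t = 138, kind = "task_start", task = "path_choice",
                        trial = 0, stimulus = "none")
  for (tr in 1:5) {
    t0 <- 140 + (tr - 1) * 20
    tt_out <- seq(0, 8, by = dt)
    tt_ret <- seq(0, 8, by = dt)[-1]
    zf_out <- tt_out / 8
    zf_ret <- 1 - tt_ret / 8
    s_out <- if (chosen_sides[2 * tr - 1] == "left") -1 else 1
    s_ret <- if (chosen_sides[2 * tr] == "left") -1 else 1
    t_p <- c(t_p, t0 + tt_out, t0 + 8 + tt_ret)
    px <- c(px, s_out * 0.8 * sin(pi * zf_out), s_ret * 0.8 * sin(pi * zf_ret))
    pz <- c(pz, 0.25 + zf_out * 3.45, 0.25 + zf_ret * 3.45)
    ev[[2 + tr]] <- data.frame(t = c(t0, t0 + 16), kind = c("trial_start",
                                                            "trial_end"),
                               task = "path_choice", trial = tr,
                               stimulus = "none")
  }
  ev[[8]] <- data.frame(t = 248, kind = "task_end", task = "path_choice",
                        trial = 0, stimulus = "none")

  # --- touch: linear constant-speed approach from touch_walk_from to the
  # table, one trial per entry of touch_times
  t_t <- c(); tx <- c(); tz <- c(); hjit <- c()
  tcur <- 250
  k <- 9
  for (tr in 1:4) {
    cd <- tcur + 10
    touch <- cd + touch_times[tr]
    tt <- seq(tcur, touch, by = dt)
    walk <- tt >= cd
    frac <- ifelse(walk, (tt - cd) / max(touch_times[tr], dt), 0)
    t_t <- c(t_t, tt)
    tx <- c(tx, rep(layout$table_position[1], length(tt)))
    tz <- c(tz, touch_walk_from +
              frac * (layout$table_position[3] - touch_walk_from))
    hjit <- c(hjit, rep(hand_jitter[tr], length(tt)))
    st <- layout$touch_order[tr]
    ev[[k]] <- data.frame(t = c(tcur, cd, touch, touch + 1),
                          kind = c("trial_start", "countdown_end",
                                   "stimulus_touch", "trial_end"),
                          task = "touch_enemy", trial = tr,
                          stimulus = c("none", "none", st, "none"))
    k <- k + 1
    tcur <- touch + 2
  }
  ev[[k]] <- data.frame(t = tcur, kind = "task_end", task = "touch_enemy",
                        trial = 0, stimulus = "none")
  evd <- do.call(rbind, ev)
  evd <- evd[order(evd$t), ]

  t_all <- c(t_f, t_p, t_t)
  x_all <- c(fx, px, tx)
  z_all <- c(fz, pz, tz)
  yaw_all <- c(fyaw, rep(0, length(t_p)), rep(0, length(t_t)))

  pelvis <- motion_track(t_all, x_all, rep(1, length(t_all)), z_all,
                         yaw = yaw_all, sensor_id = "pelvis")
  head <- motion_track(t_all, x_all, rep(1.6, length(t_all)), z_all,
                       yaw = yaw_all, sensor_id = "head")
  # hand: smooth sinusoid around the body, plus optional white jitter in
  # the touch trials
  jit <- c(rep(0, length(t_f)), rep(0, length(t_p)), hjit)
  set.seed(97)
  hx <- x_all + 0.25 + 0.01 * sin(2 * pi * 0.3 * t_all) +
    jit * rnorm(length(t_all))
  hy <- 1 + jit * rnorm(length(t_all))
  hz <- z_all + 0.2 + jit * rnorm(length(t_all))
  hand <- motion_track(t_all, hx, hy, hz, sensor_id = "right_hand")

  t_g <- seq(0, max(t_all), by = 1 / 110)
  focus <- rep("", length(t_g))
  if (!is.null(focus_spec))
    for (i in seq_len(nrow(focus_spec)))
      focus[t_g >= focus_spec$start[i] & t_g < focus_spec$end[i]] <-
        focus_spec$label[i]
  valid <- rep(TRUE, length(t_g))
  if (!is.null(blink_windows))
    for (i in seq_len(nrow(blink_windows)))
      valid[t_g >= blink_windows[i, 1] & t_g < blink_windows[i, 2]] <- FALSE
  pup <- pupil_fun(t_g)
  gaze <- gaze_stream(t_g, focus, ifelse(valid, pup, NA),
                      ifelse(valid, pup, NA), valid, valid)

  beats <- seq(0, max(t_all) + 1, by = rr_const)
  rr <- rr_series(beats, rep(rr_const, length(beats)))

  events <- task_events(evd$t, evd$kind, evd$task, evd$trial, evd$stimulus)
  vr_session("T001", group, c(fsq = fsq), c(spider = 5, turtle = 6),
             list(pelvis = pelvis, head = head, right_hand = hand),
             gaze, rr, events, layout)
}
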