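#' Configuration of the synthetic cohort generator
#'
#' A single latent spider-aversion scalar per participant drives every
#' modality: trajectory repulsion from the spider, glance hazard, body
#' orientation bias, forced-choice utilities, approach hesitation, hand
#' tremor, pre-touch pupil dilation, and RR decrease. Group sizes and
#' aversion means default to the study conditions (15 phobic / 6 fearful /
#' 10 non-fearful; latent means 2.0 / 1.0 / 0.0, SD 0.4).
#'
#' @param n_per_group named counts for `phobic`, `fearful`, `non_fearful`.
#' @param aversion_means latent aversion means per group (must be ordered
#'   phobic >= fearful >= non_fearful); draws are floored at 0.
#' @param aversion_sd latent aversion SD.
#' @param habituation multiplicative reduction of spider hesitation on the
#'   second spider presentation, in `[0, 1]` (default 0.4).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param motion_rate,gaze_rate stream rates in Hz (90 / 110).
#' @param include_gaze,include_physio generate the gaze/pupil stream and
#'   the RR series (turn off for large replicate studies that only use the
#'   behavioral readouts).
#' @param counterbalance alternate stimulus sides / first stimulus across
#'   participants.
#' @param gains per-modality effect gains (see source for the full list).
#' @param noise noise scales for trajectory, pupil, RR, and hand streams.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(phobic = 15, fearful = 6,
                                          non_fearful = 10),
                          aversion_means = c(phobic = 2, fearful = 1,
                                             non_fearful = 0),
                          aversion_sd = 0.4,
                          habituation = 0.4,
                          seed = 1,
                          motion_rate = 90, gaze_rate = 110,
                          include_gaze = TRUE, include_physio = TRUE,
                          counterbalance = TRUE,
                          gains = list(), noise = list()) {
  g <- list(repulse = 1.2, repulse_scale = 1.3, glance = 1.2, yaw = 0.35,
            rr_side = 0.05, pupil_side = 0.12, choice_beta = 2.2,
            choice_cost = 0.7, hes0 = 0.2, hes1 = 0.9, tremor = 0.003,
            pupil_pre = 0.3, rr_pre = 0.04)
  g[names(gains)] <- gains
  nz <- list(trajectory = 0.5, pupil = 0.05, rr = 0.015, hand = 3e-4)
  nz[names(noise)] <- noise
  cfg <- structure(list(
    n_per_group = n_per_group, aversion_means = aversion_means,
    aversion_sd = aversion_sd, habituation = habituation, seed = seed,
    motion_rate = motion_rate, gaze_rate = gaze_rate,
    include_gaze = include_gaze, include_physio = include_physio,
    counterbalance = counterbalance, gains = g, noise = nz
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param config a `cohort_config` to validate.
#' @export
validate_cohort_config <- function(config) {
  np <- config$n_per_group
  if (any(np < 0)) stop("group counts must be >= 0")
  if (!all(c("phobic", "fearful", "non_fearful") %in% names(np)))
    stop("n_per_group must name phobic, fearful, non_fearful")
  am <- config$aversion_means
  if (!(am[["phobic"]] >= am[["fearful"]] &&
        am[["fearful"]] >= am[["non_fearful"]]))
    stop("aversion means must be ordered phobic >= fearful >= non_fearful")
  if (config$habituation < 0 || config$habituation > 1)
    stop("habituation must be in [0, 1]")
  invisible(config)
}

# smooth AR(1) noise, stationary sd `sd`
ar_noise <- function(n, sd, phi = 0.98) .cpp_ar1(as.integer(n), sd, phi)

smoothstep <- function(u) {
  u <- clamp(u, 0, 1)
  u * u * (3 - 2 * u)
}

# yaw (degrees, 0 = +z, CCW from above) of a heading vector
heading_yaw <- function(vx, vz) atan2(-vx, vz) * 180 / pi

#' Map latent aversion to an FSQ score within a group
#'
#' Group-specific FSQ ranges honoring the cutoff-8 partition (non-fearful
#' 0..8, fearful 9..40, phobic 60..108); within a group the mapping is
#' rank-preserving in aversion with random spacing.
#'
#' @param aversion latent aversion draws of one group.
#' @param group group label.
#' @return integer FSQ totals, monotone in `aversion` within the group.
#' @export
fsq_from_aversion <- function(aversion, group) {
  rng <- switch(group, non_fearful = c(0, 8), fearful = c(9, 40),
                phobic = c(60, 108), stop("unknown group"))
  n <- length(aversion)
  draws <- sort(sample(seq(rng[1], rng[2]), n, replace = TRUE))
  draws[rank(aversion, ties.method = "first")]
}

# ---- task simulators -------------------------------------------------------
# Each simulator returns a task segment: motion samples for the three
# sensors, events, focus intervals, and additive pupil/RR modulation
# timelines, all on the session timebase.

#' Simulate the search-task segment
#'
#' 10 s standing wait followed by a 120 s bounded drift--diffusion search
#' walk with exponential repulsion from the spider plank scaling with
#' aversion; glance onsets toward the spider arrive with an
#' aversion-scaled hazard; yaw is biased toward the spider while on its
#' half; RR decreases and pupil size increases on the spider half.
#'
#' @param aversion latent aversion (>= 0).
#' @param layout a [scene_layout()].
#' @param config a [cohort_config()].
#' @param t0 session time at which the task starts.
#' @return task segment list (internal structure; consumed by
#'   [generate_cohort()]).
#' @export
simulate_fishing <- function(aversion, layout, config = cohort_config(),
                             t0 = 0) {
  g <- config$gains
  rate <- config$motion_rate
  dt <- 1 / rate
  hw <- layout$field_width / 2
  sp <- stimulus_position(layout, "fishing", 1, "spider")
  start <- layout$start_position

  wait <- 10
  active <- 120
  tail <- 5
  n_wait <- round(wait * rate)
  n_act <- round(active * rate)
  n_tail <- round(tail * rate)

  # standing sway during wait and tail
  sway <- function(n) cbind(ar_noise(n, 0.01), ar_noise(n, 0.01))
  sw1 <- sway(n_wait); sw2 <- sway(n_tail)
  walk <- .cpp_fishing_walk(n_act, dt, start[1], max(start[3], 0.3),
                            hw, layout$field_depth, sp[1], sp[3],
                            g$repulse * aversion, g$repulse_scale,
                            attract_k = 0.8, vel_tau = 1.2,
                            noise_sd = config$noise$trajectory,
                            retarget_rate = 0.35)
  x <- c(start[1] + sw1[, 1], walk$x, walk$x[n_act] + sw2[, 1])
  z <- c(max(start[3], 0.3) + sw1[, 2], walk$z, walk$z[n_act] + sw2[, 2])
  vx <- c(rep(0, n_wait), walk$vx, rep(0, n_tail))
  vz <- c(rep(0, n_wait), walk$vz, rep(0, n_tail))
  n <- length(x)
  t <- t0 + (seq_len(n) - 1) * dt

  # yaw: heading while moving, spider-bias on the spider half
  speed <- sqrt(vx^2 + vz^2)
  yaw <- heading_yaw(vx, vz)
  yaw[speed < 0.05] <- NA
  if (is.na(yaw[1])) yaw[1] <- 0
  yaw <- approx(t[!is.na(yaw)], yaw[!is.na(yaw)], xout = t, rule = 2)$y
  on_spider_half <- sign(x) == sign(sp[1])
  b <- min(0.85, g$yaw * aversion)
  if (b > 0) {
    target <- heading_yaw(sp[1] - x, sp[3] - z)
    d <- ((target - yaw + 180) %% 360) - 180
    yaw <- ifelse(on_spider_half, yaw + b * d, yaw)
  }
  yaw <- ((yaw + 180) %% 360) - 180

  pelvis <- data.frame(t = t, x = x, y = 1.0 + ar_noise(n, 0.005),
                       z = z, yaw = yaw)
  head <- data.frame(t = t, x = x, y = 1.6, z = z, yaw = yaw)
  th <- yaw * pi / 180
  hand <- data.frame(t = t,
                     x = x - sin(th) * 0.35 + 0.2 + ar_noise(n, 0.01),
                     y = 0.95 + ar_noise(n, 0.01),
                     z = z + cos(th) * 0.35 + ar_noise(n, 0.01))

  events <- data.frame(
    t = t0 + c(0, 0, wait, wait + active, wait + active + tail),
    kind = c("task_start", "trial_start", "countdown_end", "trial_end",
             "task_end"),
    task = "fishing", trial = c(0L, 1L, 1L, 1L, 0L), stimulus = "none",
    stringsAsFactors = FALSE)

  # glance onsets: Poisson hazards, spider hazard scales with aversion
  w0 <- t0 + wait; w1 <- t0 + wait + active
  draw_glances <- function(rate_hz, label) {
    k <- rpois(1, rate_hz * active)
    if (k == 0) return(NULL)
    on <- sort(runif(k, w0, w1 - 1.5))
    dur <- rlnorm(k, log(0.5), 0.4)
    iv <- data.frame(label = label, start = on, end = pmin(on + dur, w1))
    if (k > 1) {
      prev_end <- cummax(head(iv$end, -1))
      iv <- iv[c(TRUE, iv$start[-1] > prev_end + 0.25), , drop = FALSE]
    }
    iv
  }
  base_rate <- 3 / 60
  gl_sp <- draw_glances(base_rate * (1 + g$glance * aversion), "spider")
  gl_tu <- draw_glances(base_rate, "turtle")
  focus <- rbind(gl_sp, gl_tu)

  # physiology modulation: spider-half occupancy at 10 Hz
  mod_t <- seq(t0, t0 + wait + active + tail, by = 0.1)
  occ <- approx(t, as.numeric(on_spider_half), xout = mod_t, rule = 2)$y > 0.5
  rr_mod <- data.frame(t = mod_t, add = -g$rr_side * aversion * occ)
  pupil_mod <- data.frame(t = mod_t, add = g$pupil_side * aversion * occ)

  list(tracks = list(pelvis = pelvis, head = head, right_hand = hand),
       events = events, focus = focus, rr_mod = rr_mod,
       pupil_mod = pupil_mod, t_end = t0 + wait + active + tail)
}

#' Simulate the forced-choice segment
#'
#' Each of the ten legs (five trials, outward/return) is a logistic choice
#' with utility `-cost_gain * weight(side) - beta * aversion *
#' [side == spider side]`, followed by a smooth parametric path through the
#' chosen gate side.
#'
#' @inheritParams simulate_fishing
#' @return task segment list plus `chosen_sides` (length 10).
#' @export
simulate_path_choice <- function(aversion, layout,
                                 config = cohort_config(), t0 = 0) {
  g <- config$gains
  rate <- config$motion_rate
  dt <- 1 / rate
  gate <- layout$choice_gate_z

  pick_side <- function(spider_side, offset) {
    u <- vapply(c("left", "right"), function(s)
      -g$choice_cost * segment_weight(s, offset) -
        g$choice_beta * aversion * (s == spider_side), numeric(1))
    p_left <- 1 / (1 + exp(u[["right"]] - u[["left"]]))
    if (runif(1) < p_left) "left" else "right"
  }

  leg_path <- function(tt, side, outward) {
    # z runs 0.25 -> 3.7 (outward) or back; x bulges to the chosen side
    u <- smoothstep(seq(0, 1, length.out = length(tt)))
    zf <- if (outward) u else 1 - u
    amp <- if (side == "left") -0.8 else 0.8
    list(t = tt, x = amp * sin(pi * zf) + ar_noise(length(tt), 0.02),
         z = 0.25 + zf * (3.7 - 0.25))
  }

  sides <- character(0)
  chunks <- list()
  ev_t <- t0; ev_kind <- "task_start"; ev_trial <- 0L
  tcur <- t0 + 2
  for (tr in 1:5) {
    spider_side <- layout$animal_swap_schedule[tr]
    offset <- layout$book_offsets[tr]
    s_out <- pick_side(spider_side, offset)
    s_ret <- pick_side(spider_side, offset)
    sides <- c(sides, s_out, s_ret)
    dur_out <- 5.5 + runif(1, -0.5, 0.5)
    dur_dwell <- 1.2
    dur_ret <- 5.5 + runif(1, -0.5, 0.5)
    p1 <- leg_path(tcur + seq(0, dur_out, by = dt), s_out, outward = TRUE)
    dwell_t <- tcur + dur_out + seq(dt, dur_dwell, by = dt)
    p2 <- list(t = dwell_t,
               x = p1$x[length(p1$x)] + ar_noise(length(dwell_t), 0.01),
               z = p1$z[length(p1$z)] + ar_noise(length(dwell_t), 0.01))
    p3 <- leg_path(tcur + dur_out + dur_dwell + dt + seq(0, dur_ret, by = dt),
                   s_ret, outward = FALSE)
    t_end_tr <- p3$t[length(p3$t)]
    chunks[[tr]] <- list(t = c(p1$t, p2$t, p3$t), x = c(p1$x, p2$x, p3$x),
                         z = c(p1$z, p2$z, p3$z))
    ev_t <- c(ev_t, tcur, t_end_tr)
    ev_kind <- c(ev_kind, "trial_start", "trial_end")
    ev_trial <- c(ev_trial, tr, tr)
    tcur <- t_end_tr + 1.5
  }
  ev_t <- c(ev_t, tcur); ev_kind <- c(ev_kind, "task_end")
  ev_trial <- c(ev_trial, 0L)
  events <- data.frame(t = ev_t, kind = ev_kind, task = "path_choice",
                       trial = ev_trial, stimulus = "none",
                       stringsAsFactors = FALSE)
  pt <- unlist(lapply(chunks, `[[`, "t"))
  px <- unlist(lapply(chunks, `[[`, "x"))
  pz <- unlist(lapply(chunks, `[[`, "z"))
  n <- length(pt)
  yaw <- heading_yaw(c(diff(px) / dt, 0), c(diff(pz) / dt, 0))
  pelvis_df <- data.frame(t = pt, x = px, y = 1.0 + ar_noise(n, 0.005),
                          z = pz, yaw = yaw)
  head <- data.frame(t = pt, x = px, y = 1.6, z = pz, yaw = yaw)
  hand <- data.frame(t = pt, x = px + 0.25 + ar_noise(n, 0.01),
                     y = 1.0 + ar_noise(n, 0.01),
                     z = pz + 0.2 + ar_noise(n, 0.01))
  mod_t <- seq(t0, tcur, by = 0.5)
  list(tracks = list(pelvis = pelvis_df, head = head, right_hand = hand),
       events = events, focus = NULL,
       rr_mod = data.frame(t = mod_t, add = 0),
       pupil_mod = data.frame(t = mod_t, add = 0),
       chosen_sides = sides, t_end = tcur)
}

#' Simulate the approach-task segment
#'
#' Four alternating trials (two spider, two turtle). Each trial has a 10 s
#' countdown, a 1D approach walk whose speed drops with proximity to the
#' stimulus (hesitation strongest in the last third, scaling with
#' aversion on spider trials, attenuated by the habituation factor on the
#' second spider presentation), a final reach, and a touch event. Hand
#' jitter power, pre-touch pupil dilation, and pre-touch RR decrease scale
#' with the same effective aversion.
#'
#' @inheritParams simulate_fishing
#' @return task segment list.
#' @export
simulate_touch <- function(aversion, layout, config = cohort_config(),
                           t0 = 0) {
  g <- config$gains
  rate <- config$motion_rate
  dt <- 1 / rate
  start <- layout$start_position
  table <- layout$table_position
  stim_y <- table[2] + 0.1
  reach_dist <- 0.45
  total <- sqrt((table[1] - start[1])^2 + (table[3] - start[3])^2)
  walk_dist <- total - reach_dist
  uz <- (table[3] - start[3]) / total
  ux <- (table[1] - start[1]) / total

  chunks <- list()
  ev_t <- t0; ev_kind <- "task_start"; ev_trial <- 0L; ev_stim <- "none"
  focus <- NULL
  mod_t <- mod_pupil <- mod_rr <- list()
  tcur <- t0 + 1
  seen_spider <- 0
  for (tr in 1:4) {
    st <- layout$touch_order[tr]
    if (st == "spider") seen_spider <- seen_spider + 1
    a_eff <- if (st == "spider")
      aversion * (if (seen_spider >= 2) 1 - config$habituation else 1)
    else 0
    hes_jit <- exp(rnorm(1, 0, 0.45))
    spd_jit <- exp(rnorm(1, 0, 0.3))

    n_cd <- round(10 / dt)
    t_cd <- tcur + (seq_len(n_cd) - 1) * dt
    cd_x <- start[1] + ar_noise(n_cd, 0.008)
    cd_z <- max(start[3], 0.25) + ar_noise(n_cd, 0.008)

    prog <- .cpp_touch_walk(dt, walk_dist, 0.55 * spd_jit,
                            g$hes0 * a_eff * hes_jit,
                            g$hes1 * a_eff * hes_jit,
                            noise_sd = 0.35, noise_tau = 1.5,
                            max_n = as.integer(400 / dt))
    nw <- length(prog)
    t_walk <- tcur + 10 + seq_len(nw) * dt
    # lateral gait sway: smooth sub-1 Hz oscillation plus slow drift
    sway <- function(n, amp, freq = runif(1, 0.55, 0.85))
      amp * sin(2 * pi * freq * seq_len(n) * dt + runif(1, 0, 2 * pi))
    wx <- start[1] + ux * prog + sway(nw, 0.015) +
      ar_noise(nw, 0.006, phi = 0.999)
    wz <- max(start[3], 0.25) + uz * prog

    reach_dur <- 0.5 + 0.35 * a_eff * exp(rnorm(1, 0, 0.3))
    n_re <- max(4L, round(reach_dur / dt))
    t_re <- max(t_walk) + seq_len(n_re) * dt
    re_x <- wx[nw] + ar_noise(n_re, 0.005)
    re_z <- wz[nw] + ar_noise(n_re, 0.005)
    t_touch <- max(t_re)

    t_all <- c(t_cd, t_walk, t_re)
    px <- c(cd_x, wx, re_x)
    pz <- c(cd_z, wz, re_z)
    n_all <- length(t_all)
    yaw <- rep(heading_yaw(ux, uz), n_all)
    # hand: follows the body during countdown/walk -- smooth arm swing plus
    # an aversion-scaled high-frequency tremor -- then extends to the
    # stimulus during the reach
    trem_sd <- g$tremor * a_eff
    trem <- function(n)
      ar_noise(n, trem_sd, phi = 0.6) + rnorm(n, 0, config$noise$hand)
    hx_body <- px + 0.25 + sway(n_all, 0.01) +
      ar_noise(n_all, 0.004, phi = 0.997)
    hy_body <- 1.0 + sway(n_all, 0.012) + ar_noise(n_all, 0.004, phi = 0.997)
    hz_body <- pz + 0.2 + sway(n_all, 0.01) + ar_noise(n_all, 0.004, phi = 0.997)
    u_re <- smoothstep(seq(0, 1, length.out = n_re))
    idx_re <- (n_cd + nw) + seq_len(n_re)
    hx_body[idx_re] <- hx_body[idx_re] * (1 - u_re) + table[1] * u_re
    hy_body[idx_re] <- hy_body[idx_re] * (1 - u_re) + stim_y * u_re
    hz_body[idx_re] <- hz_body[idx_re] * (1 - u_re) + table[3] * u_re

    chunks[[tr]] <- list(
      t = t_all, yaw = yaw,
      pel_x = px, pel_y = 1.0 + ar_noise(n_all, 0.005), pel_z = pz,
      hd_x = px, hd_y = rep(1.6, n_all), hd_z = pz,
      hn_x = hx_body + trem(n_all), hn_y = hy_body + trem(n_all),
      hn_z = hz_body + trem(n_all))

    ev_t <- c(ev_t, tcur, tcur + 10, t_touch, t_touch + 2)
    ev_kind <- c(ev_kind, "trial_start", "countdown_end", "stimulus_touch",
                 "trial_end")
    ev_trial <- c(ev_trial, rep(tr, 4))
    ev_stim <- c(ev_stim, "none", "none", st, "none")

    # gaze locks onto the stimulus over the last stretch of the approach
    focus <- rbind(focus, data.frame(label = st,
                                     start = tcur + 10 + 0.6 * (t_touch - tcur - 10),
                                     end = t_touch + 0.5))
    # pre-touch physiology: pupil ramp over the last 3 s, RR dip last 5 s
    mt <- seq(tcur, t_touch + 2, by = 0.1)
    mod_t[[tr]] <- mt
    mod_pupil[[tr]] <- g$pupil_pre * a_eff * clamp((mt - (t_touch - 3)) / 3, 0, 1)
    mod_rr[[tr]] <- -g$rr_pre * a_eff * (mt >= t_touch - 5 & mt <= t_touch)
    tcur <- t_touch + 3
  }
  ev_t <- c(ev_t, tcur); ev_kind <- c(ev_kind, "task_end")
  ev_trial <- c(ev_trial, 0L); ev_stim <- c(ev_stim, "none")
  events <- data.frame(t = ev_t, kind = ev_kind, task = "touch_enemy",
                       trial = ev_trial, stimulus = ev_stim,
                       stringsAsFactors = FALSE)
  col <- function(nm) unlist(lapply(chunks, `[[`, nm))
  tracks <- list(
    pelvis = data.frame(t = col("t"), x = col("pel_x"), y = col("pel_y"),
                        z = col("pel_z"), yaw = col("yaw")),
    head = data.frame(t = col("t"), x = col("hd_x"), y = col("hd_y"),
                      z = col("hd_z"), yaw = col("yaw")),
    right_hand = data.frame(t = col("t"), x = col("hn_x"), y = col("hn_y"),
                            z = col("hn_z")))
  mt <- unlist(mod_t)
  list(tracks = tracks, events = events, focus = focus,
       rr_mod = data.frame(t = mt, add = unlist(mod_rr)),
       pupil_mod = data.frame(t = mt, add = unlist(mod_pupil)),
       t_end = tcur)
}

# ---- stream assembly -------------------------------------------------------

assemble_gaze <- function(segments, config, t_end) {
  rate <- config$gaze_rate
  n <- floor(t_end * rate)
  # approximately regular sampling: small timing jitter
  t <- cumsum(1 / rate * (1 + runif(n, -0.03, 0.03)))
  t <- t * (t_end / t[n])
  focus <- rep("", n)
  for (seg in segments) {
    fv <- seg$focus
    if (is.null(fv)) next
    for (i in seq_len(nrow(fv)))
      focus[t >= fv$start[i] & t < fv$end[i]] <- fv$label[i]
  }
  mod <- do.call(rbind, lapply(segments, `[[`, "pupil_mod"))
  add <- approx(mod$t, mod$add, xout = t, rule = 2)$y
  base <- 3.5 + 0.15 * sin(2 * pi * t / 60 + runif(1, 0, 2 * pi))
  pr <- base + add + ar_noise(n, config$noise$pupil, phi = 0.9)
  pl <- pr + ar_noise(n, 0.02, phi = 0.9)
  # artifact spikes (flagged later by the moving-median MAD filter)
  k <- rpois(1, t_end / 60)
  if (k > 0) {
    at <- sample.int(n, k)
    pr[at] <- pr[at] + sample(c(-1, 1), k, TRUE) * runif(k, 0.8, 1.6)
  }
  valid <- rep(TRUE, n)
  nb <- rpois(1, 12 * t_end / 60)
  if (nb > 0) {
    bs <- runif(nb, 0, t_end)
    bd <- runif(nb, 0.1, 0.4)
    for (i in seq_len(nb)) valid[t >= bs[i] & t < bs[i] + bd[i]] <- FALSE
  }
  gaze_stream(t, focus, ifelse(valid, pl, NA), ifelse(valid, pr, NA),
              valid, valid, nominal_rate = rate)
}

assemble_rr <- function(segments, config, t_end) {
  mod <- do.call(rbind, lapply(segments, `[[`, "rr_mod"))
  mod <- mod[order(mod$t), ]
  beats_t <- numeric(0)
  beats_rr <- numeric(0)
  tcur <- 0
  base <- 0.85
  while (tcur < t_end) {
    add <- approx(mod$t, mod$add, xout = tcur, rule = 2)$y
    rr <- base + add + 0.02 * sin(2 * pi * tcur / 30) +
      rnorm(1, 0, config$noise$rr)
    rr <- max(rr, 0.4)
    beats_t <- c(beats_t, tcur)
    beats_rr <- c(beats_rr, rr)
    tcur <- tcur + rr
  }
  rr_series(beats_t, beats_rr)
}

#' Generate a synthetic cohort of VR sessions
#'
#' Draws one latent aversion value per participant (group mean + noise,
#' floored at 0), simulates the three task segments, assembles the gaze and
#' RR streams, and returns the sessions together with the generating ground
#' truth. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `sessions` (list of `vr_session`) and `ground_truth`
#'   (data frame: `participant_id`, `group`, `aversion`, `fsq`,
#'   `valence_spider`, `valence_turtle`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  groups <- rep(c("phobic", "fearful", "non_fearful"),
                times = config$n_per_group[c("phobic", "fearful",
                                             "non_fearful")])
  n <- length(groups)
  aversion <- pmax(0, rnorm(n, config$aversion_means[groups],
                            config$aversion_sd))
  fsq <- numeric(n)
  for (gname in unique(groups)) {
    idx <- groups == gname
    fsq[idx] <- fsq_from_aversion(aversion[idx], gname)
  }
  sessions <- vector("list", n)
  gt <- vector("list", n)
  for (i in seq_len(n)) {
    cb <- if (config$counterbalance) i else 1
    layout <- scene_layout(
      spider_side_fishing = if (cb %% 2 == 1) "left" else "right",
      spider_side_path_first = if ((cb %/% 2) %% 2 == 0) "left" else "right",
      first_touch_stimulus = if (cb %% 2 == 1) "spider" else "turtle")
    seg_f <- simulate_fishing(aversion[i], layout, config, t0 = 0)
    seg_p <- simulate_path_choice(aversion[i], layout, config,
                                  t0 = seg_f$t_end + 5)
    seg_t <- simulate_touch(aversion[i], layout, config,
                            t0 = seg_p$t_end + 5)
    segments <- list(seg_f, seg_p, seg_t)
    t_end <- seg_t$t_end + 2

    tracks <- list()
    for (sid in c("pelvis", "head", "right_hand")) {
      df <- do.call(rbind, lapply(segments, function(s) s$tracks[[sid]]))
      tracks[[sid]] <- motion_track(df$t, df$x, df$y, df$z, yaw = df$yaw,
                                    sensor_id = sid)
    }
    gaze <- if (config$include_gaze) assemble_gaze(segments, config, t_end)
            else NULL
    rr <- if (config$include_physio) assemble_rr(segments, config, t_end)
          else NULL
    ev <- do.call(rbind, lapply(segments, `[[`, "events"))
    ev <- ev[order(ev$t), ]
    events <- task_events(ev$t, ev$kind, ev$task, ev$trial, ev$stimulus)

    val_spider <- clamp(round(7 - 2.2 * aversion[i] + rnorm(1, 0, 0.8)), 0, 10)
    val_turtle <- clamp(round(7 + rnorm(1, 0, 0.8)), 0, 10)
    scales <- c(fsq = fsq[i],
                trait_anxiety = round(clamp(35 + 8 * aversion[i] +
                                              rnorm(1, 0, 5), 20, 80)),
                disgust_sensitivity = round(clamp(20 + 6 * aversion[i] +
                                                    rnorm(1, 0, 4), 0, 50)),
                self_esteem = round(clamp(30 + rnorm(1, 0, 4), 10, 40)))
    pid <- sprintf("P%03d", i)
    sessions[[i]] <- vr_session(
      pid, groups[i], scales,
      c(spider = val_spider, turtle = val_turtle),
      tracks, gaze, rr, events, layout)
    gt[[i]] <- data.frame(participant_id = pid, group = groups[i],
                          aversion = aversion[i], fsq = fsq[i],
                          valence_spider = val_spider,
                          valence_turtle = val_turtle,
                          stringsAsFactors = FALSE)
  }
  list(sessions = sessions, ground_truth = do.call(rbind, gt))
}

#' Write a generated cohort to disk
#'
#' One session container per participant (directories `P001`, `P002`, ...)
#' plus `ground_truth.json`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create ", dir)
  for (s in cohort$sessions)
    write_session(s, file.path(dir, s$participant_id))
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
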