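# Four-step tracking state machine and the closed-loop driver.
#
# Modes: SEARCH (stage sweeps a Lissajous figure at low magnification
# until enough dark pixels enter the FOV), TRACK (full-FOV measurement,
# servo to centre), TRACK_ROI (measurement restricted to the rotated
# elliptical ROI propagated from the previous frame's state), LOST
# (full-FOV re-detection at the current magnification, stage holding).
# Transitions: SEARCH/LOST -> TRACK on detection; TRACK -> TRACK_ROI
# after a configurable number of stable frames; TRACK/TRACK_ROI -> LOST
# after `lost_patience` consecutive empty frames.

#' Tracker configuration
#'
#' @param acquire_area_px Foreground-pixel count that triggers detection
#'   in SEARCH/LOST (default 50).
#' @param roi_a,roi_b ROI semi-axes in pixels (default the bead preset
#'   `a = b = 20`; see [roi_preset()]).
#' @param roi_engage `"on"` engages the elliptical ROI after
#'   `roi_engage_after` stable TRACK frames; `"off"` reproduces plain
#'   full-FOV processing.
#' @param roi_engage_after Stable TRACK frames before the ROI turns on
#'   (default 100, i.e. 0.2 s at 500 FPS: the ROI is switched on only
#'   once tracking is steady).
#' @param lost_patience Consecutive empty frames before declaring LOST
#'   (default 25).
#' @param min_contrast Minimum intensity spread (8-bit levels) inside the
#'   ROI for a fresh adaptive threshold; below it the previous frame's
#'   threshold is reused (the ROI may lie wholly inside a large dark
#'   target at high magnification, where its patch is unimodal).
#' @param gains A [servo_gains()].
#' @param fps Sensor frame rate (default 500).
#' @param sensor_px Sensor side in pixels (default 256).
#' @param max_speed_um_s Stage speed limit.
#' @param pos_noise_sd Stage position-sensing noise sd (um).
#' @param search_ratio Magnification used while searching (default 140x,
#'   the widest FOV).
#' @param search_amplitude_um,search_freq_ratio,search_speed_um_s,search_delta
#'   Lissajous search-path parameters; the base frequency is derived so
#'   the fastest axis sweeps at `search_speed_um_s`.
#' @return List of class `tracker_config`.
#' @export
tracker_config <- function(acquire_area_px = 50L, roi_a = 20, roi_b = 20,
                           roi_engage = c("on", "off"),
                           roi_engage_after = 100L, lost_patience = 25L,
                           min_contrast = 8, gains = servo_gains(),
                           fps = 500, sensor_px = 256L,
                           max_speed_um_s = 1.5e6, pos_noise_sd = 0.2,
                           search_ratio = 140,
                           search_amplitude_um = 5000,
                           search_freq_ratio = c(3, 2),
                           search_speed_um_s = 5e4,
                           search_delta = pi / 2) {
  roi_engage <- match.arg(roi_engage)
  stopifnot(acquire_area_px > 0, lost_patience >= 1, fps > 0)
  if (gains$kp / fps >= 2)
    stop("unstable configuration: kp * dt must be < 2 for the discrete loop")
  structure(
    list(acquire_area_px = as.integer(acquire_area_px),
         roi_a = roi_a, roi_b = roi_b, roi_engage = roi_engage,
         roi_engage_after = as.integer(roi_engage_after),
         lost_patience = as.integer(lost_patience),
         min_contrast = min_contrast, gains = gains, fps = fps,
         sensor_px = as.integer(sensor_px),
         max_speed_um_s = max_speed_um_s, pos_noise_sd = pos_noise_sd,
         search_ratio = search_ratio,
         search_amplitude_um = search_amplitude_um,
         search_freq_ratio = search_freq_ratio,
         search_speed_um_s = search_speed_um_s,
         search_delta = search_delta),
    class = "tracker_config")
}

#' Initialize tracker state
#'
#' @param config A [tracker_config()].
#' @param start_mode `"SEARCH"` or `"TRACK"` (experiments that begin with
#'   the target already in view start in TRACK).
#' @return Mutable tracker state of class `tracker_state`.
#' @export
tracker_init <- function(config, start_mode = c("TRACK", "SEARCH")) {
  start_mode <- match.arg(start_mode)
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$mode <- start_mode
  st$roi <- NULL
  st$stable_frames <- 0L
  st$lost_count <- 0L
  st$last_threshold <- NA_real_
  class(st) <- "tracker_state"
  st
}

# ROI measurement fast path: crops the ROI bounding box, thresholds the
# pixels inside the ellipse (adaptive, or the previous threshold when the
# patch has no contrast), and accumulates moments directly.
measure_in_roi <- function(px, roi, min_contrast, last_thr) {
  h <- nrow(px); w <- ncol(px)
  ca2 <- cos(roi$angle)^2; sa2 <- sin(roi$angle)^2
  ext_x <- sqrt(roi$a^2 * ca2 + roi$b^2 * sa2) + 1
  ext_y <- sqrt(roi$a^2 * sa2 + roi$b^2 * ca2) + 1
  c0 <- max(1L, floor(roi$cx - ext_x)); c1 <- min(w, ceiling(roi$cx + ext_x) + 1L)
  r0 <- max(1L, floor(roi$cy - ext_y)); r1 <- min(h, ceiling(roi$cy + ext_y) + 1L)
  empty <- list(mm = raw_moments(matrix(0L, 1, 1)), thr = last_thr)
  if (c0 > c1 || r0 > r1) return(empty)
  rows <- r0:r1; cols <- c0:c1
  nr <- length(rows)
  xs <- matrix(rep(cols - 1L, each = nr), nr)
  ys <- matrix(rep(rows - 1L, times = length(cols)), nr)
  inside <- roi_contains(roi, xs, ys)
  if (!any(inside)) return(empty)
  sub <- px[rows, cols]
  vals <- sub[inside]
  thr <- if (diff(range(vals)) < min_contrast) {
    last_thr
  } else {
    otsu_threshold(tabulate(as.integer(pmin(pmax(round(vals), 0), 255)) + 1L, 256L))
  }
  if (is.na(thr)) return(empty)
  fg <- inside & sub < thr
  if (!any(fg)) return(list(mm = empty$mm, thr = thr))
  x <- as.numeric(xs[fg]); y <- as.numeric(ys[fg])
  m00 <- length(x); m10 <- sum(x); m01 <- sum(y)
  mm <- structure(
    list(m00 = m00, m10 = m10, m01 = m01,
         m11 = sum(x * y), m20 = sum(x * x), m02 = sum(y * y),
         mu11 = sum(x * y) - m10 * m01 / m00,
         mu20 = sum(x * x) - m10^2 / m00,
         mu02 = sum(y * y) - m01^2 / m00),
    class = "moment_set")
  list(mm = mm, thr = thr)
}

#' One tracker update
#'
#' Processes a frame according to the current mode and returns the
#' measurement, the stage velocity command, and the (possibly updated)
#' mode.  In TRACK the whole frame is binarized with a per-frame
#' adaptive threshold; in TRACK_ROI all processing is restricted to the
#' ellipse propagated from the previous frame's COG and posture, and the
#' ROI for the next frame is rebuilt from this frame's state.  Empty
#' measurements increment the lost counter; valid frames never raise.
#'
#' @param trk A [tracker_init()] state (modified in place).
#' @param frame The current [new_frame()].
#' @return List with elements `target` ([target_state()] or `NULL`),
#'   `cmd_um_s` (stage velocity command, or `NULL` in SEARCH/LOST),
#'   `mode` (mode after the update), `detected` (`TRUE` on a SEARCH/LOST
#'   to TRACK transition), `roi_used`, `roi` (ROI for the next frame),
#'   `threshold` and `area`.
#' @export
tracker_update <- function(trk, frame) {
  cfg <- trk$config
  px <- frame_pixels(frame)
  cp <- (cfg$sensor_px - 1) / 2
  pitch <- frame$pixel_pitch
  roi_used <- NULL
  detected <- FALSE
  target <- NULL
  cmd <- NULL
  thr <- NA_real_
  area <- 0L

  if (trk$mode %in% c("SEARCH", "LOST")) {
    mask <- binarize(px)
    thr <- attr(mask, "threshold")
    mm <- raw_moments(mask)
    area <- mm$m00
    if (area >= cfg$acquire_area_px) {
      trk$mode <- "TRACK"
      detected <- TRUE
      trk$stable_frames <- 0L
      trk$lost_count <- 0L
      trk$last_threshold <- thr
      target <- target_state(mm, frame$frame_index)
      err_um <- (c(target$xg, target$yg) - cp) * pitch
      cmd <- servo_command(err_um, cfg$gains, cfg$max_speed_um_s)
    } else if (trk$mode == "LOST") {
      cmd <- c(0, 0)                       # hold while re-detecting
    }
  } else if (trk$mode == "TRACK") {
    mask <- binarize(px)
    thr <- attr(mask, "threshold")
    mm <- raw_moments(mask)
    area <- mm$m00
    if (area > 0L) {
      trk$lost_count <- 0L
      trk$stable_frames <- trk$stable_frames + 1L
      trk$last_threshold <- thr
      target <- target_state(mm, frame$frame_index)
      err_um <- (c(target$xg, target$yg) - cp) * pitch
      cmd <- servo_command(err_um, cfg$gains, cfg$max_speed_um_s)
      if (cfg$roi_engage == "on" &&
          trk$stable_frames >= cfg$roi_engage_after) {
        trk$mode <- "TRACK_ROI"
        trk$roi <- roi_from_state(target, cfg$roi_a, cfg$roi_b)
      }
    } else {
      trk$lost_count <- trk$lost_count + 1L
      cmd <- c(0, 0)
      if (trk$lost_count >= cfg$lost_patience) {
        trk$mode <- "LOST"
        trk$stable_frames <- 0L
        trk$roi <- NULL
      }
    }
  } else {                                 # TRACK_ROI
    roi_used <- trk$roi
    res <- measure_in_roi(px, trk$roi, cfg$min_contrast, trk$last_threshold)
    thr <- res$thr
    mm <- res$mm
    area <- mm$m00
    if (area > 0L) {
      trk$lost_count <- 0L
      trk$stable_frames <- trk$stable_frames + 1L
      trk$last_threshold <- thr
      target <- target_state(mm, frame$frame_index)
      err_um <- (c(target$xg, target$yg) - cp) * pitch
      cmd <- servo_command(err_um, cfg$gains, cfg$max_speed_um_s)
      trk$roi <- roi_from_state(target, cfg$roi_a, cfg$roi_b)
    } else {
      trk$lost_count <- trk$lost_count + 1L
      cmd <- c(0, 0)
      if (trk$lost_count >= cfg$lost_patience) {
        trk$mode <- "LOST"
        trk$stable_frames <- 0L
        trk$roi <- NULL
      }
    }
  }
  list(target = target, cmd_um_s = cmd, mode = trk$mode, detected = detected,
       roi_used = roi_used, roi = trk$roi, threshold = thr, area = area)
}

#' Run the closed tracking loop on a synthetic scene
#'
#' Per frame: the scene is rendered at the current magnification, the
#' tracker measures it and issues a stage command, the command is applied
#' after the configured actuation latency, and the scene advances.  In
#' SEARCH mode the stage instead follows the Lissajous search path
#' (position-controlled, clamped to the stage speed limit).  During a
#' `zoom`, the magnification ratio ramps linearly and the pixel pitch is
#' re-evaluated every frame, so servoing continues seamlessly through the
#' zoom.
#'
#' @param scene_cfg A [scene_config()].
#' @param trajectory A trajectory model (default [traj_static()]).
#' @param tracker A [tracker_config()].
#' @param duration_s Simulated duration in seconds.
#' @param seed Integer seed controlling all stochastic components.
#' @param optics A [mag_model()].
#' @param ratio Magnification ratio (ignored while a `zoom` is active).
#' @param zoom Optional `list(from, to, t0, duration_s)` magnification
#'   ramp (defaults: `t0 = 0`, `duration_s = 1`).
#' @param start_mode `"TRACK"` (target initially centred) or `"SEARCH"`.
#' @param stop_on Character subset of `c("detect", "lost", "target_exit")`:
#'   end the run early on first detection, on entering LOST, or when the
#'   true target leaves the FOV entirely.
#' @return List of class `track_run` with elements `record` (per-frame
#'   `data.frame`), `summary` (list), and the configurations used.
#' @export
run_tracking <- function(scene_cfg, trajectory = traj_static(),
                         tracker = tracker_config(), duration_s = 2,
                         seed = 1, optics = mag_model(), ratio = 140,
                         zoom = NULL, start_mode = c("TRACK", "SEARCH"),
                         stop_on = character(0)) {
  start_mode <- match.arg(start_mode)
  stopifnot(all(stop_on %in% c("detect", "lost", "target_exit")))
  cfg <- tracker
  dt <- 1 / cfg$fps
  n <- max(1L, round(duration_s * cfg$fps))
  sp <- cfg$sensor_px

  ratio_fn <- if (is.null(zoom)) {
    function(t) ratio
  } else {
    ratio_ramp(zoom$from, zoom$to,
               duration_s = if (is.null(zoom$duration_s)) 1 else zoom$duration_s,
               t0 = if (is.null(zoom$t0)) 0 else zoom$t0)
  }

  scene <- scene_init(scene_cfg, trajectory, seed = seed)
  stage <- stage_state(fov_center0 = scene_cfg$start_pos_um,
                       max_speed_um_s = cfg$max_speed_um_s,
                       pos_noise_sd = cfg$pos_noise_sd, seed = seed)
  trk <- tracker_init(cfg, start_mode = start_mode)
  latency <- cfg$gains$latency_frames
  cmd_queue <- matrix(0, max(1L, latency), 2L)   # ring buffer of pending commands
  # batch the position-sensing draws (same stream, same sequence as
  # drawing two values per frame)
  sense_noise <- if (cfg$pos_noise_sd > 0) {
    with_stream(stage$sense_stream,
                matrix(stats::rnorm(2 * n, 0, cfg$pos_noise_sd), n, 2,
                       byrow = TRUE))
  } else matrix(0, n, 2)

  has_target <- !is.null(scene_cfg$target)
  extent_um <- if (has_target) scene_cfg$target$extent_um else 0

  num_cols <- c("t", "area", "xg", "yg", "phi", "threshold",
                "err_x_um", "err_y_um", "meas_err_um",
                "roi_cx", "roi_cy", "roi_a", "roi_b", "roi_angle_deg",
                "ratio", "pitch_um", "cmd_vx", "cmd_vy",
                "stage_x", "stage_y", "sensed_x", "sensed_y",
                "fov_x", "fov_y", "true_x_um", "true_y_um", "heading",
                "true_err_um", "target_out")
  log <- matrix(NA_real_, n, length(num_cols),
                dimnames = list(NULL, num_cols))
  modes <- character(n)
  loss_events <- 0L
  detected_t <- NA_real_
  failure_t <- NA_real_
  k_last <- n

  for (k in seq_len(n)) {
    t <- scene$t
    r_k <- ratio_fn(t)
    pitch <- pixel_pitch(optics, r_k)
    scene <- sample_noise(scene, stage, pitch)
    fr <- render_frame(scene, stage, optics, r_k)
    mode_before <- trk$mode
    upd <- tracker_update(trk, fr)
    if (upd$mode == "LOST" && mode_before != "LOST")
      loss_events <- loss_events + 1L
    if (upd$detected && is.na(detected_t)) detected_t <- t

    fovc <- fov_center(stage)
    true_err <- if (has_target) scene$pos - fovc else c(NA_real_, NA_real_)
    true_err_um <- sqrt(sum(true_err^2))
    out_now <- has_target &&
      max(abs(true_err)) > sp / 2 * pitch + extent_um
    if (out_now && is.na(failure_t)) failure_t <- t
    if (upd$mode == "LOST" && mode_before != "LOST" && is.na(failure_t))
      failure_t <- t

    # stage actuation
    if (trk$mode == "SEARCH") {
      pos_des <- -lissajous_position(
        t + dt, cfg$search_amplitude_um, cfg$search_freq_ratio,
        base_freq_hz = cfg$search_speed_um_s /
          (2 * pi * cfg$search_amplitude_um * max(cfg$search_freq_ratio)),
        delta = cfg$search_delta)
      disp <- pos_des - stage$pos
      lim <- cfg$max_speed_um_s * dt
      cmd_applied <- pmin(pmax(disp, -lim), lim) / dt
    } else {
      cmd_now <- if (is.null(upd$cmd_um_s)) c(0, 0) else upd$cmd_um_s
      if (latency == 0L) {
        cmd_applied <- cmd_now
      } else {
        slot <- (k - 1L) %% latency + 1L
        cmd_applied <- cmd_queue[slot, ]
        cmd_queue[slot, ] <- cmd_now
      }
    }
    stage <- step_stage(stage, cmd_applied, dt, noise = sense_noise[k, ])

    tgt <- upd$target
    ru <- upd$roi_used
    log[k, ] <- c(
      t, upd$area,
      if (is.null(tgt)) c(NA, NA, NA) else c(tgt$xg, tgt$yg, tgt$phi),
      upd$threshold,
      if (is.null(tgt)) c(NA, NA, NA)
      else c((tgt$xg - (sp - 1) / 2) * pitch, (tgt$yg - (sp - 1) / 2) * pitch,
             sqrt(((tgt$xg - (sp - 1) / 2) * pitch)^2 +
                  ((tgt$yg - (sp - 1) / 2) * pitch)^2)),
      if (is.null(ru)) c(NA, NA, NA, NA, NA)
      else c(ru$cx, ru$cy, ru$a, ru$b, ru$angle * 180 / pi),
      r_k, pitch, cmd_applied,
      stage$pos, stage$sensed, fovc,
      if (has_target) scene$pos else c(NA, NA),
      scene$heading, true_err_um, as.numeric(out_now))
    modes[k] <- upd$mode

    if (("detect" %in% stop_on && upd$detected) ||
        ("lost" %in% stop_on && upd$mode == "LOST") ||
        ("target_exit" %in% stop_on && out_now)) {
      k_last <- k
      break
    }
    scene <- step_scene(scene, dt)
  }

  rec <- data.frame(frame_index = seq_len(k_last) - 1L,
                    mode = modes[seq_len(k_last)],
                    log[seq_len(k_last), , drop = FALSE])
  tracked <- rec$mode %in% c("TRACK", "TRACK_ROI") & !is.na(rec$meas_err_um)
  summary <- list(
    frames = k_last,
    duration_s = k_last * dt,
    tracked_frames = sum(tracked),
    mean_meas_err_um = if (any(tracked)) mean(rec$meas_err_um[tracked]) else NA_real_,
    mean_true_err_um = if (any(tracked)) mean(rec$true_err_um[tracked]) else NA_real_,
    sd_true_err_um = if (any(tracked)) stats::sd(rec$true_err_um[tracked]) else NA_real_,
    loss_events = loss_events,
    detected_t = detected_t,
    failure_t = failure_t,
    final_mode = rec$mode[k_last])
  structure(list(record = rec, summary = summary, tracker = cfg,
                 scene_cfg = scene_cfg, trajectory = trajectory,
                 seed = seed),
            class = "track_run")
}

#' @export
print.track_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<track_run> %d frames (%.2f s), final mode %s\n",
              s$frames, s$duration_s, s$final_mode))
  if (!is.na(s$mean_true_err_um))
    cat(sprintf("  mean true error %.2f um (sd %.2f) over %d tracked frames\n",
                s$mean_true_err_um, s$sd_true_err_um, s$tracked_frames))
  if (!is.na(s$failure_t))
    cat(sprintf("  tracking failed at t = %.3f s\n", s$failure_t))
  cat(sprintf("  loss events: %d\n", s$loss_events))
  invisible(x)
}
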