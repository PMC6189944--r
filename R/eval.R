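# Evaluation harness: seeded simulation studies reproducing the
# platform's three benchmark experiments (search time vs magnification,
# tracking error vs target velocity, tracking duration vs image-noise
# density) plus the microtool-intrusion scenario.  Every run is fully
# reproducible from its seed; per-frame records are available via the
# underlying run_tracking() calls.

#' Search-time experiment
#'
#' Beads are scattered uniformly over a square region around the initial
#' FOV position; the stage sweeps a Lissajous figure until the number of
#' dark pixels in the frame reaches the detection threshold.  The same
#' bead layout (per repeat) is used at every magnification ratio so the
#' comparison across ratios is fair.  Runs exceeding `cap_s` are
#' recorded as censored at the cap.
#'
#' @param ratios Magnification ratios to test.
#' @param repeats Repeats per ratio (default 5); each repeat has its own
#'   bead layout.
#' @param n_beads Number of scattered beads (default 20).
#' @param bead_radius_um Bead radius (default 50).
#' @param scatter_um Side of the scatter square (default 10000, i.e.
#'   10 mm x 10 mm).
#' @param cap_s Search-time cap in seconds.
#' @param seed Integer seed.
#' @param tracker A [tracker_config()].
#' @param optics A [mag_model()].
#' @return List with `table` (per-ratio mean/sd search time) and `runs`
#'   (per-run `data.frame` incl. a `censored` flag).
#' @export
run_search_time <- function(ratios = c(140, 420, 1400), repeats = 5L,
                            n_beads = 20L, bead_radius_um = 50,
                            scatter_um = 10000, cap_s = 30, seed = 1,
                            tracker = tracker_config(),
                            optics = mag_model()) {
  centre <- c(15000, 15000)
  layout_stream <- new_rng_stream(seed + 404)
  layouts <- lapply(seq_len(repeats), function(r) {
    with_stream(layout_stream, data.frame(
      x_um = stats::runif(n_beads, centre[1] - scatter_um / 2,
                          centre[1] + scatter_um / 2),
      y_um = stats::runif(n_beads, centre[2] - scatter_um / 2,
                          centre[2] + scatter_um / 2),
      radius_um = bead_radius_um))
  })
  rows <- list()
  for (ratio in ratios) {
    for (r in seq_len(repeats)) {
      cfg <- scene_config(target = NULL, beads = layouts[[r]],
                          start_pos_um = centre)
      run <- run_tracking(cfg, traj_static(), tracker,
                          duration_s = cap_s, seed = seed + r,
                          optics = optics, ratio = ratio,
                          start_mode = "SEARCH", stop_on = "detect")
      found <- !is.na(run$summary$detected_t)
      rows[[length(rows) + 1L]] <- data.frame(
        ratio = ratio, repeat_id = r,
        time_s = if (found) run$summary$detected_t else cap_s,
        censored = !found)
    }
  }
  runs <- do.call(rbind, rows)
  tab <- do.call(rbind, lapply(split(runs, runs$ratio), function(d) {
    data.frame(ratio = d$ratio[1], mean_s = mean(d$time_s),
               sd_s = stats::sd(d$time_s), censored = sum(d$censored))
  }))
  tab <- tab[order(tab$ratio), ]
  rownames(tab) <- NULL
  list(table = tab, runs = runs)
}

#' Velocity-sweep experiment
#'
#' A 100-um bead moves on a phi-2.0-mm circle at each requested speed;
#' the tracker follows under a fixed magnification, with and/or without
#' the elliptical ROI.  After a speed ramp-up and settling period, the
#' tracking error (distance between the FOV centre and the true target
#' position) is averaged over `n_samples` steady-state frames.
#'
#' @param ratios Magnification ratios.
#' @param speeds_mm_s Target speeds in mm/s (default `c(1, 5, 10, 15)`).
#' @param roi_modes Character subset of `c("on", "off")`.
#' @param n_samples Steady-state frames per point (default 1000).
#' @param settle_s Ramp + settling time before sampling (default 0.75 s,
#'   of which 0.5 s is the trajectory's speed ramp).
#' @param seed Integer seed.
#' @param tracker Base [tracker_config()]; its `roi_engage` is overridden
#'   per run.
#' @param optics A [mag_model()].
#' @return `data.frame` with per-condition mean/sd error (um) and a
#'   `lost` flag (any loss event during the measured window).
#' @export
run_velocity_sweep <- function(ratios = c(140, 1400),
                               speeds_mm_s = c(1, 5, 10, 15),
                               roi_modes = c("on", "off"),
                               n_samples = 1000L, settle_s = 0.75,
                               seed = 1, tracker = tracker_config(),
                               optics = mag_model()) {
  rows <- list()
  for (ratio in ratios) for (v in speeds_mm_s) for (rm in roi_modes) {
    cfg <- tracker
    cfg$roi_engage <- rm
    dur <- settle_s + n_samples / cfg$fps
    run <- run_tracking(
      scene_config(target = target_bead(radius_um = 50)),
      traj_circular(diameter_um = 2000, speed_um_s = v * 1000, ramp_s = 0.5),
      cfg, duration_s = dur, seed = seed, optics = optics, ratio = ratio)
    rec <- run$record
    meas <- rec[rec$t >= settle_s, ]
    rows[[length(rows) + 1L]] <- data.frame(
      ratio = ratio, velocity_mm_s = v, roi = rm,
      mean_error_um = mean(meas$true_err_um),
      sd_error_um = stats::sd(meas$true_err_um),
      lost = run$summary$loss_events > 0,
      n = nrow(meas))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Noise-robustness experiment
#'
#' A 100-um bead circles at 1 mm/s under 140x magnification.  Tracking
#' starts noise-free; once it is stable (and, for the ROI method, the ROI
#' is engaged), per-frame circular image noise at the requested density
#' is switched on, and the run continues until tracking fails or the
#' time cap is reached.  Failure means the true target has left the FOV
#' entirely (full-FOV processing keeps "tracking" noise and never sees
#' an empty frame) or the tracker declared LOST.  Noise circles are kept
#' disjoint from the ROI for both methods (same scenes).
#'
#' @param noise_counts Circles per frame (default `c(1, 5, 10, 15)`).
#' @param methods Character subset of `c("full", "roi")`: full-FOV
#'   processing vs the elliptical-ROI method.
#' @param repeats Repeats per condition (default 6).
#' @param cap_s Tracking-time cap in seconds (default 60).
#' @param speed_mm_s Target speed (default 1 mm/s).
#' @param ratio Magnification ratio (default 140).
#' @param seed Integer seed.
#' @param tracker Base [tracker_config()].
#' @param optics A [mag_model()].
#' @return List with `table` (per condition: mean tracking time) and
#'   `runs` (per-run times, `failed` flags).
#' @export
run_noise_robustness <- function(noise_counts = c(1, 5, 10, 15),
                                 methods = c("full", "roi"),
                                 repeats = 6L, cap_s = 60,
                                 speed_mm_s = 1, ratio = 140, seed = 1,
                                 tracker = tracker_config(),
                                 optics = mag_model()) {
  noise_start <- (tracker$roi_engage_after + 50) / tracker$fps
  keepout <- max(tracker$roi_a, tracker$roi_b) + 2
  rows <- list()
  for (nn in noise_counts) for (m in methods) for (r in seq_len(repeats)) {
    cfg <- tracker
    cfg$roi_engage <- if (m == "roi") "on" else "off"
    cfg$lost_patience <- tracker$lost_patience
    scn <- scene_config(
      target = target_bead(radius_um = 50),
      noise = noise_config(n = nn, keepout_px = keepout,
                           start_t = noise_start))
    run <- run_tracking(
      scn, traj_circular(diameter_um = 2000, speed_um_s = speed_mm_s * 1000,
                         ramp_s = 0.5),
      cfg, duration_s = cap_s, seed = seed + 17 * r + nn,
      optics = optics, ratio = ratio,
      stop_on = c("lost", "target_exit"))
    failed <- !is.na(run$summary$failure_t)
    rows[[length(rows) + 1L]] <- data.frame(
      noise_count = nn, method = m, repeat_id = r,
      tracking_time_s = if (failed) run$summary$failure_t else cap_s,
      failed = failed)
  }
  runs <- do.call(rbind, rows)
  tab <- do.call(rbind, lapply(
    split(runs, list(runs$noise_count, runs$method), drop = TRUE),
    function(d) data.frame(noise_count = d$noise_count[1],
                           method = d$method[1],
                           mean_time_s = mean(d$tracking_time_s),
                           n_failed = sum(d$failed))))
  tab <- tab[order(tab$method, tab$noise_count), ]
  rownames(tab) <- NULL
  list(table = tab, runs = runs, cap_s = cap_s)
}

#' Microtool-intrusion scenario
#'
#' An elongated target is held at the FOV centre at high magnification
#' while a 50-um microtool enters from the chip's open side and stops
#' short of the ROI.  With the ROI engaged the measurement never sees
#' the tool; with full-FOV processing the dark tool pulls the computed
#' COG away from the target.  A no-tool reference run with the same seed
#' quantifies the displacement.
#'
#' @param roi_mode `"on"` or `"off"`.
#' @param with_tool Render the microtool?
#' @param duration_s Run length (default 4 s).
#' @param ratio Magnification (default 840).
#' @param stop_gap_um Distance from the target centre at which the tool
#'   tip stops (default 60).
#' @param seed Integer seed.
#' @param optics A [mag_model()].
#' @return A `track_run`.
#' @export
run_tool_intrusion <- function(roi_mode = c("on", "off"), with_tool = TRUE,
                               duration_s = 4, ratio = 840,
                               stop_gap_um = 60, seed = 1,
                               optics = mag_model()) {
  roi_mode <- match.arg(roi_mode)
  start <- c(15000, 15000)
  tool <- if (with_tool) {
    tool_config(y_um = start[2], start_x_um = start[1] + 600,
                stop_x_um = start[1] + stop_gap_um,
                speed_um_s = 300, start_t = 0.5)
  } else NULL
  preset <- roi_preset("paramecium")
  cfg <- tracker_config(roi_a = preset$a, roi_b = preset$b,
                        roi_engage = roi_mode)
  # vertical body axis: the tool approaches perpendicular to the target,
  # so the ROI's short axis faces it
  scn <- scene_config(
    target = target_ellipse(half_length_um = 75, half_width_um = 15),
    start_pos_um = start, start_heading = pi / 2, tool = tool)
  run_tracking(scn, traj_custom(function(t) start), cfg,
               duration_s = duration_s, seed = seed, optics = optics,
               ratio = ratio)
}
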