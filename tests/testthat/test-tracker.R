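# State machine and closed-loop behaviour.

test_that("a stationary off-centre target is centred within 50 frames", {
  # start the FOV 300 um away from the bead
  cfg <- scene_config(target = target_bead(),
                      start_pos_um = c(15000, 15000))
  tk <- tracker_config(roi_engage = "off", pos_noise_sd = 0)
  scene <- scene_init(cfg, traj_static(), seed = 1)
  stage <- stage_state(fov_center0 = c(15300, 14800), seed = 1,
                       pos_noise_sd = 0)
  trk <- tracker_init(tk, "TRACK")
  optics <- mag_model()
  pending <- c(0, 0)
  for (k in 1:50) {
    fr <- render_frame(scene, stage, optics, 140)
    upd <- tracker_update(trk, fr)
    step_stage(stage, pending, 1 / 500)
    pending <- if (is.null(upd$cmd_um_s)) c(0, 0) else upd$cmd_um_s
  }
  err <- sqrt(sum((cfg$start_pos_um - fov_center(stage))^2))
  expect_lt(err / pixel_pitch(optics, 140), 1)   # within 1 px of centre
})

test_that("detection fires exactly at the acquire-area threshold", {
  tk <- tracker_config(acquire_area_px = 50)
  trk <- tracker_init(tk, "SEARCH")
  px <- matrix(200, 256, 256)
  px[1:7, 1:7] <- 20                     # 49 dark pixels: below threshold
  upd <- tracker_update(trk, new_frame(px))
  expect_equal(upd$mode, "SEARCH")
  expect_false(upd$detected)
  px[1:10, 1:5] <- 20                    # 50 + 21 new pixels: detection
  upd <- tracker_update(trk, new_frame(px))
  expect_true(upd$detected)
  expect_equal(upd$mode, "TRACK")
})

test_that("mode sequences are legal and LOST requires patience", {
  tk <- tracker_config(roi_engage = "off", lost_patience = 5)
  trk <- tracker_init(tk, "TRACK")
  dark <- matrix(200, 64, 64); dark[30:34, 30:34] <- 20
  blank <- matrix(200, 64, 64)
  tkc <- function(px) tracker_update(trk, new_frame(px))$mode
  expect_equal(tkc(dark), "TRACK")
  for (k in 1:4) expect_equal(tkc(blank), "TRACK")   # patience not yet over
  expect_equal(tkc(blank), "LOST")                   # 5th empty frame
  # re-detection needs the acquire threshold again
  small <- matrix(200, 64, 64); small[30:31, 30:31] <- 20
  expect_equal(tkc(small), "LOST")                   # 4 px < 50
  expect_equal(tkc(dark), "LOST")                    # 25 px < 50
  big <- matrix(200, 64, 64); big[20:30, 20:30] <- 20
  expect_equal(tkc(big), "TRACK")
})

test_that("mode log of a full run never shows TRACK before detection", {
  cfg <- scene_config(target = target_bead(),
                      beads = NULL, start_pos_um = c(15000, 15000))
  run <- run_tracking(cfg, traj_static(), tracker_config(),
                      duration_s = 0.5, seed = 2, start_mode = "SEARCH")
  modes <- run$record$mode
  first_track <- match("TRACK", modes)
  expect_false(is.na(first_track))       # target sits at the start point
  if (first_track > 1)
    expect_true(all(modes[1:(first_track - 1)] == "SEARCH"))
})

test_that("ROI-on and full-FOV COG traces agree in a noiseless scene", {
  cfg <- scene_config(target = target_bead())
  mk <- function(mode) run_tracking(
    cfg, traj_circular(speed_um_s = 1000),
    tracker_config(roi_engage = mode), duration_s = 1.2, seed = 3,
    ratio = 140)$record
  on <- mk("on"); off <- mk("off")
  expect_lt(max(abs(on$xg - off$xg), abs(on$yg - off$yg), na.rm = TRUE), 0.5)
})

test_that("ROI tracking through a seamless zoom never loses the target", {
  cfg <- scene_config(target = target_bead())
  run <- run_tracking(cfg, traj_circular(speed_um_s = 1000),
                      tracker_config(roi_engage = "on"),
                      duration_s = 2.2, seed = 4, ratio = 140,
                      zoom = list(from = 140, to = 840, t0 = 0.8,
                                  duration_s = 1))
  expect_equal(run$summary$loss_events, 0)
  expect_false(any(run$record$mode == "LOST"))
  expect_equal(tail(run$record$pitch_um, 1), pixel_pitch(mag_model(), 840))
})

test_that("a degenerate zoom equals plain tracking at that ratio", {
  cfg <- scene_config(target = target_bead())
  tk <- tracker_config(roi_engage = "on")
  a <- run_tracking(cfg, traj_circular(speed_um_s = 1000), tk,
                    duration_s = 0.8, seed = 5, ratio = 420,
                    zoom = list(from = 420, to = 420, t0 = 0, duration_s = 1))
  b <- run_tracking(cfg, traj_circular(speed_um_s = 1000), tk,
                    duration_s = 0.8, seed = 5, ratio = 420)
  expect_identical(a$record$xg, b$record$xg)
  expect_identical(a$record$stage_x, b$record$stage_x)
})

test_that("targets beyond the servo capability are declared lost", {
  # 80 mm/s at 1400x: per-frame displacement far exceeds the capture range
  cfg <- scene_config(target = target_bead())
  run <- run_tracking(cfg, traj_circular(diameter_um = 8000,
                                         speed_um_s = 80000, ramp_s = 0.1),
                      tracker_config(roi_engage = "on"),
                      duration_s = 2, seed = 6, ratio = 1400,
                      stop_on = c("lost", "target_exit"))
  expect_false(is.na(run$summary$failure_t))
})

test_that("closed-loop runs are reproducible from their seed", {
  cfg <- scene_config(target = target_bead(),
                      noise = noise_config(n = 5, keepout_px = 22,
                                           start_t = 0.1))
  mk <- function() run_tracking(cfg, traj_run_and_turn(), tracker_config(),
                                duration_s = 0.6, seed = 7)$record
  expect_identical(mk(), mk())
})
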