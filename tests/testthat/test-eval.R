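# Evaluation harness smoke checks (small grids; the full experiments run
# in test-acceptance.R).

test_that("search experiment reuses layouts across ratios and is seeded", {
  a <- run_search_time(ratios = c(140, 840), repeats = 2, cap_s = 10,
                       seed = 11)
  b <- run_search_time(ratios = c(140, 840), repeats = 2, cap_s = 10,
                       seed = 11)
  expect_identical(a$runs, b$runs)
  expect_equal(nrow(a$table), 2)
  expect_true(all(a$runs$time_s >= 0 & a$runs$time_s <= 10))
})

test_that("a bead already in the initial FOV is found almost immediately", {
  # single bead exactly at the search start point
  beads <- data.frame(x_um = 15000, y_um = 15000, radius_um = 50)
  for (ratio in c(140, 1400)) {
    cfg <- scene_config(target = NULL, beads = beads,
                        start_pos_um = c(15000, 15000))
    run <- run_tracking(cfg, traj_static(), tracker_config(),
                        duration_s = 1, seed = 1, ratio = ratio,
                        start_mode = "SEARCH", stop_on = "detect")
    expect_lt(run$summary$detected_t, 0.01)
  }
})

test_that("velocity sweep reports the noise floor at zero speed", {
  sw <- run_velocity_sweep(ratios = 140, speeds_mm_s = 0, roi_modes = "off",
                           n_samples = 150, seed = 12)
  expect_lt(sw$mean_error_um, 1)
  expect_false(sw$lost)
})

test_that("velocity sweep output covers the requested grid", {
  sw <- run_velocity_sweep(ratios = 140, speeds_mm_s = c(1, 5),
                           roi_modes = c("on", "off"), n_samples = 100,
                           seed = 13)
  expect_equal(nrow(sw), 4)
  expect_equal(sort(unique(sw$velocity_mm_s)), c(1, 5))
  expect_true(all(sw$n == 100))
})

test_that("noise robustness: ROI method reaches the cap, full-FOV fails fast", {
  res <- run_noise_robustness(noise_counts = 15, methods = c("full", "roi"),
                              repeats = 2, cap_s = 2, seed = 14)
  roi_rows <- res$runs[res$runs$method == "roi", ]
  full_rows <- res$runs[res$runs$method == "full", ]
  expect_true(all(!roi_rows$failed))
  expect_true(all(roi_rows$tracking_time_s == 2))
  expect_true(all(full_rows$failed))
})

test_that("experiment tables trace back to reproducible per-run rows", {
  res <- run_noise_robustness(noise_counts = c(1, 15), methods = "roi",
                              repeats = 2, cap_s = 1, seed = 15)
  agg <- tapply(res$runs$tracking_time_s, res$runs$noise_count, mean)
  expect_equal(as.numeric(agg[as.character(res$table$noise_count)]),
               res$table$mean_time_s)
})
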