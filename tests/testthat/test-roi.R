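# Rotated-ellipse ROI construction, membership and masking.

test_that("circle ROI has the expected boundary points", {
  r <- ellipse_roi(0, 0, a = 20, b = 20)
  expect_true(roi_contains(r, 20, 0))
  expect_true(roi_contains(r, 0, 20))
  expect_false(roi_contains(r, 21, 0))
  expect_true(roi_contains(r, r$cx, r$cy))
})

test_that("rotated elongated ROI matches the ellipse equation", {
  r <- ellipse_roi(0, 0, a = 100, b = 20, angle = pi / 2)
  expect_true(roi_contains(r, 0, 100))    # on the boundary along the major axis
  expect_false(roi_contains(r, 30, 0))    # LHS = 30^2/20^2 = 2.25
})

test_that("a < b is normalized by swapping axes and rotating", {
  r <- ellipse_roi(0, 0, a = 20, b = 100, angle = 0)
  expect_equal(c(r$a, r$b), c(100, 20))
  expect_true(roi_contains(r, 0, 100))
  expect_false(roi_contains(r, 30, 0))
})

test_that("circular ROI membership is independent of the angle", {
  set.seed(3)
  pts <- matrix(stats::runif(200, -30, 30), ncol = 2)
  r1 <- ellipse_roi(5, -2, 20, 20, angle = 0)
  r2 <- ellipse_roi(5, -2, 20, 20, angle = 1.1)
  expect_identical(roi_contains(r1, pts[, 1], pts[, 2]),
                   roi_contains(r2, pts[, 1], pts[, 2]))
})

test_that("membership agrees with a brute-force rotate-then-scale oracle", {
  set.seed(11)
  for (k in 1:5) {
    r <- ellipse_roi(stats::runif(1, -10, 10), stats::runif(1, -10, 10),
                     a = stats::runif(1, 5, 60), b = stats::runif(1, 2, 40),
                     angle = stats::runif(1, -pi / 2, pi / 2))
    x <- stats::runif(200, -80, 80); y <- stats::runif(200, -80, 80)
    expect_identical(roi_contains(r, x, y), naive_inside(r, x, y))
  }
})

test_that("roi_from_state centres and orients the ROI on the previous state", {
  mask <- ellipse_mask(64, 64, 30, 25, a = 12, b = 4, angle = 0.6)
  ts <- target_state(raw_moments(mask))
  r <- roi_from_state(ts, a = 20, b = 8)
  expect_equal(c(r$cx, r$cy), c(ts$xg, ts$yg))
  expect_equal(r$angle, ts$phi)
  expect_error(roi_from_state(NULL, 20, 8))
})

test_that("masking is idempotent, monotone and clips to the frame", {
  set.seed(5)
  mask <- random_mask(50, 50, 0.3)
  r <- ellipse_roi(25, 20, 15, 7, angle = 0.4)
  once <- mask_within(mask, r)
  expect_identical(mask_within(once, r), once)
  expect_lte(sum(once), sum(mask))
  # ROI entirely outside the frame -> empty mask, no error
  far <- ellipse_roi(500, 500, 20, 20)
  expect_equal(sum(mask_within(mask, far)), 0)
  # ROI covering the whole frame -> unchanged
  all_r <- ellipse_roi(25, 25, 200, 200)
  expect_identical(mask_within(mask, all_r), mask, ignore_attr = TRUE)
})

test_that("foreground outside the ROI never changes the measurement", {
  base <- matrix(0L, 64, 64)
  base[28:36, 30:38] <- 1L
  r <- ellipse_roi(34, 32, 10, 10)
  ref <- raw_moments(mask_within(base, r))
  set.seed(9)
  for (k in 1:20) {
    noisy <- base
    # add blobs strictly outside the ROI
    cx <- sample(0:63, 1); cy <- sample(0:63, 1)
    if (sqrt((cx - 34)^2 + (cy - 32)^2) < 16) next
    noisy[max(1, cy - 1):min(64, cy + 1), max(1, cx - 1):min(64, cx + 1)] <- 1L
    got <- raw_moments(mask_within(noisy, r))
    expect_identical(got, ref)
    # and via the region argument of raw_moments
    expect_identical(raw_moments(noisy, region = r), raw_moments(base, region = r))
  }
})

test_that("presets carry the standard experiment geometries", {
  expect_equal(roi_preset("bead"), list(a = 20, b = 20))
  expect_equal(roi_preset("paramecium"), list(a = 100, b = 20))
})
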