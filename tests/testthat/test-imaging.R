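# Binarization, image moments, COG and posture.

test_that("adaptive threshold separates a dark block from the background", {
  px <- matrix(200, 64, 64)
  px[21:30, 31:40] <- 20
  m <- binarize(px)
  expect_equal(sum(m), 100)
  thr <- attr(m, "threshold")
  expect_true(thr > 20 && thr < 200)
})

test_that("uniform and all-white frames give all-background masks", {
  expect_equal(sum(binarize(matrix(255, 32, 32))), 0)
  expect_equal(sum(binarize(matrix(123, 32, 32))), 0)
  expect_true(is.na(attr(binarize(matrix(123, 32, 32)), "threshold")))
})

test_that("global illumination shift leaves the adaptive mask unchanged", {
  px <- matrix(170, 48, 48)
  px[10:19, 5:14] <- 20
  px[30:35, 30:42] <- 55           # second dark blob with its own level
  m0 <- binarize(px)
  m1 <- binarize(px + 30)
  expect_identical(m0, m1, ignore_attr = TRUE)
  expect_equal(attr(m1, "threshold") - attr(m0, "threshold"), 30)
})

test_that("fixed-level binarization marks pixels strictly darker", {
  px <- matrix(c(10, 50, 50, 90), 2, 2)
  m <- binarize(px, method = "fixed", fixed_level = 50)
  expect_equal(as.vector(m), c(1L, 0L, 0L, 0L))
})

test_that("raw moments match the spec'd hand-computed examples", {
  m <- matrix(0L, 10, 10)
  m[5, 4] <- 1L                    # (x, y) = (3, 4)
  ms <- raw_moments(m)
  expect_equal(c(ms$m00, ms$m10, ms$m01), c(1, 3, 4))
  expect_equal(unname(centroid(ms)), c(3, 4))

  m2 <- matrix(0L, 12, 12)
  m2[6:8, 5:6] <- 1L               # x in {4,5}, y in {5,6,7}
  ms2 <- raw_moments(m2)
  expect_equal(c(ms2$m00, ms2$m10, ms2$m01), c(6, 27, 36))
  expect_equal(unname(centroid(ms2)), c(4.5, 6))
})

test_that("moments agree exactly with a naive double-loop oracle", {
  set.seed(42)
  for (k in 1:60) {
    h <- sample(4:32, 1); w <- sample(4:32, 1)
    mask <- random_mask(h, w, p = stats::runif(1, 0.05, 0.5))
    got <- raw_moments(mask)
    want <- naive_moments(mask)
    expect_identical(unlist(got[c("m00", "m10", "m01", "m11", "m20", "m02")]),
                     want, ignore_attr = TRUE)
  }
})

test_that("centroid of an empty mask raises a catchable no-target condition", {
  ms <- raw_moments(matrix(0L, 8, 8))
  expect_true(is_empty_moments(ms))
  expect_error(centroid(ms), class = "servotrack_no_target")
  expect_error(orientation(ms), class = "servotrack_no_target")
  expect_null(target_state(ms))
})

test_that("orientation follows the axis of simple pixel sets", {
  horiz <- matrix(0L, 5, 5); horiz[2, 1:3] <- 1L
  expect_equal(orientation(raw_moments(horiz)), 0)
  diagm <- matrix(0L, 5, 5); diagm[cbind(1:3, 1:3)] <- 1L
  expect_equal(orientation(raw_moments(diagm)), pi / 4)
  single <- matrix(0L, 5, 5); single[3, 3] <- 1L
  expect_equal(orientation(raw_moments(single)), 0)
})

test_that("translation shifts the centroid exactly and preserves shape moments", {
  set.seed(7)
  for (k in 1:20) {
    mask <- matrix(0L, 40, 40)
    mask[5:12, 6:14] <- random_mask(8, 9, 0.5)
    if (sum(mask) == 0) next
    dx <- sample(0:20, 1); dy <- sample(0:20, 1)
    shifted <- matrix(0L, 40, 40)
    shifted[5:12 + dy, 6:14 + dx] <- mask[5:12, 6:14]
    a <- raw_moments(mask); b <- raw_moments(shifted)
    expect_equal(unname(centroid(b) - centroid(a)), c(dx, dy))
    expect_equal(b$mu11, a$mu11)
    expect_equal(b$mu20, a$mu20)
    expect_equal(b$mu02, a$mu02)
    expect_equal(orientation(b), orientation(a))
  }
})

test_that("rotating an eccentric ellipse rotates the posture estimate", {
  for (ang in c(-1.2, -0.5, 0, 0.3, 0.9, 1.4)) {
    mask <- ellipse_mask(101, 101, 50, 50, a = 30, b = 8, angle = ang)
    expect_gt(sum(mask), 500)
    phi <- orientation(raw_moments(mask))
    expect_lt(axis_diff(phi, ang), 3 * pi / 180)
  }
})

test_that("centroid and mask agree with EBImage on a random blob", {
  px <- matrix(200, 64, 64)
  px[15:40, 10:30] <- 20
  px[10:14, 40:60] <- 30
  mine <- binarize(px)
  th_eb <- EBImage::otsu(EBImage::Image(t(px) / 255), range = c(0, 1),
                         levels = 256) * 255
  expect_identical(mine == 1L, px < th_eb)      # same partition
  fm <- EBImage::computeFeatures.moment(EBImage::Image(t(mine)))
  expect_equal(unname(centroid(raw_moments(mine))),
               c(fm[1, "m.cx"] - 1, fm[1, "m.cy"] - 1), tolerance = 1e-8)
})
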