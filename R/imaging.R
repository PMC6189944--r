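# Moment-based target measurement: binarization, image moments up to
# order two, centre of gravity (COG) and posture angle.
#
# The tracked organisms appear dark on a bright brightfield background, so
# foreground (value 1 in a mask) means "darker than the threshold".  All
# geometry uses the 0-based pixel coordinates documented in frame.R.

#' Otsu threshold of an intensity histogram
#'
#' Maximizes the between-class variance over all split points of a 256-bin
#' histogram of 8-bit intensities.  Returns the threshold as a half-integer
#' `t* + 0.5` lying strictly between the two classes, so that the
#' foreground rule `intensity < threshold` is equivalent to
#' `intensity <= t*`.  Shifting every intensity by a constant shifts the
#' returned threshold by exactly the same constant, which is what makes
#' per-frame adaptive thresholding immune to global illumination drift.
#'
#' @param counts Integer vector of length 256: histogram of intensities
#'   0..255.
#' @return Numeric threshold, or `NA` if the histogram has fewer than two
#'   occupied bins (no meaningful split).
#' @export
otsu_threshold <- function(counts) {
  stopifnot(length(counts) == 256L)
  total <- sum(counts)
  if (total == 0 || sum(counts > 0) < 2L) return(NA_real_)
  counts <- as.numeric(counts)      # avoid integer overflow in the sums
  levels <- as.numeric(0:255)
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * levels)
  mt <- m0[256L]
  w1 <- total - w0
  # between-class variance for split "class0 = levels <= t"
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, 256L)
  sb[valid] <- (mt * w0[valid] / total - m0[valid])^2 /
    (w0[valid] / total * w1[valid] / total) / total^2
  t_star <- which.max(sb) - 1L   # smallest maximizer: deterministic tie-break
  t_star + 0.5
}

#' Binarize a frame into a foreground mask
#'
#' Foreground (1) marks pixels strictly darker than the threshold.  With
#' `method = "adaptive"` the threshold is recomputed on the frame's own
#' intensity histogram (per-frame Otsu), which compensates global
#' illumination changes; with `method = "fixed"` the supplied
#' `fixed_level` is used.  If `roi` is given, only pixels inside the
#' ellipse are considered: the threshold (when adaptive) is computed from
#' those pixels alone and the returned mask is zero outside the ROI.
#'
#' A frame with (near-)uniform intensity has no meaningful adaptive split
#' and yields an all-background mask.
#'
#' @param frame A [new_frame()] object or bare intensity matrix.
#' @param method `"adaptive"` (default) or `"fixed"`.
#' @param fixed_level Threshold intensity for `method = "fixed"`.
#' @param roi Optional [ellipse_roi()] restricting the computation.
#' @return Integer 0/1 matrix of the frame's shape, with the threshold
#'   actually used attached as attribute `"threshold"` (`NA` when the
#'   adaptive method found no split).
#' @examples
#' px <- matrix(200, 64, 64)
#' px[20:29, 30:39] <- 20
#' m <- binarize(px)
#' sum(m)  # 100 foreground pixels
#' @export
binarize <- function(frame, method = c("adaptive", "fixed"),
                     fixed_level = NULL, roi = NULL) {
  method <- match.arg(method)
  px <- frame_pixels(frame)
  h <- nrow(px); w <- ncol(px)
  scope <- NULL
  if (!is.null(roi)) {
    xs <- matrix(rep(0:(w - 1L), each = h), h, w)
    ys <- matrix(rep(0:(h - 1L), times = w), h, w)
    scope <- roi_contains(roi, xs, ys)
  }
  vals <- if (is.null(scope)) px else px[scope]
  thr <- if (method == "adaptive") {
    counts <- tabulate(as.integer(pmin(pmax(round(vals), 0), 255)) + 1L, 256L)
    otsu_threshold(counts)
  } else {
    if (is.null(fixed_level)) stop("`fixed_level` required for method = \"fixed\"")
    as.numeric(fixed_level)
  }
  mask <- matrix(0L, h, w)
  if (!is.na(thr)) {
    fg <- px < thr
    if (!is.null(scope)) fg <- fg & scope
    mask[fg] <- 1L
  }
  attr(mask, "threshold") <- thr
  mask
}

#' Raw and central image moments of a binary mask
#'
#' Computes the six raw moments `m00, m10, m01, m11, m20, m02` of the
#' foreground pixels (sums of x^i y^j over pixels with value 1) and the
#' derived central moments `mu11, mu20, mu02`.  If `region` is given, only
#' foreground pixels inside the elliptical region contribute.
#'
#' @param mask Binary 0/1 matrix (e.g. from [binarize()]).
#' @param region Optional [ellipse_roi()]; pixels outside it are ignored.
#' @return An object of class `moment_set`.  An empty foreground yields
#'   the all-zero (empty) moment set.
#' @examples
#' m <- matrix(0L, 10, 10)
#' m[5, 4] <- 1L             # pixel (x, y) = (3, 4)
#' raw_moments(m)$m10
#' @export
raw_moments <- function(mask, region = NULL) {
  idx <- which(mask == 1L)
  if (length(idx)) {
    h <- nrow(mask)
    x <- (idx - 1L) %/% h          # 0-based column
    y <- (idx - 1L) %% h           # 0-based row
    if (!is.null(region)) {
      keep <- roi_contains(region, x, y)
      x <- x[keep]; y <- y[keep]
    }
  } else {
    x <- y <- integer(0)
  }
  m00 <- length(x)
  if (m00 == 0L) {
    return(structure(
      list(m00 = 0, m10 = 0, m01 = 0, m11 = 0, m20 = 0, m02 = 0,
           mu11 = 0, mu20 = 0, mu02 = 0),
      class = "moment_set"))
  }
  x <- as.numeric(x); y <- as.numeric(y)
  m10 <- sum(x); m01 <- sum(y)
  m11 <- sum(x * y); m20 <- sum(x * x); m02 <- sum(y * y)
  structure(
    list(m00 = m00, m10 = m10, m01 = m01, m11 = m11, m20 = m20, m02 = m02,
         mu11 = m11 - m10 * m01 / m00,
         mu20 = m20 - m10^2 / m00,
         mu02 = m02 - m01^2 / m00),
    class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf("<moment_set> m00 = %g", x$m00))
  if (x$m00 > 0)
    cat(sprintf(", cog = (%.3f, %.3f)", x$m10 / x$m00, x$m01 / x$m00))
  cat("\n")
  invisible(x)
}

#' Is a moment set empty (no foreground)?
#' @param m A `moment_set`.
#' @return Logical.
#' @export
is_empty_moments <- function(m) m$m00 == 0

no_target_condition <- function(call = sys.call(-1)) {
  structure(
    class = c("servotrack_no_target", "error", "condition"),
    list(message = "no target: zero foreground pixels (m00 = 0)", call = call))
}

#' Centre of gravity from image moments
#'
#' `(xg, yg) = (m10 / m00, m01 / m00)` in pixel coordinates.
#'
#' @param m A `moment_set` from [raw_moments()].
#' @return Numeric `c(xg, yg)`.  An empty moment set raises a catchable
#'   condition of class `servotrack_no_target` (never a silent `NaN`).
#' @export
centroid <- function(m) {
  if (is_empty_moments(m)) stop(no_target_condition())
  c(xg = m$m10 / m$m00, yg = m$m01 / m$m00)
}

#' Posture angle from image moments
#'
#' `phi = atan2(2 mu11, mu20 - mu02) / 2`, using central moments so that
#' the posture is invariant to the target's position in the frame.  The
#' angle describes an undirected body axis and lies in `(-pi/2, pi/2]`;
#' an isotropic foreground (mu11 = 0 and mu20 = mu02) gives `phi = 0` by
#' convention (atan2(0, 0) = 0).
#'
#' @param m A `moment_set` from [raw_moments()].
#' @return Posture angle in radians.
#' @export
orientation <- function(m) {
  if (is_empty_moments(m)) stop(no_target_condition())
  atan2(2 * m$mu11, m$mu20 - m$mu02) / 2
}

#' Target state (COG, posture, area) from a moment set
#'
#' @param m A `moment_set`.
#' @param frame_index Frame index to record.
#' @return Object of class `target_state` with fields `xg`, `yg`, `phi`,
#'   `area`, `frame_index`, or `NULL` if the moment set is empty.
#' @export
target_state <- function(m, frame_index = 0L) {
  if (is_empty_moments(m)) return(NULL)
  cg <- centroid(m)
  structure(
    list(xg = unname(cg[1]), yg = unname(cg[2]), phi = orientation(m),
         area = m$m00, frame_index = as.integer(frame_index)),
    class = "target_state")
}

#' @export
print.target_state <- function(x, ...) {
  cat(sprintf("<target_state> cog = (%.2f, %.2f) px, phi = %.1f deg, area = %d px, frame %d\n",
              x$xg, x$yg, x$phi * 180 / pi, x$area, x$frame_index))
  invisible(x)
}
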