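# Rotated-ellipse region of interest (ROI).  At frame k the ROI is built
# from frame k-1's measured COG and posture, so that only pixels around
# the target are processed: image noise elsewhere in the FOV can never
# touch the measurement, and per-frame processing cost stays small.

#' Construct a rotated elliptical ROI
#'
#' The ROI interior is the set of pixel coordinates `(x, y)` with
#' `u^2/a^2 + v^2/b^2 <= 1`, where `(u, v)` are the coordinates of
#' `(x - cx, y - cy)` rotated by `-angle`.  Boundary points count as
#' inside.  If `a < b`, the axes are swapped and the angle rotated by
#' pi/2 so that `a` is always the semimajor axis.
#'
#' @param cx,cy Centre in pixel coordinates.
#' @param a,b Semimajor and semiminor axes in pixels (`> 0`).
#' @param angle Rotation of the major axis in radians; stored wrapped to
#'   `(-pi/2, pi/2]` (an ellipse is symmetric under rotation by pi).
#' @return Object of class `ellipse_roi`.
#' @examples
#' r <- ellipse_roi(0, 0, a = 100, b = 20, angle = pi / 2)
#' roi_contains(r, 0, 100)   # on the boundary -> TRUE
#' roi_contains(r, 30, 0)    # outside -> FALSE
#' @export
ellipse_roi <- function(cx, cy, a, b, angle = 0) {
  if (!(a > 0) || !(b > 0)) stop("axes `a` and `b` must be positive")
  if (a < b) {        # normalize: swap axes, rotate by pi/2
    tmp <- a; a <- b; b <- tmp
    angle <- angle + pi / 2
  }
  angle <- wrap_half_pi(angle)
  structure(list(cx = as.numeric(cx), cy = as.numeric(cy),
                 a = as.numeric(a), b = as.numeric(b),
                 angle = angle),
            class = "ellipse_roi")
}

# wrap an undirected-axis angle into (-pi/2, pi/2]
wrap_half_pi <- function(angle) {
  a <- (angle + pi / 2) %% pi
  if (a == 0) a <- pi
  a - pi / 2
}

#' @export
print.ellipse_roi <- function(x, ...) {
  cat(sprintf("<ellipse_roi> centre (%.2f, %.2f), a = %.1f, b = %.1f px, angle = %.1f deg\n",
              x$cx, x$cy, x$a, x$b, x$angle * 180 / pi))
  invisible(x)
}

#' ROI from the previous frame's target state
#'
#' Centres the ellipse at the previous COG and aligns the major axis with
#' the previous posture angle: the frame-to-frame ROI propagation rule.
#'
#' @param prev A valid [target_state()] (`area > 0`).
#' @param a,b Semi-axes in pixels (see [roi_preset()] for the standard
#'   experiment values).
#' @return An [ellipse_roi()].
#' @export
roi_from_state <- function(prev, a, b) {
  if (is.null(prev) || prev$area <= 0)
    stop("previous target state is invalid (area must be > 0)")
  ellipse_roi(prev$xg, prev$yg, a = a, b = b, angle = prev$phi)
}

#' ROI membership test
#'
#' Evaluates the ellipse equation at `(x, y)`; values `<= 1` (within a
#' 1e-9 relative tolerance absorbing rotation round-off) are inside.
#' Vectorized over `x` and `y`.
#'
#' @param roi An [ellipse_roi()].
#' @param x,y Pixel coordinates (numeric vectors or matrices).
#' @return Logical of the same shape as `x`.
#' @export
roi_contains <- function(roi, x, y) {
  ca <- cos(roi$angle); sa <- sin(roi$angle)
  dx <- x - roi$cx; dy <- y - roi$cy
  u <- dx * ca + dy * sa
  v <- -dx * sa + dy * ca
  (u / roi$a)^2 + (v / roi$b)^2 <= 1 + 1e-9
}

#' Restrict a binary mask to an ROI
#'
#' Output foreground is the input foreground intersected with the ROI
#' interior; everything outside the ellipse is set to 0.  An ROI lying
#' entirely outside the frame simply yields an empty mask (imminent
#' target loss is the tracker's decision, not an error here).
#'
#' @param mask Binary 0/1 matrix.
#' @param roi An [ellipse_roi()].
#' @return Binary matrix of the same shape.
#' @export
mask_within <- function(mask, roi) {
  h <- nrow(mask); w <- ncol(mask)
  # only pixels in the ROI's bounding box need testing
  ext <- max(roi$a, roi$b)
  c0 <- max(1L, floor(roi$cx - ext) + 1L); c1 <- min(w, ceiling(roi$cx + ext) + 1L)
  r0 <- max(1L, floor(roi$cy - ext) + 1L); r1 <- min(h, ceiling(roi$cy + ext) + 1L)
  out <- matrix(0L, h, w)
  if (c0 > c1 || r0 > r1) return(out)
  rows <- r0:r1; cols <- c0:c1
  xs <- matrix(rep(cols - 1L, each = length(rows)), length(rows))
  ys <- matrix(rep(rows - 1L, times = length(cols)), length(rows))
  inside <- roi_contains(roi, xs, ys)
  out[rows, cols] <- mask[rows, cols] * inside
  out
}

#' Standard ROI size presets
#'
#' `"bead"`: circular ROI `a = b = 20` px, sized for a 100-um polystyrene
#' bead seen at 140x magnification.  `"paramecium"`: elongated ROI
#' `a = 100, b = 20` px matching the body of a swimming *Paramecium* at
#' 840x.
#'
#' @param which `"bead"` or `"paramecium"`.
#' @return List with elements `a` and `b` (pixels).
#' @export
roi_preset <- function(which = c("bead", "paramecium")) {
  switch(match.arg(which),
         bead = list(a = 20, b = 20),
         paramecium = list(a = 100, b = 20))
}
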