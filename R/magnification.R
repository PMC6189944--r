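# Magnification-dependent optics model.  Of the three optics parameters
# tied to the magnification dial (pixel pitch, focal length, light
# intensity), only the pixel pitch acts directly on the tracking loop and
# is modelled numerically, from a measured calibration table of
# magnification ratio -> pixel pitch.  Focal-length and light-intensity
# hooks exist as stubs for a hardware port; illumination variation is
# instead emulated by the scene generator to exercise the adaptive
# threshold.

#' Default pixel-pitch calibration table
#'
#' Ten measured calibration points of the simulated instrument: the
#' seamless-zoom microscope spans ratios 140x to 1400x with pixel pitch
#' falling from 5.50 to 0.79 um/pixel.
#'
#' @return `data.frame` with columns `ratio` and `pitch_um`.
#' @export
default_calibration <- function() {
  data.frame(
    ratio = c(140, 210, 280, 420, 560, 700, 840, 980, 1120, 1400),
    pitch_um = c(5.50, 4.80, 3.50, 2.20, 1.66, 1.29, 1.09, 0.92, 0.85, 0.79)
  )
}

#' Magnification model from a calibration table
#'
#' Builds a shape-preserving monotone piecewise-cubic interpolant
#' (Fritsch-Carlson, `stats::splinefun(method = "monoH.FC")`) through the
#' calibration points.  The interpolant is exact at every calibration
#' point and strictly decreasing in between, as the physical pitch must
#' be: no overshoot is possible.
#'
#' @param calibration `data.frame` with strictly increasing `ratio` and
#'   strictly decreasing `pitch_um` columns; defaults to
#'   [default_calibration()].
#' @param sensor_pixels Sensor side length in pixels (default 256).
#' @return Object of class `mag_model`.
#' @examples
#' m <- mag_model()
#' pixel_pitch(m, 840)
#' fov_side(m, 140)
#' @export
mag_model <- function(calibration = default_calibration(), sensor_pixels = 256L) {
  stopifnot(is.data.frame(calibration),
            all(c("ratio", "pitch_um") %in% names(calibration)),
            nrow(calibration) >= 2L)
  r <- calibration$ratio; p <- calibration$pitch_um
  if (any(diff(r) <= 0)) stop("calibration ratios must be strictly increasing")
  if (any(diff(p) >= 0)) stop("calibration pitches must be strictly decreasing")
  structure(
    list(calibration = calibration,
         interpolant = stats::splinefun(r, p, method = "monoH.FC"),
         sensor_pixels = as.integer(sensor_pixels),
         range = range(r)),
    class = "mag_model")
}

#' @export
print.mag_model <- function(x, ...) {
  cat(sprintf("<mag_model> %d calibration points, ratio %g-%gx, sensor %d px\n",
              nrow(x$calibration), x$range[1], x$range[2], x$sensor_pixels))
  invisible(x)
}

#' Pixel pitch at a magnification ratio
#'
#' @param model A [mag_model()].
#' @param ratio Magnification ratio(s), within the calibration range (no
#'   extrapolation).
#' @return Pixel pitch in micrometres per pixel.
#' @export
pixel_pitch <- function(model, ratio) {
  stopifnot(inherits(model, "mag_model"))
  if (any(ratio < model$range[1] | ratio > model$range[2]))
    stop(sprintf("ratio outside calibration range [%g, %g]: no extrapolation",
                 model$range[1], model$range[2]))
  model$interpolant(ratio)
}

#' Field-of-view side length at a magnification ratio
#'
#' `sensor_pixels * pixel_pitch(ratio)`, rounded to the nearest
#' micrometre for reporting.
#'
#' @inheritParams pixel_pitch
#' @return FOV side in micrometres (integer-valued).
#' @export
fov_side <- function(model, ratio) {
  round(model$sensor_pixels * pixel_pitch(model, ratio))
}

#' Load a calibration table from CSV
#'
#' @param path CSV file with columns `ratio` and `pitch_um`.
#' @return `data.frame` usable by [mag_model()].
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("ratio", "pitch_um") %in% names(df)))
    stop("calibration CSV needs columns `ratio` and `pitch_um`")
  df[order(df$ratio), c("ratio", "pitch_um")]
}

#' Focal-length model stub
#'
#' The focal distance as a function of the magnification dial is an
#' instrument-specific fitted curve; no numeric model ships with the
#' simulator.  A hardware port supplies its own calibration here.
#'
#' @param model A [mag_model()].
#' @param ratio Magnification ratio.
#' @export
focal_length <- function(model, ratio) {
  stop("focal-length model not calibrated in the simulator; ",
       "supply an instrument-specific curve for a hardware port")
}

#' Light-intensity model stub
#'
#' See [focal_length()]; in the simulator, illumination variation is
#' generated by the scene module instead.
#'
#' @param model A [mag_model()].
#' @param ratio Magnification ratio.
#' @export
light_intensity <- function(model, ratio) {
  stop("light-intensity model not calibrated in the simulator; ",
       "illumination drift is emulated by the scene generator")
}

#' Magnification ramp for seamless zoom
#'
#' Returns a function of time giving the magnification ratio during a
#' continuous zoom: constant `from` before `t0`, linear ramp to `to` over
#' `duration_s` (the full 140x-1400x sweep takes about 1 s on the
#' instrument), constant `to` afterwards.  The tracking loop re-evaluates
#' the pixel pitch from this ratio every frame.
#'
#' @param from,to Start and end magnification ratios.
#' @param duration_s Ramp duration in seconds (default 1).
#' @param t0 Ramp start time in seconds (default 0).
#' @return `function(t)` returning the ratio at time `t`.
#' @export
ratio_ramp <- function(from, to, duration_s = 1, t0 = 0) {
  stopifnot(duration_s >= 0)
  force(from); force(to); force(t0)
  function(t) {
    if (duration_s == 0) return(ifelse(t < t0, from, to))
    s <- pmin(pmax((t - t0) / duration_s, 0), 1)
    from + (to - from) * s
  }
}
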