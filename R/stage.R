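# Virtual XY stage and servo law.  The physical stage carries the chip:
# commanding it by -kp * (image error in um) moves the field of view
# towards the target.  Drive limits follow the linear-motor stage of the
# platform: 200 nm positioning accuracy, 1500 mm/s maximum speed.

#' Virtual XY stage state
#'
#' `pos` is the physical stage position in world micrometres; the FOV
#' centre it implies is `fov_center0 - pos` (moving the chip one way
#' moves the image the other way).  The reported (sensed) position
#' carries Gaussian noise of standard deviation `pos_noise_sd`, drawn
#' from a dedicated RNG stream so sensing never perturbs other
#' stochastic components.
#'
#' @param pos Initial stage position `c(x, y)` in micrometres.
#' @param max_speed_um_s Per-axis speed limit (default 1.5e6 um/s =
#'   1500 mm/s).
#' @param pos_noise_sd Position-sensing noise sd in micrometres (default
#'   0.2, i.e. 200 nm accuracy).
#' @param fov_center0 World position of the FOV centre when `pos = 0`.
#' @param seed Seed for the sensing-noise stream.
#' @return Mutable stage state of class `stage_state`.
#' @export
stage_state <- function(pos = c(0, 0), max_speed_um_s = 1.5e6,
                        pos_noise_sd = 0.2, fov_center0 = c(0, 0),
                        seed = 1) {
  st <- new.env(parent = emptyenv())
  st$pos <- as.numeric(pos)
  st$vel <- c(0, 0)
  st$max_speed_um_s <- max_speed_um_s
  st$pos_noise_sd <- pos_noise_sd
  st$fov_center0 <- as.numeric(fov_center0)
  st$sense_stream <- new_rng_stream(seed + 303)
  st$sensed <- st$pos
  class(st) <- "stage_state"
  st
}

#' World position of the FOV centre implied by the stage
#'
#' @param stage A [stage_state()].
#' @return `c(x, y)` in micrometres.
#' @export
fov_center <- function(stage) stage$fov_center0 - stage$pos

#' Servo gains
#'
#' A saturated discrete proportional law: at 500 FPS with one frame of
#' actuation latency the closed loop has characteristic polynomial
#' `z^2 - z + kp*dt`; the default `kp = 125` 1/s gives `kp*dt = 0.25`,
#' i.e. a critically damped loop (double pole at 1/2) with steady-state
#' lag `v / kp` against a target moving at speed `v`.  `kp * dt < 2` is
#' required for stability of the discrete loop and is checked when the
#' tracking loop is configured.
#'
#' @param kp Proportional gain in 1/s on the micrometre image error.
#' @param latency_frames Actuation latency in frames (default 1,
#'   modelling the few-millisecond processing delay).
#' @return List of class `servo_gains`.
#' @export
servo_gains <- function(kp = 125, latency_frames = 1L) {
  if (!(kp > 0)) stop("`kp` must be positive")
  if (latency_frames < 0) stop("`latency_frames` must be >= 0")
  structure(list(kp = kp, latency_frames = as.integer(latency_frames)),
            class = "servo_gains")
}

#' Stage velocity command from the measured image error
#'
#' `command = -kp * error`, clamped per axis to the stage speed limit.
#' The error is the target's offset from the FOV centre in micrometres
#' (image-pixel error times the current pixel pitch); driving the
#' chip-carrying stage against it centres the target.
#'
#' @param error_um `c(ex, ey)` image error in micrometres.
#' @param gains A [servo_gains()].
#' @param max_speed_um_s Per-axis clamp (default the stage limit).
#' @return Velocity command `c(vx, vy)` in micrometres per second.
#' @export
servo_command <- function(error_um, gains, max_speed_um_s = 1.5e6) {
  cmd <- -gains$kp * as.numeric(error_um)
  pmin(pmax(cmd, -max_speed_um_s), max_speed_um_s)
}

#' Advance the stage by one time step
#'
#' Integrates the clamped velocity command and redraws the sensed
#' position (true position plus sensing noise).
#'
#' @param stage A [stage_state()] (modified in place and returned).
#' @param command Velocity command `c(vx, vy)` in micrometres per second.
#' @param dt Time step in seconds.
#' @param noise Optional pre-drawn sensing noise `c(nx, ny)` in
#'   micrometres; by default it is drawn from the stage's sensing stream
#'   (callers running long loops may batch the draws from the same
#'   stream up front — the sequence is identical).
#' @return The stage state.
#' @export
step_stage <- function(stage, command, dt, noise = NULL) {
  stopifnot(dt > 0)
  cmd <- pmin(pmax(as.numeric(command), -stage$max_speed_um_s),
              stage$max_speed_um_s)
  stage$vel <- cmd
  stage$pos <- stage$pos + cmd * dt
  if (is.null(noise)) {
    noise <- if (stage$pos_noise_sd > 0)
      with_stream(stage$sense_stream, stats::rnorm(2, 0, stage$pos_noise_sd))
    else c(0, 0)
  }
  stage$sensed <- stage$pos + noise
  stage
}

#' Position on a Lissajous search trajectory
#'
#' `(A sin(2 pi p f t), A sin(2 pi q f t + delta))` with
#' `(p, q) = freq_ratio`.  The default 3:2 figure with a 5 mm amplitude
#' covers the 10 mm x 10 mm region over which targets are scattered in
#' the search experiments; `base_freq_hz` sets how fast the figure is
#' swept.
#'
#' @param t Time in seconds (vectorized).
#' @param amplitude_um Half-side of the search square (default 5000).
#' @param freq_ratio Integer pair `c(p, q)` (default `c(3, 2)`).
#' @param base_freq_hz Base frequency `f` in Hz.
#' @param delta Phase offset of the y component (default `pi/2`).
#' @return Matrix with columns `x`, `y` (micrometres); a vector for a
#'   single `t`.
#' @export
lissajous_position <- function(t, amplitude_um = 5000, freq_ratio = c(3, 2),
                               base_freq_hz = 0.5, delta = pi / 2) {
  x <- amplitude_um * sin(2 * pi * freq_ratio[1] * base_freq_hz * t)
  y <- amplitude_um * sin(2 * pi * freq_ratio[2] * base_freq_hz * t + delta)
  if (length(t) == 1L) c(x = x, y = y) else cbind(x = x, y = y)
}
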