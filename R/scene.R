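# Synthetic scene generator.  Renders ground-truthed grayscale frames of
# a dark target moving in a 30 mm x 30 mm chip workspace on a bright
# background, with optional per-frame circular image noise, global
# illumination drift, dark chip edges and an intruding microtool.  The
# generator is the simulator's replacement for the physical
# chip/microscope/sensor chain: everything the imaging pipeline sees is
# produced here, with the true world-frame state retained for evaluation.

#' Bead target description
#'
#' A polystyrene bead: a dark disk of the given radius.
#'
#' @param radius_um Bead radius in micrometres (default 50, i.e. the
#'   100-um bead used by the tracking-performance experiments).
#' @param intensity Rendered intensity (8-bit, default 20 on a 200
#'   background).
#' @return Target description list.
#' @export
target_bead <- function(radius_um = 50, intensity = 20) {
  stopifnot(radius_um > 0)
  list(kind = "bead", radius_um = radius_um, intensity = intensity,
       extent_um = radius_um)
}

#' Elongated (Paramecium-like) target description
#'
#' An ellipse with the given semi-axes, rendered at the swimmer's current
#' heading.  Defaults approximate a 150-um-long, 30-um-wide cell body.
#'
#' @param half_length_um,half_width_um Semi-axes in micrometres.
#' @param intensity Rendered intensity.
#' @return Target description list.
#' @export
target_ellipse <- function(half_length_um = 75, half_width_um = 15,
                           intensity = 20) {
  stopifnot(half_length_um > 0, half_width_um > 0)
  list(kind = "ellipse", half_length_um = half_length_um,
       half_width_um = half_width_um, intensity = intensity,
       extent_um = half_length_um)
}

#' Image-noise configuration
#'
#' Per-frame circular noise: `n` circles with image coordinates and radii
#' redrawn independently every frame, rendered at target-like intensity.
#' Circles are rejection-sampled so that no noise pixel falls within
#' `keepout_px` of the target's image position (the default keep-out is
#' the target's rendered extent plus 2 px; experiments that engage an ROI
#' pass the ROI radius instead so noise stays disjoint from the ROI).
#'
#' @param n Number of circles per frame (0 disables noise).  The standard
#'   densities are 1, 5, 10 and 15 (very low / low / medium / high).
#' @param radius_px Range of circle radii in pixels.
#' @param intensity Rendered intensity (same as the target by default,
#'   which is the hard case for moment-based detection).
#' @param keepout_px Keep-out radius around the target centre in pixels,
#'   or `NULL` for the default rule above.
#' @param start_t Time (s) at which noise generation begins.
#' @return Noise configuration list.
#' @export
noise_config <- function(n = 0L, radius_px = c(5, 25), intensity = 20,
                         keepout_px = NULL, start_t = 0) {
  stopifnot(n >= 0, length(radius_px) == 2L, radius_px[1] <= radius_px[2])
  list(n = as.integer(n), radius_px = radius_px, intensity = intensity,
       keepout_px = keepout_px, start_t = start_t)
}

#' Noise density presets
#'
#' Maps the four standard noise situations to circle counts.
#'
#' @param level One of `"very_low"`, `"low"`, `"medium"`, `"high"` (1, 5,
#'   10 and 15 circles per frame).
#' @return Integer circle count.
#' @export
noise_preset <- function(level = c("very_low", "low", "medium", "high")) {
  c(very_low = 1L, low = 5L, medium = 10L, high = 15L)[[match.arg(level)]]
}

#' Microtool configuration
#'
#' A 50-um-wide stainless bar inserted from the chip's open (right, +x)
#' side: rendered dark wherever world `x >= tip_x(t)` within the bar's
#' width.  The tip advances from `start_x_um` towards the target at
#' `speed_um_s`, stopping at `stop_x_um`.
#'
#' @param y_um World y of the bar's axis.
#' @param start_x_um,stop_x_um World x of the tip at start and stop.
#' @param speed_um_s Approach speed (default 200 um/s).
#' @param width_um Bar width (default 50 um).
#' @param intensity Rendered intensity.
#' @param start_t Time (s) at which the tool starts moving.
#' @return Tool configuration list.
#' @export
tool_config <- function(y_um, start_x_um, stop_x_um, speed_um_s = 200,
                        width_um = 50, intensity = 20, start_t = 0) {
  stopifnot(stop_x_um <= start_x_um, speed_um_s >= 0, width_um > 0)
  list(y_um = y_um, start_x_um = start_x_um, stop_x_um = stop_x_um,
       speed_um_s = speed_um_s, width_um = width_um, intensity = intensity,
       start_t = start_t)
}

#' Scene configuration
#'
#' @param target Target description ([target_bead()], [target_ellipse()])
#'   or `NULL` for target-free scenes (e.g. search over scattered beads).
#' @param background Background intensity (8-bit, default 200).
#' @param noise A [noise_config()].
#' @param drift_amplitude,drift_period_s Global sinusoidal illumination
#'   drift added to every pixel:
#'   `drift(t) = drift_amplitude * sin(2 pi t / drift_period_s)`.
#' @param workspace_um Chip workspace extents `c(wx, wy)` in micrometres
#'   (default 30 mm x 30 mm); beyond them the dark chip edge is rendered.
#' @param start_pos_um Target start position in world micrometres
#'   (default the workspace centre).
#' @param start_heading Initial heading in radians (default 0); sets the
#'   rendered body axis of an elongated target.
#' @param beads Optional `data.frame(x_um, y_um, radius_um)` of static
#'   beads (search scenes).
#' @param tool Optional [tool_config()].
#' @param sensor_px Sensor side length in pixels (default 256).
#' @return Scene configuration list of class `scene_config`.
#' @export
scene_config <- function(target = target_bead(), background = 200,
                         noise = noise_config(), drift_amplitude = 0,
                         drift_period_s = 5,
                         workspace_um = c(30000, 30000),
                         start_pos_um = workspace_um / 2,
                         start_heading = 0,
                         beads = NULL, tool = NULL, sensor_px = 256L) {
  structure(
    list(target = target, background = background, noise = noise,
         drift_amplitude = drift_amplitude, drift_period_s = drift_period_s,
         workspace_um = workspace_um, start_pos_um = start_pos_um,
         start_heading = start_heading,
         beads = beads, tool = tool, sensor_px = as.integer(sensor_px)),
    class = "scene_config")
}

# ---- trajectory models ----------------------------------------------------

#' Trajectory models for the simulated target
#'
#' `traj_static()` keeps the target still.  `traj_circular()` moves it on
#' a circle of the given diameter (the bead-on-a-stage arrangement of the
#' tracking-performance experiments), accelerating smoothly from rest
#' over `ramp_s` seconds so the servo sees a physically plausible start.
#' `traj_run_and_turn()` is a run-and-tumble stand-in for a swimming
#' *Paramecium*: constant cruise speed, Poisson-timed reorientation
#' events, occasional speed bursts, and specular reflection at the
#' workspace walls.  It is a motion-statistics caricature, not a
#' biologically calibrated model.  `traj_custom()` takes any function
#' `t -> c(x_um, y_um)`.
#'
#' @param diameter_um Circle diameter (default 2000, i.e. phi 2.0 mm).
#' @param speed_um_s Target speed in micrometres per second.
#' @param ramp_s Linear speed ramp-up duration in seconds.
#' @return A trajectory description list of class `trajectory`.
#' @export
traj_circular <- function(diameter_um = 2000, speed_um_s = 1000, ramp_s = 0.5) {
  stopifnot(diameter_um > 0, speed_um_s >= 0, ramp_s >= 0)
  structure(list(kind = "circular", radius_um = diameter_um / 2,
                 speed_um_s = speed_um_s, ramp_s = ramp_s),
            class = "trajectory")
}

#' @rdname traj_circular
#' @export
traj_static <- function() structure(list(kind = "static"), class = "trajectory")

#' @rdname traj_circular
#' @param cruise_um_s,burst_um_s Cruise speed (default 1000 um/s = 1 mm/s)
#'   and burst-speed cap (default 2000 um/s).
#' @param turn_rate_hz Poisson rate of reorientation events per second.
#' @param turn_sd_rad Heading-change standard deviation at an event.
#' @param burst_prob Probability that an event triggers a speed burst.
#' @param burst_duration_s Burst duration in seconds.
#' @export
traj_run_and_turn <- function(cruise_um_s = 1000, burst_um_s = 2000,
                              turn_rate_hz = 0.5, turn_sd_rad = pi / 3,
                              burst_prob = 0.2, burst_duration_s = 0.5) {
  stopifnot(cruise_um_s >= 0, burst_um_s >= cruise_um_s)
  structure(list(kind = "run_and_turn", cruise_um_s = cruise_um_s,
                 burst_um_s = burst_um_s, turn_rate_hz = turn_rate_hz,
                 turn_sd_rad = turn_sd_rad, burst_prob = burst_prob,
                 burst_duration_s = burst_duration_s),
            class = "trajectory")
}

#' @rdname traj_circular
#' @param fn Function `t -> c(x_um, y_um)` (world micrometres).
#' @export
traj_custom <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(kind = "custom", fn = fn), class = "trajectory")
}

# ---- scene state ----------------------------------------------------------

#' Initialize a scene
#'
#' @param config A [scene_config()].
#' @param trajectory A trajectory model (default [traj_static()]).
#' @param seed Integer seed; the scene derives independent RNG streams
#'   for noise synthesis and trajectory randomness from it, so runs are
#'   exactly reproducible and noise draws never perturb the motion.
#' @return Mutable scene state (class `scene_state`).
#' @export
scene_init <- function(config, trajectory = traj_static(), seed = 1) {
  stopifnot(inherits(config, "scene_config"))
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$trajectory <- trajectory
  st$pos <- as.numeric(config$start_pos_um)
  st$heading <- config$start_heading
  st$theta <- 0          # circular-trajectory phase
  st$speed <- if (trajectory$kind == "run_and_turn") trajectory$cruise_um_s else 0
  st$burst_until <- -Inf
  st$t <- 0
  st$frame_index <- 0L
  st$noise <- NULL       # matrix (cx, cy, r) in image pixels, or NULL
  st$noise_stream <- new_rng_stream(seed + 101)
  st$traj_stream <- new_rng_stream(seed + 202)
  class(st) <- "scene_state"
  st
}

#' Advance the scene by one time step
#'
#' Moves the target along its trajectory (the per-frame image noise is
#' redrawn by [sample_noise()], which needs the camera geometry).
#' Reproducible given the seed passed to [scene_init()].
#'
#' @param scene A [scene_init()] state (modified in place and returned).
#' @param dt Time step in seconds (default 1/500 s).
#' @return The scene state.
#' @export
step_scene <- function(scene, dt = 1 / 500) {
  stopifnot(dt > 0)
  traj <- scene$trajectory
  t1 <- scene$t + dt
  if (traj$kind == "circular") {
    v <- traj$speed_um_s *
      (if (traj$ramp_s > 0) min(1, scene$t / traj$ramp_s) else 1)
    scene$theta <- scene$theta + v / traj$radius_um * dt
    centre <- scene$config$start_pos_um - c(traj$radius_um, 0)
    scene$pos <- centre + traj$radius_um * c(cos(scene$theta), sin(scene$theta))
    scene$heading <- wrap_half_pi(scene$theta + pi / 2)
  } else if (traj$kind == "run_and_turn") {
    with_stream(scene$traj_stream, {
      if (stats::runif(1) < traj$turn_rate_hz * dt) {
        scene$heading <- scene$heading + stats::rnorm(1, 0, traj$turn_sd_rad)
        if (stats::runif(1) < traj$burst_prob)
          scene$burst_until <- scene$t + traj$burst_duration_s
      }
    })
    speed <- if (scene$t < scene$burst_until) traj$burst_um_s else traj$cruise_um_s
    scene$speed <- speed
    p <- scene$pos + speed * dt * c(cos(scene$heading), sin(scene$heading))
    w <- scene$config$workspace_um
    # specular reflection at the chip walls
    if (p[1] < 0) { p[1] <- -p[1]; scene$heading <- pi - scene$heading }
    if (p[1] > w[1]) { p[1] <- 2 * w[1] - p[1]; scene$heading <- pi - scene$heading }
    if (p[2] < 0) { p[2] <- -p[2]; scene$heading <- -scene$heading }
    if (p[2] > w[2]) { p[2] <- 2 * w[2] - p[2]; scene$heading <- -scene$heading }
    scene$pos <- p
  } else if (traj$kind == "custom") {
    p0 <- scene$pos
    scene$pos <- as.numeric(traj$fn(t1))
    d <- scene$pos - p0
    if (any(d != 0)) scene$heading <- atan2(d[2], d[1])
  }                      # static: nothing moves
  scene$t <- t1
  scene$frame_index <- scene$frame_index + 1L
  scene
}

# image position (0-based px) of a world point given the FOV centre
world_to_px <- function(world_um, fov_center_um, pitch, sensor_px) {
  (world_um - fov_center_um) / pitch + (sensor_px - 1) / 2
}

#' True target position in image coordinates
#'
#' @param scene A scene state.
#' @param stage A [stage_state()].
#' @param pitch Pixel pitch in micrometres per pixel.
#' @return `c(x, y)` in 0-based pixels.
#' @export
target_image_pos <- function(scene, stage, pitch) {
  world_to_px(scene$pos, fov_center(stage), pitch, scene$config$sensor_px)
}

#' Redraw the per-frame image noise
#'
#' Samples the configured number of circles with centres uniform over the
#' frame and radii uniform in the configured range, rejecting (up to 100
#' retries per circle) any circle whose pixels would come within the
#' keep-out radius of the target's image position.  Uses the scene's
#' noise RNG stream only.
#'
#' @param scene Scene state (noise is stored in it).
#' @param stage A [stage_state()] (for the target's image position).
#' @param pitch Pixel pitch in micrometres per pixel.
#' @return The scene state.
#' @export
sample_noise <- function(scene, stage, pitch) {
  nc <- scene$config$noise
  if (nc$n == 0L || scene$t < nc$start_t) {
    scene$noise <- NULL
    return(scene)
  }
  sp <- scene$config$sensor_px
  tgt <- scene$config$target
  keep <- nc$keepout_px
  if (is.null(keep))
    keep <- (if (is.null(tgt)) 0 else tgt$extent_um / pitch) + 2
  tp <- if (is.null(tgt)) c(-1e9, -1e9) else target_image_pos(scene, stage, pitch)
  out <- with_stream(scene$noise_stream, {
    m <- matrix(NA_real_, 0L, 3L)
    need <- nc$n
    for (round in 1:100) {
      cx <- stats::runif(need, 0, sp - 1)
      cy <- stats::runif(need, 0, sp - 1)
      r <- stats::runif(need, nc$radius_px[1], nc$radius_px[2])
      ok <- sqrt((cx - tp[1])^2 + (cy - tp[2])^2) > r + keep + 1
      if (any(ok)) m <- rbind(m, cbind(cx[ok], cy[ok], r[ok]))
      need <- nc$n - nrow(m)
      if (need == 0L) break
    }
    m
  })
  scene$noise <- if (nrow(out)) out else NULL
  scene
}

# ---- rendering ------------------------------------------------------------
#
# Painting helpers return small patches (bounding-box row/col ranges plus
# a coverage matrix) rather than touching the canvas: the canvas is
# modified in place only inside render_frame, which avoids copying the
# full frame on every painted object.

# disk coverage with linear-ramp anti-aliased edge (aa = TRUE) or as a
# hard membership mask (aa = FALSE; used for nuisance noise circles,
# whose edge profile carries no measurement)
circle_patch <- function(cx, cy, r, h, w, aa = TRUE) {
  c0 <- max(1L, floor(cx - r)); c1 <- min(w, ceiling(cx + r) + 2L)
  r0 <- max(1L, floor(cy - r)); r1 <- min(h, ceiling(cy + r) + 2L)
  if (c0 > c1 || r0 > r1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer(((rows - 1) - cy)^2, ((cols - 1) - cx)^2, "+")
  if (!aa) {
    cov <- d2 <= r * r          # logical membership: painted as a hard disk
    if (!any(cov)) return(NULL)
    return(list(rows = rows, cols = cols, cov = cov))
  }
  cov <- pmin(1, pmax(0, r + 0.5 - sqrt(d2)))
  if (!any(cov > 0)) return(NULL)
  list(rows = rows, cols = cols, cov = cov)
}

# rotated-ellipse coverage, estimated by ss x ss supersampling; the
# bounding box uses the rotated ellipse's true per-axis extents
ellipse_patch <- function(cx, cy, a, b, angle, h, w, ss = 3L) {
  ca2 <- cos(angle)^2; sa2 <- sin(angle)^2
  ext_x <- sqrt(a^2 * ca2 + b^2 * sa2) + 1
  ext_y <- sqrt(a^2 * sa2 + b^2 * ca2) + 1
  c0 <- max(1L, floor(cx - ext_x)); c1 <- min(w, ceiling(cx + ext_x) + 1L)
  r0 <- max(1L, floor(cy - ext_y)); r1 <- min(h, ceiling(cy + ext_y) + 1L)
  if (c0 > c1 || r0 > r1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  nr <- length(rows); nc_ <- length(cols)
  xs <- matrix(rep((cols - 1) - cx, each = nr), nr)
  ys <- matrix(rep((rows - 1) - cy, times = nc_), nr)
  ca <- cos(angle); sa <- sin(angle)
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  cov <- matrix(0, nr, nc_)
  for (ox in off) for (oy in off) {
    u <- (xs + ox) * ca + (ys + oy) * sa
    v <- -(xs + ox) * sa + (ys + oy) * ca
    cov <- cov + ((u / a)^2 + (v / b)^2 <= 1)
  }
  cov <- cov / (ss * ss)
  if (!any(cov > 0)) return(NULL)
  list(rows = rows, cols = cols, cov = cov)
}

# axis-aligned microtool bar entering from +x; separable edge coverage
tool_patch <- function(tip_x_px, y_px, half_w_px, h, w) {
  c0 <- max(1L, floor(tip_x_px)); if (c0 > w) return(NULL)
  r0 <- max(1L, floor(y_px - half_w_px))
  r1 <- min(h, ceiling(y_px + half_w_px) + 1L)
  if (r0 > r1) return(NULL)
  cols <- c0:w; rows <- r0:r1
  cov_x <- pmin(1, pmax(0, (cols - 1) - tip_x_px + 0.5))
  cov_y <- pmin(1, pmax(0, half_w_px - abs((rows - 1) - y_px) + 0.5))
  cov <- outer(cov_y, cov_x)
  if (!any(cov > 0)) return(NULL)
  list(rows = rows, cols = cols, cov = cov)
}

# dark half-planes where the FOV sees past the chip workspace edges;
# full-canvas coverage, or NULL when no edge is visible (the usual case)
chip_edge_cov <- function(fov_center_um, pitch, workspace_um, h, w) {
  half_w <- w / 2 * pitch; half_h <- h / 2 * pitch
  near <- fov_center_um[1] - half_w < pitch || fov_center_um[2] - half_h < pitch ||
    fov_center_um[1] + half_w > workspace_um[1] - pitch ||
    fov_center_um[2] + half_h > workspace_um[2] - pitch
  if (!near) return(NULL)
  wx <- (0:(w - 1) - (w - 1) / 2) * pitch + fov_center_um[1]
  wy <- (0:(h - 1) - (h - 1) / 2) * pitch + fov_center_um[2]
  cov_x <- pmax(pmin((0 - wx) / pitch + 0.5, 1), 0) +
           pmax(pmin((wx - workspace_um[1]) / pitch + 0.5, 1), 0)
  cov_y <- pmax(pmin((0 - wy) / pitch + 0.5, 1), 0) +
           pmax(pmin((wy - workspace_um[2]) / pitch + 0.5, 1), 0)
  pmin(1, outer(cov_y, rep(1, w)) + outer(rep(1, h), cov_x))
}

#' Render the current scene into a sensor frame
#'
#' Draws, in order: background (with illumination drift), chip edges,
#' static beads, the target (a disk, or an ellipse at the current
#' heading), the microtool, and the per-frame noise circles.  Objects are
#' anti-aliased by area-coverage blending so sub-pixel motion is not
#' quantized to whole pixels.  A target outside the FOV simply does not
#' appear (this is how target loss is exercised).
#'
#' @param scene Scene state (noise as last drawn by [sample_noise()]).
#' @param stage A [stage_state()]; its FOV centre fixes the camera.
#' @param optics A [mag_model()].
#' @param ratio Current magnification ratio.
#' @return A [new_frame()] with intensities in `[0, 255]`.
#' @export
render_frame <- function(scene, stage, optics, ratio) {
  cfg <- scene$config
  pitch <- pixel_pitch(optics, ratio)
  sp <- cfg$sensor_px
  fc <- fov_center(stage)
  canvas <- matrix(as.numeric(cfg$background), sp, sp)
  blend <- function(p, intensity) {
    if (is.null(p)) return(invisible())
    sub <- canvas[p$rows, p$cols]
    if (is.logical(p$cov)) {
      sub[p$cov] <- intensity
      canvas[p$rows, p$cols] <<- sub
    } else {
      canvas[p$rows, p$cols] <<- round(sub * (1 - p$cov) + intensity * p$cov)
    }
    invisible()
  }
  ec <- chip_edge_cov(fc, pitch, cfg$workspace_um, sp, sp)
  if (!is.null(ec)) canvas <- round(canvas * (1 - ec) + 20 * ec)
  if (!is.null(cfg$beads) && nrow(cfg$beads)) {
    bp <- cfg$beads
    bx <- (bp$x_um - fc[1]) / pitch + (sp - 1) / 2
    by <- (bp$y_um - fc[2]) / pitch + (sp - 1) / 2
    br <- bp$radius_um / pitch
    vis <- bx + br >= -1 & bx - br <= sp & by + br >= -1 & by - br <= sp
    for (i in which(vis))
      blend(circle_patch(bx[i], by[i], br[i], sp, sp), 20)
  }
  tgt <- cfg$target
  if (!is.null(tgt)) {
    tp <- world_to_px(scene$pos, fc, pitch, sp)
    if (tgt$kind == "bead") {
      blend(circle_patch(tp[1], tp[2], tgt$radius_um / pitch, sp, sp),
            tgt$intensity)
    } else {
      blend(ellipse_patch(tp[1], tp[2], tgt$half_length_um / pitch,
                          tgt$half_width_um / pitch, scene$heading, sp, sp),
            tgt$intensity)
    }
  }
  if (!is.null(cfg$tool)) {
    tl <- cfg$tool
    tip_x <- max(tl$stop_x_um,
                 tl$start_x_um - tl$speed_um_s * max(0, scene$t - tl$start_t))
    tip_px <- world_to_px(c(tip_x, tl$y_um), fc, pitch, sp)
    blend(tool_patch(tip_px[1], tip_px[2], tl$width_um / 2 / pitch, sp, sp),
          tl$intensity)
  }
  if (!is.null(scene$noise)) {
    for (i in seq_len(nrow(scene$noise))) {
      p <- circle_patch(scene$noise[i, 1], scene$noise[i, 2],
                        scene$noise[i, 3], sp, sp, aa = FALSE)
      if (!is.null(p)) {
        sub <- canvas[p$rows, p$cols]
        sub[p$cov > 0] <- cfg$noise$intensity
        canvas[p$rows, p$cols] <- sub
      }
    }
  }
  if (cfg$drift_amplitude != 0) {
    drift <- cfg$drift_amplitude * sin(2 * pi * scene$t / cfg$drift_period_s)
    canvas <- round(canvas + drift)
    canvas[canvas < 0] <- 0
    canvas[canvas > 255] <- 255
  }
  new_frame(canvas, t = scene$t, pixel_pitch = pitch,
            frame_index = scene$frame_index)
}
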