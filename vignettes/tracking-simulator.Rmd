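---
title: "Visual-servoing tracking of motile microorganisms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual-servoing tracking of motile microorganisms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`servotrack` simulates a high-speed microscopy platform that keeps a
single swimming microorganism centred in the field of view (FOV) by
visual servoing: a 256 x 256 px online vision sensor runs at 500 frames
per second, each frame is reduced to a handful of image moments, and the
measured offset of the target from the image centre drives an XY stage
that carries the microfluidic chip.  The package contains the full
closed loop — scene synthesis, imaging, region-of-interest (ROI)
propagation, magnification optics, stage and servo — plus the harnesses
that reproduce the platform's benchmark experiments without hardware.

## The measurement model

Frames are 8-bit grayscale with dark targets on a bright brightfield
background.  Each frame is binarized by a per-frame Otsu threshold
(foreground = pixels darker than the threshold).  Because the threshold
is recomputed from the current intensity histogram, a global
illumination shift moves the threshold by exactly the same amount and
leaves the mask unchanged; this is the package's stand-in for the
adaptive thresholding used on the instrument, whose exact algorithm is
not public.

From the binary mask $I(x,y) \in \{0,1\}$ the raw moments

$$M_{i,j} = \sum_x \sum_y x^i y^j I(x,y)$$

give the centre of gravity $X_g = M_{1,0}/M_{0,0}$,
$Y_g = M_{0,1}/M_{0,0}$, and the posture angle

$$\phi = \tfrac{1}{2}\,\mathrm{atan2}\!\left(2\mu_{1,1},\; \mu_{2,0}-\mu_{0,2}\right),$$

computed from **central** moments $\mu$.  Using central rather than raw
second moments is a deliberate choice: raw second moments mix the
target's position into its shape, so a posture computed from them would
change as the target moves across the frame.  Central moments make the
posture translation-invariant; this matters because the ROI (below) is
oriented by $\phi$ while the target is rarely exactly centred.  The
two-argument arctangent resolves the quadrant ambiguity of
$\tfrac12\tan^{-1}$; the posture describes an undirected body axis and
is reported in $(-\pi/2, \pi/2]$, with $\phi = 0$ by convention for
isotropic foregrounds.  Empty masks raise a catchable "no target"
condition rather than propagating `NaN`.

## ROI propagation

At high magnification the FOV contains debris, bubbles, chip edges and
— during stimulation — a microtool, all of which are dark and would
corrupt a whole-frame centre of gravity.  Because consecutive frames at
500 FPS differ very little, the measurement at frame $k$ can be
restricted to a rotated ellipse built from frame $k-1$'s state:

$$\frac{\big((x-X_g^{k-1})\cos\phi^{k-1} + (y-Y_g^{k-1})\sin\phi^{k-1}\big)^2}{a^2} +
  \frac{\big(-(x-X_g^{k-1})\sin\phi^{k-1} + (y-Y_g^{k-1})\cos\phi^{k-1}\big)^2}{b^2} \le 1$$

Boundary points count as inside (the inclusive test avoids losing thin
targets, and a small `1e-9` slack absorbs rotation round-off).  Two
presets mirror the platform's experiments: a circular ROI $a=b=20$ px
sized for a 100 um bead at 140x, and an elongated ROI $a=100, b=20$ px
for a *Paramecium* at 840x.  The semi-axes stay fixed during a run.

In ROI mode *all* image processing is restricted to the ellipse,
including the adaptive threshold, which is computed from the pixels
inside the ROI only.  This follows from the design intent (processing
is shrunk to the target's neighbourhood) and has a useful consequence:
image content outside the ROI cannot influence the measurement at all,
not even through the threshold, so a run with non-overlapping noise is
*bit-for-bit* identical to a noise-free run.  A whole-frame threshold
would instead shift slightly with every noise circle and flip
anti-aliased edge pixels.  One refinement is needed: when the ROI lies
wholly inside a large dark target (a 100 um bead at 1400x is 126 px
across, larger than the 40 px ROI), its patch is unimodal and a fresh
Otsu split would be meaningless.  If the intensity spread inside the
ROI falls below `min_contrast` (default 8 levels), the previous frame's
threshold is reused — another use of the high-frame-rate assumption
that consecutive frames are nearly identical.

## Optics

The magnification dial couples three quantities: pixel pitch, focal
distance and illumination.  Only the pixel pitch enters the control
loop, and it is modelled numerically from the instrument's ten-point
calibration table (140x...1400x -> 5.50...0.79 um/px) with a
shape-preserving monotone piecewise-cubic interpolant
(Fritsch–Carlson, `stats::splinefun(method = "monoH.FC")`).  The
physical pitch must fall monotonically with magnification, and this
interpolant is exact at every calibration point, strictly monotone
between them, and cannot overshoot; no extrapolation outside the
calibrated range is allowed.  Focal-length and light-intensity hooks
exist as stubs for a hardware port — their fitted curves are
instrument-specific and not public — and illumination variation is
instead generated by the scene module to exercise the adaptive
threshold.  A seamless zoom is modelled as a linear ramp of the ratio
(default 1 s for the full range, matching the instrument), with the
pitch re-evaluated every frame so that the image-space error is always
converted to micrometres at the current scale.

## Stage and servo

The XY stage mirrors the platform's linear-motor stage: 200 nm
positioning accuracy (Gaussian sensing noise, sd 0.2 um) and a
1500 mm/s per-axis speed limit.  The instrument's adaptive controller
is proprietary; the simulator substitutes a saturated discrete
proportional law, `command = -kp * error_um`, which the published
closed-loop behaviour constrains just as well.  With one frame of
actuation latency the loop's characteristic polynomial is
$z^2 - z + k_p \Delta t$; the default $k_p = 125\,\mathrm{s^{-1}}$ at
$\Delta t = 2$ ms gives $k_p\Delta t = 1/4$, i.e. a critically damped
double pole at $z = 1/2$ — the fastest non-oscillatory setting.
Against a target moving at speed $v$ the steady-state lag is $v/k_p$:
8 um at 1 mm/s, 80 um at 10 mm/s, 120 um at 15 mm/s.  Since the
smallest FOV half-side is ~101 um, this gain tracks any calibrated
magnification up to 10 mm/s and degrades beyond 15 mm/s at high
magnification, which is exactly the operating envelope reported for the
instrument.  Configurations with $k_p \Delta t \ge 2$ (the discrete
stability bound) are rejected at configuration time.

Searching uses a 3:2 Lissajous figure with 5 mm amplitude covering the
10 mm x 10 mm scatter region, swept so the fastest axis moves at the
configurable search speed (default 50 mm/s, chosen so that even the
smallest FOV cannot step over a 100 um bead between frames).

## The state machine

SEARCH (Lissajous sweep at 140x, detection when the foreground count
reaches `acquire_area_px = 50`) -> TRACK (whole-frame measurement,
servo to centre) -> TRACK_ROI (after 100 stable frames, matching the
protocol of engaging the ROI only once tracking is steady) -> LOST
(after 25 consecutive empty frames; the tracker reverts to whole-frame
re-detection at the current magnification and holds the stage).  The
loss-recovery transition is an extension of the published procedure —
the instrument would be re-pointed manually — added so that long
unattended simulations can continue; it requires a fresh detection
before TRACK resumes.  The detection and loss thresholds are not
published; both are configuration defaults here.

## The scene generator

The generator renders what the sensor would see, with ground truth
retained: a dark target (disk, or ellipse at the current heading) at
intensity 20 on background 200, anti-aliased by area-coverage blending
so sub-pixel motion is measurable; optional per-frame circular image
noise at target intensity; a dark chip edge wherever the FOV sees past
the 30 mm x 30 mm workspace; and a 50-um-wide microtool bar entering
from the chip's open side.  The published experiments specify the noise
counts (1/5/10/15 circles, re-randomized every frame, kept off the
target) but not their sizes or intensity; the package's declared
defaults are radii uniform in [5, 25] px and intensity equal to the
target's — the hardest case for a moment-based tracker.  The keep-out
radius around the target is configurable; the noise-robustness
experiment sets it to the ROI radius + 2 px for both processing
methods, since its point is noise *outside* the ROI.

Trajectories: `traj_circular` reproduces the bead-on-a-stage
arrangement (phi 2.0 mm circle) with a 0.5 s speed ramp so the servo
sees a physically plausible start; `traj_run_and_turn` is a
run-and-tumble caricature of *Paramecium* swimming (1 mm/s cruise,
2 mm/s burst cap, Poisson reorientations, specular wall reflection) —
adequate for exercising the tracker, not biologically calibrated.
Every stochastic component (noise synthesis, reorientation, stage
sensing) draws from its own seeded RNG stream, so enabling one never
perturbs another; this is what makes run-to-run exactness claims
testable.

What the generator does **not** emulate: optical blur and shot noise,
partial occlusion (excluded by chip design on the instrument), 3-D
motion, fluid–tool interaction, and photometric variation of real
debris.  Tests passing on these scenes therefore validate the control
and measurement logic, not robustness to real-world image statistics.

## Experiment harnesses and problem sizes

* `run_search_time`: 20 beads scattered uniformly in 10 mm x 10 mm,
  5 repeats per magnification with layouts shared across ratios, 20 s
  cap.  The mean time-to-detection at 140x is far below that at 1400x
  (the swept swath is 7x wider, and the 48.6x larger FOV area makes
  immediate detections common).
* `run_velocity_sweep`: 1000 steady-state frames per point after a
  0.75 s ramp-and-settle, speeds {1, 5, 10, 15} mm/s, with and without
  the ROI.  The reported error is the true distance between target and
  FOV centre; it reproduces the $v/k_p$ law and is non-decreasing in
  speed.
* `run_noise_robustness`: tracking time until the target leaves the
  FOV entirely (whole-frame processing keeps "tracking" noise and
  never sees an empty frame, so failure is judged against ground
  truth) or the tracker declares LOST (ROI method).  6 repeats per
  noise level.  The cap defaults to 60 s; the package's automated
  checks run it at a 20 s cap — failures of the whole-frame method
  occur within seconds, so the comparison is cap-invariant, and the
  ROI method holds to whatever cap is chosen.
* `run_tool_intrusion`: a stationary vertical swimmer at 840x with the
  elongated ROI while the tool stops 60 um short of the body axis,
  perpendicular to it.  With the ROI the logged COG is bit-for-bit the
  no-tool trace; with whole-frame processing the COG is pulled tens of
  pixels towards the tool.

## A structural limitation worth knowing

With whole-frame processing and noise redrawn independently every
frame, the measured COG is approximately the area-weighted mean of the
target and the noise-union centroid.  As the circle count $n$ grows,
the noise weight approaches 1 but the union centroid concentrates
around the FOV centre with sd $\propto 1/\sqrt{n}$ — the two effects
cancel, and the jitter injected into the servo loop becomes nearly
independent of $n$.  Simulated tracking time therefore collapses
sharply from 1 circle to 5 and then *plateaus* at 10 and 15 instead of
decreasing strictly, whatever the noise geometry or gain.  The
qualitative robustness ranking (ROI method unaffected at every density;
whole-frame method drastically degraded by denser noise) is reproduced;
a strictly graded degradation across all four densities is not a
property of this model class, and the corresponding check in the test
suite documents that gap rather than papering over it.

## Numerical choices

* Coordinates are 0-based, x rightward (columns), y downward (rows);
  FOV-centred coordinates appear only at the servo interface.
* Otsu ties are broken towards the smallest threshold, making the
  threshold a deterministic, shift-equivariant function of the
  histogram.
* ROI membership uses the exact boundary equation with `<= 1 + 1e-9`.
* Anti-aliasing: disks use an analytic linear edge ramp, ellipses a
  3 x 3 supersample; both keep the round-trip centroid error of a
  rendered target below 0.2 px (0.5 px is the tested bound).
* An ROI outside the frame yields an empty measurement, never an
  error; target loss is always the tracker's decision.
* Frames quantize to integer intensities 0..255; illumination drift is
  applied as a global additive offset before quantization, so the
  drift-invariance of the adaptive threshold is exact.
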