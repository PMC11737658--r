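---
title: "Display timing, photodiode verification, and dome geometry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Display timing, photodiode verification, and dome geometry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domesync)
```

This vignette is the package's own account of its methods: the timing model
and the conventions it rests on, the photodiode transition-time estimator,
what the session simulator emulates (and what it does not), the geometry
conventions, and the numerical choices made where the design was genuinely
open.

## 1. The session log dialect

A session log is plain text: a header block of `# key: value` lines
(level start time, subject, experimenter, experiment, level name,
verbosity), then one tab-separated line per event with at least four
columns — game-thread time, object id, line type, payload. Line types are
`EVENT_MARKER` (marker id + high-resolution send timestamp), `INPUT`
(forward/sideways/rotation), `POSITION` (Cartesian coordinates + rotation,
optionally dome angles), `STATE_ENTER`/`STATE_EXIT`, `STIMULUS_CREATE`/
`STIMULUS_DESTROY`, `FRAME` (frame index + flip timestamp) and `CUSTOM`.

Design choices where the on-disk format was open: tabs as separators, times
printed with seven decimals (0.1 µs — an order below the high-resolution
clocks being recorded), and verbosity levels 0–3 for the abbreviated log
(0 = states + markers only, 1 adds stimulus lifecycle, 2 adds frame timing
and input, 3 = the continuous log). Record constructors snap times to the
printed resolution, so `parse(serialize(r))` is exactly `r` and
re-serialization is byte-identical — a property the test suite asserts on
randomized record sets.

The parser streams fixed-size chunks, so peak memory is a constant (chunk
buffers) plus the returned subset; a 100 MB log parsed with a marker filter
stays well under a 250 MB heap cap in the tests. Unmatched state *exits*
are errors (they indicate a corrupt log); states still open at end-of-file
are warnings, because truncated sessions are normal.

## 2. The timing model

A game engine prepares frames ahead of display. Three numbers describe a
setup (`timing_config()`): the frame rate (reference dome: 59.952 Hz), the
rendering pipeline depth in frames (2 — each dome frame passes through
camera-rig capture and fisheye/warp composition before its flip), and the
display delay from flip to light (projector latency, 18 ms). Their
combination is the a-priori fixed latency
`fixed_display_delay() = pipeline_frames · period + display_delay_ms`
(51.360 ms for the reference configuration).

The raw log's FRAME line for prepared frame *k* carries the flip timestamp
of the frame *being displayed* at that moment, i.e. frame
*k − pipeline_frames* — that is what the graphics card exposes while *k* is
still in flight. `build_frame_table()` re-indexes these so the table pairs
each frame with its **own actual flip**; the last `pipeline_frames` frames,
whose flips were never observed, are extrapolated at the nominal period and
flagged. `to_screen_time()` then assigns an event to the frame whose
preparation interval contains it (half-open on preparation start times) and
returns that frame's flip plus the display delay.

Anchoring on the frame's own (re-indexed) flip rather than on the
displayed-frame timestamp plus a nominal pipeline offset is deliberate: the
two agree in steady state, but only the former remains exact when a frame
sticks — events prepared just after a stall inherit the late actual flip,
and injected frame skips leave conversion accuracy untouched. Frame skips
themselves are detected as flip intervals exceeding 1.5 nominal periods,
the midpoint between one and two periods, robust to jitter far below half
a period.

Events logged before the first tabulated frame (the first two frames are
never tabulated, as frame timing is only available from the third game
frame) fall back to game time plus the median (logged flip − preparation)
offset — which carries the clock offset between the game and
high-resolution clocks — plus the fixed delay, and are flagged unadjusted.
Event markers, which carry both clocks, provide anchor pairs for a
piecewise-linear monotone clock map used for diagnostics and drift
absorption.

## 3. Photodiode verification

A probe object rendered over a photodiode switches brightness every frame
(initial value 0.5; once a state machine runs, the 4-periodic pattern 1,
0.3, 1, 0), sending an event marker at each switch. Verification selects
the full-contrast falling transitions (1 → 0), predicts each one's screen
time from the adjusted log, maps predictions onto the acquisition clock
via a least-squares fit of the markers' logged timestamps to their
recorded acquisition sample times, and measures each transition in the
trace.

The trace is low-pass filtered at 500 Hz with a 4th-order Butterworth
filter applied forward and backward, so filtering is zero-phase and adds no
delay to measured times. The implementation pads with an odd-symmetric
signal reflection before filtering so that edge transients from the
filter's zero initial conditions never reach the data. The transition time
is the time of maximum signal change: the extreme of the first difference
of the filtered trace inside a ±5 ms window around the prediction,
sign-selected by the expected polarity, with parabolic interpolation
between samples. A window whose matching-polarity extreme does not exceed
a noise floor (5× the median absolute first difference of the window's
flanks) or is dominated by an opposite-polarity change yields a
missing-value result rather than a bogus time.

**Instrument-response correction.** The max-change statistic is unbiased
for an instantaneous step, but a real photodiode edge is a first-order
rise. For a time constant τ = 0.5 ms filtered at 500 Hz, the steepest
point of the *filtered* edge sits ≈ 0.36 ms after the edge onset — a
systematic displacement an order of magnitude above the 0.0333 ms sample
period, which would otherwise masquerade as a display-delay error.
`transition_residual()` therefore subtracts the deterministic offset of
the estimator for the known edge model, computed by passing template edges
(τ, filter order, cutoff and sample rate all as configured) through the
identical measurement path, averaged over sub-sample phases, and cached.
With the correction, a noiseless synthetic edge is located to well under
one sample at any phase; on real data τ is a property of the photodiode
and can be measured once from the average step response. Setting
`edge_tau_ms = NULL` disables the correction and recovers the raw
statistic.

`alignment_stats()` summarizes residuals by median and 5th/95th
percentiles (linear interpolation between order statistics) and exposes
two headline conventions: `fraction_within(tol)` — the fraction of
residuals with |r| ≤ tol — and `central_width(p)` — the width of the
central *p* probability interval. The second is the convention in which
"90% of traces aligned to within 0.1667 ms" describes a distribution whose
5th-to-95th percentile range spans 0.1667 ms regardless of its median;
with the instrument-response correction in place the median sits at zero
when the configured display delay is correct, and the two conventions
coincide. A mis-specified display delay Δ appears directly as a median of
−Δ, which is also how an over-estimated projector delay would be
discovered on a real setup.

## 4. The session simulator

`simulate_session()` generates the complete artifact set with known ground
truth. Its defaults are the reference study conditions: 59.952 Hz, 2
pipeline frames, 18 ms true display delay, 2% per-frame skip probability,
30 kHz acquisition, Gaussian noise at 2% of full amplitude, and a 0.5 ms
first-order photodiode rise. Frame flips advance one nominal period at a
time, two after a stuck frame; the game thread is paced by the flips
(preparation = flip − pipeline·period − clock offset), so skips propagate
into preparation times exactly as a blocked render queue would. FRAME
lines start at the third game frame and carry displayed-frame flips; every
commanded brightness switch emits a marker whose id encodes the new level
(2000 + 100·value), logged on both clocks and recorded in the marker
channel; a wandering object provides INPUT/POSITION traffic; optional
trials write outcome-state intervals for the performance pipeline.

Pauses model how skips are provoked deliberately: during a pause the state
machine stops (logged as exiting the Running state), the screen renders
black, the flicker pattern freezes, no markers are sent, and deterministic
stuck frames are injected at the pause boundaries (the loading hitch at
pause/resume). A 1 → 0 marker pair that straddles a pause has no physical
edge at the resume frame (black to black) and correctly comes back as a
missing value.

The photodiode trace is the displayed luminance (black 0 V, full 2 V — the
affine scale is irrelevant to timing) passed through an exact first-order
response whose edges originate at the *continuous* display times, not at
sample boundaries, so ground-truth edge positions are not quantized to the
grid; noise is added white. The first-order rise is a modeling choice — it
reproduces the rounded transition shoulders seen on real recordings, but a
real photodiode amplifier may have higher-order dynamics, and the
correction in §3 is exactly as good as the edge model. Other things the
simulator does not emulate: acquisition-clock drift and marker-transmission
jitter (an optional constant clock offset is supported; markers are exact),
display persistence and backlight modulation, and any behavior beyond
outcome-state bookkeeping.

What passing tests on synthetic sessions shows, therefore, is that the
*analysis chain* — log dialect, frame re-indexing, conversion, clock
mapping, transition measurement, statistics — is internally exact and
robust to skips, noise and clock offset at the stated levels; it does not
certify any particular hardware's delays, which is precisely why the
photodiode verification exists as a procedure.

**Problem sizes.** The verification tests use 6,000-frame sessions
(~100 s), giving ≈ 1,500 analyzed full-contrast transitions — comfortably
above the 1,000 the acceptance conditions require — with five 30-frame
pauses in the pause scenario; determinism, conservation and recovery
properties use 200–800 frame sessions.

## 5. Dome and fisheye geometry

Axes: forward +X, right +Y, up +Z. Dome coordinates are azimuth (positive
rightward) and elevation (positive up) at fixed radius (reference dome:
60 cm, extending 250°, i.e. polar angle ≤ 125°), with (0, 0) at
front-center. For a subject at the center gazing at (0, 0), dome
coordinates equal visual angles by construction —
`dome_to_visual_angle()` makes the pass-through explicit. Conversions to
and from Cartesian coordinates are closed-form and round-trip to 1e-9
degrees over the sphere minus the poles (where azimuth is undefined).

The fisheye law is equidistant (image radius ∝ polar angle), the
convention of the mesh-warping projection method this geometry follows;
forward maps to image center (0.5, 0.5) and the image circle radius 0.5
corresponds to the 125° rim. The five-camera rig (90° square frusta
facing front/left/right/up/down — orientations chosen so corner coverage
between faces reaches the rim) projects a direction onto its covering
face and maps the face pixel through the face's warp onto the fisheye;
this composition agrees with the direct law to 1e-6 everywhere in
coverage, including at face seams, and directions behind the rig's
coverage raise an error naming the gap. Warp meshes use the text format
of that method's ecosystem (projection type, `nx ny`, then
`x y u v intensity` nodes) so externally produced meshes load; nodes with
texture coordinates outside [0, 1]² mark unused regions and render
transparent. Mesh *generation* for a specific mirror/dome is out of
scope.

## 6. Receptive-field schedules

All schedules are pure functions of parameters and seed (Mersenne-Twister,
recorded in the schedule attributes), emit 0-based frame indices, and keep
every element within the 125° dome coverage. The moving bar is a
great-circle strip of fixed angular width, advancing speed/frame-rate
degrees per frame with the per-frame center logged; the flash grid flashes
every grid location exactly once per repetition in a seeded permutation
with exact duration/gap accounting; sparse noise draws its squares per
frame without replacement from a spacing lattice anchored at (0, 0)
(background: intermediate gray), with polarities uniform over {black,
white}. Blob profiles are circular Gaussians in angular coordinates,
truncated at 3σ when rendered.

## 7. Known limitations

* The streaming parser holds filter-passing records in memory; a filter
  matching most of a very large file approaches whole-file cost by
  construction.
* The edge-bias correction assumes a first-order edge; strongly
  non-exponential photodiode dynamics would need their own template.
* The clock map between log and acquisition is fitted linearly
  (offset + drift); pathological non-monotone clock behavior is flagged,
  not repaired.
* Input-device latency (between physical movement and logged input values)
  is outside the log's observability and is not estimated.
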