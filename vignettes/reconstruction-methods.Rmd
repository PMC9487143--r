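---
title: "Reconstructing images and volumes from time-tagged photon streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing images and volumes from time-tagged photon streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagscope)
```

## The problem

In photon-counting (digital) two-photon microscopy, the detector signal is
discriminated into a stream of discrete events, each recorded by a fast
multichannel digitizer as a *time tag*: a channel id plus an arrival time,
here an integer number of picoseconds since the stream origin. Alongside
photon tags the digitizer records synchronization signals — the resonant
scanner's line sync, optionally a frame sync, the pulsed laser's sync, and
the phase pulse of a varifocal (TAG) lens. Reconstruction means turning
this one-dimensional event stream back into 2D images or continuous 3D
volumes whose pixel values are exact photon counts.

tagscope implements that reconstruction offline, together with a virtual
microscope that emits synthetic tag streams with a per-photon ground-truth
ledger, so the full pipeline is testable without any acquisition hardware.

## The snake

The core data structure is the *snake*: an ordered vector of cells, one per
pixel of the upcoming frame, each holding an end time and an output
coordinate. Line `k` of a frame occupies `[s_k, s_k + T_line)` where `s_k`
is the measured k-th line sync and `T_line` the nominal line period. Only a
fraction `ff` (the fill fraction) of each line maps to visible columns; the
remainder is mirror turnaround, discarded as in all raster-scanning
software. The visible window is centered, opening at
`t0 = (1 - ff)/2 * T_line`, and pixel boundaries within it are uniform in
time with dwell `tau = ff * T_line / columns`. On odd lines of a
bidirectional scan the column order is reversed, and an optional
`bidir_phase_ps` shifts odd-line windows only (the line-shift correction).

A photon is allocated to the first cell whose end time *strictly exceeds*
its arrival time, provided the arrival lies inside that cell's own
`[start, end)` interval; otherwise it falls in a turnaround gap and is
discarded rather than snapped to a neighboring pixel. Because all times are
integers, the tie-break is exact: a photon landing exactly on a boundary
belongs to the next cell. `find_cell()` implements the search as a binary
search over the end-time vector and is contractually identical to a
left-to-right linear scan — an equivalence the test suite checks on 10^4
randomized cases.

The snake is rebuilt for every frame from the measured line syncs, so sync
jitter is tracked rather than accumulated; gaps larger than 1.5 nominal
line periods are repaired by inserting inferred syncs at nominal spacing
(counted in the run statistics, never fatal). With a frame-sync-only
wiring, line starts are inferred by equal division of each measured frame
interval, the last frame falling back to the nominal period.

## The axial phase map

The TAG lens sweeps focal depth sinusoidally at its resonance (about
189 kHz for the lens modeled here), unsynchronized with the lateral
scanners. Given the latest TAG sync pulse, depth is

    phi = 2 * pi * (t - last_sync) / P_tag + phase0
    z   = (1 + sin(phi)) / 2
    plane = min(floor(z * planes), planes - 1)

The snake itself stays two-dimensional; the plane index is computed per
photon from its arrival time, composing lazily into the voxel coordinate.
Two conventions were genuinely open:

* **z-uniform vs phase-uniform binning.** Bins uniform in `z` are the
  default. They make the characteristic *skipped voxels* of a single
  volume emerge directly from the line/TAG frequency mismatch, and give
  the arcsine dwell-time law (outer planes visited longest) that the test
  suite verifies against direct numerical integration of the sinusoid.
* **Where plane 0 sits relative to the sync pulse.** Not derivable from
  the hardware description, so it is exposed as `tag_phase0_rad` rather
  than guessed; the default 0 puts `sin = 0` (mid-stack) at the sync.

Volumetric configurations require an even plane count and a TAG sync
channel; both are enforced by `validate_config()`.

## Temporal demultiplexing

Two excitation beams can share one detector when the second pulse train is
optically delayed by half the laser inter-pulse period — 6.25 ns for an
80 MHz source. The digitizer duplicates the laser sync and shifts it by
`T/2`, so the two trains gate two alternating streams: a photon with
`Delta = (t - last_pulse) mod T` belongs to stream 0 when `Delta < T/2`
and stream 1 otherwise. Gates are half-open, the boundary photon going to
the later stream, matching the allocator's strict-"exceeds" convention (the
boundary convention is declared here, not derivable from the hardware
description).

Two supporting pieces mirror the digitizer's behavior:

* `pair_with_last_pulse()` is the conditional filter: a laser pulse is
  only recorded when a photon follows it, so the recorded event rate
  tracks the photon rate, not the doubled pulse repetition rate.
* `phase_track()` reconstructs the full train from sparse references
  (every Nth pulse) by extrapolation at the nominal period — exact for a
  periodic train, with phase error bounded by the drift accumulated
  between references otherwise.

With prompt emission and beams exactly `T/2` apart, demultiplexing is
perfectly pure — every photon lands in its true beam's stream, and the
simulator round trip confirms crosstalk is exactly zero. Crosstalk in a
real instrument stems from the beams *not* being exactly half a period
apart; note that a deterministic delay error alone cannot produce it, since
all of a beam's prompt photons shift together within their gate. The
physical channel that converts delay error into crosstalk is the spread of
arrival times around the pulse — dominated by the fluorophore's emission
lifetime (a few ns, comparable to the 6.25 ns gate). The simulator
therefore exposes `lifetime_ps`, an exponential emission delay, off by
default (so purity stays exact) and enabled in the crosstalk studies: with
a 3 ns lifetime, crosstalk is strictly positive at 1 ns delay error and
grows at 2 ns.

## Accumulation and display

Photon records accumulate into per-(channel, demux-stream) count arrays —
never blended — by plain tabulation over linear voxel indices, a
commutative operation: batch order and splitting cannot change the result,
and the total always equals the allocator's allocated count. The rolling
display buffer keeps the *sum* of the last N frames, the divisor applied
only at render time, so integer counts stay exact photon numbers. The
offline depth projection sums all frames and then takes the maximum across
planes; brightness normalization along z and smoothing are deliberately
left as post-export steps.

## The virtual microscope

`simulate_acquisition()` emits everything the allocator consumes: line (or
frame) syncs at the configured rate with optional Gaussian jitter, TAG
syncs at the lens frequency with a seeded random initial phase (the lens is
free-running), laser references (every pulse or every Nth), and photon tags
drawn per laser pulse as a Bernoulli trial with probability
`brightness * p_pulse_max * I(x(t), z(t))`. The per-pulse excitation
probability is capped at `p_pulse_max = 0.1` by default — the regime in
which excitation saturation does not broaden the effective point-spread
function — and the photon-count statistics follow the implied binomial law,
which the suite checks at 5 sigma.

The scan position `x(t)` is uniform in time across the visible window,
mirroring the snake's binning exactly. This is a deliberate idealization:
with zero jitter and prompt emission the allocator inverts the simulator
*photon for photon* (exactness 1.0 against the emission ledger), which is
the package's strongest end-to-end property. What the simulator does not
model — the resonant mirror's sinusoidal velocity within the window,
optical point-spread, detector dead time and afterpulsing — means a passing
round trip demonstrates the correctness of the event-stream bookkeeping,
not image fidelity on a physical instrument.

Built-in phantoms: `uniform` (fluorescein-bath analogue), `grid`, `blobs`
(soma-like spots), and `vessels3d` (connected tubes threading all planes).
All are deterministic functions of their parameters and seed.

## Study conditions and problem sizes

The default conditions mirror the modeled instrument: an 80 MHz laser
(`laser_period_ps = 12500`), a 15.36 kHz resonant line rate (the scanner
that yields 30 frames/s at 512 lines), a 189 kHz TAG lens, fill fraction
0.8, and `p_pulse_max = 0.1`. Scanner and lens rates are physical
constants, so scaled-down test frames keep the *frequencies* and shrink
the pixel counts: a 64-line volume at the physical line rate completes in
4.2 ms. This preserves the line/TAG frequency ratio that causes voxel
skipping — the mechanism under test — whereas slowing the scan to hold
"volumes per second" fixed at a small frame size would let each pixel
dwell a full TAG cycle and erase the effect. The projection-fidelity study
conversely uses a slow 1.92 kHz (galvo-style) line rate precisely so every
plane is sampled within a short recording.

The shipped checks use 64 x 64 (x 8) frames, 3-20 frames or volumes per
run, and photon budgets of roughly 10^3-10^4 per run; each completes in
seconds. Fill fraction's centered-window convention, the 0.8 default, and
the sum-not-average display convention are package choices exposed in the
configuration, since the instrument description fixes none of them.

## Numerical choices

* All periods are rounded once, to integer picoseconds, at configuration
  time; every later comparison is exact integer arithmetic in doubles
  (values stay far below 2^53).
* Pixel boundaries are rounded per boundary (`round(c * tau)`), so a
  line's cells tile its window exactly with no accumulating drift.
* Streams are processed frame by frame (bounded memory in the frame size,
  unbounded stream length); the causal pairing of syncs and photons never
  crosses a frame boundary.
* Degenerate inputs fail loudly and early: sub-picosecond pixel dwell,
  reordered syncs after jitter, records outside a buffer. Photons before
  any sync are counted (`pre_sync`), never fatal.

## Known limitations

* No spatial linearization of the resonant mirror's sinusoidal velocity;
  image space is indexed by pixel/plane number, not micrometers.
* Exactly two demultiplexed streams; the schema carries `n_streams` so a
  generalization would not change stored records.
* No live hardware acquisition; replay of recorded open-format streams
  and simulation cover the computational contract. Vendor-proprietary
  stream containers need an external converter to the open dialect.
* Detector dead time, afterpulsing and optical blur are not modeled, so
  simulator-based fidelity numbers are upper bounds for real instruments.
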