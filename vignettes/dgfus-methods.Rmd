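---
title: "Mechanistic monitoring of focused-ultrasound neuromodulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic monitoring of focused-ultrasound neuromodulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgfus)
```

## What this package computes

Displacement-guided focused ultrasound (DgFUS) neuromodulation experiments
monitor three linked readouts while an acoustic beam stimulates the brain
through a cranial window:

1. **In-situ brain displacement.** The acoustic radiation force (ARF) of the
   FUS pulse pushes tissue axially by a few micrometres.  Imaging this push
   confirms that the beam is on target and quantifies the delivered
   mechanical dose.
2. **Cerebral blood volume (CBV).** Functional ultrasound (fUS) images blood
   volume at a 1 Hz functional rate via power Doppler; stimulus-locked CBV
   increases are a proxy for evoked neural activity.
3. **Motor output.** EMG records compound muscle action potentials (CMAPs)
   evoked by the stimulation; video keypoint tracking yields paw
   kinematics; the open-field assay indexes anxiety-related behaviour.

`dgfus` implements the full processing chain for each readout, the
cross-modal statistics linking them, and a seeded synthetic-data generator
that provides ground truth for validating every stage.  The generator is
the package's test bench: it emulates the acquisition physics well enough
to exercise the estimators, while making the quantity each estimator
should recover available in closed form.

## Acquisition model

All protocol constants live in spec constructors:

* `transducer_spec()` — a 128-element linear array at a 15.625 MHz carrier.
  The receive sampling rate defaults to four times the carrier
  (62.5 MHz); the element pitch defaults to 100 µm, approximately one
  wavelength (both are declared package defaults, configurable).
* `displacement_scheme_preset()` — 12 plane waves evenly spaced in ±3°,
  1.5 transmitted cycles, one compounded RF frame every 0.768 ms.
* `doppler_scheme_preset()` — 13 plane waves in ±7°, 500 Hz compound frame
  rate, 150 compound frames per power-Doppler image (1 Hz functional rate).
* `fus_pulse_spec()` — a single continuous 80 ms pulse at 4 MHz
  (`pulse_cycles(0.080, 4e6)` = 320 000 cycles), 10 s trains at 1 Hz.
* `session_spec()` — 270 functional samples at 1 Hz with seven 10 s
  stimulation periods.  The inter-stimulus interval is not a protocol
  constant; the preset places a 30 s baseline and onsets every 34 s so
  that all seven periods and their relaxations fit in the session.

The mechanical index is `pressure [MPa] / sqrt(f_c [MHz])`, truncated (not
rounded) to two decimals as conventionally reported: 3.39 MPa at 4 MHz
gives MI 1.69.

## Synthetic data: what it emulates, and what it does not

`make_phantom()` scatters point reflectors with standard-normal
reflectivities over a 2D imaging plane; vessels are axis-aligned boxes with
their own blood scatterer population and flow velocity.  A density near
1500 scatterers/mm² gives ~10 scatterers per resolution cell at
15.625 MHz — fully developed speckle, which the displacement estimator
requires.  `evolve_phantom()` produces the medium state at time *t*:

* tissue and blood are displaced axially by a Gaussian ARF push field
  (`arf_push_spec()`: focal widths, peak micron displacement, rise/decay
  envelope);
* blood scatterers advect along the vessel flow with wrap-around, which
  decorrelates blood speckle between compound frames as real flow does;
* blood reflectivity **variance** is scaled by
  `1 + a · response(t)` inside the active region, so expected Doppler
  power — which is what power Doppler estimates — carries the prescribed
  fractional CBV change exactly.

The hemodynamic response (`hemodynamics_spec()`) treats every 10 s
stimulation as one event eliciting a stereotyped gamma-shaped response with
mode 4 s (shape 3), normalized to peak 1, so `response_amplitude` is the
peak fractional CBV change and the response persists 10–20 s past onset.
This mirrors the measured behaviour of FUS-evoked CBV — peaking ~4 s after
train onset and outlasting the train — rather than an integrating boxcar
response, which would necessarily peak only after the train ends.  No
quantitative FUS hemodynamic response function is established; this kernel
is a declared generator stand-in, not a measured quantity.

`simulate_rf()` implements the standard plane-wave point-scatterer echo
model: element *e* receives from scatterer *s* a 1.5-cycle raised-cosine
burst delayed by `(z cosθ + x sinθ)/c + |r_e − r_s|/c`.  The carrier phase
is centred on the envelope so the pulse is exactly zero-mean; a transducer
is band-pass and transmits no DC, and a DC-bearing pulse floods the
beamformed image with low-frequency haze that destroys speckle tracking.
Omitted on purpose (neutral knobs): attenuation, element directivity,
elevation dimension, nonlinearity, skull aberration.  Passing tests
therefore show the *estimators* are correct, not that the simulator
reproduces every property of in-vivo RF data.

For full-length functional sessions, per-frame RF simulation is
prohibitively slow, so `synth_functional_session()` generates compound
frames at the statistical level: a low-rank, slowly drifting tissue
clutter component, frame-independent blood speckle whose variance follows
the same `1 + a · response(t)` law, and white noise.  Blocks are produced
lazily and reproducibly (block *k* reseeds at `seed + k`).  The RF route
and the statistical route are cross-checked against each other in the test
suite on a reduced grid.

## Beamforming

`das_beamform()` is classic delay-and-sum with linear inter-sample
interpolation onto a fixed grid: lateral spacing equal to the pitch and
axial spacing `c/(2 f_s)`, so one RF sample corresponds to one axial pixel
and the NCC lag-to-micron conversion `c/(2 f_s)` = 12.32 µm/sample is
exact.  `compound()` averages the per-angle frames coherently.

The receive aperture is gated by an f-number (default 1): only elements
within `|x − x_e| ≤ z/2` contribute to a pixel at depth *z*.  At
millimetre depths under a 12.8 mm aperture, an ungated sum admits receive
angles beyond 60°, whose contributions carry axial frequencies down to
`f_c(1 + cosθ)/c`; the axial spectrum broadens and shifts low, and
sub-sample speckle tracking becomes biased far beyond tolerance.  `f_number
= 0` restores the full aperture.  No apodization is applied by default.

## Displacement estimation

`ncc_displacement()` estimates the per-pixel axial shift between a
reference and a current compound RF frame:

* per lateral line, overlapping axial windows (default 16 samples ≈ two
  carrier wavelengths, 80% overlap) are normalized-cross-correlated over
  integer lags within ±8 samples;
* each line is first upsampled 4× by FFT zero-padding.  Micron pushes are
  0.1–0.2 samples at the native grid, and any 3-point sub-sample fit
  shrinks such estimates toward zero by ~10%; correlating on the 4× grid
  removes that bias (the effect is verified in the test sweep);
* the integer peak is refined by a 3-point cosine fit — exact when the
  correlation peak is locally sinusoidal, which carrier-band RF
  guarantees — with a parabolic fallback when the local peak frequency
  leaves the well-conditioned band;
* flat (zero-variance) windows return displacement 0 with quality 0 and
  are counted.

`displacement_sequence()` tracks every frame against the first, pre-push
frame: the peak displacement is a plateau metric, and cumulative tracking
reads it directly (consecutive-pair tracking is available as
`mode = "interframe"`).  `focal_contour()` thresholds a map at
−3 dB of its maximum; for a Gaussian push field the resulting area has the
closed form `2π ln(10^{3/20}) σ_x σ_z`, used as the recovery oracle.
`roi_displacement()` averages a 5×5 pixel window centred, by cross-module
contract, on the activation map's correlation argmax.

Positive displacement means motion away from the array (deeper), the
direction of the ARF push.

## Clutter filtering, power Doppler, activation

`svd_clutter_filter()` forms the Casorati matrix (pixels × frames) of a
150-frame block and zeroes the 30 largest singular components — the
stationary and slowly moving tissue signal — leaving blood speckle.
Energy splits exactly between the kept and removed subspaces
(orthogonality), which the tests assert to 1e-6 relative.

`power_doppler()` sums squared filtered samples per pixel.  Doppler power
is quadratic in blood amplitude, and for i.i.d. noise its expectation is
`block_len · σ²`; both properties anchor the tests.  `cbv_series()`
converts power-Doppler sequences to percent change from a pre-stimulus
baseline (all samples before the first stimulation by default).

`activation_map()` correlates each pixel's time series with the binary
stimulus vector, optionally shifted by a lag (positive lag delays the
stimulus; overhang is truncated, never wrapped).  The significance
threshold r > 0.2 is one-sided and corresponds, via the Fisher transform
`z = atanh(r)·sqrt(n−3)`, to z > 3.3 and p < 0.001 at n = 270 samples;
`null_threshold_fpr()` verifies the calibration by Monte-Carlo simulation.
No multiple-testing correction is applied, matching the fixed-threshold
convention.  `activated_area()` reports mask size across a lag grid;
because a robust effect saturates the mask over several lags,
`area_peak_lag()` reports the centroid of the ≥95%-of-max plateau rather
than a bare argmax.  `roi_response()` averages stimulus-locked epochs and
reports the peak percent change and its latency within 20 s of onset —
responses outlast the 10 s train, so the search window extends past it.

One caveat established during validation: with a fixed cutoff of 30, the
leading *blood* singular components concentrate in the highest-variance
(active) pixels, so part of the modulation itself is removed and percent
CBV amplitudes are compressed by roughly 10–20% on synthetic sessions.
Detection, localization and timing are unaffected; amplitude-accuracy
tests therefore match the cutoff to the generator's tissue rank.

## EMG and kinematics

`rms_envelope()` takes a centred moving RMS of the rectified trace.  The
default window is 1 ms: the CMAP detection window ends at 79 ms and the
FUS-offset artifact of an 80 ms pulse begins at 80 ms, so a centred window
wider than 2 ms would smear the artifact into the detection window.
`detect_peaks()` searches each pulse's 50–79 ms post-onset window for
local envelope maxima and keeps the largest; pulses whose envelope peaks
outside the window yield no peak and are reported in a diagnostics table.
`normalize_peaks()` divides amplitudes by the mean peak of the
highest-pressure group.  Latency is reported at envelope-sample resolution
(0.1 ms at 10 kHz).

`paw_velocity()` differentiates the paw-edge keypoint trajectory,
converting to px/ms, with the sign taken from the lateral component so
lateralized movements are signed; frames below the likelihood cutoff
(0.9) are linearly interpolated and counted.

## Cross-modal statistics and behaviour

`colocalization()` takes a displacement map and an activation map on a
common grid, computes the pixelwise Spearman correlation inside a brain
mask, and compares displacement between activated (r > 0.2) and
non-activated pixel groups with a Welch t-test.  `spearman()` uses
mid-ranks with an exact permutation p for n ≤ 10 and the t-approximation
otherwise (validated against full enumeration in the tests); `linreg()`
wraps ordinary least squares.  Group-comparison wrappers (`paired_t()`,
`welch_t()`, `anova_tukey()`, `anova_welch()`) expose the standard test
menu through base R.

`zone_spec()` fixes the open-field geometry — a 40 cm arena with an 8 cm
peripheral band leaves a 576 cm² centre, 36% of the arena.
`time_in_center()` classifies samples (the border line itself counts as
periphery; the centre is the open set), accumulates dwell time in
5-minute intervals, and reports path length and centre-time per distance.

## Numerical choices and degenerate inputs

* Delays beyond a recorded RF trace contribute zero to beamforming and are
  counted (`n_clipped`), never extrapolated.
* Zero-variance correlation windows, zero-baseline Doppler pixels, empty
  pixel groups and zero-distance tracks are flagged or NA'd with counts,
  not silently dropped.
* Truncation, not rounding, in the mechanical index (a safety index is
  conventionally reported conservatively).
* All generators are bit-reproducible for a fixed seed; derived seeds stay
  below 2³¹.

## Problem sizes used in validation

The test suite exercises the RF route at reduced but physical scale: a
64-element aperture with 6 angles for displacement recovery sweeps, the
full 128-element / 12-angle configuration for the 2 µm push recovery, a
32-element / 3-angle configuration for the RF-to-activation end-to-end
check, and statistical-level sessions (64×64 pixels, 270 s) for the
detection, lag and localization checks.  These sizes were chosen as the
smallest at which the estimators' behaviour is representative of the full
acquisition geometry.

## Known limitations

* 2D imaging plane only; no elevation beam profile.
* No attenuation, directivity, or skull; the simulator validates
  estimators, not transcranial physics.
* The hemodynamic kernel is a stand-in; quantitative CBV amplitudes in
  vivo depend on vascular physiology the generator does not model.
* SVD cutoff effects on amplitude (above) mean percent-CBV values from
  real sessions should be interpreted as filter-conditional.
* A single camera cannot compensate recording angle in paw kinematics;
  velocities are reported in pixel units.
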