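---
title: "Correlator models of reverse-phi motion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlator models of reverse-phi motion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revphi)
library(dplyr)
```

## The problem

When a periodic pattern is displaced in discrete steps and its contrast is
reversed on every step ("reverse-phi" motion), motion detectors — and
behaving animals — tend to report the opposite direction of motion. In the
fly, this illusion reverses back ("re-inverts") at high pattern
velocities. This package implements the modelling and analysis machinery
needed to study that phenomenon end to end: stimulus synthesis,
elementary-motion-detector (EMD) simulation, spatiotemporal Fourier
analysis, and the summarization pipeline for behavioral and physiological
recordings, together with seeded synthetic-data generators that make every
pipeline stage testable without any recorded data.

## The detector models

Both models are one-dimensional arrays of Hassenstein–Reichardt-type
correlators. Each of `n_detectors` units (default 60) reads two
photoreceptors separated by `receptor_spacing_deg` (default 4°, covering
240° of azimuth with 61 receptors; no wrap-around). The shared front end
high-pass filters each receptor signal ($\tau_{HP}$ = 250 ms) and, where a
DC fraction is configured, adds back an attenuated copy of the raw
luminance:

$$x_i(t) = \mathrm{HP}(s_i)(t) + \mathrm{dc} \cdot s_i(t).$$

The **four-quadrant (4Q)** model multiplies these arm signals directly.
For detector $i$, with $\mathrm{LP}$ the delay filter
($\tau_{LP}$ = 50 ms),

$$R_i = \mathrm{LP}(x_i)\,x_{i+1} - x_i\,\mathrm{LP}(x_{i+1}),$$

which is the classical correlator: sign-correct multiplication computes
all four ON/OFF sign combinations at once, so mixed-polarity input (the
essence of reverse-phi) yields negative output at any velocity.

The **two-quadrant (2Q)** model half-wave rectifies the arm signal into
non-negative ON and OFF channels *before* correlation, modelling the
split into T4 (ON) and T5 (OFF) pathways. Each channel runs its own
mirror-symmetric correlator and the two subunit outputs are combined with
weights `w_on`, `w_off` after the subtraction stage. With perfect
rectification the channels never see opposite-polarity interactions; the
tonic DC component (default 10% for the 2Q model) deliberately makes the
rectification leaky, restoring a controlled amount of cross-polarity
sensitivity. Because luminance is positive, the DC term biases the ON arm
upward (it survives ON rectification) and is removed by OFF rectification
— which is why only the ON subunit inverts under reverse-phi at the
default settings, and why `dc_scan()` over signed DC fractions maps the
full transition from veridical to inverted tuning in either subunit.

Array output is the sum over detectors; `mean_response()` averages it
over the motion interval (default `[0.5, 9.5)` s of a 10 s run — the
stimulus-on period; averaging the full run would only rescale results, as
output outside motion is null). `smooth_display()` applies a 200 ms
low-pass to the summed output to emulate the temporal integration of the
visuomotor transformation when analysing time-resolved (biphasic)
dynamics.

### Numerical scheme

All filters are first-order RC filters integrated with the Euler forward
method at `dt_s` = 1 ms:
`y[n+1] = y[n] + (dt/tau) * (x[n] - y[n])`. The high-pass is realized in
complement form, `HP(x) = x - LP(x)`, so `HP + LP` reconstructs the input
exactly. Filter states are initialized to the first input sample, which
makes a static lead-in produce no onset transient and a constant input an
exact fixed point. The step `dt` must be below every time constant
(stability); the defaults keep it at $\tau_{LP}/50$. Half-wave
rectification is `max(x, 0)` exactly — zero stays zero, no offset, and
the rectified decomposition identity `ON(x) - OFF(x) = x` holds at
machine precision, as does the reconstruction of the 4Q multiplication
from its four signed rectified quadrant products.

### The resolution floor for sign claims

A 60-detector array holds 2.67 wavelengths of a 90° grating with the
stripe-boundary phase pinned at receptor 0, so spatial truncation leaves
small phase-dependent residues in time-averaged responses. Probing
responses across pattern-phase origins shows these residues reach a few
percent of a tuning curve's peak magnitude — large enough to flip the raw
sign of points whose true (phase-averaged) response is near zero.
Qualitative sign statements about tuning curves are therefore evaluated
through `response_signs()` / `sign_changes()`, which leave responses
below 5% of the curve's peak magnitude unclassified. The same 5% appears
as the tolerance for mirror antisymmetry of mean responses, which is
exact only up to the same boundary effects. The floor is a reporting
convention, not a model parameter: raw responses are always available.

## Stimuli

Gratings are three-level square waves: alternating "gray" stripes at the
intermediate luminance and "non-gray" stripes that are dark or bright
according to the polarity state. Default luminance levels are
1.05/1.30/1.55 (dark/gray/bright), symmetric about the gray level. Two
clocks drive the dynamics during the motion interval: a displacement
clock (`motion_hz = velocity / step`) that jumps the pattern by
`step_deg`, and a contrast-reversal clock (`flicker_hz`) that flips the
non-gray stripes between dark and bright. Displacements occur at
`onset + k / motion_hz` and reversals at
`onset + (k + phase_offset_frac) / flicker_hz`, so at zero phase offset
the reversal accompanies each jump (reverse-phi) and at offset 0.5 it
falls midway between jumps (the out-of-phase control). `flicker_hz = 0`
is phi motion; setting the clocks independently
(`make_decoupled_stimulus()`) spans the full flicker-by-motion design,
whose zero-flicker row and equal-rate diagonal reduce to phi and
reverse-phi bit-for-bit because all three constructors share one
renderer.

Design choices on points the trial structure leaves open:

* **Flicker gating.** Outside the motion interval the pattern is frozen —
  no displacement *and* no contrast reversal. We treat flicker as a
  property of the moving stimulus; a free-running flicker clock would
  only affect the static lead-in/lead-out, which the analysis window
  excludes.
* **Initial polarity.** Each rendered trial starts with bright non-gray
  stripes by default; every experiment function simulates both initial
  polarities and averages them, emulating per-trial polarity
  randomization and cancelling polarity-dependent transients.
* **Pattern phase.** The stripe boundary sits at receptor 0, with phase
  tracked continuously so wavelengths incommensurate with the array are
  handled exactly.
* **Coordinates.** Receptor index is 0-based, azimuth in degrees, time on
  the half-open interval `[0, duration)`.

Time steps larger than half an active update interval are rejected
(temporal aliasing). Translating noise (`make_translating_noise()`) draws
a random profile at receptor resolution, holds it on a 10×-oversampled
master grid, and translates it rigidly with nearest-sample (0.4°)
displacement quantization — band-limited near the receptor sampling rate,
so its spectral energy falls on the true velocity line.

## Spectral analysis

`magnitude_spectrum()` demeans the luminance grid and applies an
unwindowed 2-D DFT with both axes centered. `quadrant_energy()` averages
squared magnitude (switchable to plain magnitude; the squared form is the
standard motion-energy quantity) within the two direction-signaling
quadrant pairs, excluding the zero-frequency row and column — static
pattern structure and full-field flicker belong to neither direction —
and, on even-sized grids, the sign-ambiguous Nyquist bins, which makes
the pd/nd swap under spatial mirroring exact. The mapping from quadrant
pair to direction is fixed by `calibrate_convention()`, which localizes a
known rightward sinusoid; the default argument calibrates on the fly
(deterministically), and passing `convention = NULL` raises an explicit
error. Stimulus durations are long relative to the pattern periods, so no
taper is needed.

## Empirical-trace pipeline

The summarization procedures mirror a standard tethered-walking /
patch-clamp / two-photon workflow:

* `mirror_subtract()` halves the difference between responses to
  mirrored (rightward vs leftward) presentations, removing any
  direction-independent turning bias exactly and linearly.
* `summarize_turning()` takes the time-mean over `[1.5, 3.0)` s from
  trial onset (motion runs 1.0–2.0 s; the window captures the sustained
  tail of the response).
* `select_flies()` retains flies with a contiguous 40-of-70-trial window
  whose mean walking speed exceeds 4 mm/s (strictly) and whose mean
  turning stays within `bias_tol` of zero, choosing the earliest
  qualifying window on ties. The default `bias_tol` is 10% of the
  cohort's response scale, operationalized as the maximum absolute
  per-trial mean turning — an observable proxy for the peak evoked
  response (about 1.5–2 deg/s under the default generator). Retention is
  monotone in the speed threshold by construction.
* `summarize_voltage()` reports mean depolarization over the first 2 s of
  stimulation against a 0.5 s pre-onset baseline (the baseline length is
  configurable; the recordings' own convention is unstated).
  `cell_included()` applies the 6 mV preferred-direction phi quality
  gate.
* `delta_f_over_f()` estimates the fluorescence baseline as the minimum
  within a centered 15 s sliding window (truncated at the record edges —
  a symmetric choice, since the alignment is otherwise arbitrary) and
  returns `(F - B)/B`, which is invariant to multiplicative rescaling.
* `summarize_imaging()` is the PD−ND difference of window means over
  1–4 s after stimulation onset.
* `bootstrap_ci()` is the percentile bootstrap of the mean with 1,000
  resamplings, deterministic given its seed.
* `downsample()` is integer-factor block averaging (2 kHz → 50 Hz voltage
  traces and the like).

## Synthetic data: what it emulates, and what it does not

`gen_behavior()` produces cohorts with the study's trial structure
(3.5 s trials at 20 Hz, motion 1.0–2.0 s, 70 trials per fly) and planted
ground truth: per-condition turning amplitudes shaped like the bilobed
reverse-phi tuning plus a rising phi tuning, a first-order response
kernel (250 ms rise while motion is on, 1 s decay after offset, so the
1.5–3.0 s window captures a sustained component), a constant per-fly
turning bias (SD 1 deg/s, placing roughly a tenth of flies outside the
bias gate, matching the study's reported ~10% discard rate), white
turning noise (SD 15 deg/s), and per-fly walking speeds around 10 mm/s.
Trials are block-randomized — each consecutive block of 20 presents every
condition × direction cell once — so any contiguous 40-trial window
contains a complete block and the mirror stage never lacks a direction.
The stored `expected_turning_deg_s` is the planted amplitude scaled by
the kernel's mean over the summary window: the quantity an unbiased
pipeline recovers exactly at zero noise.

`gen_voltage()` and `gen_calcium()` plant per-(condition, direction)
amplitudes: sustained depolarization for preferred-direction phi, weak
hyperpolarization for null-direction phi, an inverted null-direction
response under reverse-phi (voltage); and a T4-like profile for calcium —
null-dominant at low, preferred-dominant at high reverse-phi velocities —
on a strictly positive baseline with bounded exponential bleaching and
multiplicative-plus-additive noise.

The noise model is deliberately minimal: additive Gaussian on turning and
voltage, no temporal correlations, no saccades, no adaptation, no
realistic indicator kinetics. Passing plant-and-recover tests therefore
demonstrates that the pipeline's algebra is correct and unbiased under
known ground truth — not that it is robust to every artifact of real
recordings.

A note on coverage: with cohorts of 10 flies, the 95% percentile
bootstrap interval of the mean is slightly anticonservative — a
well-known small-sample property of the percentile method — so the
fraction of conditions whose planted value falls inside the CI sits just
below the nominal level even though the estimator itself is unbiased (the
same machinery covers at ~95% in a Gaussian Monte-Carlo at n = 50). This
is a property of the spec'd method at the study's cohort size, and the
package reports it as measured.

## Problem sizes and determinism

Default experiments use the full array (60 detectors, 1 ms steps, 10 s
runs, 20 log-spaced velocities from 1 to 1000 deg/s). The test suite
exercises the same code paths on reduced grids (about 12 detectors, 2 ms
steps, 3 s runs) where the property under test does not depend on the
full scale, and at full scale for the end-to-end checks; wavelength-law
peak ratios are measured on dense 25-point local velocity grids because
the standard 20-point grid quantizes peak locations to a factor of 1.44.
Everything outside the noise stimulus and the synthetic generators is
deterministic given its configuration; all randomness flows through
explicit seeds.

## Known limitations

* One spatial dimension, no photoreceptor optics or blur, no display
  gamma, no perspective geometry.
* Purely multiplicative nonlinearity: no preferred-direction enhancement
  combined with null-direction suppression, no adaptation, no conductance
  or spiking dynamics.
* The finite, non-wrapping array leaves boundary residues of up to a few
  percent of peak in mean responses (hence the resolution floor).
* Model parameters are fixed defaults taken from the established
  parameter set for this detector family, not fitted to data; the
  package intentionally provides no fitting machinery.
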