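---
title: "Methods: contactless tremor quantification from hand-landmark trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contactless tremor quantification from hand-landmark trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorkit)
```

## The measurement model

A markerless hand tracker turns each video frame into 21 landmark
positions (wrist, finger joints, fingertips), with x and y normalized to
[0, 1] by the frame width and height. Holding the camera and hand framing
fixed, a landmark's y-trace over time is a uniformly sampled displacement
signal at the video frame rate, and rhythmic hand movement appears as a
spectral peak. Three rhythmic components matter in a resting or postural
hand:

* **tremor** — in classical parkinsonian tremor a 4–6 Hz oscillation,
  clinically the object of interest;
* **ballistocardiographic movement** — the heart beat (60–90 bpm at rest,
  i.e. 1–1.5 Hz) conducted into the limbs; in hands without overt tremor
  this is the *dominant* rhythmic component, so tremor-free recordings
  legitimately yield 1–2 Hz estimates;
* **postural drift** — slow baseline wander well below 0.5 Hz.

The estimator assumes the hand stays in frame and roughly in posture over
the analysis window, that the tracker's per-frame jitter is broadband and
small relative to the movement of interest, and that the movement is
narrowband enough within each 2-s segment for a single dominant peak to be
meaningful. It does not assume the tremor frequency is constant across the
recording — that is precisely why short segments are fused rather than one
long FFT taken.

## Pipeline and tunable parameters

`estimate_tremor()` chains the following stages. Every tunable lives in
one configuration (`default_config()`, YAML-loadable with schema
validation via `load_config()`).

| stage | parameter (key) | default | why |
|---|---|---|---|
| trim | `trim.cut_start_s`, `cut_end_s` | 2 s, 2 s | hands enter/leave the test posture at the ends of a recording |
| trim | `trim.analysis_window_s` | 10 s | fixed-length window makes recordings comparable; 5 segments |
| filter | `band.low_hz`, `band.high_hz` | 0.5, 15 Hz | below 0.5 Hz is drift, above 15 Hz only noise; tremor sits well inside |
| filter | `filter.order`, `filter.zero_phase` | 4, true | 4th-order Butterworth band-pass, forward–backward so peak locations are phase-undistorted |
| segment | `segment.length_s` | 2 s | tracks frequency variation over time; native grid 0.5 Hz |
| spectrum | `spectrum.resolution_hz` | 0.05 Hz | zero-padded read-off grid; see numerical choices |
| spectrum | `spectrum.window` | rectangular | simplest calibrated choice; Hann available for strong out-of-band interference |
| signal | `signal.axis` | y | cameras are placed so tremor shows as vertical motion |
| signal | `signal.differentiate` | none | see open choices |
| fusion | `outlier.k`, `outlier.sd_mode` | 3, sample | single-pass 3-SD elimination; sample SD because per-recording counts are small (15–105 values) |
| fusion | `outlier.pooling` | pooled | reject elementwise over all landmark × segment values |

Amplitudes are calibrated so that a pure in-band sinusoid of displacement
amplitude *a* yields a spectral peak of height ≈ *a* (one-sided amplitude
spectrum, normalized by the unpadded segment length, non-DC bins doubled,
coherent-gain–corrected under Hann). Video amplitudes are therefore in
normalized-coordinate units (multiply by frame height via `to_pixels()`
for pixels); accelerometer amplitudes are in cm/s². The two scales are
not mutually convertible without knowing the hand's physical extent in
the frame, which is why cross-method amplitude agreement is assessed by
correlation, never by absolute comparison.

## Numerical choices

* **Sub-bin frequencies.** A 2-s segment has a native 0.5 Hz grid.
  Segments are zero-padded until the grid spacing is at most
  `spectrum.resolution_hz` (0.05 Hz). Padding interpolates the spectrum —
  it adds no information, but it lets a peak sit at a fractional
  frequency, and averaging many segment peaks then produces the
  three-decimal cohort values practitioners report. This is a documented
  choice, not the only defensible one (parabolic peak interpolation would
  serve equally).
* **Filter edge transients.** Zero-phase filtering is applied after
  odd-reflection padding of 3/`low_hz` seconds at both ends (the impulse
  response of the 0.5 Hz edge is the longest); without it, start/end
  transients corrupt the first and last segments.
* **Windowing and leakage.** With the rectangular window, a strong tone
  just outside the band can leak sidelobes (−13 dB first lobe) onto the
  refined grid inside the band and outweigh a much weaker in-band tone.
  In the full pipeline the band-pass filter removes such tones before the
  spectrum; for spectrum-only use with strong out-of-band interference,
  select the Hann window (−31 dB sidelobes).
* **Detrending.** Segment means are removed before the FFT; the band-pass
  already suppresses DC, this guards short-segment leakage.
* **Ties.** If two grid points attain the identical maximal power, the
  lowest frequency wins — deterministic and reproducible.
* **Degenerate inputs.** A constant frequency vector (SD = 0) and a
  single value are never rejected; single-pass k·SD rejection on finite
  data cannot reject everything (the value nearest the mean is always
  within k·SD), which the fusion asserts. Recordings too short for the
  trim policy, bands at or above Nyquist, and signals shorter than one
  segment all raise explicit errors rather than degrading silently.
* **Report rounding.** Tables print at 3 decimals, half away from zero
  (`round_half_up()`); all internal computation is full precision.

## Outlier fusion and its breakdown point

The single-pass rule marks a value f with |f − mean| > k·SD, then averages
the survivors. For a contaminated fraction *p* of values clustered a
distance *d* from the clean peak, the outlier deviation is (1 − p)·d while
the threshold is 3·√(p(1 − p))·d: rejection succeeds only for
*p* < 1/10. With 21 landmarks × 5 segments, that is up to ~10 aberrant
cells — one or two fully occluded landmarks, or scattered bad segments
across several. This is the operating regime the estimator is designed
for; it is *not* a high-breakdown estimator, and a majority-contaminated
recording (half the hand out of frame throughout) will bias the fused
value. The `outlier.pooling = "per_landmark_mean"` mode applies the same
rule to the 21 per-landmark mean frequencies instead, which is coarser
but more interpretable when whole landmarks fail.

## What the synthetic generator emulates — and what it does not

`simulate_recording()` generates each visible landmark as
baseline + tremor sinusoid + heartbeat sinusoid + slow drift + white
jitter (defaults: 180 fps, 14 s, tremor 4 Hz at 0.01 normalized units
≈ 10 px at 1080p, heartbeat 1.2 Hz at 0.002, drift 0.005 at 0.1 Hz,
jitter SD 0.001 ≈ sub-pixel). `simulate_accelerometer()` returns the
analytic second derivative of the same displacement model (a displacement
*a* at *f* Hz → *a*·(2π*f*)² scaled by a configurable 10 cm per
normalized unit), plus sensor noise.

**Occluded landmarks.** Trackers never report a missing landmark: they
infer its position from the visible hand. The generator therefore models
an occluded landmark as the hand-coherent displacement *plus* a
structured wander (a random walk low-pass filtered at 2 Hz, uncorrelated
with the tremor, RMS 0.01) and doubled jitter. A minority of such
landmarks' segments then peak at a non-tremor frequency — which the 3-SD
fusion rejects. We deliberately did not model occluded landmarks as pure
tremor-uncorrelated noise: with 4 of 21 landmarks occluded that would put
~19% of pooled values in a coherent off-tremor cluster, beyond the 10%
breakdown fraction derived above, and *no* mean-plus-k·SD estimator could
absorb it. The inference-anchored model matches how trackers actually
produce pseudo-landmarks and keeps the contamination in the estimator's
design regime.

The generator does **not** emulate: tracker dropout correlated with pose,
perspective changes or camera motion, amplitude differences between
fingertips and wrist (all landmarks share the hand motion), harmonic-rich
non-sinusoidal tremor waveforms, or frequency drift within a recording.
Passing the synthetic recovery suite therefore demonstrates the signal
path and the fusion logic are correct; it does not certify performance on
real video, which is what the accelerometer-validation statistics on the
shipped benchmark cohort are for.

`make_cohort()` mirrors a realistic study: 11 patients, 2 of them with
4–5 Hz parkinsonian tremor, the rest with 1–1.5 Hz ballistocardiographic
movement; medication reduces frequency by 0.5 Hz (floored at 0.9 Hz so
the signal stays inside the band — the realized per-patient deltas are
recorded in the returned ground-truth table) and halves displacement.

## Open design choices

* **Change scores.** Medication tables compute change strictly as
  `after − before`. In the shipped benchmark amplitude table one
  patient's printed change (−1.900) is inconsistent with its own
  before/after values (2.213 / 2.023 → −0.190); the package recomputes
  from before/after, so its cohort mean change (−4.134 a.u.) differs from
  the historically printed one (−4.304 a.u.). The before/after column
  means themselves (8.167 → 4.033) are unaffected.
* **Displacement vs. acceleration.** Whether to difference the video
  signal to acceleration before the spectrum is a genuine fork: frequency
  estimates are invariant for narrowband signals, amplitudes are not
  (they gain (2π*f*)² and lose displacement units). The default analyses
  displacement (`signal.differentiate: none`), keeping video amplitudes
  interpretable; `second_difference` is one switch away.
* **Accelerometer sampling rate** is a required user input — device rates
  vary and guessing one silently would corrupt every frequency. Synthetic
  traces default to 100 Hz, a typical clinical accelerometer rate and
  comfortably above the 30 Hz Nyquist need of the 15 Hz band.
* **Visibility flags.** The interchange format carries an optional
  per-landmark `visible` column, but the estimator ignores it: occlusion
  is handled by outlier rejection downstream, not by imputation or
  weighting, so recordings from trackers that report no visibility remain
  first-class inputs.

## Problem sizes used by the test suite

The property suite runs the full pipeline on 100 seeded replicates per
tremor frequency in {1, 1.5, 2, 4, 5} Hz, 100 occlusion replicates with
1–4 occluded landmarks, and brute-force cross-checks of the rejection
rule on 300 random vectors; the acceptance script uses 20 replicates per
frequency and 50 occlusion pairs. These sizes give binomial standard
errors of ~2% on the reported rates while keeping a complete run in the
low minutes on a laptop; they are the package's chosen reporting sizes,
and all are driven by a single seed.

## Known limitations

* Amplitude is reported in normalized units for video; comparisons across
  cameras, fields of view, or subjects require an external physical scale.
* One dominant frequency per recording: multi-peak tremors (rest +
  re-emergent postural components), harmonics, and time–frequency
  structure are out of scope.
* The 3-SD fusion tolerates at most ~10% aberrant values (see breakdown
  analysis); heavily corrupted recordings need manual review — the
  `excluded_mask` and `plot()` method exist to make that review easy.
* Estimates at the low band edge (≤ 1 Hz) are slightly attenuated and
  skewed by the high-pass shoulder; the floor on synthetic medication
  effects (0.9 Hz) keeps tests away from the worst of it, but real
  recordings with sub-1 Hz movement deserve caution.
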