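# tremorkit

Contactless quantification of hand tremor from markerless hand-landmark
trajectories, with accelerometer validation and before/after-medication
comparison statistics.

## The problem

Tremor — involuntary rhythmic movement, classically 4–6 Hz in Parkinson's
disease — is usually quantified with contact sensors (accelerometers, EMG).
High-frame-rate video plus an AI hand tracker offers a contactless
alternative: per frame, a tracker returns 21 hand landmarks (wrist, finger
joints, fingertips) with coordinates normalized to [0, 1] by the frame
dimensions. The vertical (y) trace of each landmark is then an ordinary
uniformly sampled signal whose dominant spectral peak is the movement
frequency of the hand. tremorkit implements the analysis side of this
pipeline for clinical movement-disorder researchers: it starts at landmark
trajectories (any tracker that can emit a per-frame landmark CSV/JSON
works) and produces per-recording frequency/amplitude estimates plus the
statistics used to validate them and to measure medication effects.

## The estimator

For a recording with frame rate `fs` (≥ 180 fps recommended so waveforms
are blur-free and well sampled):

1. **Trim** a couple of seconds from both ends (hands enter/leave the test
   posture) and keep a 10-s analysis window — defaults (2 s, 2 s, 10 s).
2. **Extract** the y-trace of each of the 21 landmarks.
3. **Band-pass** 0.5–15 Hz (4th-order Butterworth, applied
   forward–backward so peaks do not shift).
4. **Segment** into non-overlapping 2-s windows (5 per 10-s video window;
   15 per 30-s accelerometer trace).
5. **FFT** each segment (mean-removed, zero-padded to a 0.05 Hz grid); the
   band-restricted peak gives that segment's dominant frequency *f* and
   amplitude *A* (calibrated so a sinusoid of amplitude *a* reads
   *A ≈ a*).
6. **Fuse** the pooled 21 × 5 (or 1 × 15) values robustly: values with
   |f − mean| > 3·SD — typically produced by occluded, pseudo-inferred
   landmarks — are eliminated automatically in a single pass, and the
   surviving frequencies (and the amplitudes at the same positions) are
   averaged:

   f̂ = mean{ f_ij : |f_ij − f̄| ≤ 3·SD }.

Validation against a simultaneous accelerometer uses, per patient *i*,
the absolute error Δf_i = |f_acc,i − f_vid,i|, the cohort RMSE
√(1/n · Σ (f_acc,i − f_vid,i)²), and the Pearson correlation of the paired
frequencies (and amplitudes). Medication effect is summarized per patient
as `after − before` with cohort mean ± SD.

## Worked example

```r
library(tremorkit)

# A synthetic 14-s, 180-fps recording: 4 Hz tremor of 0.01 normalized
# units displacement, a 1.2 Hz heartbeat component, drift, tracker jitter.
rec <- simulate_recording(sim_config(tremor_freq_hz = 4, tremor_amp = 0.01,
                                     seed = 7))
est <- estimate_tremor(rec)
print(est)
#> Tremor estimate (video)
#>   patient: synthetic  session: unspecified
#>   dominant frequency: 4.000 Hz
#>   amplitude:          0.009986 normalized
#>   values used: 105, excluded as outliers: 0 (|v - mean| > 3 SD)
coef(est)
#> dominant_freq_hz        amplitude
#>      4.000000000      0.009986469
```

The estimator recovered the configured 4 Hz tremor exactly (the spectral
grid is 0.05 Hz) and its displacement amplitude within 0.2%. The same
`estimate_tremor()` call accepts an accelerometer `uni_signal` (30 s →
15 segments). Per-patient estimate sets are compared with
`build_comparison_table()` (accelerometer vs. video: AE, RMSE, Pearson r)
and `build_medication_table()` (before vs. after medication). The
package ships the per-patient benchmark tables of an 11-patient PD cohort
(`pd_cohort_table()`); running the evaluation module on them prints the
cohort statistics: mean AE 0.230 (±0.174) Hz, RMSE 0.283 Hz, frequency
r = 0.98, mean frequency 2.013 → 1.526 Hz after medication (change
−0.487 Hz), mean amplitude 8.167 → 4.033 a.u.

A thin command-line wrapper over these functions is included at
`inst/cli/tremorkit.R` (`simulate`, `analyze`, `compare`, `meds`
subcommands; YAML config via `load_config()`).

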