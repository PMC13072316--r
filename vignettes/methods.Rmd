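---
title: "Measuring broiler respiratory rate by phase-based video magnification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring broiler respiratory rate by phase-based video magnification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrvideo)
```

## The measurement problem

Breathing in broilers is driven by the thoracic cage and the air sacs. Both
transmit to the body surface: the chest/back region undulates with the
thoracic cage, and the tail moves with the air sacs, in the same rhythm.
On thermal video at typical pen working distances these undulations are a
fraction of a pixel, invisible to direct tracking. The package therefore
amplifies the *phase* of a complex multi-scale image decomposition — where
sub-pixel translation appears as a clean, linear phase shift — and reads
the respiratory rate (RR) from the amplified signal's spectrum.

Measurement is only meaningful while the bird is otherwise still, so a
screening stage precedes everything: 10-second windows whose integrated
body motion exceeds 1.5 px are rejected.

## Model

For a one-dimensional intensity profile translating by δ(t), each Fourier
component at spatial frequency ω is

  S_ω(x, t) = A_ω e^{iω(x + δ(t))}.

A DC-balanced temporal filter applied to the phase ω(x + δ(t)) removes the
static ωx term, leaving the motion term B_ω(x, t) = ω δ(t). Scaling the
phase deviation by α and re-inserting it yields

  Ŝ_ω(x, t) = S_ω e^{iαB_ω} = A_ω e^{iω(x + (1+α)δ(t))},

i.e. a displacement gain of exactly (1 + α). The pipeline never renders
Ŝ_ω as video: the amplified phase signal is itself the measurement, which
avoids reconstruction distortion. The series stored per pixel/sub-band is
(1 + α)·B_ω, so that at α = 0 it reduces to the band-passed phase and the
amplitude ratio between α = 40 and α = 0 is 41 — both facts are enforced by
tests. (A reading of "multiply by α" that stored α·B_ω alone would make the
α = 0 output identically zero and the gain α rather than 1 + α; the stored
form is the one consistent with the gain law above.)

RR is then the frequency of the largest magnitude-spectrum peak inside the
physiological band:

  F_k = Σ_{n=0}^{N−1} f_n e^{−i2πkn/N},  k chosen as argmax |F_k| over
  0.3 Hz ≤ f_k ≤ 3.0 Hz,

with every peak outside the band treated as interference and discarded.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| quiet threshold | 1.5 | px per 10-s window | integrated-trajectory bound separating breathing from locomotion |
| screening window | 10 | s | longer windows degrade magnification of weak transient signals; shorter ones lose spectral resolution |
| window stride | 1 | s | latency/cost balance (unspecified upstream; chosen here) |
| pyramid levels | adaptive 1–4 | — | `clamp(floor(log2(min(H,W))) − 4, 1, 4)`: keeps the coarsest band ≥ ~16 px |
| orientations | 8 | — | fixed; spans 180° with analytic half-plane filters |
| band | 0.3–3.0 | Hz | broiler RR range; absolute bandwidth 2.7 Hz |
| α | 40 | — | amplification factor |
| peak refinement | on | — | 3-point parabolic interpolation of log-magnitude |

## Numerical choices

**Steerable pyramid dialect.** Frequency-domain, polar-separable filters:
raised-cosine-in-log₂ radial profiles with octave bandwidth, cos⁷ angular
windows, non-decimated (all sub-bands at frame resolution). The squared
filters sum to 1 pointwise, so reconstruction (kept only as a self-test)
and the energy identity hold to machine precision; the suite requires
≤ 1e−4 relative error and observes ~1e−15. The upstream construction is
not named anywhere, so this dialect is declared and tested by its own
invariants rather than assumed to match any reference binary. Note the
cos⁷ angular windows overlap adjacent orientations by design; orientation
"purity" tests therefore compare bands at angular distance ≥ 2. Boundary
handling is periodic (FFT); ROIs are interior crops, so wrap-around
artifacts do not touch the measured arcs.

**Phase handling.** The temporal filter is applied to *unwrapped* phase
(successive differences folded into (−π, π], then re-integrated), not to
wrapped phase differences; both satisfy the small-motion model, but
unwrapping keeps the series linear for excursions past ±π. Pixels whose
time-mean amplitude falls below 10⁻⁶ of the input intensity maximum are
excluded — the phase of a near-zero coefficient is noise. The floor
comparison is strict, so an all-zero input retains nothing and fails
loudly rather than averaging noise.

**Aggregation.** Nothing upstream specifies how thousands of per-pixel
phase series become one signal. Local phase sign follows the local
gradient direction, so the two sides of a ridge oscillate in antiphase and
naive averaging cancels them. Each series is therefore sign-aligned
(flipped when negatively correlated with the highest-weight series),
pooled by amplitude²-weighted mean, and re-aligned once against the pooled
estimate. The thoracodorsal and tail ROIs are pooled together by default
(`roi_mode = "fused"`) since they share one rhythm; `"separate"` measures
them independently and keeps the stronger peak.

**Motion amplitude.** The screening literature leaves "motion amplitude"
underdefined (mean, median, max, integrated?). Summing per-frame
displacement *magnitudes* would integrate monotonically and eventually
trip the threshold even for zero-mean breathing motion, contradicting the
requirement that breathing itself must never cause rejection. The package
instead integrates the per-frame *median flow vector* (over
structure-tensor-valid pixels) from the window start and takes the peak
trajectory norm: drift and locomotion accumulate, zero-mean breathing does
not, and flow noise grows only as a random walk. Restricting the median to
gradient-valid pixels matters for the same reason: a drifting,
texture-poor body moves only at its silhouette, and an unrestricted median
over the box would read zero during whole-body drift.

**Optical flow.** No flow implementation exists in the supported R
dependency set, so the package ships an iterative dense Lucas–Kanade
solver (7×7 window sums via separable cumulative sums, bilinear warping,
2 refinement iterations). Its contract — documented accuracy ≤ 0.2 px on
1-px synthetic shifts — is asserted in the suite, which measures ~0.003 px
error on smooth texture.

**Peak refinement.** A 10-s window at 30 fps has 0.1-Hz native resolution;
3-point parabolic interpolation of the log-magnitude around the argmax
recovers sub-bin precision (≤ 0.03 Hz on clean off-grid tones, measured).
Refinement is skipped when the neighbouring bins are negligible (an
exact-bin tone has no leakage to interpolate), and the sub-bin offset is
clamped to ±half a bin. Ties at exact equality resolve to the lower
frequency — the physiologically conservative choice. An optional
signal-quality gate (`require_peak_snr`) rejects spectra whose in-band
maximum is under 5× the in-band median; it is **off** by default because
the plain rule always returns the global in-band maximum.

## The synthetic world

`generate_clip()` renders a warm ellipse (default 200 intensity units on a
60-unit background, logistic edge with ~3-px 10–90% width) whose boundary
displaces radially by `breath_amp_px · sin(2π·f·t)` on two angular arcs —
the dorsal crest and the tail end — in phase, as the air sacs and thoracic
cage move together (an `antiphase` switch exists purely to stress-test
sign alignment). Sub-pixel motion enters through the analytic edge, not
through interpolation, so the (1+α) gain test is not confounded by
resampling artifacts. Defaults state the target acquisition: 30 fps, 60-s
clips, 120×160 px frames, 0.2-px breathing amplitude (the true surface
amplitude at working distance is unreported; 0.05–0.5 px is the documented
assumption and the suite sweeps within it), Gaussian sensor noise of 1
unit, 8-bit integer rendering.

Stage presets draw true RR from N(mean, 0.12 Hz) truncated to
[0.3, 3.0] Hz — 0.12 Hz being the dispersion of careful manual counting —
with means:

| stage | +0 °C | +2 °C | +4 °C | +5 °C |
|---|---|---|---|---|
| brooding | 1.10 | 1.62 | 2.10 | 2.70 |
| growing | 0.90 | 1.22 | 1.55 | 1.71 |
| fattening | 0.60 | 0.72 | 0.84 | 0.90 |

The printed anchors are the stage baselines (1.1/0.9/0.6 Hz), the brooding
elevations at +4 °C (≈2.1 Hz) and +5 °C (≈2.7 Hz), and the fattening +5 °C
response (+50%); the remaining cells are interpolated from the per-stage
linear response of relative RR increase to temperature. Body semi-axes
grow with stage (30×18, 40×25, 50×30 px).

What a green test does and does not establish: the simulator exercises
sub-pixel periodic motion, drift, bursts, sensor noise and quantization,
so it validates the screening rule, the phase gain law, and frequency
recovery end to end. It does not emulate feather texture, multi-bird
occlusion, pseudo-color compression artifacts, breathing-waveform
asymmetry, or radiometric drift — agreement on synthetic cohorts is a
property check, not a field-accuracy claim, and the headline accuracies
reported for real footage are not reproducible from this package alone.

## I/O scope

No video/image codec bindings exist in the supported dependency set, so
the package reads and writes lossless frame stacks directly: PGM/PPM
frame directories (fps in a JSON sidecar) and minimal uncompressed
multi-page grayscale TIFF (8/16-bit, validated against an independent
TIFF reader during development). AVI/MP4 containers must be exported to
frames upstream. fps precedence is caller > container metadata > error,
because thermal exports frequently carry wrong rate metadata.
Pseudo-colored ("rainbow") exports are collapsed to a scalar intensity
proxy by nearest-neighbour lookup against a bundled 256-entry palette;
synthetic fixtures are grayscale, so no test depends on that palette.

## Evaluation conventions

The coefficient of determination is computed against the identity line,
R² = 1 − Σ(y−x)²/Σ(y−ȳ)², not from a fitted regression — a constant
offset between methods lowers it even at Pearson r = 1. MAPE uses the
manual value as denominator. σ uses the population (n) denominator and SD
the sample (n−1) denominator, with SD²·(n−1) = σ²·n asserted as an
invariant. Bland–Altman differences are taken algorithm − manual (a
declared convention, as the direction is not fixed upstream), with limits
of agreement at bias ± 1.96·SD of the differences. The age-trend helper
reports an ordinary regression R², deliberately distinct from the
identity-line R². Group-comparison statistics (ANOVA, post-hoc tests,
inter-observer ICC) are routine and out of scope; the report schema leaves
room to attach them.

## Known limitations

- Periodic FFT boundaries assume the ROI crop is interior; ROIs touching
  the frame edge can alias edge energy into the coarsest band.
- The in-band-maximum rule cannot distinguish a fundamental from its
  second harmonic if the harmonic dominates (shallow, fast breathing with
  strong waveform asymmetry).
- The fallback intensity-threshold detector is a geometric stand-in for a
  learned detector, adequate for single-bird frames with a clear thermal
  contrast only.
- Runtime scales with ROI area × frames; the defaults are sized for
  single-bird clips, not full-house footage.
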