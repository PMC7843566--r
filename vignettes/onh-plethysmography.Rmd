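---
title: "Measuring the cardiac pulse of the optic nerve head: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the cardiac pulse of the optic nerve head: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onhpleth)
```

## The measurement

Every heartbeat pushes a bolus of blood through the capillaries of the
optic nerve head (ONH). More blood absorbs more light, so in a fundus
video the ONH tissue darkens slightly — a fraction of a percent — during
systole and brightens again in diastole. `onhpleth` turns a short
(~10 s, 25 frames/s) grayscale fundus video into this plethysmographic
waveform and summarizes each subject's averaged heartbeat by five
descriptors: peak amplitude (%A), steepness of the systolic rise (%A/s),
time-to-peak (s and % of beat duration), full width at half maximum
(s and %), and beat duration (s). Reduced amplitude and steepness
accompany glaucomatous loss of ONH perfusion, which is what the group
statistics layer quantifies.

The pipeline is: rigid registration → frame averaging → ONH and vessel
segmentation → tissue-ROI merge → intensity trace → trend correction →
pulse selection → beat averaging → parameter extraction → group
statistics. Every stage is a documented exported function, and
`analyze_video()` chains them.

## Signal model

The ROI-mean grey level is modeled multiplicatively:
`I(n) = B(p) * (1 - a(n)/100)` with `B` the static scene and `a(n)` the
pulsatile absorption in %A. The plethysmographic signal is

```
A(n) = (1 - I(n) / I_avg(n)) * 100    [%A]
```

with `I_avg(n)` a slowly varying trend. For display, `100 + A(n)` reads
as a relative absorption level (105 = 5% more absorption than average).

Two consequences of this definition matter for validation:

* **Scale invariance.** Global illumination and camera gain cancel in the
  ratio. Tests confirm a grey-level rescaling leaves `A(n)` unchanged to
  machine precision, and a ±10% linear drift over 10 s changes the
  recovered amplitude by < 2%.
* **Baseline bias.** Any centred trend sits *below* the diastolic
  baseline by the beat-mean absorption, so the recovered excursion is
  scaled by `1 / (1 - mean(a)/100)` — about +2.6% for a typical 5 %A
  beat. This is the definition's exact output, not an implementation
  error; the synthetic round-trip tests compare against this analytic
  expectation.

## Trend estimation

`estimate_trend()` is a centred moving average (reflect-padded, flagged
frames excluded from each window), default window 1.5 s — longer than
any plausible beat. A boxcar of arbitrary length, however, leaks the
cardiac fundamental (gain −0.21 at 1 Hz for a 1.5 s window) and the
subtraction then *amplifies* the pulse by ~13%. `analyze_video()`
therefore runs a second, period-locked pass: after a first pulse
detection it re-estimates the trend with the window set to an integer
number of detected beat periods (choosing, among the first few
multiples, the one whose odd-forced frame count stays closest to an
exact multiple), where the boxcar response has a null at the pulse rate.
With 25-frame beats the 75-frame window removes the leakage entirely.

## Registration

Eye drift and microsaccades move the retina under the camera by several
pixels. `estimate_rigid()` estimates rotation first, from the angular
correlation of the two frames' Hann-windowed magnitude spectra
(rotation rotates the spectrum; translation does not affect its
magnitude), iterated on the residual and refined by a parabola fit.
Translation then comes from phase correlation with an upsampled local
DFT refinement. Two numerical details are worth recording:

* The whitened cross-power is tapered by a radial Gaussian low-pass
  (σ = 0.15 cycles/px). Bilinear resampling imprints a *nonlinear* phase
  on high frequencies, which otherwise biases subpixel estimates by
  ~0.15 px toward integer shifts.
* The estimate is two-pass: integer correction first, then subpixel
  refinement near zero residual, where window-induced bias vanishes.

On noise-free phantoms the estimator recovers injected motion to
≤ 0.1 px and ≤ 0.1°, against contracts of 0.25 px and 0.2°. The
reference frame is the temporally middle artifact-free frame; frames
are resampled bilinearly, out-of-field pixels are marked invalid and
excluded from all ROI statistics, and low-confidence frames are flagged
(`edge_loss`), never dropped, so the frame clock stays intact.

Artifact flags: a frame is `blink` when its mean grey exceeds 1.15× the
median frame mean (eyelid reflections saturate the image), `blur` when
its gradient energy falls below half the median (fast motion or
defocus). Both ratios are configurable; a pure quantile rule would
always flag the brightest frames of a clean video, so a relative rule
is used instead.

## Segmentation

The averaged image (artifact-free frames only, invalid pixels excluded
per frame) feeds three masks:

* **ONH** — manual-first: a supplied mask is validated (single connected
  component after hole filling) and passed through. The automatic
  fallback thresholds at a brightness quantile (default 0.90), closes
  across vessel gaps, keeps the largest component, re-thresholds midway
  between the inside and outside means, and fills the convex hull. On
  clean phantoms it reaches Dice ≥ 0.95 against the true disc.
* **Vessels** — multiscale Hessian ridge (vesselness) response of the
  inverted image at σ = 1–3 px, gated to pixels darker than their local
  median by a real contrast margin (removing the shoulder responses
  that flank the disc rim), binarized by hysteresis with thresholds
  expressed as fractions of the median grey level (2% grow, 8% seed),
  and cleaned by a minimum component size. Manual vessel masks are also
  accepted and take precedence.
* **Tissue ROI** — ONH AND NOT dilated vessels. Dilation uses a
  Euclidean disc, default size 5 px read as the *diameter* (radius 2,
  13 px); the radius reading is available via
  `dilate_vessels(interpret = "radius")`. A ROI under 500 px aborts the
  run — the aggregate signal of a tiny region is noise-dominated.

## Pulses and parameters

Beat boundaries are local minima of `A(n)` (minimum separation 0.33 s,
prominence ≥ 0.3× the median trough prominence, nothing within 2 frames
of a flagged frame). Manual minima labels are the primary path — label
files carry no diagnosis field, so the labeller is masked to grouping by
construction. Automatic screening keeps beats with no flagged frame,
duration within ±25% of the median and amplitude within ±50%, requires
at least 2 and caps at 7 (keeping those closest to the median duration).
Labels more than 2 s apart delimit no beat; they mark a skipped,
distorted stretch.

Each beat is re-referenced to its first sample (the heartbeat start is
the reference value), linearly resampled to the median beat length, and
averaged sample-wise with per-sample SD. The reported duration is the
mean of the contributing beat durations, so 24- and 26-frame beats at
25 fps average to exactly 1.0 s.

Parameter extraction locates fractional-amplitude crossings by linear
interpolation between samples (at 25 fps, nearest-sample quantization
would be ±0.02 s — the same order as the between-group differences of
interest). Peak ties break to the earliest sample. The steepness default
is the 30–70% rise estimator; `min_max`, `rise_47_53` and
`max_derivative` are provided and agree exactly on a linear rise.

## The synthetic generator

`scene_phantom()` + `render_video()` build a phantom fundus video with
exact ground truth: a bright disc (static absorption 0 inside, 0.35
outside, 0.55 on vessels), a 3-branch vessel tree, a smooth multiplicative
texture, a parametric beat injected multiplicatively into ONH tissue,
per-frame rigid motion, near-saturated blink frames, Gaussian-blurred
frames, and seeded sensor noise. Same spec + same seed gives bit-identical
output.

Two beat families are provided. The `triangle` is piecewise-linear and
analytically checkable; since a triangle returning to zero at the beat
end forces FWHM = duration/2, the family accepts a general FWHM by
placing the zero crossing of the decay at `2 * fwhm` and staying flat
afterwards. The `smooth` family is a sine rise with a cosine-power decay
— continuously differentiable at the peak, exactly zero at the beat end,
with the decay exponent solved in closed form from the requested FWHM,
giving the asymmetric fast-rise/slow-decay shape of a real volume pulse.
Infeasible (time-to-peak, FWHM, duration) triples are rejected with the
violated constraint named.

`generate_cohort()` draws per-subject parameter tables from
truncated-normal marginals (truncated at zero — all quantities are
positive) at the published group means and SDs for the four diagnostic
groups (19 normal, 17 ocular hypertension, 24 preperimetric, 50
perimetric), with amplitude and steepness coupled to RNFL thickness
through a Gaussian copula. The default within-group rank correlation is
0.35; combined with the between-group gradient of the group means this
lands the pooled amplitude–RNFL Spearman R near the published ~0.5.

What the generator does *not* emulate: skewed or heavy-tailed parameter
distributions (only the printed first two moments are available),
choroidal or peripapillary signal, non-rigid intra-frame distortion,
and vessel pulsation. Consequently, passing tests demonstrate that the
pipeline inverts its own forward model and that the statistics layer is
correct — not that real fundus videos are this well behaved. One
concrete instance: simulating from the printed means ± SDs makes
time-to-peak, FWHM and duration reject the Kruskal-Wallis null far more
often than the original study reported, because summary moments
overstate the separability of non-normal data. The acceptance suite
records this honestly rather than retuning the generator.

## Problem sizes and numerical choices

Tests run phantoms of 64–100 px and 5–250 frames; the full end-to-end
recovery uses the study's own acquisition geometry (100×100 px, 250
frames at 25 fps, ±4 px drift, mild noise). Statistical calibration
loops use 200–1000 replicates. Degenerate inputs are contracts, not
accidents: constant frames register with confidence 0 and the identity
transform; a fully tied Kruskal-Wallis sample returns H = 0, p = 1; an
all-zero pulse, a peak at the first sample, or a beat ending above half
maximum raise named errors.

## Limitations

Rigid shift+rotation is the motion model; torsional or rolling-shutter
distortion within a frame is out of scope. The ONH is the only ROI —
no peripapillary or single-vessel analytics. The trend construction of
the original instrument software is unknown; the moving-average choice
here is validated by its invariance properties (drift rejection, scale
invariance), not by equivalence to that software. Published per-subject
example values (e.g. an amplitude of 7.6 %A for one normal subject)
serve as plausibility ranges only, since the original videos are not
available.
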