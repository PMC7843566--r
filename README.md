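# onhpleth — video plethysmography of the optic nerve head

Each heartbeat drives a pulse of blood through the capillaries of the
optic nerve head (ONH). The extra blood absorbs extra light, so in a
short fundus video (≈10 s at 25 frames/s) the ONH tissue darkens by a
few percent during systole. `onhpleth` extracts this cardiac waveform
and the descriptors used to compare glaucoma stages: it is written for
ophthalmic imaging researchers who have fundus video sequences (or want
validated synthetic ones) and need a tested, reproducible pipeline from
raw frames to group statistics.

The pipeline implements, stage by stage:

1. **Registration** — rigid (shift + rotation) frame-to-frame alignment:
   Fourier–Mellin angular correlation for rotation, subpixel phase
   correlation for translation; blink/blur frames flagged, never dropped.
2. **Segmentation** — averaged image → ONH mask (manual-first, automatic
   fallback) and vessel mask (multiscale vesselness + hysteresis); the
   vessel tree is dilated with a 5 px circular element and subtracted
   from the ONH to give the microvascular **tissue ROI**.
3. **Plethysmographic signal** — per-frame ROI-mean intensity `I(n)`,
   trend `I_avg(n)` (centred moving average, period-locked second pass),
   and the absorption signal

   `A(n) = (1 − I(n)/I_avg(n)) · 100  [%A]`,

   displayed as `100 + A(n)` (105 ⇔ 5% more absorption than average).
4. **Pulses** — beat boundaries at labelled or detected signal minima
   (manual labels are the primary path; automatic screening keeps 2–7
   clean beats), each beat re-referenced to its start, resampled to the
   median beat length, and averaged with per-sample SD.
5. **Parameters** — peak amplitude (%A), steepness of the 30–70% rise
   (%A/s; three alternative estimators included), time-to-peak and FWHM
   (seconds and % of beat duration, crossings by linear interpolation),
   and beat duration.
6. **Statistics** — Kruskal–Wallis across the four diagnostic groups
   (normal / ocular hypertension / preperimetric / perimetric glaucoma),
   Mann–Whitney vs normals with Bonferroni correction, Spearman
   correlation and OLS slope against RNFL thickness, and a
   repeated-measures coefficient of variation.

A synthetic-data module (`scene_phantom()`, `render_video()`,
`generate_cohort()`) produces phantom videos with exact ground truth and
subject cohorts calibrated to the published group statistics, so every
stage is testable without patient data.

## Worked example

```r
library(onhpleth)

# a 10 s phantom: 5 %A triangle beat, 60 bpm, ±4 px eye drift, sensor noise
spec <- waveform_spec(amplitude = 5, time_to_peak = 0.3, duration = 1.0, fwhm = 0.5)
wave <- tile_waveform(generate_pulse_waveform(spec, fps = 25), 250)
art  <- motion_artifact_spec(dx = sinusoidal_drift(250),
                             dy = sinusoidal_drift(250, phase = 1.3),
                             n = 250, noise_sd = 1.5, seed = 42)
sim  <- render_video(scene_phantom(), wave, art)

res <- analyze_video(sim$video)
res
#> ONH plethysmography analysis
#> averaged_pulse: 7 beats, duration 1.000 s, 26 samples (dt 0.0400 s), peak 4.87 %A
#>   amplitude 4.87 %A | steepness 16.7 %A/s (rise_30_70) | TTP 0.32 s (32%) |
#>   FWHM 0.52 s (52%) | duration 1.00 s | 60 bpm
```

The injected 5 %A beat (steepness 5/0.3 ≈ 16.7 %A/s, time-to-peak
0.30 s, FWHM 0.50 s) is recovered through registration, segmentation,
trend correction and beat averaging to within a frame period in timing
and a few percent in amplitude.

The statistics layer, on a synthetic cohort drawn at the published group
means/SDs (n = 19/17/24/50):

```r
co <- generate_cohort(glaucoma_cohort_spec(seed = 1))
st <- cohort_stats(co)
round(st$kruskal, 4)
#> peak_amplitude   steepness   ttp_s   ttp_pct   fwhm_s   fwhm_pct   duration_s
#>         0.0011      0.0000  0.2568    0.2649   0.0172     0.0045       0.0393
st$correlation[1:2, ]
#>        parameter         R            p slope_per_10
#> 1 peak_amplitude 0.5133 9.82e-09        0.573
#> 2      steepness 0.6408 4.69e-14        3.251
```

Amplitude and steepness separate the groups strongly and correlate with
RNFL thickness (R ≈ 0.51 and 0.64 here), with regression slopes of
≈0.6 %A and ≈3 %A/s lost per 10 µm of RNFL — the perfusion pattern the
method is designed to detect.

A thin command-line wrapper with `simulate`, `simulate-cohort`,
`analyze`, `batch` and `cohort-stats` subcommands is installed at
`inst/cli/onhpleth`.

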