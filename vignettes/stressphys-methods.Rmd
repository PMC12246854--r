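---
title: "Methods: multimodal stress-recovery analysis with stressphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal stress-recovery analysis with stressphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressphys)
```

## The experiment this package models

stressphys analyses staged stress-and-recovery experiments in which a
participant passes through a fixed timeline — rest baseline, anticipation,
a stress task, a short intermediate rest, a sound (or silence) intervention
and two recovery periods — while three physiological modalities are
recorded:

* **prefrontal fNIRS**: a 2×12-channel continuous-wave montage sampling
  optical-density changes at two near-infrared wavelengths, 50 Hz;
* **wrist EDA**: skin conductance in microsiemens at 4 Hz from one or two
  wrist-worn dry-electrode devices;
* **salivary cortisol**: five samples (baseline, post-stress, post-sound,
  +10 min, +20 min) in nmol/L.

The stage schedule is the single clock: all signals are segmented against
it, and the timeline (5/5/10/5 min plus the audio-track duration and two
5-min rests) ships as `default_schedule()`.

## Signal models and preprocessing

### EDA: artifact repair and tonic level

Wrist devices intermittently lose skin contact; the reading collapses for a
second or a few and no linear filter can undo that. Detection
(`eda_detect_artifacts()`) flags a sample when its difference to the
previous *valid* sample exceeds a jump threshold (default 0.01 μS) **and**
the sample leaves a local acceptable band. The band is a rolling
median ± k·IQR (default k = 3) over a 30 s window. The two-condition rule
matters: the jump threshold alone fires on ordinary measurement noise, and
the band alone would flag slow drift; requiring both isolates abrupt,
implausible excursions while genuine skin-conductance responses — which at
the wrist are small (typically below 0.1 μS) and rise over about a second —
stay inside the adaptive band.

The published description of this step leaves the repair semantics of a
shifted segment open (re-anchor the segment versus discard it). We discard
and interpolate: each flagged segment is replaced by a straight line
between its valid neighbours (`eda_repair_artifacts()`), with
nearest-value extension at the recording edges. Repair is idempotent and
never touches unflagged samples; the mask is kept so stage summaries can
report the repaired fraction.

After repair the series is smoothed with a zero-phase 4th-order Butterworth
low-pass at 0.5 Hz and min-max normalised to [0, 1] **per participant over
the whole session**. Per-stage normalisation is deliberately rejected — it
would erase exactly the stage differences the analysis quantifies. A
constant series maps to all-zeros by convention. The tonic skin conductance
level per stage is the mean of fully-overlapping 2-min rolling-window
means (step one sample), which equals a centre-weighted stage mean and
suppresses edge transients.

With two wristbands, stage summaries are computed per device and averaged
across devices whose overall valid fraction reaches 70%
(`fuse_eda_summaries()`); if neither qualifies, the better device is used
alone with a warning. The fusion rule is this package's choice; redundant
recordings admit several defensible rules.

### fNIRS: conversion, quality control, filtering

Optical densities convert to haemoglobin concentration changes through the
modified Beer-Lambert law: per channel and sample the 2×2 system

$$\Delta OD(\lambda) = \left[\varepsilon_{OHb}(\lambda)\,\Delta C_{OHb} +
\varepsilon_{HHb}(\lambda)\,\Delta C_{HHb}\right] d \cdot DPF(\lambda)$$

is solved for (ΔOHb, ΔHHb) in μmol/L, with d the source-detector distance
(3 cm throughout the default montage) and DPF the general age- and
wavelength-dependent differential pathlength factor

$$DPF(\lambda, A) = 223.3 + 0.05624\,A^{0.8493}
 - 5.723\times10^{-7}\lambda^3 + 0.001245\,\lambda^2 - 0.9025\,\lambda ,$$

A in years, λ in nm (about 6 for young adults at 760/850 nm). The
extinction coefficients ship as a packaged table at the default device
wavelengths 760/850 nm (0.1486/0.3843 and 0.2526/0.1798 cm⁻¹·μM⁻¹ for
OHb/HHb); both the wavelengths and the table are configurable because
device documentation, not the analysis, fixes them. No partial-pathlength
or scattering correction beyond the DPF is applied.

Channel quality is screened with the scalp coupling index: both wavelength
traces are band-passed to the cardiac band (0.7–1.5 Hz), scaled to unit
variance, and their zero-lag cross-correlation is the SCI. A well-coupled
optode pair shares the cardiac pulsation (SCI near 1); a detached one
records independent noise (SCI near 0). Channels below 0.75 are excluded;
the boundary value is kept. The SCI is computed over the whole recording
(a windowed variant exists behind an argument); a zero-variance trace
yields SCI 0 by convention. Retained channels are band-passed to
0.02–0.18 Hz to remove cardiac and respiratory components, then averaged
per stage with the same 2-min rolling-window rule as EDA.

### Laterality Index Response

For homologous right/left channel pairs, the LIR over stage-mean ΔOHb is

$$LIR = \frac{R - L}{R + L},$$

positive when right-dominant. Two subtleties are handled explicitly:

* **Negative stage means.** ΔOHb stage means are concentration *changes*
  and can be negative, making the raw ratio unbounded. The default
  `rectified` mode shifts each participant-pair's stage means by their
  joint minimum and floors at zero before the ratio, restoring the
  [−1, 1] range while preserving stage ordering; `raw` mode applies the
  formula verbatim and is reported alongside as the fidelity reference.
* **Degenerate sums.** When |R + L| falls below 1e-9 μmol/L the index is
  undefined and propagates as `NA` — never ±∞ and never silently zero.

Pairs are catalogued in the montage, stored as printed in channel-level
reports and oriented right-versus-left against the montage's hemisphere
labels at computation time. A pair with a rejected member is skipped and
logged, not imputed.

### Cortisol trajectory metrics

`stage_delta()` is the plain concentration difference between two stages.
`baseline_return()` reports the earliest post-stress stage whose
concentration is within a tolerance of the participant's own baseline;
"returned to baseline" is quantified as within 5% (configurable — the
underlying study reports the phenomenon without a numeric criterion). The
function is monotone in the tolerance by construction.

### Statistical battery

The battery mirrors the standard analysis of such designs: Levene's test
(median-centred, i.e. Brown-Forsythe) for variance homogeneity; two-sided
paired t within participants and pooled-variance independent t between
groups, each with Cohen's d (paired: mean difference over SD of
differences; independent: pooled-SD standardised mean difference); and a
mixed repeated-measures ANOVA (stage within, group between) via the
classical univariate sums-of-squares decomposition. Effect sizes for the
ANOVA default to partial eta-squared, with classical eta-squared also
reported; no sphericity correction is applied by default (a
Greenhouse-Geisser option exists) since two- and three-level stage factors
dominate the planned comparisons. Channel-level p-values are reported
uncorrected at α = 0.05, matching the conventional report for this
channel count, with an optional Benjamini-Hochberg column for modern use.
Signed t-values are preserved as computed, with the first-listed stage or
group minus the second.

`run_battery()` executes a declarative analysis plan
(`default_analysis_plan()` reproduces the standard set: cortisol Levene +
rm-ANOVAs + a soothing-versus-pooled-controls recovery contrast, the
five-stage EDA rm-ANOVA, per-channel paired and between-group t-tests for
ΔOHb/ΔHHb, and per-pair LIR tests) and emits one tidy row per comparison
with hemisphere and Brodmann-area annotation.

## The synthetic-cohort generator

No raw participant data accompany studies of this kind, so the generator
is a first-class module: every pipeline stage is tested against cohorts
with known ground truth. Defaults emulate the study conditions — 35
participants in groups of 12 (soothing voice), 11 (robotic voice) and 12
(silence) — and inject effects whose magnitudes are free parameters chosen
once, via a design-time power analysis at those sample sizes:

* **Cortisol**: lognormal baseline (median 10 nmol/L, 0.3 log-SD), an
  additive stress rise of 8 ± 1.5 nmol/L at the post-stress sample —
  roughly a doubling, typical of effective social-evaluative stressors —
  first-order exponential recovery at 0.11 min⁻¹ for the soothing group
  versus 0.055 min⁻¹ for both controls (the 2× ratio is the designed
  contrast), and 5% multiplicative assay noise.
* **EDA**: participant tonic level 3 ± 0.8 μS with stage increments up to
  +1 μS under stress, smooth 20 s transitions, Poisson skin-conductance
  responses (~3/min) with bi-exponential shape and wrist-realistic
  amplitudes (exponential, mean 0.05 μS), slow drift, white noise, and
  detachment artifacts (reading drops to 5% of its value for 1–4 s at
  ~0.2/min) injected clear of stage boundaries. The clean trace and the
  injected mask are retained as ground truth.
* **fNIRS**: true ΔOHb/ΔHHb stage-level traces (baseline 0.2 μmol/L, a
  right-lateralised stress increase of +0.5 μmol/L right / +0.15 left, and
  a sound-stage contrast of +0.3 μmol/L confined to a four-channel set for
  the control groups) pushed through the *same* forward Beer-Lambert model
  and extinction table as the analysis inverse — so round-trip identity is
  meaningful — with per-participant variation of the stage levels (SD
  0.15 μmol/L, recorded in the ground truth), plus shared cardiac
  pulsation (1.1 Hz) scaled by coupling,
  Mayer waves (0.1 Hz), respiration (0.25 Hz) and white noise in OD space.
  Decoupled channels record pure independent sensor noise, as a detached
  optode does.

A summary-level fast path (`simulate_cohort_summaries()`) draws stage
summaries directly from the same effect model; calibration and power
studies over hundreds of replicate cohorts use it, because synthesising
50 Hz signals there would add runtime without adding evidence about the
statistics. Signal-level fidelity is exercised separately by the full
generator. `null_config()` zeroes every injected effect for
type-I-error calibration.

What the generator does **not** emulate: biophysically realistic
neurovascular coupling, 1/f noise spectra, motion artifacts other than EDA
detachment, skewed or heteroscedastic assay errors, and participant
dropout. Passing tests therefore certify the pipeline's algebra,
filtering, detection and statistical calibration under a plausible
generative model — not robustness to every pathology of real recordings.

## Numerical choices

* **Band-pass realisation.** A direct 8-pole Butterworth band-pass at
  0.02–0.18 Hz with a 50 Hz sampling rate is numerically unstable in
  double precision (pole radii exceed 1 in the designed coefficients).
  Band-passes are therefore realised as a cascade of a 4th-order high-pass
  at the lower edge and a 4th-order low-pass at the upper edge, each
  applied forward-backward. The cascade keeps each section
  well-conditioned and satisfies the same contracts (0.1 Hz within 3 dB,
  1.1 Hz attenuated far beyond 40 dB).
* **Edge handling.** Forward-backward recursive filtering starts from zero
  state; without padding the settling transient bleeds into the data.
  Signals are extended by odd reflection over ten settling time constants
  of the slowest corner frequency before filtering, then trimmed, which
  preserves DC exactly (well below 1e-9) and keeps symmetric pulses
  symmetric.
* **EDF transport.** EDF stores 16-bit integers against an 8-character
  ASCII physical range; the writer formats the *negative* bound first
  (the sign costs a character), mirrors it exactly, and quantises against
  the stored values, bounding round-trip error by one quantisation step of
  the stored range.
* **Degenerate inputs.** Constant series normalise to zero; zero-variance
  SCI traces score 0; identical samples give t = 0 with p = 1 while a
  non-zero constant difference with zero variance is an error (a
  degenerate contrast, not evidence); an all-flagged EDA series cannot be
  repaired and says so; rm-ANOVA on constant data reports all effects as
  zero rather than 0/0.

## Problem sizes in the test suite

Unit tests run signal-level checks on a 1/10-scale schedule (270 s) and
small cohorts (6 participants); the property suite uses 1000 random draws.
The calibration and power studies use 200 replicate cohorts at the study's
full sample size via the summary-level path, the EDA repair study 50
full-length participants, and the SCI study 200 one-minute channels.
These sizes give binomial standard errors of about 1.5 percentage points
on calibrated rejection rates while keeping the default suite fast enough
to run habitually.

## Known limitations

* The 0.02 Hz high-pass removes most of a constant stage offset over
  5–10 min stages; stage contrasts in real band-passed data ride on
  within-stage dynamics. The pipeline's band-pass can be disabled
  (`fnirs_opts = list(bandpass = FALSE)`) when stage-level offsets are the
  target quantity, and the generator's recovery tests use exactly that
  configuration.
* Wavelengths, extinction coefficients and the channel→Brodmann map are
  configuration, reconstructed from published channel-level reports; the
  seven montage channels never named in those reports carry interpolated
  labels and are marked as such in the packaged YAML.
* Levene's test with two observations per group is degenerate (the
  auxiliary regression fits perfectly); the statistic is still defined and
  the spurious diagnostic is muffled, but such group sizes have no power.
* The rm-ANOVA requires a balanced within-factor; participants missing a
  stage must be excluded or imputed upstream, and the error message names
  the offending cells.
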