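# stressphys

Multimodal stress-recovery analysis for staged experiments: prefrontal
fNIRS haemodynamics, wrist-worn electrodermal activity (EDA) and salivary
cortisol, processed from raw device exports to a tidy table of
statistical comparisons.

## The problem

Acute-stress studies routinely record several loosely coupled stress
markers around a common timeline — rest baseline, a stress task, an
intervention (for example a soothing voice, a robotic voice, or silence),
and recovery periods — and ask stage-by-group questions: did the stressor
raise cortisol, EDA tonic level and right-lateralised prefrontal
activation; did one intervention speed recovery? Getting there requires a
chain of unglamorous steps that are easy to get subtly wrong: device
dialect parsing, detachment-artifact repair, optical-density conversion,
channel quality control, zero-phase filtering at awkward corner
frequencies, rolling stage summaries and a battery of paired/independent
tests and mixed repeated-measures ANOVAs. stressphys packages that chain
as composable, tested, tibble-first functions, for researchers analysing
such recordings and for methodologists who want a ground-truth simulator
to probe the pipeline.

## The core quantities

* **Modified Beer-Lambert conversion.** Per channel and sample the system
  ΔOD(λ) = [ε_OHb(λ)·ΔC_OHb + ε_HHb(λ)·ΔC_HHb]·d·DPF(λ) is solved for the
  haemoglobin concentration changes, with an age- and
  wavelength-dependent differential pathlength factor
  DPF(λ, A) = 223.3 + 0.05624·A^0.8493 − 5.723e−7·λ³ + 0.001245·λ² −
  0.9025·λ.
* **Scalp coupling index (SCI).** Per channel, the zero-lag correlation
  of the two wavelength traces after 0.7–1.5 Hz cardiac band-passing and
  unit-variance scaling; channels below 0.75 are excluded.
* **EDA artifact repair and tonic level.** Abrupt jumps (> 0.01 μS) that
  leave a rolling median ± 3·IQR band are flagged and linearly
  interpolated; the tonic skin conductance level per stage is the mean of
  2-min rolling-window means of the filtered, min-max-normalised trace.
* **Laterality Index Response.** LIR = (R − L)/(R + L) over stage-mean
  ΔOHb of homologous right/left channel pairs; positive is
  right-dominant, bounded in [−1, 1] under the default rectified mode.
* **Cortisol trajectory metrics.** Stage deltas and the earliest
  post-stress stage back within 5% of the participant's baseline.
* **Statistical battery.** Levene (median-centred), paired and
  pooled-variance independent t with Cohen's d, and mixed
  repeated-measures ANOVA (stage × group) with partial eta-squared,
  emitted one comparison per row.

A synthetic-cohort generator (`generate_cohort()`,
`simulate_cohort_summaries()`) produces complete cohorts — device-dialect
EDA CSVs, fNIRS EDFs built through the same forward Beer-Lambert model
the analysis inverts, cortisol panels with group-specific recovery
kinetics — with the ground truth retained, so every claim the pipeline
makes is testable without any participant data.

## Worked example

Generate a small synthetic cohort (12 participants, 1/10-scale schedule,
one deliberately decoupled channel) and run the full pipeline:

```r
library(stressphys)

sched <- stage_schedule(tibble::tibble(
  stage = c("baseline", "anticipation", "stress", "intermediate_rest",
            "sound", "rest1", "rest2"),
  start_s = c(0, 30, 60, 120, 150, 210, 240),
  end_s   = c(30, 60, 120, 150, 210, 240, 270)))
cfg <- synth_config(
  n_per_group = c(soothing = 4, robotic = 4, silence = 4),
  schedule = sched,
  fnirs = list(decoupled_channels = "Tx2-Rx2"))
generate_cohort("cohort", cfg, seed = 42)

out <- run_pipeline("cohort", "results",
                    eda_opts = list(window_s = 20),
                    fnirs_opts = list(window_s = 20, bandpass = FALSE))
#> (see results/pipeline.log for the per-participant QC notes)

dplyr::filter(out$results,
              measure %in% c("cortisol", "cortisol_recovery"),
              test %in% c("rm_anova_stage", "rm_anova_group", "independent_t"),
              stages != "baseline,stress,sound")[,
  c("measure", "test", "stages", "statistic", "df1", "df2", "p_value", "effect_size")]
#> # A tibble: 3 × 8
#>   measure           test        stages statistic   df1   df2 p_value effect_size
#>   <chr>             <chr>       <chr>      <dbl> <dbl> <dbl>   <dbl>       <dbl>
#> 1 cortisol          rm_anova_g… basel…    0.0633     2     9 9.39e-1      0.0139
#> 2 cortisol          rm_anova_s… basel…  496.         1     9 3.52e-9      0.982
#> 3 cortisol_recovery independen… rest2    -2.21      10    NA 5.12e-2     -1.36
```

Reading the rows: the stress task raised cortisol strongly within
participants (the rm-ANOVA stage effect over baseline/stress; partial
η² = 0.98 at this small, low-noise scale) while the groups did not differ
at baseline/stress (group effect p = 0.94). The soothing group's rest2
excess over its own baseline sits below the pooled controls with a large
effect (t = −2.21, d = −1.36) that is borderline at this 4/4/4 demo size
(p = 0.051); at the default 12/11/12 cohort size the same contrast is
detected in about 90% of simulated cohorts (see the acceptance script).
The decoupled channel `Tx2-Rx2` is rejected by the SCI screen for every
participant and appears in no channel-level comparison.

Plot helpers: `plot_cortisol_trajectories(panel)`, `autoplot(sci_report)`,
`autoplot(eda_series)`, `plot_lir(lir)`.

Command-line wrappers for whole-cohort runs live in `inst/cli/`
(`stress-pipeline.R run|qc`, `synth-cohort.R`).

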