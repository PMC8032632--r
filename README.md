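# workhrr

Aerobic workload from continuous workplace heart-rate measurements.

Occupational-health researchers increasingly measure workers' heart rate
around the clock with chest-worn devices to ask a classic work-physiology
question in the field rather than the laboratory: **does higher
cardiorespiratory fitness lower the relative aerobic load of everyday
work?** `workhrr` provides the complete, tested computational chain for
that kind of study:

1. **IBI quality control** — discard rules for raw inter-beat intervals
   (physiological range 36–200 bpm, 15% neighbour deviation, >50%
   beat-error epochs), 4 Hz resampling by linear interpolation of
   instantaneous heart rate, and diary-based splitting into work, leisure
   and sleep periods;
2. **Workload outcomes** — the Karvonen percentage of heart rate reserve

   $$\%\mathrm{HRR} = \frac{\mathrm{HR}_{work}-\mathrm{HR}_{min}}{\mathrm{HR}_{max}-\mathrm{HR}_{min}}\times 100,\qquad \mathrm{HR}_{max} = 208 - 0.7\times\mathrm{age},$$

   with HR<sub>min</sub> the 10-beat moving-window minimum over the whole
   measurement; per-worker mean %HRR at work, the maximum %HRR sustained
   for at least one cumulative minute, and the proportion of work time at
   or above 30 %HRR; valid-day rules (≥ 4 h of work-period data or ≥ 75%
   of the worker's usual work hours);
3. **Fitness** — Åstrand–Ryhming submaximal cycle-ergometer estimation of
   VO<sub>2max</sub> with the protocol's steady-state, power-adjustment and
   10-minute rules;
4. **Association analysis** — the work-time composition above/below
   30 %HRR analysed through its isometric log-ratio coordinate
   (`z = log(p/(1-p))/sqrt(2)`), unadjusted and covariate-adjusted linear
   models of each outcome on fitness, fitness×age interaction tests,
   stratified analyses, and back-transformation of the ilr effect to an
   absolute change in percent of work time;
5. **A calibrated synthetic cohort generator** (metric-level draws or full
   beat-level streams plus diaries and injected measurement artifacts) so
   that every stage is validated by parameter recovery against known
   injected effects.

## Worked example

Simulate a cohort of 497 workers under the default calibrated scenario and
fit the unadjusted fitness–workload model:

```r
library(workhrr)

cfg <- default_scenario(n_workers = 497, seed = 1)
ac  <- simulate_analysis_cohort(cfg)

fit_model(ac$rows, "hrr_mean")
#> # A tibble: 1 × 8
#>   model      outcome  estimate  ci_lo  ci_hi        p     n stratum
#>   <chr>      <chr>       <dbl>  <dbl>  <dbl>    <dbl> <int> <chr>
#> 1 unadjusted hrr_mean   -0.267 -0.333 -0.201 1.31e-14   497 <NA>

backtransform_delta_pct(fit_model(ac$rows, "ilr_z"))
#> # A tibble: 1 × 4
#>   delta_pct ci_lo ci_hi   z_ref
#>       <dbl> <dbl> <dbl>   <dbl>
#> 1     -1.50 -1.83 -1.17 -0.0982
```

The first slope says that in this replicate each additional
mlO₂/min/kg of fitness lowers mean %HRR at work by 0.27 points
(95% CI 0.20–0.33); the injected population value is −0.32, and averaging
over replicate cohorts recovers it. The back-transformed composition
effect says one fitness unit shifts 1.5% of work time from above to below
the 30 %HRR cut-off in this replicate (injected value −1.8). Cohort
summaries are calibrated: this replicate has mean %HRR 29.9 (SD 7.3),
mean maximum %HRR 56.8 and a median 45% of work time above the cut-off.

The full pipeline (simulation → QC → outcomes → fitness → models → report)
runs as one call:

```r
run_pipeline(default_scenario(seed = 1), "out/")
report_run("out/")
```

and a beat-level scenario (`fidelity = "beat_level"`) exercises the raw
IBI path: `simulate_beat_cohort()` → `workload_from_streams()`.

## Package layout

| Path | Contents |
| --- | --- |
| `R/scenario.R`, `R/synth_*.R` | scenario configuration, calibration, cohort/outcome/beat-stream simulation, artifact injection |
| `R/ibi_qc.R` | discard rules, 4 Hz resampling, diary splitting |
| `R/hrr.R` | HR min/max, %HRR, the three outcomes, validity rules, stream pipeline |
| `R/fitness.R` | Åstrand–Ryhming estimation, protocol rules, session harness |
| `R/coda.R`, `R/models.R` | ilr transform, zero replacement, models, interaction, stratification, back-transform |
| `R/pipeline.R` | end-to-end orchestration, manifests, text report |
| `inst/extdata/` | versioned nomogram parameter tables with provenance notes |
| `vignettes/aerobic-workload.Rmd` | methods vignette: models, assumptions, generator design, limitations |
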