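---
title: "From wearable beat streams to aerobic workload: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wearable beat streams to aerobic workload: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Whether a work task is aerobically demanding depends on who performs it: the
same task loads an unfit worker's cardiovascular system much more than a fit
one's. The individual-relative measure used here is the percentage of heart
rate reserve,

$$\%\mathrm{HRR} = \frac{\mathrm{HR}_{work} - \mathrm{HR}_{min}}
{\mathrm{HR}_{max} - \mathrm{HR}_{min}} \times 100,$$

where HR~min~ is the lowest sustained heart rate over the whole measurement
(captured during sleep by a 24-h recording) and HR~max~ is the age-predicted
maximum $208 - 0.7 \times \mathrm{age}$. `workhrr` implements the full chain
from raw wearable inter-beat intervals (IBIs) to three per-worker workload
outcomes —

* **mean %HRR at work**,
* **maximum %HRR**, defined as the highest level at or above which at least
  one cumulative minute of work time was spent, and
* **the proportion of work time at or above 30 %HRR** —

and the regression analysis relating them to cardiorespiratory fitness
(VO~2max~, mlO~2~/min/kg, from a submaximal cycle-ergometer test), with a
calibrated synthetic cohort generator standing in for the (non-deposited)
field data so that every stage is testable by parameter recovery.

## The measurement pipeline

**IBI quality control.** Three discard rules run in a fixed order — range,
neighbour deviation, beat error — before any analysis:

1. beats with instantaneous heart rate (60000/IBI ms) *strictly* below
   36 bpm or above 200 bpm are discarded (boundary beats retained, guarded
   against floating-point round-off);
2. beats deviating by more than 15% from their neighbours are discarded.
   The comparison basis is a genuine design choice: this package discards a
   beat only when it deviates from *both* adjacent beats (isolated-outlier
   semantics), because a one-sided rule would also delete the leading beat
   of every genuine step change in heart rate. The one-sided variant is
   available via `mode = "one_sided"`;
3. 60-second epochs whose device-flagged error fraction exceeds 50% are
   removed, and a measurement whose overall flagged fraction exceeds 50% is
   invalidated outright. The epoch length is our choice — the original
   device software does not document its window — so it is a visible
   parameter (`epoch_s`), and both the epoch-level and measurement-level
   readings of the rule are applied and reported separately.

**Resampling.** The cleaned instantaneous heart rate is anchored at beat
times and linearly interpolated onto a 4 Hz grid. Interpolation is done on
heart rate, not on interval length (the two differ only at second order);
for beat streams whose heart rate is affine in time the resampled signal is
exact to machine precision, which the test suite asserts. Samples inside
inter-beat gaps longer than `max_gap_s` (default 10 s) are masked rather
than interpolated: bridging long dropouts would manufacture data.

**Diary splitting and validity.** Diary intervals are half-open
`[start, end)` and must not overlap. A day is valid with ≥ 4 h of
work-period heart-rate data or ≥ 75% of the worker's average diary work
hours; a worker needs at least one valid day. Outcomes pool all valid work
samples sample-weighted (every 4 Hz sample counts equally) rather than
averaging day summaries; day-level summaries remain available, but
sample-weighting is primary because days contribute information in
proportion to their usable data.

**Outcomes.** HR~min~ is the minimum over all 10-beat moving windows of the
window-mean instantaneous heart rate, computed once over the whole pooled
measurement — a single aberrant beat cannot define it. %HRR values are
clamped to [0, 100] with clamp counts reported: a working heart rate above
the Tanaka-predicted maximum is physiologically possible and the source
material does not say how it was handled, so we truncate and count. The
maximum-%HRR outcome uses *cumulative* (not contiguous) time at level: with
samples sorted in decreasing order it is the value at rank
`ceiling(60 s × 4 Hz)`, which the tests verify against a brute-force
threshold scan.

## Fitness estimation

VO~2max~ is estimated from the steady-state pulse at a known power output.
The protocol rules are implemented exactly: steady state is a change of
strictly less than 5 beats/min between consecutive minute readings (checked
from minutes 5–6, capped at 10 minutes); a first-minute pulse below
110 beats/min triggers a power increase targeting max(60% of estimated
maximal heart rate, 120 bpm).

The nomogram itself is represented by its underlying linear pulse-rate
model — the mean pulse at 50% of maximal uptake (128 bpm for men, 138 for
women) and a reference maximal pulse of 195 — together with the standard
oxygen-cost ladder of cycle work (0.9 L/min at 300 kpm/min up to 3.5 at
1500, watts converted at 6.12 kpm/min/W) and the published age-correction
factors (1.00 at age 25 down to 0.65 at 65). We chose this parametric
representation over transcribing nomogram cells because no authoritative
copy of the cell table was available to transcribe and a from-memory
transcription would be unauditable; the parameters, their provenance and
the tabulated validity range (pulse 120–170, no extrapolation) live in
commented CSVs under `inst/extdata/`. All the properties that matter
downstream hold: estimates are strictly decreasing in pulse at fixed power,
increasing in power at fixed pulse, and multiplicatively separable in age.

The session harness (`simulate_test_session()`) inverts the same relation
to produce per-minute readings converging exponentially (time constant
1.2 min, readings rounded to whole beats) toward the pulse implied by a
worker's true VO~2max~, which gives a noiseless round trip within 5%
(interpolation and rounding are the only error sources). An `hr_drift`
option adds upward cardiovascular drift, the realistic mechanism by which
a session fails to steady before the 10-minute cap.

## Compositional analysis

Time at work above vs below 30 %HRR is a two-part composition; its single
isometric log-ratio coordinate is $z = \log(p/(1-p))/\sqrt{2}$, positive
when more work time is above the cut-off. Workers with an empty part get a
one-sample replacement (0.25 s relative to total work time) with closure
preserved. Linear models are ordinary least squares: an unadjusted model on
fitness, and an adjusted model adding age, sex, self-rated health (ordinal
code entered numerically), shift work (binary: fixed-day vs other),
prescription medication (the binary item) and occupation, retained
regardless of significance, complete cases only, Wald-type 95% intervals.
Interactions use mean-centred products; stratified analyses drop the
stratifying covariate and use type-7 sample quantiles, with the published
age bands (≤37, 38–45, 46–51, ≥52) and steps-per-hour cut-offs available as
pinned breaks for replication-style runs. Strata under 20 workers are
flagged unstable.

The ilr-scale fitness slope is reported back-transformed as the absolute
change in the percentage of work time above the cut-off: the fitted ilr
prediction at covariate means (the mean fitted value, in a linear model) is
inverse-transformed at mean fitness and at mean fitness + 1, and the
difference of proportions is the reported Δ%, with the same monotone map
applied to the confidence limits. How the original analysis derived its Δ%
from the ilr coefficient is not documented; this +1-unit contrast at the
compositional mean is our definition, it is recorded in output metadata,
and — crucially — the synthetic generator derives its injected ilr slope by
*exactly inverting this same contrast*, so parameter recovery is
well-defined.

## The synthetic cohort generator

The generator is first-class, tested code, with two fidelity levels:

* **metric level** draws per-worker outcomes directly — fast enough for
  full-cohort (n = 497) regression studies;
* **beat level** emits full 24-h beat streams and diaries per worker-day,
  so the entire QC/outcome pipeline can be exercised end to end (used at
  small n; a full cohort of beat streams would be needlessly expensive for
  inference that only consumes per-worker summaries).

Demographics draw from truncated normals and categoricals set to the cohort
table of the study population: age 44 (SD 9.8, truncated 18–68), 41%
female, fitness 32 (SD 8.9) with an age–fitness correlation of −0.3
(fitness declines with age; the cohort correlation itself is not published,
so it is a configurable default), occupation 15/9/67/8%, fixed-day shift
80%, self-rated health 9/62/28/1/0%, 1–4 measured days with median 3 (IQR
2–3). Values the sources do not state were fixed once at realistic levels
and not revisited: medication prevalence 25%, steps/hour lognormal matching
the published quartile cut-offs (845/1166/1493), body mass 80 ± 14 kg, true
minimum heart rate 60 ± 6 bpm, 6.7 ± 1.5 valid work hours per measured day
(≈ 18.5 h over a median 3 days).

Outcomes are generated as linear functions of fitness plus small fixed
covariate offsets (≤ 2 %HRR — large enough that adjusted and unadjusted
models differ testably, small enough not to dominate; magnitudes are not in
the source material) plus correlated Gaussian residuals (mean–max 0.6,
mean–composition 0.7). Calibration is by construction, not tuning:
intercepts equal the target means with analytically centred offsets;
residual SDs are the target cohort SDs minus the variance explained by the
injected slope and offsets; and because the realized mean and variance of
truncated, age-correlated fitness have no convenient closed form, they are
computed once by a deterministic internal Monte-Carlo (N = 200{,}000, fixed
internal seed, caller's RNG state restored). The composition outcome is
generated on the ilr scale with location at the ilr of the target median
(0.47) and spread set from the target interquartile range (0.23–0.70).
All stage streams derive from the scenario seed through an integer
scramble: consecutive integer seeds give R's generator weakly correlated
streams, which is enough to bias slope recovery by a few percent at
n ≈ 500.

Beat-level streams follow a piecewise-constant heart-rate profile: sleep at
the worker's true minimum, leisure at 12 %HRR, and a work window shaped so
the derived outcomes equal the worker's ground truth — a below-cut-off
block, an above-cut-off block, and a 120 s bout at the exceedance level,
with block levels solved from the target mean and proportion (infeasible
target triples are projected onto the feasible set and the achieved values
recorded as ground truth). Beat-to-beat variability is multiplicative
lognormal jitter (SD 0.005 by default). Two consequences are worth knowing:

* the 1-minute exceedance outcome is an upper order statistic, so any
  jitter biases the pipeline's estimate upward relative to the constructed
  level by roughly one jitter SD on the heart-rate scale (~0.6 %HRR points
  at the default), and the 10-beat minimum is biased slightly low by the
  same mechanism. The end-to-end consistency test therefore runs noiseless
  (isolating profile construction and resampling, which agree within
  0.5 points), with a separate bounded check (< 1.5 points) under default
  jitter;
* the generator makes no claim to realistic heart-rate-variability spectra
  or activity patterns — it emulates exactly the features the pipeline
  consumes. Passing tests demonstrate algorithmic correctness and
  calibration, not that real Actiheart data would be this clean.

Artifact injection contaminates clean streams with each class the QC rules
target — out-of-range beats, isolated ectopic beats, flagged-error runs,
non-wear gaps — with an injection log, so removal recall is measurable
(range recall must be 1.0; ectopic recall ≥ 95%).

## Interaction scenarios

The age-interaction scenario injects band-specific fitness slopes for the
pinned age bands; its defaults follow the published age-stratified
estimates (−0.29, −0.37, −0.45, −0.28 for mean %HRR). Note that this
profile is u-shaped: its linear-in-age component is tiny (≈ −0.0008 per
year against a product-term standard error of ≈ 0.004 at n = 497), so a
linear product term has essentially no power against it — recovery of this
profile is demonstrated through the stratified analysis instead, and the
product-term detection test uses a monotone profile, where the linear
interaction is the right alarm. Under the default (homogeneous) scenario
the product-term p-values are uniform, which the suite checks.

## Problem sizes and numerical choices

The test suite runs 20 replicate cohorts at n = 497 for parameter-recovery
checks (tolerances in Monte-Carlo standard errors of the replicate
estimates), 1,000 random series against the brute-force exceedance oracle,
and 20 noiseless beat-level workers end to end — sizes chosen so the whole
suite completes in about a minute while keeping Monte-Carlo tolerances a
small fraction of the effects being recovered. Quantiles are type 7
throughout; the ilr and its inverse round-trip to 1e−12; degenerate factor
levels inside strata are dropped with a warning rather than silently
aliased; and rank-based computations (exceedance) avoid any histogram
binning.

## Known limitations

* The nomogram's parametric representation reproduces the published linear
  pulse relation, not the exact printed cell values; absolute fitness
  estimates could differ by a few percent from a cell-table implementation
  (the cohort fitness *distribution* used in the association analyses comes
  from the generator's ground truth, so this does not touch the regression
  surface).
* Covariate offsets are independent of fitness by construction, so
  unadjusted slope recovery is clean; real confounding structure (e.g.
  occupation–fitness association) can be emulated only by extending the
  generator.
* Self-rated health enters models as a numeric ordinal code; with 5 sparse
  levels a factor coding would be fragile in strata.
* Beat-level simulation at the full cohort size is possible but slow by
  design; metric-level fidelity exists precisely so inference-scale studies
  do not pay for beat streams they never read.
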