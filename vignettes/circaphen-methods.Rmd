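---
title: "Methods: circadian phenotyping of home-cage recordings with circaphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian phenotyping of home-cage recordings with circaphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaphen)
```

# The problem

Long-term home-cage phenotyping systems record locomotion (infrared
beam-break counts), feeding (grams from a suspended food scale), and
indirect calorimetry (respiratory exchange ratio, RER = VCO~2~/VO~2~, and
energy expenditure in kcal/hr) for weeks at a time. A central experimental
manipulation in circadian biology is the *T-cycle*: housing animals under a
light/dark cycle whose period differs from 24 h. A 20-h day (10 h light :
10 h dark) sits outside the range of entrainment of the mouse's ~23.8-h
endogenous clock, producing *environmental circadian desynchronization*
(ECD): behavior is pulled between the imposed 20-h cycle (via masking —
direct stimulation of activity by darkness without entrainment of the
clock) and the free-running endogenous rhythm.

circaphen analyzes such recordings: it normalizes time across cycle
lengths, detects daily behavioral peaks and onsets, quantifies peak-phase
clustering with circular statistics, detects and measures periodicity with
the chi-square periodogram, measures lagged coupling between channels, and
applies the quality-control rules such data need. A seeded simulator
generates cohorts with the same statistical structure so every stage is
testable without instrument exports.

# Elastic zeitgeber time

Zeitgeber time (ZT) expresses time relative to the light cycle: one full
cycle spans 24 "ZT hours" with ZT 0 at lights-on, so for half-light
schedules lights-off falls at ZT 12 regardless of the real cycle length.
Under a 20-h day each ZT hour therefore lasts 50 real minutes
(`zt_hour_duration(light_schedule(20, 10))`); under 24 h it is the familiar
60. Internally all times are real minutes since recording start; ZT exists
only as a derived view (`real_to_zt()`), because the elastic coordinate is
schedule-dependent and lossy. ZT is continuous; hourly figure-style
profiles quantize by `floor(zt)`. The lights-on anchor defaults to 0 min
(recordings aligned to a lights-on event) and is configurable, since
instrument exports rarely share an absolute clock convention.

Profiles and phase summaries computed in ZT make 20-h and 24-h cohorts
directly comparable, and peak phases mapped to angles by
`zt_to_angle()` (= 2π·zt/24) occupy the same circle for both schedules.

# Daily peak and onset detection

The detector works on 5-min bins and has four stages:

1. **Smoothing** — convolution with a normalized Gaussian kernel
   (`kernel_sigma_min`, default 60 min; truncated at 4 SD). Reflection
   padding at the edges avoids manufacturing boundary troughs that the
   minima stage would mistake for real ones.
2. **Minima** — a sample is an activity minimum when it attains the lowest
   smoothed value within a centered sliding window (`minima_window_hr`,
   default 12 h). Runs of tied window-minimal values (flat stretches) are
   thinned left-to-right to one candidate per window span, so a constant
   series yields one minimum per non-overlapping window rather than every
   sample.
3. **Peaks** — one candidate per inter-minima interval (earliest argmax of
   the smoothed signal); candidates closer than 12 h are discarded greedily
   by descending amplitude (keep the tallest, drop conflicting neighbors,
   repeat), which is deterministic and order-independent. Surviving peaks
   are always ≥ 12 real hours apart.
4. **Onsets** — within each window strictly between two consecutive peaks,
   the onset is the last sample strictly below the `beta_percentile`-th
   percentile (default 20) of the window's values, assigned to the peak
   that closes the window. A window with nothing below its percentile
   (e.g. constant) yields a missing, flagged onset.

The first partial window (before the first minimum) and the stretch after
the last peak yield no peak/onset — they are undefined rather than
extrapolated. Peak *times* are equivariant under adding a constant to the
signal and invariant under positive rescaling, so detector output does not
depend on the units of the activity channel.

The three tunables (smoothing SD, minima window, onset percentile) are
deliberately exposed: the intended workflow is to fit them on
control-condition animals with `fit_control_parameters()` — a grid search
scored by the fraction of inter-peak intervals within ±1 h of 24 h — and
then freeze the selected configuration for *all* conditions, so that
group comparisons are never confounded by per-group tuning. The defaults
(60 min, 12 h, 20th percentile) are sensible for nocturnal rodent
locomotion at 5-min resolution. With overdispersed count data the daily
argmax jitters across the broad nocturnal activity plateau, so even
well-entrained animals rarely place *every* interval inside the ±1 h band;
the fitting score is a mean fraction, not an all-or-nothing criterion, and
a best score below 0.5 flags the fit as low-confidence.

# Rayleigh test of peak-phase clustering

Daily peak ZTs are mapped to angles and summarized by the mean resultant
vector: length *R* ∈ [0, 1], and the Rayleigh statistic *Z = nR²*. *Z = n*
for identical angles, 0 for perfectly symmetric ones. The p-value uses the
standard series approximation
p ≈ exp(−Z)·[1 + (2Z − Z²)/(4n) − (24Z − 132Z² + 76Z³ − 9Z⁴)/(288n²)],
clamped to (0, 1]. The significance level defaults to α = 0.05 and is
configurable. The test's type-I error is verified by Monte-Carlo
(10,000 uniform replicates at n = 10) in the test suite. Peak angles are
taken in ZT, not real time, so clustering is assessed against the animal's
own light cycle on either schedule.

# Chi-square periodogram

For a candidate period of *P* bins, the series (uniformly sampled; missing
values tolerated to 20% and mean-imputed for folding) is folded into *K*
complete cycles, truncating the incomplete tail, and

Q~P~ = K·N·Σ~h~(M~h~ − M)² / Σ~i~(x~i~ − M)²,  N = K·P,

with M~h~ the fold-column means and M the grand mean — the Sokolove–Bushell
statistic, referenced to χ² with P − 1 degrees of freedom. Q~P~ is
invariant under affine transforms of the signal, so counts, grams and
kcal/hr are all comparable. Candidate periods step at one sampling
interval (the classical whole-bin folding); the default search range is
18–30 h with α = 0.001, and a 16–32 h `"wide"` preset is provided since
both ranges are in routine use. Supra-threshold local maxima are ranked by
power: the largest is the primary peak, the next distinct local maximum
the secondary; a series with no supra-threshold peak (or zero variance) is
flagged arrhythmic. `classify_rhythmicity()` labels primaries within
±0.5 h of 24 or 20 h — the entrained-versus-masked dichotomy that matters
under a 20-h day.

The implementation is checked exactly against an independent brute-force
folding oracle on 3-day toys in the test suite.

# Cross-channel coupling

`cross_correlate()` computes the classical sample cross-correlation
between two channels rebinned to 1 h: both series are centered by their
full-series means and normalized by full-series (population) standard
deviations; per-lag renormalization is deliberately not used. At lag +k
the response at time *t* is paired with the predictor at *t − k*, so a
positive lag means the predictor leads. Pairs with a missing member are
dropped per lag, and the averaged cross-product divides by the pair count
(a full-length divisor has no natural definition under complete-case
deletion; at lag 0 the two conventions coincide and equal the Pearson
coefficient exactly). The default lag grid is ±12 h.
`max_correlation()` takes the global maximum, breaking exact ties toward
the smallest |lag| and then the positive lag. `pearson()` reports r with
the two-sided t-transform p-value. `percent_change_transform()` —
100·(v − m)/m against the mean of the final 120 h — is a display transform
for putting channels on one axis; no analysis path consumes it.

# Quality control

* **Hoarding replacement.** Feeding is binned into daily light/dark
  phases; within each group (e.g. genotype × condition × phase) any binned
  value strictly above Q3 + 2.5·IQR is replaced by the group median. The
  observation count never changes, and every replaced value equals its
  group median exactly.
* **RER bounds.** RER below 0.7 or above 1.2 is physiologically
  implausible (outside the fat-to-carbohydrate oxidation range) and is
  excluded; the bounds are strict, so 0.7 and 1.2 themselves are retained.
* **Tukey fences.** Assay-style values are excluded strictly outside
  [Q1 − 1.5·IQR, Q3 + 1.5·IQR] within their group.
* **Duplicate reconciliation.** For duplicate wells whose percent CV
  (sample SD of the pair over its mean) exceeds 10, the replicate more
  distal from the group mean is dropped; otherwise the pair mean is used.
  A zero pair mean leaves the CV undefined: the pair mean is returned,
  flagged.

Quartiles and percentiles use linear interpolation between order
statistics (`stats::quantile` type 7) everywhere — fences and onset
percentiles are sensitive to the convention, so it is pinned, recorded,
and configurable. Fences are applied in a single pass with fences frozen
from the original data; recomputing fences after exclusion can cascade,
which the pipeline deliberately avoids. A practical consequence, visible
in the test suite: when hoarding spikes contaminate a large share of a
group, they inflate that group's own fences and the replaced fraction
saturates — the rule is designed for sporadic artifacts, not systematic
contamination.

# Summaries

Phase means assign each bin by the ZT of its midpoint; extensive channels
(counts, grams) are totalled per phase within each cycle and the per-cycle
totals averaged across cycles, intensive channels (RER, EE) averaged per
phase per cycle then across cycles. Hourly ZT profiles average within
animal and ZT hour first, then across animals (mean ± SEM) — two-stage
averaging is mandatory, since pooled averaging lets animals with more data
dominate. Energy intake converts grams at 3.16 kcal/g (standard chow
metabolizable energy density; configurable via `diet_config()`).

# The synthetic cohort generator

`simulate_cohort()` is mechanism-light by intent: templates plus noise,
no physiological differential equations, because the pipeline's
correctness claims concern statistical structure, not physiology. The
latent activity drive is

A(t) = baseline + entrainment·E(t) + freerun·F(t) + masking·D(t)

with E a half-sine locked to the dark phase, F a half-sine at the
free-running period (default 23.8 h, random initial phase per animal),
and D the dark indicator. Channels:

* locomotion — negative-binomial counts, mean 40·A(t) per 5-min bin
  (size 5), giving realistic overdispersed beam-break counts;
* feeding — Poisson events at 0.5·A(t) per bin × 0.05 g/event, ≈ 3.5–4
  g/day concentrated in the dark phase;
* RER — 0.80 + 0.15 × (hour-smoothed feeding, normalized, delayed by
  `coupling_delay_hr`, default 1 h) + a small dark-phase circadian term
  (0.02) + Gaussian noise (SD 0.02), clipped to the physiologic band
  [0.7, 1.05] so the QC bounds fire only on deliberately injected
  artifacts (`rer_artifact_rate`);
* energy expenditure — 0.30 kcal/hr basal + 0.004 kcal/hr per locomotion
  count (instantaneous coupling) + circadian term (0.03) + noise
  (SD 0.02).

The feeding signal is smoothed with a *centered* 1-h window before the
delay is applied, so the effective generative feeding→RER delay equals the
configured value exactly; a trailing window would add half its width to
the delay and bias hourly lag recovery upward. Hoarding artifacts are
Poisson-placed single-bin spikes (`inject_hoarding()`).

Presets encode the three study conditions: `control` (12:12; entrainment
1, free-run 0, masking 0), `ecd_masking` (10:10; entrainment 0.2, free-run
0.15, masking 1 — behavior locked to the 20-h dark phase without
entrainment), and `ecd_freerun` (10:10; entrainment 0.2, free-run 0.8,
masking 0.2 — the ~23.8-h clock expressed against the cycle, with lower
and less precise periodogram power). Cohort defaults are 7 animals × 35
days at 5-min sampling; per-animal seeds derive deterministically from the
master seed (`animal_seed()`), and identical (config, seed) pairs are
bit-identical.

What the simulator does *not* emulate: ultradian feeding-bout structure,
meal-size/meal-frequency trade-offs, light-pulse phase resetting,
sex/genotype differences, torpor, weekly calibration drift, or
instrument-specific noise (air-sampling duty cycles, scale settling).
Passing tests therefore demonstrate that the pipeline recovers the
structure it assumes — entrainment, masking, free-run, lagged coupling,
artifact contamination — not that it is robust to every pathology of real
instrument exports.

# Numerical and design choices

* Degenerate inputs are explicit: zero-variance series are arrhythmic
  (periodogram) or errors (correlation); empty QC groups are skipped with
  a warning in the report; fewer than 2 minima yields an empty peak set
  with a warning.
* Ties: earliest time for minima/argmax; smallest |lag| then positive for
  CCF maxima; the first replicate for equidistant duplicates.
* Text outputs are TSV at 6 significant digits; full precision is kept
  internally. Every pipeline run writes its resolved configuration
  (`config.yaml`), and re-running from that file reproduces the outputs
  byte-for-byte.
* Problem sizes in the test suite: full-scale cohorts (7 × 35 days at
  5-min sampling) for the end-to-end checks, 14-day 3–7-animal cohorts
  for parameter-recovery properties, and ≤ 3-day toys for exact oracle
  comparisons — chosen so the whole suite runs in well under a minute
  while still exercising full-length folding.

# Known limitations

Periodogram candidate periods are quantized to whole bins, so period
resolution is one sampling interval (5 min by default). The chi-square
threshold is pointwise per candidate period; with ~150 candidates the
family-wise false-positive rate at α = 0.001 is higher than 0.001 (the
conventional usage). Onset detection depends on the percentile convention
within inter-peak windows and is undefined in flat windows. The CCF
assumes a shared uniform grid; irregular sampling must be rebinned first.
Group-level circular statistics (second-order tests across animals) are
out of scope, as are mixed-effects rhythm models.
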