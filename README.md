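# circaphen

Circadian behavioral phenotyping for long-term home-cage recordings —
locomotion, feeding, respiratory exchange ratio (RER) and energy
expenditure — under standard 12:12 light/dark cycles **or** non-24-h
T-cycles such as the 20-h (10:10) day used to produce environmental
circadian desynchronization (ECD) in mice.

It is written for circadian/metabolism labs analyzing multi-week
indirect-calorimetry exports (TSE Phenomaster-style data converted to a
simple long CSV) who need the whole chain from raw channel time series to
per-animal rhythm statistics, with every step testable and reproducible.

## What it computes

* **Elastic zeitgeber time (ZT).** One full light/dark cycle spans 24 "ZT
  hours" whatever its real length: ZT 0 = lights-on, ZT 12 = lights-off
  for half-light cycles. On a 20-h day each ZT hour lasts
  20 × 60 / 24 = 50 real minutes, so 20-h and 24-h cohorts share one time
  axis.
* **Daily peak/onset detection.** 5-min binning → normalized Gaussian
  smoothing → activity minima (lowest point in a 12-h sliding window) →
  peaks as the argmax between consecutive minima, discarding peaks within
  12 h of each other → onset as the last sample below the β-th percentile
  of each inter-peak window.
* **Rayleigh test of circular uniformity** on daily peak phases:
  resultant length *R* and *Z = nR²*, with the standard series
  approximation for *p*.
* **Chi-square periodogram** (Sokolove–Bushell):
  Q<sub>P</sub> = K·N·Σ<sub>h</sub>(M<sub>h</sub> − M)² / Σ<sub>i</sub>(x<sub>i</sub> − M)²
  against χ²(P − 1), searched over 18–30 h (16–32 h preset available) at
  α = 0.001, with primary/secondary supra-threshold peaks.
* **Lagged cross-correlation** between hourly-binned channels
  (feeding → RER, locomotion → energy expenditure), with the lag of
  maximum correlation; Pearson r; a percent-change display transform.
* **Quality control**: hoarding-artifact replacement at Q3 + 2.5·IQR with
  the group median, strict physiologic RER bounds [0.7, 1.2], Tukey-fence
  exclusion, duplicate-well reconciliation above 10% CV.
* **Summaries**: light/dark phase means, hourly ZT profiles with
  two-stage (within-animal, then across-animal) averaging, energy intake
  at 3.16 kcal/g chow.
* **A seeded cohort simulator** (`control`, `ecd_masking`, `ecd_freerun`
  presets) generating 7-animal × 35-day × 4-channel cohorts with
  entrainment, masking, free-running (~23.8 h) components, a 1-h
  feeding→RER metabolic delay, instantaneous locomotion→EE coupling, and
  injectable hoarding/RER artifacts.

## Worked example

```r
library(circaphen)

# simulate a 7-animal control cohort: 35 days, 12:12, 5-min sampling
cohort <- simulate_cohort(simulation_preset("control", seed = 1))
cohort
#> <cohort> 7 animals x 4 channels, 35 days @ 5 min, 24-h cycle

animal <- cohort$animals$animal01

# rhythm detection: chi-square periodogram on locomotion, 18-30 h
pg <- chi_square_periodogram(animal$locomotion, c(18, 30), alpha = 0.001)
pg
#> <periodogram_result> animal01/locomotion: 145 periods in [18.00, 30.00] h
#>   primary peak 24.00 h (Qp = 6215.5); secondary 23.08 h (Qp = 360.0)
classify_rhythmicity(pg)
#> [1] "rhythmic_24"

# daily peak detection and Rayleigh clustering of peak phase
peaks <- detect_daily_peaks(animal$locomotion,
                            schedule = cohort$config$schedule)
head(peaks, 3)
#>   peak_time_min peak_value onset_time_min  peak_zt
#> 1          1055   47.98603             NA 17.58333
#> 2          2595   40.67407           2115 19.25000
#> 3          4010   48.09740           3455 18.83333
rayleigh_on_peaks(peaks, cohort$config$schedule)
#> <rayleigh_result> n=35 R=0.973 Z=33.102 p=7.1e-14 (significant at alpha=0.05)

# feeding -> RER coupling at 1-h bins
cross_correlate(animal$feeding, animal$rer, max_lag_hr = 12)
#> <ccf_result> animal01: feeding -> rer, lags -12..12 h; max r = 0.936 at +1 h
```

Reading the output: this entrained animal shows a single sharp 24.00-h
periodogram primary far above the α = 0.001 significance line
(Q<sub>p</sub> = 6215.5); its 35 daily locomotion peaks cluster tightly in
the dark phase (mean near ZT 18, *R* = 0.97, Rayleigh *Z* = 33.1,
*p* ≈ 10⁻¹⁴); and its RER tracks feeding with maximum correlation at a
+1 h lag — the metabolic delay between intake and substrate oxidation.

The full pipeline (`run_pipeline()`) chains QC → peaks → Rayleigh →
periodogram → cross-correlation → summaries and writes per-stage TSVs, a
QC report, a run log, and its resolved configuration. A thin CLI wrapper
with `simulate`, `qc`, `peaks`, `rayleigh`, `periodogram`, `ccf`,
`summarize` and `run` subcommands is installed at
`system.file("cli", "circaphen", package = "circaphen")`.

## Data format

Long CSV, one row per sample:
`animal_id, genotype, condition, channel, t_min, value`, with `channel` in
{`locomotion`, `feeding`, `rer`, `energy_expenditure`}, `t_min` in real
minutes since recording start, and an empty `value` meaning missing. Light
schedules are small YAML files (`period_hours`, `light_hours`,
`lights_on_anchor_min`). See `read_cohort()` / `write_cohort()` /
`read_schedule()`.

See `vignettes/circaphen-methods.Rmd` for the models, parameter defaults,
numerical conventions and limitations.
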