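# tonofit

Imaging-based tonotopic fitting of cochlear implants, and the analysis of
daily-randomized within-patient crossover trials evaluating it.

## What it does, and for whom

Cochlear implants map acoustic frequency bands to electrode contacts through
a frequency allocation table (FAT). Because electrode insertion depth and
cochlear size vary widely, a fixed clinical FAT leaves most users with a
frequency-to-place mismatch of an octave or more between what a contact's
neurons are tuned to and what the processor sends to it. `tonofit` is for
audiology researchers who want to (a) build individualized FATs from imaging-
derived electrode geometry and (b) evaluate them against the clinical
standard with a daily-randomized wearing schedule and a longitudinal
learning-curve analysis.

The core pieces, in the field's notation:

* **Greenwood map** `F(x) = A(10^{a·x} − K)` (defaults `A = 165.4` Hz,
  `a = 2.1`, `K = 0.88`) converts each contact's relative distance from the
  apex, `x = (CDL − d)/CDL`, into a tonotopic place frequency.
* **FAT construction**: place frequencies become channel lower bounds, a
  virtual (phantom) channel spans 238 Hz up to the most apical contact's
  place frequency, channels at or above the 8,598 Hz processor ceiling are
  disabled, and a low-frequency rule set (≥ 2 channels below 1 kHz, ≥ 4 below
  2 kHz, ≥ 7 below 4 kHz, basal channel ≤ 8,598 Hz) is enforced by a
  deterministic geometric repair.
* **Mismatch** per channel is `Δoct = log2(place / assigned)` octaves.
* **Daily randomization**: 1:1 test/control over 84 days, runs ≤ 2 days in
  the first four weeks and ≤ 4 thereafter, drawn by constrained sequential
  sampling with exact lookahead feasibility; plus per-visit processor-label
  shuffling and diary compliance auditing.
* **Outcomes**: scoring/substitution rules (20% guessing score, 15 dB SNR
  assignment, invalid-SRT exclusion, CNC test–retest averaging), linear
  interpolated learning curves with Begin / End / AUC / learning-rate
  parameters, exact Wilcoxon signed-rank comparisons with bootstrap CIs and
  Holm–Bonferroni correction, ACALOS loudness-growth AUCs, listening-effort
  levels, and a 1-up/1-down spectral-ripple staircase.
* **Synthetic cohorts**: anatomy, schedules, diaries and saturating learning
  curves with noise and missingness, fully reproducible from one seed, so the
  complete pipeline runs with no patient data.

## Worked example

```r
library(tonofit)

# one subject: 16 contacts, apical contact 22 mm deep, CDL 35 mm
geom <- electrode_geometry(seq(22, by = -0.95, length.out = 16), 35,
                           subject_id = "S01")
pf <- place_frequencies(geom)
round(pf[c(1, 8, 16)], 1)
#> [1]  851.1 2352.1 6991.8

fat <- build_tonotopic_fat(pf, subject_id = "S01")
fat
#> Frequency allocation table [S01]: 17 channels (17 enabled, incl. virtual channel)
#>   enabled band: 238 - 8598 Hz
#> ...

mismatch_profile(standard_fat(), pf)
#> Frequency-to-place mismatch (geomean representative): median 0.82 octaves (IQR 0.92), median |mismatch| 0.82
mismatch_profile(fat, pf)
#> Frequency-to-place mismatch (geomean representative): median -0.10 octaves (IQR 0.01), median |mismatch| 0.10

generate_schedule(84, seed = 1)
#> Wearing schedule: 84 days (control = 42, test = 42)
#>   run caps: <= 2 days within days 1-28, <= 4 thereafter

# end-to-end on a simulated 14-subject cohort
res <- run_pipeline(pipeline_config(
  cohort = cohort_config(n_subjects = 14, master_seed = 1),
  n_boot = 1000, seed = 1))
res
#> Pipeline result: 14 subjects
#>   mismatch (median octaves): standard 0.63, imaging-based -0.10
#>   median compliance deviation: 1.19%
#>   cnc End: control 67.98 vs test 47.92, p = 0.000122
#>   sentence_quiet End: control 86.45 vs test 78.02, p = 0.0353
#>   sentence_noise End: control 0.19 vs test 1.66, p = 0.0245
```

Reading the output: for this mid-range insertion the standard FAT mis-places
frequencies by a median 0.82 octaves while the imaging-based FAT is within
0.10; the simulated cohort (whose generator deliberately gives the control
arm a higher CNC asymptote) yields End medians of 68.0% vs 47.9% with an
exact signed-rank p ≈ 1.2 × 10⁻⁴. SRT is in dB SNR, lower is better.

A thin CLI wrapping the same functions ships in `inst/cli/tonofit`
(`map`, `schedule`, `simulate`, `analyze`, `run` subcommands).

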