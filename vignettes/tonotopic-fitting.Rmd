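---
title: "Tonotopic CI fitting and daily-randomized trial analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tonotopic CI fitting and daily-randomized trial analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonofit)
```

## The problem

A cochlear implant (CI) routes acoustic frequency bands to electrode
contacts through a frequency allocation table (FAT). Clinical default FATs
ignore where the electrode actually sits in the cochlea, so most users face a
substantial frequency-to-place mismatch: the characteristic frequency of the
neurons near a contact differs — often by more than an octave — from the
frequencies the processor sends to it. `tonofit` implements the computational
chain needed to build individualized, imaging-based FATs from electrode
geometry and to evaluate them against the clinical standard in a
daily-randomized within-patient crossover trial, together with a synthetic
cohort generator so the whole pipeline runs and can be tested without any
patient data.

## Tonotopic mapping

Insertion depth of each contact is the arc length from the round window to
the nearest point of a lateral-wall polyline (`insertion_depth()`; the
projection is onto segments, not vertices). Depth `d` relative to the
cochlear duct length (CDL) gives the relative distance from the apex,
`x = (CDL - d)/CDL`, and the Greenwood map

$$F(x) = A\,(10^{a x} - K)$$

yields the place frequency (`place_frequencies()`). The study this design
follows cites the Greenwood function without printing constants; we default
to the published human fit `A = 165.4` Hz, `a = 2.1`, `K = 0.88`, all
configurable via `greenwood_params()`. The lateral wall is marked at
basilar-membrane height but no organ-of-Corti or spiral-ganglion length
correction is applied; `place_frequencies()` exposes an optional
multiplicative `length_correction` (default 1) for users who want one.
Contact 1 is the most apical throughout, and all I/O tables carry explicit
contact indices.

## Building the imaging-based FAT

`build_tonotopic_fat()` allocates each contact's place frequency to the lower
bound of its channel. Full alignment is constrained three ways:

1. **Processor range.** Channels whose lower bound would reach the 8,598 Hz
   ceiling are disabled (typically the most basal one to four contacts);
   bounds below the 238 Hz floor are clamped up to it, with ties spread
   geometrically so bounds stay strictly increasing.
2. **Virtual channel.** A phantom channel (index 0) spans 238 Hz up to the
   most apical contact's place frequency, delivering low-frequency content
   apical to the array. It counts as a channel for the rule set. If the
   apical place frequency is at or below the floor the virtual channel is
   degenerate and disabled, and the apical physical channel reaches down to
   238 Hz instead.
3. **Low-frequency rule set** (`fat_rules()`): at least 2 enabled channels
   below 1,000 Hz, 4 below 2,000 Hz, 7 below 4,000 Hz, and the most basal
   enabled channel at or below 8,598 Hz.

The source study calls this rule set an arbitrary trade-off and does not
describe how conflicts were resolved, so the repair here is one deterministic
choice: processing thresholds in ascending order, the offending channels
among the apical-most `count` enabled channels are lowered to geometric
spacing between the last compliant bound and the threshold, leaving all other
channels untouched. This perturbs as few channels as possible, keeps bounds
strictly increasing, and is reproducible; other repairs would be equally
defensible. Enabled channels are finally made contiguous (each upper bound
equals the next enabled lower bound; the top enabled channel is capped at
8,598 Hz), and every built FAT passes `validate_fat()` by construction — a
property fuzz-tested over hundreds of random geometries.

The standard (control) FAT is fixed: 16 enabled channels tiling
238–8,598 Hz. Only the floor and ceiling are published; the default uses log
spacing, `lower_k = 238\,(8598/238)^{(k-1)/16}`, and any transcription of the
true clinical table can be supplied instead.

### Mismatch

`mismatch_profile()` reports, per enabled physical channel,
`log2(place / assigned)` octaves. The representative assigned frequency is
the geometric mean of the band edges by default (the band centre on a log
axis — the conventional choice for a table whose bounds were not designed
tonotopically); setting `representative = "lower"` reproduces the
by-construction zero mismatch of an unrepaired imaging-based FAT. Reported
group medians of standard-FAT mismatch depend on this choice and on the real
anatomy distribution, so the package asserts the scale-free property instead:
on every synthetic subject, pooled absolute mismatch of the imaging-based FAT
never exceeds the standard FAT's.

## Daily randomization

`generate_schedule()` draws the within-subject wearing schedule: one label
(test or control) per day over 84 days (first fit to +12 weeks), 1:1 overall
(exactly 42:42 on even lengths), no more than 2 consecutive identical days
within days 1–28 and no more than 4 from day 29 on. Runs straddling the
boundary are judged per phase — the run counter resets at day 29 — which is
the weakest reading consistent with a per-phase cap and keeps the state space
small. Generation is constrained sequential sampling: a backward-induction
feasibility table (cached per period/caps) marks every state from which the
schedule can still be completed, and each day's label is drawn uniformly
among the feasible ones. This is linear-time, never restarts, and gives every
valid schedule positive probability (not uniform over the constrained set,
which the design does not require). The 1:1 ratio is enforced overall, not
per week. `shuffle_labels()` models the per-visit fair coin that maps
fittings to the circle/triangle processor labels, and
`compliance_deviation()` audits diaries as the absolute difference between
intended and reported shares of test-fitting days over reported days — a
total-exposure measure, so a diary in which both fittings are swapped on
every day still deviates by 0, while wearing control on every scheduled test
day deviates by 50 percentage points.

## Outcome analysis

`apply_score_rules()` encodes the scoring conventions: too-difficult
sentence-in-quiet visits are scored at the 20% guessing level; sentence
recognition in noise (SRT, dB SNR, lower is better) is accepted only when the
same visit's quiet score is at least 50%, otherwise 15 dB SNR is assigned;
measured SRTs above 15 dB SNR or outside the presented level range are
invalidated and excluded; CNC word scores average the test and retest lists.
The rules are idempotent, so cleaning an already cleaned table is a no-op.

`learning_curve()` interpolates visits linearly onto a daily grid over
days 0–84 (calendar days as the abscissa; a different span can be passed).
Interior missing visits are bridged linearly; boundary missing visits are
carried flat from the nearest observation, since interpolation is defined
between visits but extrapolation is not — flat carrying is the least
assumptive choice. `curve_params()` extracts Begin (day 0), End (day 84), AUC
(trapezoidal integral over the span, units × days, exact for the
piecewise-linear curve) and the learning rate, `(value(28) - value(0))/28`
units/day.

`paired_compare()` is a two-sided Wilcoxon signed-rank test with zero
differences dropped. For up to 25 nonzero differences the p-value comes from
the exact null distribution computed by convolution over doubled average
ranks — identical to enumerating all $2^n$ sign assignments (tested against
full enumeration up to n = 12) while handling ties exactly; above that a
normal approximation with tie correction is used. Descriptives are medians
and IQRs per arm plus percentile-bootstrap 95% confidence intervals (default
10,000 resamples, seeded; subjects resampled jointly so the
difference-of-medians CI is consistent). `holm_bonferroni()` applies the
step-down correction, used over Begin and End per measure in
`run_pipeline()`.

Secondary-outcome utilities: `effort_levels()` (six SNRs at ±3 dB steps
around the individual SRT), `acalos_auc()` (trapezoidal loudness-growth AUC
per 1/3-octave band over a 0–105 dB HL range, with the across-frequency AUC
summed over a 17-point log-frequency grid from 250 to 4,000 Hz after linear
interpolation — grid, range and category mapping are configuration, since the
companion method's exact surface is published elsewhere and this one is a
documented stand-in), and `smrt_staircase()` (1-up/1-down track from 0.5
ripples per octave with 0.2 rpo steps; the published procedure gives no
stopping criterion, so the track stops after 10 reversals — or a 150-trial
guard — and the threshold is the mean of the last 6 reversal values, a common
convention for this staircase family).

## The synthetic cohort

`generate_cohort()` emulates the study conditions end to end: cochlear duct
lengths ~ Normal(35, 2) mm truncated to [28, 42]; apical insertion depths
~ Normal(22, 2) mm truncated to keep all 16 contacts (0.95 mm spacing) at
non-negative depth and at least 1 mm short of the CDL; learning curves
follow saturating exponentials `S(t) = asymptote (1 - e^{-t/\tau})` (the SRT
mirrored so it improves downward from 15 dB SNR), with per-arm asymptotes
defaulting to the group medians of the trial the design follows
(control/test CNC 68/47%, quiet 89/79%, SRT 0.25/1.9 dB SNR; τ = 21 days
puts the control CNC end score near 66.8%). Visit noise (6% CNC, 7% quiet,
1.5 dB SRT), 10% visit missingness and a 5% daily diary error rate are
literature-plausible single choices, not fits. CNC visits emit two list
scores; early quiet visits whose underlying score is below 25% are flagged
too difficult, and early noisy SRTs can exceed 15 dB SNR, so all scoring
rules are exercised in moderate cohorts. Per-subject seeds are drawn once
from the master seed and each subject is generated under its own seed, so
datasets are byte-reproducible and swapping one subject's seed perturbs only
that subject.

What the generator does *not* emulate: real cochlear spiral shapes (only arc
lengths), between-subject correlation structure, learning-curve shapes beyond
a single exponential, carry-over between fittings, and the anatomy–outcome
coupling of real patients. Passing tests therefore validate the *machinery*
— constraint satisfaction, statistical calibration, pipeline integrity — not
clinical effect sizes, and group-level results from the real trial (e.g. its
1.50-octave median standard-FAT mismatch) are not reproduced at desk scale.

## Numerical choices and limitations

Problem sizes in the test suite were chosen for a laptop-class run: 50–300
fuzzed geometries, 10,000 schedule draws, 500 replicate cohorts each for the
type-I and power checks of the End comparison (n = 14 subjects, 20-point
asymptote gap, exact test at α = 0.05). FAT contiguity is checked to a
relative 10⁻⁶; the Greenwood inverse round-trips to 10⁻⁹ relative; CSV I/O
preserves numerics to at least 10⁻⁹ relative. Degenerate inputs fail loudly:
fewer than 8 usable channels is an unsatisfiable-rules error, fewer than two
non-missing visits cannot form a curve, and an all-zero set of paired
differences yields p = 1 with a warning rather than an error.
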