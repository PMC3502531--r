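---
title: "Methods: plate QC and SSMD-based hit selection"
author: "ssmdscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate QC and SSMD-based hit selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmdscreen)
```

ssmdscreen analyses high-throughput RNAi and small-molecule screens run
in 96- or 384-well plates: per-plate quality control, well scoring,
effect-size classification and hit selection, with tabular and graphical
reporting.  This vignette records the statistical model behind each
step, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-screen validation does and does not demonstrate.

## Data model

A screen is a set of plates, each a matrix of signal intensities
(8 x 12 or 16 x 24).  Every well carries exactly one role:

* **sample** — the library reagents under study;
* **negative reference** — the well population supplying the baseline
  location and spread for scoring.  In an unfocused genome-scale
  library a high hit rate is not expected, so all sample wells are the
  reference (the default).  In focused or confirmatory screens the
  negative controls can be flagged as the reference instead — the only
  permitted dual designation;
* **negative control / positive controls 1–3** — wells with known
  inactive/active reagents, used for plate quality metrics only;
* **blank** — wells excluded from every computation.

Wells marked `NaN` in the input files are treated as missing and
excluded from every statistic.  An optional log2 or log10 transform is
applied before any computation; luminescence-type readouts are strongly
right-skewed and approximately log-normal, so the log transform
symmetrises them (the per-plate raw/transformed histogram pair lets the
analyst verify this).  Nonpositive values under a log transform become
missing with a counted warning rather than an error, because
background-subtracted readouts legitimately go negative; a plate with
*no* positive values is an error.

## Plate quality control

For each plate, each control set is summarised by `n`, mean, sample SD
(`n - 1` denominator throughout) and CV, and each positive-control set
is compared with the negative control through three metrics:

* **Z'-factor** `1 - 3(s_p + s_n) / |m_p - m_n|`: at most 1 (exactly 1
  only when both SDs vanish), undefined when the means coincide.  The
  conventional small-molecule acceptance threshold is 0.5; RNAi screens
  routinely sit below that, which is one motivation for the SSMD-based
  metric.
* **SSMD (method-of-moment)** `(m_p - m_n) / sqrt(s_p^2 + s_n^2)`:
  signed, comparable across screens with positive controls of
  different strengths.
* **Signal window** `(|m_p - m_n| - 3(s_p + s_n)) / s_n`: the
  separation left between the two 3-SD control bands, in units of the
  negative-control SD; negative means no usable window.  The signal
  window has no single canonical definition in the QC literature; this
  is the assay-guidance form with the negative-control SD in the
  denominator.

All three are affine-invariant (unchanged under `x -> a x + b`,
`a > 0`), which the test suite verifies.

### Control-outlier knockout

Pipetting failures and edge artifacts corrupt control wells often
enough that an automated, capped trimming step is useful.  With
parameters `k` (SD multiplier, default 2) and `f` (maximum fraction,
default 0.3), each control set is trimmed iteratively: recompute the
set's mean and SD, take the point with the largest absolute deviation,
remove it if it exceeds `k` SD, and stop when no point qualifies or
when `floor(f * n0)` removals have been made (`n0` the initial size —
the cap uses `floor`, so `f = 0.3` on a 16-well set allows at most 4
removals).  Recomputing after every removal is deliberate: a gross
outlier inflates the SD and can mask a second one, and the sequential
form unmasks it.  Ties on the deviation are broken toward the earliest
well in row-major order, making the procedure deterministic.  The
negative reference is never trimmed — it is a scoring baseline, not a
QC arm.  All metrics and figures are produced for both stages
(`before_knockout`, `after_knockout`).

The tests compare this implementation against a brute-force
re-derivation on 10^4 random small sets, and verify on synthetic
screens that a single injected 6-SD outlier in a 16-well control set is
removed in at least 99% of seeds.

## Scoring

Let `m_N`, `s_N`, `med_N`, `MAD_N` be the per-plate mean, SD, median
and MAD of the negative-reference wells (computed after the transform).
MAD carries the 1.4826 normal-consistency factor, so robust and
classical scores agree on Gaussian data — worth stating prominently
because it rescales every robust score.  For single-copy screens:

| method | score |
|---|---|
| z-score | `(x - m_N) / s_N` |
| robust z-score | `(x - med_N) / MAD_N` |
| SSMD | `(x - m_N) / (sqrt(2) s_N)` |
| robust SSMD | `(x - med_N) / (sqrt(2) MAD_N)` |
| percent activity | `100 (x - m_N) / (m_high - m_N)` |

The `sqrt(2)` arises because the single-copy SSMD estimates the
standardised difference between one well and a reference draw, whose
difference has variance `2 s_N^2`.  SSMD is therefore exactly
`z / sqrt(2)` — the implementation computes it in that form so the
identity holds to the last bit, and the tests assert it.  The
non-robust SSMD centres on the reference mean and the robust variant
on the median, mirroring the z-score pair.  Percent activity uses a
user-designated positive-control set as the high signal (its mean is
taken after knockout when knockout is enabled, so scoring and QC see
the same cleaned controls) and is undefined when the high and low
means coincide.

For replicated screens (3 or more copies; copies listed consecutively
in the plate-ID file, each group referencing one source plate), each
well is scored from its per-replicate differences
`d_j = x_j - med_N(plate j)` — pairing against the plate median is
robust to plate-level shifts:

* **UMVUE SSMD** `c_n * mean(d) / sd(d)` with
  `c_n = Gamma((n-1)/2) / Gamma((n-2)/2) * sqrt(2/(n-1))`, the factor
  that removes the small-sample bias of the naive ratio
  (`c_3 = 1/sqrt(pi) ≈ 0.564`, increasing to 1).  Unlike a t-statistic,
  the estimate does not grow with the replicate count, so scores are
  comparable across screens.
* **paired t-test** `t = mean(d) / (sd(d)/sqrt(n))` with a two-sided
  p-value on `n - 1` degrees of freedom.  Two-sided because the test
  by construction cannot tell signal-increasing from signal-decreasing
  wells; correspondingly its hits are "unclassified".

Wells with fewer than 3 non-missing replicates, or zero-variance
differences, are reported with an undefined score and are never hits.
Control wells are scored too (the score table is grouped by well
type), but only sample wells can be hits.

## Hit selection and effect classes

The cutoff is interpreted per method: for the z/SSMD families a sample
well is a signal-increasing hit when `score >= +cutoff` and
signal-decreasing when `score <= -cutoff`; percent activity is
single-sided in a user-chosen direction; for the t-test the cutoff is
the maximum p-value.  Comparisons are inclusive so that the popular
SSMD cutoff 1.28 coincides exactly with the lower bound of the
"moderate" effect class.  No multiple-testing correction is applied to
t-test p-values — the raw-p cutoff convention of the screening
literature — which is a documented limitation.

SSMD scores are additionally classified on the standard 21-bin
effect-size scale (extremely weak through extremely strong, signed,
plus "no effect" for exactly 0).  The up side uses half-open intervals
`[lower, upper)` — e.g. strong is `3 > SSMD >= 2` — and the down side
is the exact mirror `(-upper, -lower]`.  Published versions of this
table sometimes carry sign typos on the down side; the mirror-symmetric
form is the intended reading and is what the partition and symmetry
property tests enforce.  Two further boundary decisions keep the
partition disjoint: exactly 0 belongs to "no effect" only, so the
up-side "extremely weak" bin is open at 0.

Two screen-level diagnostics summarise the hit set: per-well hit
frequencies across plates (hotspots betray systematic errors; the
denominator is all plates, including any on which the well was
missing) and per-plate hit counts (which should be consistent across a
screen).

### The false-positive rate at cutoff 1.28

Under a Gaussian null the single-copy robust SSMD score is
approximately `N(0, 1/2)`, so the two-sided exceedance of cutoff 1.28
is `2 * pnorm(-1.28 * sqrt(2)) ≈ 7.0%` of null wells — and about 5.4%
in the synthetic validation screens, where the spiked wells inflate
the reference MAD slightly.  Cutoff 1.28 is therefore a deliberately
permissive primary-screen choice that trades specificity for
sensitivity (about 99% at true SSMD ±3); analysts wanting a null flag
rate nearer 1% should cut at 1.645 or higher, or rank by effect class.
The acceptance suite records this measured trade-off.

## Synthetic screens

`synthetic_spec()` / `simulate_screen()` / `generate_screen()` produce
screens with known ground truth so every stage is testable without an
external dataset.  The defaults emulate a genome-scale luminescence
siRNA screen and are fixed study conditions, not tuning knobs:

* 12 plates, 384-well, standard layout: 320 sample wells (all negative
  reference), 16 negative controls (column 1), 16 + 16 wells of
  positive controls 1 and 2 (columns 2 and 23), 8 of positive control
  3 (column 24 rows A–H), 8 blanks (column 24 rows I–P);
* baseline log-normal: `log2(signal) ~ N(10, 0.5)` (a ~1000-unit
  median with a realistic ~35% CV), giving visibly right-skewed raw
  histograms that log2 symmetrises;
* positive-control shifts +3, +2 and −2 log2 units — strong, medium
  and inverted controls;
* five spiked hits per plate, three at true SSMD +3 and two at −3, at
  fixed sample wells.  A spike of true SSMD `beta` is a log2 shift of
  `beta * sqrt(2) * sdlog2` (the inversion of the single-copy SSMD
  formula); `true_ssmd_spike()` exposes the map;
* optional outlier injections (a chosen control set, plate and z
  offset) to exercise the knockout; blanks are written as `NaN`,
  exercising the missing-value path end to end.

Generation is deterministic given the seed (byte-identical files).
The generator reproduces the distributional features that drive the
statistics — skewness, control separation, effect sizes — but not
spatial artifacts (edge effects, dispenser stripes) or reagent-level
biology (off-target effects, variable knockdown efficiency).
Normalisation for spatial/systematic error is out of scope, so passing
tests say nothing about performance on plates needing such correction;
the heat maps, series plots and hit-frequency maps exist precisely so
an analyst can notice those artifacts in real data.

Validation highlights (all in the test suite): a spiked well's robust
SSMD estimate is unbiased — averaged over 200 single-plate seeds it
sits within 0.15 of the true value 3 (a single-seed estimate has SD
near `1/sqrt(2)`, so the invariant is about bias, not per-well noise);
t-test p-values under the null are uniform (Kolmogorov–Smirnov at
alpha 0.01 on 10^4 simulated wells); recovery of ±3 spikes at cutoff
1.28 exceeds 95% sensitivity with the null flag rate discussed above.

## Numerical and interface decisions

* Score tables are serialised with 6 significant digits; re-reading
  and re-writing is byte-stable, so golden files diff cleanly across
  platforms.
* Undefined metrics (zero denominators, equal means) are reported as
  missing values and plotted as gaps — never as zeros, and never as
  silent drops; the affected well or plate is named in errors.
* Every abort path carries one of the `validation_codes()` —
  currently `r nrow(ssmdscreen::validation_codes())` distinct codes —
  and `validate_protocol()` reports *all* detectable problems in one
  pass, while `run_analysis()` refuses to start computing on the first.
  The command-line driver maps code families to exit-status families
  (2 validation, 3 I/O, 4 numeric degeneracy).
* Run folders are suffixed with a timestamp (name limited to 25
  characters) and staged in a temporary directory, so reruns never
  overwrite results and aborted runs leave no partial folder.
* Plate-ID-to-file matching prefers an exact file-stem match, then a
  unique substring; IDs are claimed longest-first so `P10` cannot be
  shadowed by `P1`, and a residual ambiguity is an error rather than a
  warning.
* Figures (50-bin histograms, fixed across plates for comparability;
  heat maps on both the plate's own scale and the screen-wide
  rescaled bounds `min(negref means) - 2 min(negref SDs)` to
  `max(negref means) + 2 max(negref SDs)`; series, control, QC,
  scatter, hit-frequency and hit-count plots) are written as JPEG with
  a `.tsv` dump of the plotted values beside each image — regression
  tests compare data, not pixels.  t-test scatters use a `-log10(p)`
  axis with the line at `-log10(cutoff)`.  The HTML report is a pure
  function of the run folder and is byte-identical on re-assembly.

## Worked example

```{r example}
sim <- simulate_screen(synthetic_spec(n_plates = 3, seed = 42))
design <- screen_design("robust_ssmd", cutoff = 1.28, transform = "log2",
                        knockout = knockout_params(k = 2, f = 0.3),
                        plate_pairs = sim$plate_pairs)
res <- analyze_screen(sim$data, sim$config, design,
                      annotations = sim$annotations)
glance(res)
head(tidy(res)[, c("assay_plate_id", "well", "score", "hit_category",
                   "effect_class")])
summarise_effect_counts(res$effect_counts, at_least = "moderate")
```

The test-scale problem sizes used throughout (2–12 plates, 200-seed
recovery studies, 10^4-case oracles) were chosen as the smallest sizes
at which the stochastic checks are stable to their stated tolerances.

## Known limitations

* No spatial normalisation (B-score, loess, edge correction): flagged
  for inspection in the figures but not corrected.
* No gene-level aggregation across reagents, no FDR estimation, no
  moderated t statistics.
* Percent activity inherits the usual caveat that it ignores
  within-plate variability; it is provided for comparison with the
  SSMD family, which is the recommended path.
* 1536-well plates are not supported.
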