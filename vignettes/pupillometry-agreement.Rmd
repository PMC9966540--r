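---
title: "Reading pupillary light reflex traces and assessing their reproducibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading pupillary light reflex traces and assessing their reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilagree)
```

## Scope and data model

`pupilagree` works on continuous binocular pupil-diameter recordings of
a fixed examination protocol: 3 s of darkness followed by a 10 s light
stimulus, under mesopic (4 lux) and photopic (300 lux) conditions, five
repeats per condition, both eyes recorded but (by convention) only the
right eye analyzed. Because native pupillometer exports are proprietary,
the package defines its own long-format trace CSV (one row per sample:
timestamp, diameter in mm, device validity flag, plus session metadata)
and a per-session reading CSV. Missing diameters (lost pupil tracking)
and device-invalid samples are distinct states; both are discarded by
the reading algorithm but accounted separately.

Timestamps are seconds from recording start with stimulus onset at
3.0 s; all window arithmetic is relative to the per-trace
`stimulus_onset_s` field, never hard-coded. The sampling rate defaults
to 30 Hz — consistent with the step filter's equating of a 0.5 mm
per-sample change with roughly 15 mm/s — but is a per-trace field.

## The automated reading algorithm

Per trace, in order:

1. **Hampel/MAD pass.** For each present-diameter sample, the median
   `m` and scale `S = 1.4826 * median(|x_j - m|)` are computed over a
   centered 1.4 s window of present samples (truncated at trace edges;
   a trailing window is available via `filter_config(hampel_centered =
   FALSE)`). The sample is *removed* — not replaced, as a classic
   Hampel filter would — when `|x - m|` exceeds 1.5 mm or `3 * S`,
   whichever is smaller. When `S = 0` (locally constant signal) only
   the absolute rule applies, so flat segments are never annihilated.
   Window endpoints are inclusive with a 1e-9 s tolerance so grid
   samples exactly half a window away are treated deterministically.
2. **Validity rules.** Device-invalid samples, missing diameters, and
   diameters outside the 2–9 mm plausibility band are discarded; then a
   chain scan in time order removes samples differing by more than
   0.5 mm from the *last retained* sample. Anchoring on the last
   retained point keeps one spike from cascading into removal of the
   recovered signal; the raw-predecessor variant is available via
   `step_anchor = "raw"`. A consequence worth knowing: if a genuine gap
   (e.g. a blink during a steep constriction) leaves the next valid
   sample more than 0.5 mm away, the remainder of that repeat is
   discarded and its quality score collapses — which is exactly how a
   repeat ends up excluded by the quality rule below.
3. **Window statistics.** Over the half-open window `[onset + 2,
   onset + 4)` the median and 10th percentile of retained diameters are
   computed with the linear-interpolation percentile definition
   (`stats::quantile` type 7; a stated convention is required for exact
   reproducibility). The quality score `q` is the ratio of retained to
   *all* samples falling in the window by timestamp, including
   device-invalid ones. The weight is `w = q * exp(-2 d)` with
   `d = |median - p10|`.
4. **Session estimate.** Repeats qualify only with `q > 0.5` (strict,
   per the printed inequality); the estimate is the weighted mean of
   qualifying 10th percentiles. If no repeat qualifies the session
   reading is *missing* — never zero — and flagged
   `below_quality_threshold`, which downstream comparisons handle by
   pairwise deletion (reproducing reduced-N patterns).

The window's lower tail has a useful physical reading: with all 60
samples of a 2 s, 30 Hz window retained, the 10th percentile rests on
6 samples, i.e. 200 ms of recording, whereas the human-assisted reading
may rest on a single data point.

**Emulated human-assisted reading.** The GUI procedure is not an
algorithm, so the package emulates it transparently: the minimum
present diameter over the whole 10 s stimulus, after discarding
device-invalid samples and diameters outside 2–9 mm (a blink-spike
guard), with no Hampel pass and no windowing; the session value is the
unweighted mean of the five repeat minima. Outputs label the method as
emulated. Two mechanisms make it read lower than the automated method:
pupillary escape (re-dilation from the phasic trough, larger under
mesopic light) pushes the windowed percentile up whenever escape begins
inside the window, and late latent constrictions are visible only to
the whole-stimulus minimum.

## Agreement statistics

`bland_altman()` computes per-subject differences `a - b` (or ratios
`a / b`), bias, the sample SD (n − 1 denominator; the standard choice),
LOA `bias ± 1.96 SD`, and the agreement/repeatability coefficient
`1.96 SD`. Interval estimates use `SE(bias) = sqrt(SD^2/n)`,
`SE(LOA) = sqrt(3 SD^2/n)` and the two-sided t quantile with n − 1
degrees of freedom; 1.96 appears only inside the LOA definition itself.
Outliers are defined on the all-data fit as values more than 3 SD from
the bias and removed in a single pass (no iteration), with both fits
reported — mirroring "all" and "outliers excluded" table rows.

`proportional_bias()` is the two-sided Pearson test of values against
averages `(a + b)/2`. `analyze_pair()` triggers the ratio-scale
analysis when that correlation is significant at `alpha = 0.05`
(judged on the outlier-excluded difference fit when one exists, the
most robust of the reported rows). The ratio analysis is equivalent to
a log transformation (`log_ratio_equivalence_check()` verifies the
identity numerically). For method comparisons the orientation is
`a = automated`, `b = human`, so a larger automated reading appears as
a positive bias and a mean ratio above 1; the orientation is an
argument and is recorded in the output labels.

Normality of differences is assessed visually: `qq_data()` emits
standardized order statistics against normal quantiles at
`(i - 0.5)/n`, with no automatic accept/reject.

## The synthetic generator

No public pupillometer recordings accompany this problem, so the
generator provides ground-truth-bearing fixtures. A trace is a
piecewise trajectory: flat dark baseline; a scaled-exponential
constriction reaching the phasic minimum exactly at `time_to_min`
(shape exponent 2, keeping peak constriction velocity near
`2.3 * depth / time` — well under the ~15 mm/s the step filter treats
as artifact); exponential escape toward `phasic_min +
escape_amplitude` after an optional delay; an optional Gaussian-shaped
latent constriction dipping to an absolute level `depth_mm`; additive
Gaussian noise; and blink artifacts as Poisson-placed runs of
missing, device-invalid samples flanked by sub-2 mm spikes, so both the
validity and plausibility filters are exercised. Everything is
deterministic given the parameter seed.

Session and cohort structure encode the study conditions as defaults:
43 subjects; across-subject minimal pupil sizes 4.12 (0.70) mm mesopic
and 2.73 (0.29) mm photopic; five repeats redrawn (cap 100) until their
spread fits the 1.0 mm device tolerability range; between-visit SDs
0.454/0.122 mm — the values implied by agreement coefficients of
0.89/0.24 mm via `coefficient = 1.96 * SD`. Two generator design
decisions deserve emphasis:

* **Visits are stationary, not a random walk.** Each visit deviates
  independently from a subject's latent size with SD
  `between_visit_sd / sqrt(2)`. Adding the full between-visit change to
  visit 1 would inflate visit-2 variance and manufacture a spurious
  correlation between differences and averages that the over-time
  comparisons should not show.
* **The method gap is built in per repeat.** Every generated repeat
  places the analysis-window plateau at `minimum * method_bias`
  (mesopic default 1.023) and a latent constriction dipping to the
  drawn minimum at 10.5 s. Real recordings show latent constrictions
  only occasionally; making the event systematic is the simplest way to
  give a cohort a controlled multiplicative method bias, and it is what
  the ratio-recovery checks rely on. The photopic default is 1.0
  because the intrinsic asymmetry of the two readings — a 10th
  percentile versus a single minimum of noisy samples — already
  produces a small positive gap of the observed order without any true
  proportional bias.

What the generator does **not** emulate: mechanistic autonomic
dynamics, hippus, accommodation-driven pupil changes, realistic blink
kinematics, correlated left/right eyes, or the variable depth and
timing of real latent constrictions. The last omission makes simulated
between-method SDs (coefficients ~0.03–0.06 mm) tighter than published
inter-method coefficients (0.15–0.25 mm); recovery checks therefore
target the over-time coefficients and the mean method ratio, which the
generator does control. Passing tests demonstrate that the pipeline
recovers known structure from data shaped like the protocol — not that
any physiological claim holds.

## Numerical and testing choices

* Percentile convention: linear interpolation (type 7), verified
  against a brute-force sort-and-interpolate oracle on random windows.
* Degenerate inputs: zero-MAD Hampel windows fall back to the absolute
  rule; single-sample windows retain their sample; empty analysis
  windows yield `q = 0`; zero-variance difference sets give flagged
  zero-width limits; zero-variance correlation inputs give a flagged
  missing `r`, treated as non-significant by the ratio trigger.
* Determinism: all generator randomness flows through explicit seeds
  (`withr::with_seed`), so identical configuration reproduces traces,
  readings and reports byte-for-byte (timestamps excluded).
* Problem sizes: unit tests run on single traces and 3–8 subject
  cohorts; statistical recovery runs one full 43-subject cohort through
  the complete pipeline plus 200 reading-level replicates for ratio-CI
  coverage — sizes chosen to match the study scale where the statistics
  demand it and to stay small where they do not.
* Recovery tolerances come from sampling theory, not convenience: a
  sample SD at n = 43 lies within `sqrt(chisq / df)` bands of the truth,
  so estimated coefficients are checked against the 99% chi-distribution
  interval around 0.89/0.24 mm.

## Known limitations

* The human-assisted emulation is an interpretation of a GUI
  procedure; it reads the minimum of *noisy* samples and is therefore
  biased slightly low relative to the trajectory minimum, an effect
  real human readers share only partially.
* Whether the original Hampel window was centered or trailing is not
  documented; centered is the default, the alternative is a switch.
* The step-rule anchor (last retained point) is a reconstruction; the
  raw-predecessor variant is provided for sensitivity analysis.
* Agreement functions assume one reading per subject and side;
  within-session repeatability coefficients (replicate-based designs)
  are out of scope.
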