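---
title: "Quantifying DNA supercoiling from topoisomer ladders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA supercoiling from topoisomer ladders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoquant)
```

## The measurement

Covalently closed plasmid DNA extracted from bacteria is a mixture of
topoisomers — molecules identical in sequence but differing in linking
number (Lk) by integers. On an agarose gel containing an intercalator such
as chloroquine, these species migrate to discrete positions, producing a
ladder of 7–8 visible bands per lane. Densitometry of such a lane gives the
distribution of the plasmid population over apparent linking numbers, and
its intensity-weighted mean,

$$\bar{Lk} = \frac{\sum_i I_i \, Lk_i}{\sum_i I_i},$$

is the per-lane supercoiling statistic everything else builds on. The
topmost band of a ladder is assigned apparent Lk = 0, the band below it 1,
and so on; the scale is relative because intercalator gels do not resolve
the sign of supercoiling, and because absolute band identities shift from
gel to gel.

That gel-to-gel shift is why cross-experiment comparison uses **Relative
Supercoiling Units (RSU)**: every gel carries two reference lanes, and a
lane's RSU is the position of its weighted mean Lk on the line through the
two references,

$$\mathrm{RSU} = \frac{\bar{Lk} - \bar{Lk}_{\mathrm{ref0}}}
                     {\bar{Lk}_{\mathrm{ref1}} - \bar{Lk}_{\mathrm{ref0}}},$$

so ref0 is 0 RSU and ref1 is 1 RSU by construction. The scale is invariant
under any affine transform applied to all three weighted means, which is
exactly the freedom a gel has (index origin and, to first order, spacing).
In the motivating assay the two references differ by about half a linking
number, so one full linking number of change converts to about 2 RSU.

DNA gyrase activity is scored on the same statistic: activity is the signed
change in weighted mean Lk per hour of incubation relative to the starting
relaxed distribution, and conditions are compared as percent variation
against the enzyme-only baseline (0% by construction).

## The densitometry model and its tunables

`quantify_lane()` is the fitting function: it takes a raw lane profile
(intensity versus migration position, top of the gel at position 0) and
returns a classed object holding the detected band table and the weighted
mean Lk. Its stages, with the parameters that matter:

* **Background subtraction** (`subtract_background()`): a rolling minimum
  over `window_px` followed by a rolling mean with the same window. The
  window (default 91 px, about three band spacings) must be wide enough
  that the minimum inside any window reaches the true inter-band baseline.
  Two numerical refinements matter in practice. First, the rolling minimum
  of a noisy trace is biased low by roughly the expected minimum of
  `window_px` noise draws; the estimator adds back that amount using a
  robust noise-sd estimate (median absolute successive difference /
  \(\sqrt2\)), a correction that vanishes identically on noise-free data.
  Second, `fit = "linear"` replaces the rolling estimate by its
  least-squares line. For washed gel lanes the true background is very
  nearly constant-plus-drift, and the rolling estimate's residual spatial
  wiggle is otherwise the single largest contributor to weighted-Lk
  variance (about 0.014 Lk sd at 1% noise, versus an irreducible 0.006 Lk
  from band-area noise). The pipeline default is `"linear"`; the bare
  operation defaults to `"none"`.

* **Band detection** (`detect_bands()`): local maxima filtered by
  topographic prominence at `min_prominence_frac` (default 0.05) of the
  profile maximum, then a minimum-separation rule keeping taller peaks
  first (ties keep the topmost — deterministic). Peak finding may run on a
  lightly smoothed copy of the trace (`smooth_px`, default off; the
  pipeline uses 5) so that bands sitting near the prominence threshold do
  not flicker in and out with noise; integration always uses the
  unsmoothed profile. Integrated intensities are trapezoidal areas between
  the midpoints to neighboring bands; the outermost bands integrate half a
  band spacing beyond their centers rather than to the profile ends, which
  is identical on clean data (band tails carry no area there) but keeps
  far-field noise from being booked as edge-band intensity.

* **Index assignment** (`assign_linking_numbers()`): integer indices by
  rounding distances to the estimated spacing. The spacing estimator
  treats the smallest "substantial" gap as one spacing unit and refits over
  all gaps rounded to multiples, so a band that dropped below the detection
  threshold (doubling its gap) does not distort the ladder, while a
  spurious sub-spacing doublet still collides onto one index and raises an
  explicit ambiguity error. When several lanes come from one gel, passing a
  common `reference_center` (the pipeline anchors on the ref0 lane's top
  band) puts all lanes on one index scale; this is what makes weighted
  means comparable across lanes, and it is required for RSU and for
  activity scoring.

## Group comparisons

`compare_groups()` implements the two tests the assay uses. Student/Welch
t-tests handle two-condition comparisons. For multi-condition panels it
runs a one-way ANOVA and Tukey–Kramer pairwise comparisons, with the
studentized range distribution evaluated by Gauss–Legendre quadrature of
its defining double integral (`ptukey_sr()`); this distribution function is
the package's own, cross-checked in the test suite against R's `ptukey`
(agreement to ~1e-4) and against a 10^5-permutation oracle on small
designs. Group labels are summarized as a compact letter display via
insert-and-absorb: groups ordered by mean (descending, ties by label), one
letter column split per significant pair, subset columns absorbed. Two
groups share a letter exactly when their adjusted p-value is at or above
alpha. Groups of n = 2 are accepted — gel experiments frequently run
duplicates — with an explicit low-replication warning, since the studentized
range at 2 observations per group has very little power.

## Polyamine quantitation and expression arithmetic

The polyamine module mirrors a standard HPLC calibration: a standard
mixture (20 mM putrescine, 10 mM spermidine, 10 mM spermine) serially
diluted four-fold, an ordinary least-squares line of response on
concentration per species (a nonpositive slope is refused as a calibration
failure), inversion of sample responses, and conversion to intracellular
concentration as amount / (CFU × cell volume), with 4 μm³ as the default
cell volume. Free concentrations apply configured free fractions — 0.40
for putrescine, 0.05 for spermidine, none for spermine — which are
literature-derived constants of the analysis, not quantities the package
computes; the binding equilibria behind them are out of scope. Values
below the 0.2 mM detection limit are censored inclusively (a value exactly
at the limit passes) and reported as "<limit".

The expression module is downstream arithmetic on a published FPKM table:
fold change is log2 of the low-Mg2+ (0.8 mM) value over the high-Mg2+
(10 mM) value — the direction is stated here prominently because the table
header does not state it, and it was fixed by cross-checking several rows —
and a gene is flagged differential when its q-value is below the threshold
(default 0.05). q-values of the form "<x" are stored as upper bounds and
compared as such; q-values are never recomputed. Recomputing fold changes
from the printed FPKM pairs reproduces the printed column within ±0.01 for
most rows; the handful that differ in the last digit (printed FPKM are
themselves rounded) are documented in the tests and excluded from exact
checks.

## What the simulator emulates — and what it does not

`generate_scenario()` produces fully labeled synthetic gels so that every
downstream stage can be tested against known ground truth:

* topoisomer distributions as discretized Gaussians over integer Lk
  (sd 1.35 Lk, support ±6), the standard physical model for a relaxed
  ladder;
* band positions linear in Lk (30 px spacing, optional quadratic
  compression for non-uniform ladders, default off), Gaussian band profiles
  (sd 5 px), total lane intensity split across bands in proportion to
  topoisomer probabilities;
* smooth linear background plus additive Gaussian noise (default 1% of the
  tallest band's amplitude), seeded per lane with no global RNG state;
* gyrase time courses as linear drift of the distribution mean.

The default scenario encodes the assay's normalization anchors: ref0 and
ref1 separated by 0.5 weighted Lk, plus a sample lane offset one full
linking number from ref0 (true RSU exactly 2). The ladder sd of 1.35 was
chosen so that exactly 7 bands sit well above the 5% prominence threshold
(the 8th pair sits at ~1% — a clear gap, so the detected band set is stable
under noise), matching the 7–8 visible bands of real chloroquine gels. On
this scenario the full pipeline recovers the 2-RSU lane with a standard
deviation of about 0.035 RSU across noise realizations, and zero-noise
lanes round-trip to the true mean within 0.003 Lk.

The simulator deliberately omits several features of real gels: lane
curvature and smiling, intercalator-dependent mobility (including the
folded mobility of highly supercoiled species), saturation of the imager,
and any physical model of chloroquine–DNA binding. Passing tests therefore
demonstrate that the quantification pipeline is correct and well
conditioned for ladder-shaped signals — not that it is robust to every
imaging artifact a wet-lab gel can produce.

## Problem sizes and numerical choices

The test suite and the acceptance script run synthetic lanes of 480–560
pixels with 3 lanes per scenario, Tukey designs of up to 17 observations,
and a 10^5-permutation oracle on a 12-observation design; everything
completes in well under a minute on one CPU. Tie-breaks are deterministic
throughout (equal peaks keep the topmost; equal group means order by
label). Degenerate inputs are first-class: flat profiles return empty band
tables rather than errors, a lone band is index 0, reference lanes closer
than 1e-9 Lk raise a degenerate-reference error, and a zero FPKM is a hard
error unless a pseudocount is requested.

## Known limitations

* RSU transfers supercoiling onto a relative scale only; no attempt is
  made to estimate absolute superhelical density or the sign of
  supercoiling, which intercalator gels cannot resolve.
* The weighted mean is computed over detected bands; species that never
  rise above the prominence threshold (heavily dispersed ladders) bias the
  mean toward the detected core. With the default 5% threshold this
  truncation error is below 0.01 Lk for ladders up to sd ≈ 1.5.
* Tukey p-values assume the usual one-way ANOVA model; at n = 2 per group
  they are exact under normality but fragile, which is why the permutation
  oracle is kept in the test suite.
* The expression module trusts the upstream differential-expression
  engine's q-values entirely.
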