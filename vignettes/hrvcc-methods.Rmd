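---
title: "Methods: HRV and cardiac-complexity analysis of ambulatory IBI recordings"
author: "hrvcc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRV and cardiac-complexity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hrvcc)
```

This vignette documents the models, conventions and design choices
behind `hrvcc`, in the spirit of a statistical-methods appendix: what
each stage computes, which parameters matter and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and where the genuinely open design decisions were settled.

## The analysis problem

Ambulatory recorders worn for about two hours export a sequence of
interbeat intervals (IBIs, milliseconds). From each recording the
pipeline derives a per-subject bundle of cardiac measures in two
families: *variability magnitude* (AVNN, HR, RMSSD, LF and HF spectral
power) and *cardiac complexity* (DFA scaling exponents, the
allometric-aggregation fractal dimension, multiscale sample entropy).
Cohort-level questions — do the sexes differ on these measures, and do
the measures predict internalizing-symptom scores, possibly differently
per sex — are then answered with grouped univariate comparisons and
two-step moderated regressions.

## Preprocessing

A recording passes through three stages, in a fixed order:

1. **Adaptation trim** (`trim_minutes = 15` per end). The boundaries are
   cumulative-time, not beat-count: an interval is kept iff it *ends*
   after the leading boundary and *starts* before the trailing one
   (half-open on both sides). A 120-min recording therefore yields a
   90-min analysed series whose length in beats depends on the
   subject's heart rate.
2. **Band filter** (`high_pass_ms = 400`, `low_pass_ms = 1100`).
   Physiologically impossible intervals are removed outright. Running
   this before the moving-window stage keeps gross artifacts from
   poisoning window means.
3. **Central-window filter** (11 intervals: `window_halfwidth = 5`,
   `exclusion_fraction = 0.20`). Each candidate central interval is
   compared with the mean of its ten neighbours (central excluded); it
   is removed when it deviates from that mean by more than 20% of the
   mean, and the window advances to the next interval.

Three semantics needed fixing where a verbal description underdetermines
an implementation:

* **Removal, not interpolation.** Excluded intervals are deleted; all
  downstream measures operate on the gapless surviving sequence. This
  matches reporting exclusions as counts; interpolation would
  manufacture data the device never recorded.
* **Single pass over the evolving series.** Once an interval is
  excluded it no longer participates in later windows; the scan never
  revisits earlier positions. "Advance to the next interval" reads as a
  single forward sweep; rescanning from the start after each removal
  could cascade differently. The test suite pins this semantics against
  an independent mask-based re-implementation.
* **Edges.** The first and last five intervals have no complete window
  and are never exclusion candidates. The window test is defined only
  for a full 11-interval window.

The exclusion report counts intervals relative to the trimmed series
entering the artifact filters, so `excluded_fraction` is comparable to
the ≈2% loss typical of healthy ambulatory recordings.

## HRV measures

Time-domain measures follow their defining formulas: AVNN is the
arithmetic mean NN interval; HR = 60000/AVNN (so HR·AVNN = 60000 holds
exactly); RMSSD is the root mean square of successive differences.

For spectral measures the NN series is an *unevenly sampled* signal on
its own cumulative-time axis. The default estimator
(`spectral_config(method = "resampled_fft")`) interpolates it with a
cubic spline onto a uniform 4 Hz grid — comfortably above twice the
0.40 Hz upper band edge — removes a linear trend, applies a Hann taper,
and computes a one-sided periodogram scaled by the taper power gain so
that band integrals are in ms². A Lomb–Scargle estimator
(`method = "lomb"`) works directly on the irregular beat times and is
kept as a cross-check; the two agree within 15% band power on clean
modulated test series. The FFT route is the default because it is the
named transform of the classical HRV toolchain; the Lomb route exists
because several reference toolkits use it, and which one a given study
actually ran is often ambiguous.

Conventions: band integrals are half-open, `[lo, hi)`, so the shared
0.15 Hz edge is counted once; LF is 0.04–0.15 Hz and HF 0.15–0.40 Hz
(a 0.4–0.15 "LF" is an obvious transposition and is not supported);
power below 0.04 Hz contributes to the Parseval total (the spectrum
object carries `signal_var`, the variance of the detrended analysis
signal, and the full-range integral matches it within 5%) but is not
reported as a measure. HF power is right-skewed across subjects, so
`ln_transform()` provides lnHF for parametric statistics; the package
reports lnHF rather than raw HF in cohort analyses.

## Cardiac-complexity measures

**DFA.** The mean-centred series is integrated; within non-overlapping
boxes of n beats a least-squares polynomial (order 1 by default) is
removed; F(n) is the RMS residual. α1 is the unweighted log–log slope
over boxes 4–11, α2 over 12–64. The α2 ceiling of 64 beats is a
convention (the short/long split at 11 beats has no stated upper
partner); it is config-exposed, and estimates are insensitive to it on
scaling series since the fit is a straight line in log–log space.
Incomplete trailing boxes are dropped. A constant series has F(n) = 0
and raises an error rather than returning a spurious exponent.

**Allometric aggregation.** Blocks of 1, 10, 20, …, 100 adjacent points
are *summed* (not averaged); per level the mean and SD of the
aggregated series are regressed as log SD on log mean; the slope is h
and FD = 2 − h holds exactly by construction. SD rather than variance
is fitted (the variance slope would be 2h); the log base cancels in the
slope. Levels with zero SD are dropped with a warning, and fewer than
three usable levels is an error. The default level grid suits series of
roughly 9,000 points (max level ≈ length/100).

**Multiscale entropy.** Coarse-graining *averages* non-overlapping
windows of τ points (τ = 1, 5, 10, 15, 20). Note the deliberate
asymmetry with the allometric stage, which *sums*: the two methods are
defined that way and the package preserves it. SampEn uses template
length m = 2 and tolerance r = 0.15 × SD, the convention of the
canonical multiscale-entropy reference implementation, because studies
in this literature rarely state m and r explicitly; both are
config-exposed. The tolerance is fixed from the original (scale-1)
series and reused at every scale — this is what makes entropy fall with
scale for white noise (coarse-graining shrinks its variance relative to
the fixed r) and is the behaviour the canonical implementation
exhibits; a per-scale-SD mode is available behind
`mse_config(r_mode = "per_scale")` for sensitivity analyses. Matching
uses the Chebyshev metric with self-matches excluded, counting over the
common N − m template set at both lengths (the C++ kernel is pinned to
a brute-force all-pairs R oracle exactly, to 1e−12, in the tests). A
series with no matches has undefined entropy and returns `NA` with a
warning — never a silent zero.

## Cohort statistics

**HR adjustment.** Many HRV/CC measures depend mathematically on mean
HR. Each measure's cross-subject correlation with HR decides the
correction: negative → divide by HR, positive → multiply by HR. The
exactly-zero (or undefined) boundary case is left unadjusted with a
warning — the sign rule simply does not apply there. HR itself is never
adjusted (it would become a constant). Both raw and adjusted values are
carried through all downstream analyses.

**Group comparisons.** Per measure, a one-way F on two groups
(equivalently the squared pooled-variance t; the equivalence is
asserted to 1e−9 in the tests) with p from F(1, N−2), plus pooled-SD
Cohen's d reported as a magnitude. Measures are grouped into four
Bonferroni families — time domain, frequency domain, scaling (DFA + FD)
and entropy — giving per-test alphas 0.05/2, 0.05/2, 0.05/3 and 0.05/5.
Only the univariate statistics are computed: a multivariate test
statistic adds nothing reportable when the target of inference is the
per-measure difference, and no multivariate quantity is part of the
package's output surface.

**Hierarchical regressions.** For each subscale × measure pair: step 1
is OLS of the subscale total on the sex code (1 = boys, 2 = girls,
entered raw and uncentred, mirroring the coding convention) and the
cohort-standardized measure; step 2 adds their product. Standardizing
the measure before forming the interaction is the multicollinearity
guard; the measure is standardized over the complete-case rows of that
regression (listwise deletion), so the z-scores are cross-cohort, not
within-sex. Reported coefficients are standardized βs
(b·sd(x)/sd(y)); each step reports R² and ΔR². Rank deficiency (e.g., a
single-sex cohort) is an error naming the collinear columns rather
than a silently dropped term.

## The synthetic-data generator

`gen_series()` emulates what the downstream stages *assume* about a
recording: a mean interval in the 600–700 ms range (HR ≈ 89–93 bpm, so
9,000–12,000 intervals in two hours), respiratory-band and slow
sinusoidal modulation on the beat-time axis, optionally long-range
correlated fluctuations (exact fractional Gaussian noise via circulant
embedding of the fGn autocovariance), and isolated artifacts — half
out-of-band values, half in-band spikes ≈40% off the local level,
planted at least 12 beats apart with their positions recorded so filter
recovery is measurable. The default artifact rate in the example
workflow (2%) matches the exclusion level a clean ambulatory recording
typically shows.

`gen_cohort()` defaults to 86 girls and 80 boys with per-group measure
means and SDs typical of mid-adolescent cohorts (HR near 90 bpm with
girls ≈4 bpm higher; RMSSD in the mid-30s ms; α1 ≈ 1.4; FD ≈ 1.09;
entropy ≈1.45–1.5 at large scales — group gaps of roughly 0.3–0.5
pooled SDs on most measures). Measures are drawn at the measure level,
each with an assumed cross-subject correlation of ±0.3 with HR
(positive only for the short-term DFA exponent, matching the
directionality the HR-adjustment rule expects); the true cross-measure
correlation matrix of real cohorts is not identifiable from published
summaries, so ±0.3 is a documented assumption, configurable per
measure. Symptom subscale totals are built from a standardized linear
model (default slopes ≈ +0.2 on HR, −0.17 on lnHF, small sex effects)
with residual SD chosen so the subscale SD matches its target when
predictors are uncorrelated, then rounded and floored at zero — item
totals on 0–3 scales, not item-level simulation. Whole symptom rows go
missing completely at random at 7% by default, reproducing the typical
gap between cardiac and questionnaire ns.

What the generator does *not* emulate — and therefore what passing
tests do not establish about real data: closed-loop baroreflex
dynamics, circadian drift, movement artifacts with temporal clustering,
non-Gaussian interval distributions, and any real cohort's actual
cross-measure correlation structure. Tests against the generator
validate the *estimators and their calibration*, not claims about any
particular population. A slow `from_series` mode generates an actual
IBI series per subject and pushes it through the full pipeline, used
for end-to-end consistency checks at reduced recording lengths.

## Numerical choices and degenerate inputs

* Aggregation and coarse-graining drop trailing remainders shorter than
  the block; level/scale 1 is the identity.
* DFA and allometric fits are unweighted least squares in log–log
  space; no weighting by box count.
* Constant series: error for DFA, SampEn and MSE (the quantities are
  undefined); zero-SD aggregation levels are dropped with a warning.
* SampEn with zero matches: `NA` with a warning, flagged per scale in
  MSE without affecting other scales.
* The Hann taper's power gain (mean w²) is divided out so band powers
  are unbiased; Parseval holds within 5% on white-noise checks.
* File parsing refuses non-numeric and non-positive intervals with the
  offending line number; nothing is silently dropped.
* All generators are bit-reproducible for a fixed seed.

## Problem sizes used in the test suite

The suite runs on one CPU in well under a minute. Estimator-calibration
checks use the series length the measures are designed for (n = 9000):
20 seeds for the white-noise DFA and allometric anchors, 12 seeds per
Hurst value in {0.5, 0.7, 0.9} for fGn recovery, with a ±0.05 band on
ensemble means. Statistical properties use the cohort geometry (80/86
or 77/77): 1,000 null replicates for the type-I rate of the group
comparison (band 0.04–0.06 at α = 0.05), 200 replicates for Cohen's-d
and standardized-β recovery (±0.05 on the mean). Sample-entropy
correctness is exact (1e−12) against a brute-force oracle on 100 series
up to n = 200, where the O(N²) oracle is cheap.

## Known limitations

* The central-window filter is O(window × n) in R; adequate for
  two-hour recordings, not tuned for days-long Holter data.
* The Lomb estimator loops over frequencies; for the default 90-min
  series it is noticeably slower than the FFT route and is intended as
  a cross-check, not the workhorse.
* Standardized βs are computed from OLS fits; no robust/sandwich
  variants are provided.
* The univariate comparison surface deliberately omits multivariate
  (Pillai-type) statistics; users needing them should fit
  `stats::manova()` on the measure matrix themselves.
* Symptom generation is at the subscale-total level; item-level
  response simulation (and hence internal-consistency structure) is out
  of scope.
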