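---
title: "Age-conditional reference centiles for gross motor function: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-conditional reference centiles for gross motor function: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmfmref)
```

## The problem

Children with cerebral palsy (CP) develop gross motor skills along five
distinct trajectories indexed by the Gross Motor Function Classification
System (GMFCS, levels I–V, from least to most limited). Clinicians follow a
child's GMFM-66 score — an interval-scaled 0–100 measure of gross motor
capacity — over repeated visits, and want to know not only whether the score
rose, but whether it rose *more or less than expected* for a child of that
age and functional level. That question needs age-conditional reference
percentiles per GMFCS level, built from longitudinal registry data in which
each child contributes between one and many tests.

`gmfmref` implements the full pipeline: the three-parameter distribution
that carries the centiles, its penalized-likelihood fit with age-varying
parameters, a repeated-measures adjustment by subsample resampling, bootstrap
machinery for comparing reference curves across cohorts, and a synthetic
cohort generator with known ground truth so that every stage can be
validated without access to registry data (which is available only on
request).

## The distributional model

Scores at a given age and level are modelled by the Box–Cox Cole–Green
(BCCG) distribution, the basis of the LMS method of centile estimation. A
positive score $y$ maps to a standard normal z-score through

$$ z = \frac{(y/\mu)^{\nu} - 1}{\nu\,\sigma} \;(\nu \neq 0), \qquad
   z = \frac{\log(y/\mu)}{\sigma} \;(\nu = 0), $$

with median $\mu > 0$ (LMS "M"), coefficient-of-variation-like scale
$\sigma > 0$ ("S") and Box–Cox power $\nu$ ("L") governing skewness;
$\nu = 1$ is the normal, $\nu = 0$ the lognormal, $\nu > 1$ left-skew — the
natural shape for a bounded score with a ceiling. The $p$-centile is
$\mu(1 + \nu\sigma z_p)^{1/\nu}$. Because $y > 0$ truncates the z-range at
$-1/(\nu\sigma)$, the density carries an exact truncation normalization
$\Phi(1/(\sigma|\nu|))$; it is included by default (`truncate = TRUE` in
`dbccg`) and can be switched off for compatibility with LMS software that
ignores it (for $\sigma \le 0.2$ the constant is numerically negligible,
which is why both behaviours are offered). Reported z-scores and centile
lookups use the plain untruncated transform, as centile charts do.

## Fitting age-varying L(t), M(t), S(t)

`fit_lms()` maximizes the penalized BCCG log-likelihood over three smooth
curves by iterative backfitting: an outer loop cycles over $\mu$, $\sigma$,
$\nu$; each inner step computes the parameter's score and expected-
information weight (identity link for $\mu$ and $\nu$, log link for
$\sigma$) and fits a weighted cubic smoothing spline to the Fisher working
response at a fixed effective-df budget. The analytic scores were verified
against numerical differentiation of the log-density, and the expected
weights are $(1+2\sigma^2\nu^2)/(\mu\sigma)^{-2}$-type standard forms; the
$\nu$ step uses a series expression stable as $\nu \to 0$ and is damped by
a factor 0.5 with $\nu$ clamped to $[-5, 5]$, because the power is the
least-identified parameter. If a full cycle would increase the deviance the
whole cycle is step-halved (up to six times), so the deviance trace is
non-increasing up to the convergence tolerance — the fit stops when the
deviance changes by less than `tol_deviance` (default $10^{-4}$) or after
`max_outer_iters` (default 50) cycles, warning in the latter case.

Degrees of freedom are counted per parameter as effective df beyond a
constant: `df = 0` a constant, `df = 1` a straight line in age, `df >= 2` a
cubic smoothing spline of total edf `df + 1`. Defaults are (4, 2, 0) for
$(\mu, \sigma, \nu)$: a flexible median, a gently varying scale, and a
constant power, which is weakly identified in small strata. Strata smaller
than `min_group_size = 50` are refused outright — shape parameters are
unstable below that. Scores of exactly 0 sit outside the BCCG support; when
present, all scores are shifted up by 0.5 units for fitting and curves are
shifted back (registry scores bottom out near 4, so this path is rarely
active). Curves are reported on an age grid with 0.05-year steps spanning
the training ages; evaluation outside that support is an error unless
extrapolation (clamped at the boundary) is requested explicitly. An optional
power transform of age is available for populations observed from birth,
but is off by default since observed ages start at 0.5 years.

### Choosing the smoothness: stepwise GAIC

`select_smoothing()` starts every parameter at the grid minimum and
alternately attempts single-step df increases and decreases (sweep order
$\mu$, $\sigma$, $\nu$, deterministic), accepting a move only when
GAIC = deviance $+ k \times$ total edf improves, with $k = 2$; equal-GAIC
ties resolve toward the smaller df. Two properties are worth knowing.
First, GAIC decreases monotonically along the accepted path by
construction. Second, $k = 2$ selection is AIC-like and therefore *not*
consistent: under a truth that is constant in age, each parameter still has
a ~15% chance of picking up one extra step (the classical $\chi^2_1 > 2$
overshoot), independent of sample size. What it reliably avoids is genuine
smoothing: in our null simulations (constant truth, n = 5000, 20 seeds) the
selected model had no spline term in 19/20 runs — at most a linear trend,
never a smoothed one — while a genuinely age-varying median earns spline
df essentially always.

When the data are longitudinal, run the selection on a one-per-child
subsample rather than the full stratum: correlated repeat tests inflate the
apparent information, and GAIC then buys more df than one child-worth of
data supports (on our synthetic registry cohort, selection on the full
level-I stratum hits the df grid ceiling while a subsample selects a
markedly leaner model). The analysis scripts follow this rule.

## Repeated measures: the median of one-per-child subsample fits

Registry children contribute 1–14 tests (mean ≈ 3); tests of one child are
correlated, and children with many visits would otherwise dominate the fit.
Rather than modelling the correlation, the pipeline neutralizes it:
`median_of_samples()` draws `n_samples = 100` subsamples with exactly one
randomly chosen test per child, fits each independently, and reports the
pointwise median of the fitted centile curves. Each subsample fit spans only
its own sampled ages, so curves are assembled on the full stratum's age
grid and grid ages covered by fewer than 80% of the successful fits are
dropped (the pointwise median needs enough contributing samples; the
threshold is a design choice). Subsample seeds derive deterministically
from the master seed, failed fits are dropped and counted, and more than
10% failures aborts. The pointwise median of monotone centile families is
monotone, so centile ordering survives the aggregation.

## Comparing reference curves across cohorts

`bootstrap_compare()` implements the cross-cohort uncertainty evaluation:
per replicate, eight one-per-child reference-curve fits per cohort; all
8 × 8 cross-cohort pairs are differenced and averaged pointwise (which
equals the difference of the two 8-fit means); the mean of the replicate
means is the mean-difference curve, and the pointwise 2.5/97.5 percentile
of replicate means the 95% band. A static, externally published curve
table can stand in for the second cohort, in which case only the first
cohort contributes uncertainty — the right behaviour when the comparator's
raw data are unavailable.

One design question deserves care: *what uncertainty should the band
carry?* With the replicates built purely from one-per-child subsampling
(the default, matching the described procedure), the band reflects
within-child measurement and subsampling noise *conditional on the observed
children*. In a calibration experiment — two independent cohorts of 800
children drawn from the identical generator — that band covered zero at
only ~9% of grid ages: the realized between-cohort difference is dominated
by child-level sampling noise the subsample scheme cannot see. Resampling
children with replacement before the eight subsamples
(`resample_children = TRUE`) restores honest cohort-level calibration
(~90–95% of ages covering zero in the same experiment) while still
detecting a true 5-unit shift over most of the age range. Both variants are
provided; calibration statements in the package's tests use the
child-resampling variant, and conditional-on-cohort statements the default.

`two_age_median_test()` asks whether the fitted median differs between two
ages (e.g. an apparent decline from 10 to 12 years): `n_reps` replicate
one-per-child fits give median estimates at both ages, all
`n_reps`² cross-replicate differences are pooled, and significance is read
from whether zero falls outside the central 95% interval. A paired
(diagonal-only) variant is available; the cross-combination form is the
default.

## The synthetic cohort generator

`cohort_config()` + `generate_cohort()` emulate a national CP registry
cohort: five GMFCS strata with prevalences 52/16/9/11/12%, 40% girls,
1–14 tests per child with mean 3.0 (a shifted, capped negative binomial,
solved numerically so the capped mean is exactly 3), test ages uniform on
0.5–17.3 years, rounded to 0.01 y and kept unique within child. Each child
at level $g$ follows a saturating mean trajectory
$m(t) = \text{limit}_g\,(1 - e^{-(t-\text{offset}_g)_+/\text{rate}_g})$ —
the classical rate-and-limit parameterization of motor development — with
child-level heterogeneity on the limit (sd 8 score units) and log-rate
(sd 0.25), and BCCG observation noise ($\sigma = 0.10$, $\nu = 1.3$, mild
left skew) clamped to [0, 100] by truncation (clamping preserves the mean
structure and keeps the ground-truth quantile easy to compute, at the cost
of a point mass at the bounds).

The per-level trajectory parameters — limits 90/75/60/42/22 for I–V,
time constant 2.3 y for I–IV so the mean reaches ~95% of its limit near
7 years, and a fast-saturating (rate 0.3 y), low-limit level V that is flat
over the observed ages — are **synthetic choices, not published values**:
the source registry publishes no trajectory parameters, so the defaults
were set once to reproduce the qualitative curve shapes (rise to a plateau
near 7 years for I–IV, flat V, stratum ordering) and left alone.
`true_percentile()` exposes the generator's ground truth: closed-form BCCG
quantiles when heterogeneity is off, seeded Monte Carlo (≥10⁵ draws)
otherwise.

What the generator deliberately does *not* emulate: visit schedules (test
ages are independent; the registry's follow-up intervals vary anyway),
dropout and mortality, intervention effects, item-level score construction,
age-dependent test frequency, and any real decline in older children
(trajectories are monotone non-decreasing — the declining-truth scenarios
in the tests are built directly from BCCG draws around a declining median).
Passing tests therefore show the *procedures* are correct and calibrated
under a realistic correlation and noise structure — they do not validate
the synthetic trajectory shapes against real children.

## Numerical choices, in one place

* BCCG branches switch at $\nu = 0$ exactly, with `log1p`/`expm1` forms
  keeping quantile and z-score continuous through $\nu \to 0$ (verified to
  $10^{-6}$ against the lognormal branch at $\nu = 10^{-8}$).
* Extreme lower centiles that cross the Box–Cox support boundary return the
  boundary value 0 with a warning rather than `NaN`.
* $\mu$ is floored at 0.05 and $\sigma$ confined to $[10^{-3}, 2]$ during
  fitting; fitted cohorts sit far from these guards.
* Subsample seeds: sample $i$ uses `derive_seed(master, i)`, an integer
  congruential hash kept below $2^{31}$; all randomness flows from
  user-visible seeds and every caller's RNG state is saved and restored.
* Centile curves are clipped to [0, 100] with a truncation flag, because a
  score cannot leave its scale even when the fitted distribution's tail
  does.
* Stepwise ties ($\Delta$GAIC = 0) keep the smaller df.

## Problem sizes used in the validation suite

The tests and the acceptance script run the pipeline at sizes chosen to
make their statistical assertions sharp but cheap: parameter recovery on
2000 independent children; centile calibration with a 5000-child training
stratum and 5000 fresh observations; null GAIC selection at n = 5000 over
20 seeds; repeated-measures recovery with 1500 children and 25 subsample
fits; bootstrap comparison with two 800-child cohorts and 200 replicates;
two-age testing with 50 replicate fits across 20 seeds. The full-scale
procedure (100 subsamples, 1000 bootstrap replicates) is what
`analysis/03_fit_reference_curves.R` and the defaults implement.

## Known limitations

* The fitter offers no monotonicity constraint; in small strata a fitted
  median can wiggle non-monotonically even when the truth is monotone.
* $\nu$ is fitted constant-in-age by default; an age-varying power is
  selectable but weakly identified below a few thousand observations.
* GAIC with $k = 2$ occasionally admits a spurious linear trend under a
  constant truth (see above); users wanting consistency should raise
  `gaic_penalty` toward $\log n$.
* The percentile band of the bootstrap comparison is pointwise; no
  multiplicity adjustment across grid ages is attempted.
* Scores piled at the 0 or 100 bound violate the continuous BCCG model;
  centiles near a heavy ceiling are truncated at the bound and calibration
  statements there are conservative.
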