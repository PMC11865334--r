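---
title: "Methods: quantifying discordance between spirometry reference equations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying discordance between spirometry reference equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spirodiscord)
```

## The problem

Spirometric measurements (FEV~1~, FVC, and their ratio) are interpreted
against reference equations that predict the distribution of each index for
a healthy person of a given sex, age and height. A measurement below the
lower limit of normal (LLN) — the 5th centile of the reference
distribution, z = −1.645 — is called abnormal. Historically the most used
equation families are race-specific; newer "race-neutral" families pool all
populations. Because the two systems place the LLN at different values for
the same patient, they can disagree about who has airway obstruction or a
restrictive pattern. This package provides the full machinery to quantify
that disagreement and to ask, on a given cohort, whether race is a
statistically necessary covariate of a best-fit reference equation:

1. evaluate reference equations of two engine kinds to z-scores and limits
   of normal;
2. classify obstructive/restrictive patterns and compare two equation
   systems with Cohen's κ and a confusion-matrix metric suite;
3. develop best-fit equations on a normal-spirometry subset and test race
   necessity by BIC;
4. validate by repeated 10-fold cross-validation with permutation and
   bootstrap tests of the RMSE difference;
5. generate synthetic cohorts so every step is testable without patient
   data.

## Equation engines

**LMS engine.** The reference distribution of an index is described by a
median M, coefficient of variation S and skewness L, each a function of sex,
age and height:

$$M = \exp\Big(\textstyle\sum_i m_i x_i + M_{\mathrm{spline}}(\mathrm{age})\Big),\qquad
  S = \exp\Big(\textstyle\sum_i s_i x_i + S_{\mathrm{spline}}(\mathrm{age})\Big),\qquad
  L = \textstyle\sum_i l_i x_i,$$

with covariates $x_i$ drawn from the closed vocabulary {intercept,
ln(height), ln(age), age}, and per-age spline contributions tabulated on an
ascending age grid. The z-score of a measurement $x$ is

$$z = \frac{(x/M)^L - 1}{L\,S} \quad (|L| > 10^{-6}), \qquad
  z = \frac{\ln(x/M)}{S} \quad (L \to 0),$$

with the branch threshold $|L| < 10^{-6}$ chosen so that the two branches
agree to well below $10^{-6}$ in z (verified by a continuity test). The LLN
and ULN are the values at z = ∓1.645. Between age-grid knots the spline
contribution is interpolated by a natural cubic spline by default, with a
linear alternative (`interp = "linear"`); published lookup software does not
document its interpolation, so the scheme is configurable rather than
asserted. Ages beyond the grid are an error unless extrapolation is allowed
explicitly, in which case the contribution is clamped to the nearest knot
with a warning.

**Polynomial engine.** US-style equation families publish separate
coefficient sets for the predicted value and the LLN, both linear in
{intercept, age, age², height²}. For metric interoperability the package
derives a pseudo z-score

$$z = 1.645\,\frac{x - \mathrm{predicted}}{\mathrm{predicted} - \mathrm{LLN}},$$

so a measurement exactly at the LLN maps to z = −1.645 and the same
classification and κ machinery applies to both engines. This is a
convention of this package, not part of the published equations; likewise
the ULN of a polynomial table is defined by symmetry (predicted mirrored
about the LLN), since those families publish no ULN.

Units are fixed throughout: age in years, height in cm, volumes in liters,
the FEV~1~/FVC ratio dimensionless. No published coefficient values ship
with the package — coefficient tables are user inputs in a delimited long
format (`read_equations()`/`write_equations()`); the file under
`inst/extdata/` is a synthetic demonstration set derived from the
generator's truth model.

## Classification and its boundary conventions

With z-scores for all three indices under one equation set
(`classify_patterns()`), each record gets exactly one label:

* **obstruction**: z(FEV~1~/FVC) < −1.645 and z(FVC) ≥ −1.645;
* **restrictive**: z(FEV~1~/FVC) ≥ −1.645 and z(FVC) < −1.645;
* **mixed**: both below;
* **normal**: neither below.

"Below the LLN" is strict: a z of exactly −1.645 is normal. Note that some
published definitions print obstruction as "FEV~1~/FVC ≥ LLN and FVC ≥
LLN", which describes a normal study; the package implements the standard
convention (ratio below its LLN) and treats that printed form as a typo.
Mixed records are tracked separately; obstruction tallies can optionally
include them (`pattern_positive(..., include_mixed = TRUE)`) because
whether published obstruction counts include mixed patterns is usually not
stated.

## Concordance metrics

For a pattern and a pair of classification runs, the benchmark
(race-specific) call is treated as truth. Cohen's
$\kappa = (p_o - p_e)/(1 - p_e)$ is computed from the observed and
chance agreement; discordance is $1 - \kappa$, binned as [0, 0.1)
negligible, [0.1, 0.2) very low, [0.2, 0.4) low, [0.4, 0.6) moderate,
[0.6, 0.8) high, ≥ 0.8 very high. The published bin scheme leaves small
gaps (e.g. 0.2–0.21); they are closed here as contiguous half-open
intervals. Bin inputs are snapped to 10 decimals first so floating-point
noise (1 − 0.8 = 0.1999…) cannot cross a bin edge. The κ confidence
interval uses the large-sample standard error
$\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}$ by default (published tables bracket κ
without naming a method); a nonparametric bootstrap is available by
argument.

The metric suite computes TPR, TNR, PPV, NPV, their complements FNR, FPR,
FDR = FP/(FP+TP), FOR = FN/(FN+TN), the Matthews correlation coefficient,
F1, and — when continuous scores are supplied — a rank-statistic
(Mann–Whitney) AUC. The default AUC score in the pipeline is the
alternative system's z-score for the pattern-defining index (the ratio for
obstruction, FVC for restriction), negated so larger scores mean "more
abnormal"; published AUCs of this kind rarely state their underlying score,
so this is configurable. MCC categories are >0.80 robust, 0.60–0.80
moderately strong, 0.30–0.50 fair, <0.30 poor; the unassigned 0.50–0.60
band maps to "fair–moderate". One legend conflict is worth noting: some
published tables label NPV as "Specificity"; the package implements the
standard definitions. A metric with a zero denominator is reported as `NA`
together with its identity partner. Report percentages are rounded half
away from zero to whole percent, matching common table formatting;
`round_half_away()` pins the tie-break so reports are platform-stable.

## Development of best-fit equations

The development subset (`select_normal_subset()`) keeps records with BMI in
[18.5, 34.9] kg/m², height in [142, 206] cm, weight in [42, 140] kg, and
all three indices inside [−1.645, +1.645] (inclusive at both limits) under
a race-neutral equation set. Covariates are screened by standardized LASSO
(`lasso_select()`, glmnet with 10-fold internal CV); the default penalty is
the CV-error minimizer rather than the one-SE rule because LASSO is used
here purely as a screening step ahead of an OLS refit — the liberal rule
costs little when a BIC comparison follows, and the one-SE rule is
available by argument. Whether published analyses of this design
standardized covariates is typically unstated; standardization is the
glmnet default and is used here.

Final coefficients come from the OLS refit (`fit_reference_model()`).
Records with externally (leave-one-out) studentized residuals ≥ 3.00 in
absolute value are trimmed and the model refit, iterated to a fixpoint with
at most 5 rounds; the external variant is chosen because the internal one
understates gross outliers (published rules rarely say which variant they
used). The BIC uses the Gaussian form $n\ln(\mathrm{RSS}/n) + k\ln n$;
its additive constant is irrelevant because only between-model differences
are interpreted, and the tests verify agreement of ΔBIC with `stats::BIC`
on the underlying `lm` objects.

Multicollinearity is screened by VIF = 1/(1−R²) per design column with a
nonparametric bootstrap 95% CI (1000 resamples by default; the cited
analytic CI construction is not reproduced in the literature at hand). A
column whose CI upper bound exceeds 10 is flagged for removal unless the
collinearity lies within one variable's polynomial family (age/age²/age³
or height/height²) — detected by recomputing the VIF with the family
mates set aside — in which case it is tolerated.

`race_necessity_test()` fits twin models with and without race on
identical records (trimming, when on, is driven by the with-race model) and
reports ΔBIC = BIC(without) − BIC(with) on Raftery's evidence scale: 0–2
weak, 2–6 positive, 6–10 strong, >10 very strong. Sex enters pooled fits
as an indicator by default; per-sex fits are a matter of subsetting the
input tibble.

## Validation

`repeated_cv()` re-partitions the data into k = 10 near-equal random folds
per repeat, fits OLS on 9 folds, scores RMSE and actual-vs-predicted
Pearson correlation on the held-out fold, and averages fold-level values
per repeat; 1000 repeats by default at top level. The permutation test of
the race term permutes the race label vector across records, keeping every
other covariate attached to its record, so exactly the race contribution is
broken; permuting fold assignments instead was rejected because it tests
nothing about race. The statistic is the CV-RMSE of the race-neutral model
minus that of the race-specific model, with shared fold partitions for the
two models, and two-sided p = (1 + #{|null| ≥ |obs|})/(n~perm~ + 1).
Inside resampling loops the CV repeats are reduced (default 20) for
tractability. The bootstrap test resamples records with replacement and
reports the percentile CI and a two-sided p from the bootstrap
distribution's position relative to zero (whether published bootstrap
p-values of this design are percentile- or SE-based is unstated; percentile
is used). All randomness in a run descends from one seed argument.

## The synthetic cohort generator

`generate_cohort()` draws demographics from range-truncated normals
(rejection sampling, cap 10^5 draws per stratum) using six race × sex
strata whose counts, means, SDs and ranges mirror the normal-spirometry
development population of a large single-center adult clinical dataset
(e.g. White males: height 178 (8) [149–206] cm). The latent truth model
sets

* FVC mean linear in {age, height², male}: −2.41 − 0.020·age +
  0.00025·height² + 0.10·male, residual SD σ = 0.40 L — coefficients chosen
  so stratum-mean FVC matches the emulated population (≈4.4 L White males,
  ≈3.1 L White females); σ = 0.40 L is typical of adult clinical FVC about
  a reference surface;
* FEV~1~/FVC ratio drawn from a truncated normal, mean 0.82 declining
  0.002/year after age 40 (a modeling choice mimicking the observed
  age-related ratio spread, not a published value), SD 0.05, support
  (0.18, 0.95);
* FEV~1~ = ratio × FVC, then per-race offsets are subtracted from both
  indices: Black FVC +0.40 → +0.70 L and FEV~1~ +0.27 → +0.48 L linearly
  over heights 140 → 185 cm; Hispanic FEV~1~ a constant +0.56 L and FVC
  +0.25 L at 140 cm shrinking to zero at 175 cm (all favoring Whites);
* FEV~1~ finally capped at 0.95 × FVC so fev1 < fvc holds for every emitted
  record;
* BMI is derived from height and weight, never drawn, so the three stay
  consistent.

`inject_disease()` designates records as obstructed (FEV~1~ multiplied by a
U(0.5, 0.9) draw, dropping the ratio) or restricted (FVC and FEV~1~
proportionally shrunk, preserving the ratio) at configurable prevalences
(17%/17% by default); shrink factors deliberately straddle the LLN so the
discordance machinery sees boundary cases, and true labels are returned for
classifier oracles.

`derive_equation_set()` produces calibrated synthetic coefficient tables by
projecting the truth mean functions onto the polynomial vocabulary on a
deterministic demographic grid (per race for a race-specific set, pooled
with stratum weights for a race-neutral one), widening the LLN by the
projection error so the tables stay honest about their own approximation.

Two things the generator deliberately does not emulate. First, the joint
disease/demographic dependence of a real clinical population — disease is
injected independently of covariates — so passing tests demonstrate the
machinery's correctness and calibration, not clinical performance on real
data. Second, the printed per-index race offsets for Hispanics (FEV~1~
+0.56 L with an FVC offset near zero) mathematically imply a lower Hispanic
FEV~1~/FVC ratio at equal covariates, whereas the raw demographic tables of
the emulated population show a higher Hispanic ratio; the generator follows
the per-index offsets, and the derived equation tables are calibrated to
the offset-consistent ratio so classification remains coherent. Users who
want ratio-faithful Hispanic cohorts should scale the FEV~1~ offset down.

One further printed-value discrepancy is handled explicitly: the emulated
population's female Hispanic age minimum is printed as 15 despite an ≥18
inclusion rule; the generator enforces ≥18.

## Degenerate inputs and numerical choices

* κ is undefined when both raters are constant (chance agreement 1); this
  is a typed error, never a propagated NaN.
* Perfect collinearity yields an infinite VIF, reported as such and
  flagged; rank-deficient OLS designs error naming the collinear columns.
* CV folds with fewer than 2 records trigger a repartition with a warning.
* Permutation/bootstrap resample counts below 19 are rejected (p
  resolution coarser than 0.05 is meaningless at that level).
* The MCC denominator is computed in double precision (the four-marginal
  product overflows 32-bit integers near n ≈ 1200).
* Whole-number report figures round half away from zero.

## Problem sizes used by the test suite

The packaged checks exercise the machinery at sizes chosen to be decisive
yet quick: κ/MCC identities on 10^4 random tables and exhaustive 2×2
enumeration to n = 12; LMS round-trips on a ~2400-point parameter grid;
race-necessity recovery on 100 cohorts of n = 3771 (offset 0.4 L, σ =
0.4 L) plus 200 null cohorts; permutation calibration at n = 400 with 199
permutations × 200 simulations at k = 5 and 2 CV repeats; and CV
consistency at n = 3000 with 100 repeats. These sizes are the package's own
choices for decisive Monte-Carlo checks; the user-facing defaults (1000 CV
repeats, 1000 bootstrap resamples) remain full-size.

## Known limitations

* The package ships no published coefficient values; conclusions about any
  real equation family require the user to supply its tables.
* The pseudo z-score for polynomial tables is an interoperability
  convention; its tail behaviour differs from a true LMS z away from the
  LLN.
* The asymptotic κ CI is known to be anticonservative for small n; use the
  bootstrap CI below a few hundred pairs.
* The race-necessity ΔBIC compares two pre-specified covariate sets; it is
  not a search over model space, and LASSO screening ahead of it uses the
  liberal min-CV rule by design.
* Population projections are plain arithmetic with no uncertainty
  intervals.
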