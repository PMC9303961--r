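---
title: "Methods: restricted imputation, standardized rates and joinpoint trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restricted imputation, standardized rates and joinpoint trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Population-based cancer registries record histological type and stage at
diagnosis incompletely: early diagnosis periods carry nonspecific
morphology codes (8010 "carcinoma NOS", 8046 "non-small-cell carcinoma")
and unknown or unreported SEER summary stage. Dropping those cases
(complete-case analysis) biases long-term incidence trends, because
missingness is concentrated in particular periods, ages and registries.
`registrytrends` implements the full inferential chain for
histology- and stage-specific incidence trends under a
missing-at-random (MAR) assumption:

1. recode morphology codes and stage strings into analysis categories,
   treating 8010/8046 and unknown/missing stage as absent values;
2. complete the registry `m` times by restricted multiple imputation by
   chained equations (MICE);
3. compute direct age-standardized incidence rates (ASIR) per year and
   stratum, pool them across imputations by Rubin's rules, and attach
   Fay–Feuer gamma confidence intervals with Tiwari's modification;
4. estimate trends by joinpoint segmented log-linear regression with
   Monte Carlo permutation model selection, reported as annual percent
   change (APC) per segment and average annual percent change (AAPC);
5. compare female-to-male incidence rate ratios (FM-IRR) year by year;
6. validate the imputation by stratified Kaplan–Meier/log-rank
   comparison of imputed versus complete cases, and test covariate
   associations of the missingness indicators.

Because real registry extracts of this kind are not redistributable, the
package ships a synthetic-registry generator whose outputs have the same
statistical structure, so every stage of the pipeline is testable
end to end.

## The synthetic registry generator

`default_scenario()` encodes the reference conditions: 3 prefectures ×
diagnosis years 1993–2015 × 2 sexes × 18 five-year age bands (0–4 …
85+). Published registry series of this kind rarely state their age-band
scheme; 18 bands ending in 85+ is standard Japanese vital-statistics
practice and is a configurable default. Per-stratum person-years default
to 21,500, which yields roughly 62,000 cases — the size of the
motivating three-registry lung-cancer series.

Case counts are Poisson per (prefecture, year, sex, age band, histology,
stage) cell. The mean combines: a steep age gradient in baseline
incidence (female rates 40% of male), a per-sex histology mix dominated
by adenocarcinoma among women, a stage composition that drifts from
regional toward localized and distant disease over calendar time (the
"stage shift", +0.045/year on the localized logit), and per-series
piecewise log-linear trends (declining small-cell and squamous-cell
disease among men, rising adenocarcinoma with a late-series slowdown in
both sexes). `inject_joinpoint_trend()` overrides any series with an
exact two-slope trend, which is what trend-recovery tests run against.
The Poisson cell model was chosen because it matches the variance model
used downstream for standardized rates.

Missingness is generated by two logistic MAR models on sex, age 80+,
prefecture, calendar year, treatment, observation time and
death-certificate-only (DCO) status. Intercepts are calibrated so that
overall about 11% of cases carry a nonspecific morphology code and about
23.6% an unknown/missing stage, with stage missingness falling from
roughly a third early in the series to about one seventh at the end —
the pattern long-running registries show. A masked histology becomes
code 8046 with probability 0.12 (8010 otherwise), never 8046 for true
small-cell disease since that code excludes it, and never any
nonspecific code for cases whose true group is "other specified and
unspecified": both candidate sets exclude that group, so a masked
record's truth must lie inside its candidate set. Missingness is
therefore MAR *within the five specific groups*. Masked stage is
labelled "Unknown" with probability 0.56 and left blank otherwise; the
two labels are kept for tabulation and pooled for imputation.

Survival is exponential by stage × histology (localized adenocarcinoma
0.06/year up to distant small-cell 1.10/year), administratively censored
at 2017. DCO cases get zero observation time. A separate truth table
retains the pre-masking values so downstream modules cannot peek.

What the generator does **not** emulate: real ICD-O code frequency
distributions beyond the six-group mix, demographic population change,
non-proportional or non-exponential survival, registration delay, or
code-standard changes over time. Passing tests therefore demonstrate
correctness of the statistical machinery under a faithful MAR structure,
not robustness to every real-data pathology.

## Restricted chained-equation imputation

Both conditional models are baseline-category multinomial logistic
regressions (fitted with `nnet::multinom`) of the target on: prefecture,
diagnosis year (linear by default, period-categorical optional), age
(linear plus an 80+ indicator, because missingness concentrates in the
oldest patients), sex, screening status, the four treatments,
observation time, vital status, the observation-time × vital-status
interaction, and the registry quality indices (DCN%, DCO%, MV%, Gini),
plus the other imputation target. The survival terms matter: with
exponential survival the true conditional log-odds of stage given
follow-up are linear in time and status, so including them lets the
model track the survival signal of the missing value — which is what
makes the survival-based validation meaningful.

Each imputation initializes absent values by restricted draws from the
observed marginal frequencies, then runs 5 sweeps alternating stage
(given covariates + current histology) and histology (given covariates +
current stage). Five sweeps is the standard chained-equations default;
with only two imputed variables and fully observed covariates the chain
stabilizes within two or three sweeps, and doubling the sweep count
changes pooled marginals by far less than their Monte Carlo error.

The restriction — the method's key amendment — is applied at every draw:
predicted probabilities outside the record's candidate set are zeroed
and the remainder renormalized (`restricted_draw()`). Renormalization
was chosen over refitting separate per-candidate-set models because it
uses all observed records for estimation, enforces the constraint
exactly, and has a clean probabilistic justification: masking within the
specific groups is covariate-only, so observed-data category odds among
the candidates are unbiased for the population odds. A flag for the
refit alternative is deliberately not offered; the degenerate case where
every candidate has zero predicted mass falls back to a uniform draw
over the candidates and is counted.

Draws come from the fitted predictive distribution without posterior
perturbation of the coefficients. This is a simplification relative to
proper multiple imputation: between-imputation variance reflects draw
noise but not parameter uncertainty, so pooled total variances are
slightly anti-conservative at small n. At registry scale (tens of
thousands of observed cases per model) parameter uncertainty is
negligible next to draw noise. This is the package's main known
limitation.

Records with zero observation time (DCO-like) are imputed like any
other; excluding them would bias the marginals.

Computationally, refits within a chain are warm-started from the
previous sweep's coefficients with a slightly looser stopping tolerance
(`reltol = 1e-6`; measured coefficient effect ~3e-6), making an
m = 20 run on ~63,000 cases take about two minutes on one CPU.

## Pooling and standardized rates

`rubin_pool()` implements Rubin's rules exactly: pooled point = mean of
the m estimates, total variance `T = W + (1 + 1/m) B`, degrees of
freedom `(m−1)(1 + W/((1+1/m)B))²`, with `B = 0` flagged as degenerate
(infinite df). `asir()` computes `1e5 · Σ w_a d_a/n_a` with Poisson
variance `1e10 · Σ w_a² d_a/n_a²`. The bundled standard population is a
clearly-labelled synthetic stand-in with a 1985-Japan-like age
structure; all computations are weight-agnostic and tests use synthetic
standards, so the official table can be dropped in without touching
code.

Confidence intervals use the gamma method: lower bound the α/2 gamma
quantile with shape `rate²/var`; upper bound from the
continuity-adjusted form. The adjustment term is the *mean* over bands
of `1e5·w_a/n_a` (Tiwari's modification, the default) rather than the
maximum (original Fay–Feuer); both are available. For pooled series the
gamma interval is applied with the Rubin total variance in place of the
single-sample variance — the only composition that uses both the pooling
rule and the gamma interval. Empirical coverage at a true standardized
rate of 50/100,000 over 18 bands is about 95.2% (10,000 replicates).

Zero-case strata contribute zero rate and variance and get a lower bound
of exactly 0. FM-IRR intervals are computed after pooling, on the log
scale by the delta method: `exp(log IRR ± z·sqrt(T_f/R_f² + T_m/R_m²))`;
the alternative (per-imputation ratios pooled afterwards) is noted but
not used, since the pooled-variance route keeps the IRR consistent with
the published per-sex intervals.

## Joinpoint trends

`fit_segmented()` does weighted least squares of `log(rate)` on the
continuous piecewise-linear basis, weights `1/SE(log rate)²` with
`SE(log rate) = SE(rate)/rate` (for pooled series, the Rubin total SE —
the weighting the reference implementation of joinpoint regression uses
for rates with standard errors). The 1-year grid search is exhaustive
over all placements with at least three observations strictly between a
joinpoint and either end and between consecutive joinpoints; ties break
to the earliest placement in lexicographic order. Years with zero rate
are offset by half the smallest positive rate and flagged, since sparse
synthetic strata can hit zero.

Model selection (`permutation_select()`) follows the sequential
permutation scheme: test `k = k0` against `k = k_max` at
Bonferroni-split level `α/(k_max − k0)`, rejecting upward until a null
survives. The statistic is the F-ratio of weighted SSEs of the two
best-fitting models; its null distribution comes from permuting the
weight-standardized residuals of the null fit and re-running both grid
searches on every permuted series, `p = (1 + #{F* ≥ F})/(1 + n_perm)`.
The default maximum is 3 joinpoints for a 23-point series (the motivating
analyses select at most 1); the pipeline default uses `k_max = 2` and
999 permutations, with 4500 available when runtime is no concern. The
permutation engine precomputes an orthonormal basis per admissible
placement, so all permuted responses are scored with one matrix product;
999 permutations on a 23-point series take well under a second.

APC per segment is `100(e^b − 1)` with a t-interval on the residual df.
AAPC over a period is the segment-length-weighted average slope,
back-transformed, with a normal-quantile interval from the WLS
covariance at *fixed* joinpoint locations — location uncertainty is not
propagated, matching standard practice; a single-segment fit reproduces
its APC to machine precision. Normal rather than t quantiles are used
because the composite spans segments with differing df.

## Survival-based validation

`validate_imputation()` compares, within strata of diagnosis period ×
sex × stage × histology, the survival of cases observed in the stratum
against cases imputed into it (log-rank). The default assignment is
*per draw*: the test runs once per imputation with each case in the
stratum its own drawn labels indicate, and rejection indicators are
averaged. This choice is deliberate: if the imputation model equals the
true conditional distribution, a case drawn into stratum s has exactly
the survival law of observed s-cases (Bayes' rule cancels the posterior
against the likelihood), so the test is calibrated — about 5% of strata
reject at the 5% level. Majority-vote assignment (available as
`method = "vote"`) is stabler for labelling individual strata but
selects a deterministic region of survival space, making the imputed arm
a truncated mixture; it over-rejects whenever survival depends strongly
on the imputed variable and should not be used for calibration claims.

Calibration also depends on what the masking may depend on. Masking on
age, period, treatment or observation time is *not* survival-independent
here even though it is MAR: DCO status (a point mass at zero follow-up)
and administrative censoring vary with age and period, so those masking
channels genuinely shift within-stratum survival mixtures and the
log-rank comparison picks that up at scale. The calibration test
therefore masks on sex and prefecture only (measured rejection 5–6% for
most seeds at full size, with occasional seeds near 9% because the
per-stratum tests are correlated across imputations and a handful of
large strata dominate), while a deliberately MNAR scenario — masking loaded on the
true stage being distant — drives rejection above 40%, demonstrating the
diagnostic's power. Real-data users should read a large rejection
fraction as "masking carries survival information the model does not",
not necessarily as a broken imputation model.

`missingness_diagnostics()` runs Pearson chi-square tests (no continuity
correction) for categorical covariates and Kruskal–Wallis tests for
continuous ones against each missingness indicator, with a Fisher exact
fallback when an expected cell drops below 1, and reports
Benjamini–Hochberg-adjusted p-values alongside the raw ones.

## Numerical and testing choices

- All randomness flows from one integer seed through fixed named
  substreams (generation, imputation, trends, validation), so changing
  trend settings never perturbs imputation draws; identical
  configuration and seed give byte-identical output files, each of which
  carries its seed in a header comment.
- Display tables round to one decimal ("x.x (lo to hi)"); computation is
  always on full precision, and full-precision CSVs are written
  alongside.
- Test problem sizes: the restriction/recovery checks run one full-size
  default-scenario imputation (≈63,000 cases, m = 20, 5 sweeps); the
  replicated bias check uses 20 replicates at ≈12,000 cases with m = 4;
  joinpoint recovery uses 20 replicates (break) and 50 (flat) at 999
  permutations; gamma-interval coverage uses 10,000 Poisson replicates;
  the validation calibration runs one full-size null scenario with
  m = 5. These are the package's own choices of simulation size, scaled
  to keep the full suite fast while leaving Monte Carlo error well below
  the tested tolerances.

## Known limitations

- Predictive (non-Bayesian) imputation draws understate between-imputation
  variance slightly (see above).
- AAPC intervals ignore joinpoint-location uncertainty.
- The generator's survival is exponential and conditionally independent
  of covariates given stage and histology; real registry survival is
  neither.
- The bundled morphology map covers only a minimal code set at six-group
  resolution; extend the CSV for real data.
- The reference year treatment in imputation models is linear; switch to
  period categories when trends in missingness are strongly non-linear.
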