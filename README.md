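# registrytrends

Histology- and stage-specific cancer-incidence trend analysis for
population-based registry data with partially missing histology and
stage, built around restricted multiple imputation.

## The problem

Long-term registry series carry nonspecific ICD-O morphology codes
(8010 "carcinoma NOS", 8046 "non-small-cell carcinoma") and unknown or
unreported SEER summary stage, concentrated in early diagnosis periods
and older patients. Complete-case trend analysis is therefore biased.
The nonspecific codes are informative: an 8010 case must be one of the
five specific histology groups, and an 8046 case one of the four
non-small-cell groups. `registrytrends` exploits that by *restricted*
multiple imputation by chained equations — multinomial conditional
models whose predicted probabilities are zeroed outside each record's
candidate set and renormalized before every draw — and then carries the
m completed registries through the full inferential chain:

- **ASIR**: direct age standardization, `ASIR = 10^5 Σ_a w_a d_a / n_a`
  with Poisson variance `10^10 Σ_a w_a² d_a / n_a²`;
- **Rubin's rules**: pooled point = mean of the m estimates, total
  variance `T = W + (1 + 1/m) B`;
- **Gamma confidence intervals** (Fay–Feuer, with Tiwari's mean-
  adjustment modification) computed with the pooled total variance;
- **Joinpoint regression**: continuous piecewise log-linear fits on a
  1-year grid, Monte Carlo permutation selection of the number of
  joinpoints, per-segment APC = `100(e^b − 1)` and segment-length-
  weighted AAPC;
- **FM-IRR**: female-to-male incidence-rate-ratio series with log-scale
  delta-method intervals;
- **Validation**: stratified Kaplan–Meier/log-rank comparison of imputed
  versus observed cases, plus chi-square/Kruskal–Wallis missingness
  diagnostics.

Because registry extracts of this kind are not redistributable, the
package includes a synthetic-registry generator
(`default_scenario()`, `generate_registry()`) that reproduces the
statistical structure of a three-prefecture, 1993–2015, ~62,000-case
lung-cancer series — gender-dependent histology mix, stage-shift
dynamics, calibrated MAR missingness (~11% nonspecific histology,
~23.6% unknown/missing stage), stage/histology-dependent exponential
survival — together with a held-back truth table so recovery can be
measured. See the methods vignette
(`vignettes/registrytrends-methods.Rmd`) for the model details and
design decisions.

## Worked example

```r
library(registrytrends)

# a scaled-down registry: ~12,000 cases, 1993-2015, MAR-masked
scenario <- default_scenario(seed = 2024, person_years = 4000)
reg <- generate_registry(scenario)
records <- recode_stage(recode_histology(reg$records))

# restricted multiple imputation (m = 5 for the example)
stack <- multiple_impute(records, imputation_spec(m = 5, seed = 2024))

# Rubin-pooled age-standardized rates, female adenocarcinoma
std <- scenario_standard(scenario)
series <- pooled_rate_series(stack, reg$population, std,
                             sex = "female", histology = "ADC")
head(series[series$source == "imputed",
            c("year", "rate", "variance", "ci_low", "ci_high")], 3)
#>    year  rate variance ci_low ci_high
#> 1  1993  20.3     5.83   15.8    25.8
#> 2  1994  16.2     4.38   12.3    21.1
#> 3  1995  15.3     3.75   11.7    19.9

# joinpoint trend with permutation model selection
tr <- trend_summary(series, "imputed", k_max = 2, n_perm = 999, seed = 2024)
tr$aapc_fmt
#> [1] "2.5 (1.9 to 3.1)"
tr$apc_fmt
#> [1] "1993-2004: 1.5 (0.2 to 2.8); 2004-2010: 7.5 (5.3 to 9.7); 2010-2015: -1.2 (-3.9 to 1.7)"
```

The registry here masks 11.2% of histologies and 24.2% of stages. The
pooled female-ADC rate rises from about 20 to about 30 per 100,000
person-years across the series; the permutation test selects a
multi-segment trend whose whole-period AAPC of 2.5%/year (95% CI 1.9 to
3.1) matches the generating trend, whose exact full-period average is
2.5%/year. `run_pipeline()` chains all of the
above (generation → recode → imputation → rates → trends → IRR →
validation) and writes tidy CSVs plus a manifest whose hashes are
reproducible from configuration and seed alone.

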