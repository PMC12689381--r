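# upfburden

Estimating the population burden of clinical mental distress associated with
ultra-processed food (UPF) consumption frequency from cross-sectional survey
data.

Large internet surveys of mental wellbeing collect a composite 47-item Likert
assessment (scored onto a −100..+200 scale, with a strictly negative score
defining *clinical mental distress*) alongside a 5-level UPF consumption
frequency question and a broad set of life-context factors (exercise,
traumas/adversities, income, sleep, substance use, ...). `upfburden` turns the
analysis of such data into a tested, reusable pipeline for epidemiologists
and quantitative mental-health researchers:

- **Scoring & screening** — composite wellbeing scoring with a clinical
  threshold; auditable quality-control exclusions (completion < 7 min,
  flat-response SD < 0.2, comprehension failures, countries under 1,000
  clean records).
- **Weighting** — two-step post-stratification: age–sex cells to national
  demographics within country, then internet-enabled population between
  countries, with sparse-cell pooling.
- **Dose–response statistics** — ordinal exposure coding (Rarely/Never = 1
  … Several times a day = 5), OLS trend, Welch t-contrasts, and
  high/low-confounder stratified comparisons.
- **Distress classifier** — a gradient-boosted tree model (plus logistic
  regression, naive Bayes and random forest behind the same interface) over
  108 one-hot life-context features, with stratified cross-validation,
  repeated splits, correlated-feature and exposure-exclusion sensitivity
  analyses, calibration curves, and exact TreeSHAP attributions oriented so
  positive values push toward positive wellbeing.
- **Burden estimators** — the data-based linked percentage / burden ratio,
  and the simulation-based (g-computation) estimate obtained by forcing the
  exposure to Rarely/Never through the fitted model on held-out test draws.

At the core are two quantities. The **linked percentage** is the share of
the sample whose distress is attributable to the exposure,

  linked = P(distress) − P(distress | exposure at reference),

estimated either from observed prevalences ("data") or by model-based
standardization ("simulation": predict, set the exposure one-hot block to
Rarely/Never, re-predict, subtract). The **burden** divides the linked
percentage by the baseline distressed percentage,

  burden % = linked / baseline × 100,

an attributable-fraction-among-distressed analogue. Because the motivating
survey data are access-restricted, the package includes a synthetic-cohort
generator with a Gaussian-additive latent wellbeing model whose true
attributable fraction is available in closed form — every estimator is
validated by parameter recovery against that oracle.

## Worked example

Generate a study-like cohort (known ground truth), filter, score, and
estimate the burden both ways:

```r
library(upfburden)

cfg    <- paper_like_config(n_respondents = 10000, seed = 7)
gen    <- generate_cohort(cfg)
dirty  <- inject_qc_failures(gen$cohort, 0.03, 0.03, 0.01, seed = 8)
qc     <- apply_record_exclusions(dirty)
qc$log
#> Exclusion log: 10000 in, 9300 kept, 700 excluded
#>    SPEEDER : 300
#>    FLATLINE : 300
#>    NOT_UNDERSTOOD : 100

cohort <- score_cohort(apply_country_exclusions(qc$kept)$kept)
round(100 * tapply(cohort$distressed,
                   encode_upf_ordinal(cohort$upf_freq), mean), 1)
#>    1    2    3    4    5
#> 20.7 26.7 31.8 44.9 53.1

fit_linear_trend(cohort$mhq_score, encode_upf_ordinal(cohort$upf_freq))
#>   slope intercept   p_value     n
#> 1 -7.28      34.6 7.47e-134  9300
```

Distress prevalence climbs from 20.7% among Rarely/Never consumers to 53.1%
among several-times-a-day consumers, and the composite score drops about 7.3
points per exposure level (p ≪ 0.001) — the dose–response pattern the
pipeline is built to quantify. Now the two burden estimates:

```r
data_burden(cohort)[, c("linked_pct", "baseline_pct", "burden_pct")]
#>   linked_pct baseline_pct burden_pct
#> 1       7.38         28.1       26.3

sim <- simulation_burden(cohort, n_iterations = 5, seed = 9,
                         estimator = "expectation")
sim[, c("linked_pct", "baseline_pct", "burden_pct")]
#>   linked_pct baseline_pct burden_pct
#> 1       5.69         27.7       20.5

100 * oracle_attributable_fraction(cfg, n_mc = 2e5)
#> 24.3
```

The data-based burden (26.3%) overstates the truth because the generator
builds in confounding (adversity both lowers wellbeing and raises UPF
consumption); the model-based simulation (20.5% at this cohort size) lands
near the generative oracle's 24.3%. For the published-scale worked
arithmetic: `linked_percentage_data(27.7, 19.9)` returns 7.8 and
`burden_ratio(7.8, 27.7)` returns 28.2.

## Scope

The package estimates association-based burden under explicit assumptions
(no indirect exposure effects, cross-sectional data); it makes no causal
identification claims, and it does not attempt to reproduce restricted
real-survey effect sizes — synthetic validation verifies the estimators, not
the epidemiology. See `vignettes/upfburden-methods.Rmd` for the generative
model, calibration, estimator conventions and known limitations.
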