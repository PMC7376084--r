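# fraxpath

Probability-based osteoporosis case finding with age-dependent
intervention thresholds, for epidemiologists and guideline developers who
want to study, audit or stress-test the NOGG-style FRAX pathway rather
than call a closed calculator.

## What it does

Fracture-risk guidance increasingly works from an individual's absolute
10-year fracture probability. `fraxpath` implements the whole pathway as
transparent, testable code:

* **Probability engine** — 10-year probabilities of major osteoporotic
  fracture (MOF) and hip fracture with death as a competing risk,

  P = ∫₀¹⁰ h_f(t) · exp(−∫₀ᵗ [h_f(u) + h_d(u)] du) dt,

  from age-indexed baseline hazards (Gompertz or tabulated) scaled by
  multiplicative clinical-risk-factor effects, a BMI term and an
  age-centred femoral-neck T-score gradient. This is an explicit,
  configurable *surrogate* for proprietary FRAX calculators — same
  interface, documented non-FRAX coefficients.
* **Thresholds** — the age-specific intervention threshold (IT: the
  probability of a woman of average BMI whose only risk factor is a
  prior fragility fracture), lower assessment threshold (LAT: no risk
  factors) and upper assessment threshold (UAT = 1.2 × IT), weighted
  over ethnic sub-populations; published threshold tables load verbatim.
* **Imputation** — the missing-risk-factor simulation procedure: fixed
  covariate-set regressions fitted on a fully observed reference cohort,
  then stochastic assignment by the uniform-draw rule, with prevalence
  and OSTA screening checks.
* **Triage** — prior fracture ⇒ treat; below LAT ⇒ discharge; above
  UAT ⇒ treat without BMD; in between ⇒ BMD test and re-assessment
  against the IT — plus a guidance-style disposition audit.
* **Synthetic cohorts** — seeded generators for a Singapore-like target
  cohort (blanked columns plus a truth file), an elderly fully observed
  reference cohort, and simulated follow-up, so every stage is
  exercisable and checkable end to end.
* **Calibration** — expected vs observed hip fractures in left-closed
  probability bins.

## Worked example

```r
library(fraxpath)
m <- default_hazard_models()$chinese

ten_year_probability(risk_profile(age = 65, bmi = 23,
                                  prior_fracture = 1), m)
#> 10-year probability (without BMD): MOF 14.87%, hip 5.73%

curve <- build_threshold_curve()
curve
#> <threshold_curve> (engine), UAT factor 1.2
#>  age it_pct lat_pct uat_pct
#>   50   4.38    2.46    5.26
#>   65  14.09    8.11   16.91
#>   90  44.71   29.98   53.65   (rows abridged)
```

The age-65 IT (14.09%) is, by construction, the MOF probability of the
prior-fracture woman above up to ethnic weighting; a 65-year-old without
prior fracture is referred for BMD when her probability lies in
[8.11, 16.91] and treated after BMD when the re-assessed probability
reaches 14.09%.

```r
cohort <- generate_target_cohort(cohort_spec(n = 2000), seed = 1)
ref    <- generate_reference_cohort(4000, seed = 2)
imp    <- fit_imputation_model(ref)
cohort <- impute_missing(cohort, imp, seed = 3)
rec    <- triage(cohort, curve, m)
disposition_summary(rec, cohort, m)
#> Disposition of the cohort
#>                 group    n    pct mean_fn_tscore mean_mof_no_bmd ...
#>         entire_cohort 2000 100.00          -1.86            8.77
#>  treat_prior_fracture  139   6.95          -2.28           17.64
#>       treat_above_uat   11   0.55          -1.61           11.69
#>        bmd_then_treat  280  14.00          -2.98           10.15
#>     bmd_then_no_treat 1086  54.30          -1.64            8.23
#>    no_treat_below_lat  484  24.20          -1.60            6.59
#>    otherwise_eligible  291  14.55          -2.92           10.21
#>             bmd_tests 1366  68.30          -1.91            8.62
#>          no_treatment 1570  78.50          -1.63            7.72
```

Reading the audit: 6.95% of the cohort is treated on a prior fracture
alone; a further 14.55% becomes eligible through a high probability
(mean T-score −2.92 — the pathway finds low-BMD women without testing
everyone); 68.3% get a BMD test; the rest are discharged at low risk.
The last three rows deliberately overlap, mirroring guidance-style
reporting.

`run_full_pipeline(run_config(out_dir = "run1", n = 2000, seed = 1))`
executes every stage and writes the cohort, threshold, disposition,
calibration and manifest artifacts; re-running the same configuration
reproduces each CSV byte-identically. A thin CLI over the same functions
lives at `inst/scripts/fraxpath.R`
(`fraxpath.R {simulate, reference, fit-impute, impute, thresholds,
triage, run}`).

## Package layout

| Area | Files |
| --- | --- |
| Engine | `R/hazard_model.R`, `R/risk_profile.R`, `R/probability.R` |
| Thresholds | `R/thresholds.R`, `R/population.R`, `inst/extdata/singapore_thresholds.csv` |
| Imputation | `R/imputation.R`, `R/imputation_io.R`, `R/osta.R` |
| Pathway | `R/pathway.R`, `R/calibration.R` |
| Synthetic data | `R/synthetic.R` |
| Orchestration | `R/pipeline.R`, `R/io.R`, `inst/scripts/fraxpath.R` |

The methods vignette (`vignettes/fraxpath-methods.Rmd`) documents the
model assumptions, default parameters, numerical choices and known
limitations in detail.
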