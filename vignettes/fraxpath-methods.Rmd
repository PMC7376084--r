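---
title: "Probability-based osteoporosis case finding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-based osteoporosis case finding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraxpath)
```

## The problem

Osteoporosis treatment decisions are increasingly guided not by bone
density alone but by an individual's absolute 10-year fracture
probability, combining age, body mass index (BMI), a handful of
dichotomous clinical risk factors (CRFs: prior fragility fracture,
parental hip fracture, current smoking, glucocorticoid use, rheumatoid
arthritis, secondary osteoporosis, alcohol 3+ units/day) and, optionally,
the femoral-neck bone-density T-score. The NOGG-style case-finding
pathway turns such probabilities into decisions through three
age-dependent curves:

* **Intervention threshold (IT)** — the probability of a woman of average
  BMI whose only risk factor is a prior fragility fracture. The
  risk-equivalence rationale: if a prior fracture alone justifies
  treatment, so does an equivalent probability reached any other way.
* **Lower assessment threshold (LAT)** — the probability of a woman with
  no CRFs; below it neither treatment nor a bone-density (BMD) test is
  indicated.
* **Upper assessment threshold (UAT)** — 1.2 × IT; above it treatment is
  recommended without a BMD test, because additional BMD information
  rarely reclassifies someone that far from the IT.

Women between the LAT and UAT are referred for densitometry and
re-assessed, with the T-score included, against the IT.

`fraxpath` implements this pathway end to end — probability engine,
thresholds, triage, missing-risk-factor imputation, synthetic cohorts and
calibration reporting — so that the *method* can be studied, audited and
stress-tested on cohorts with known structure.

## The probability engine

Closed FRAX calculators are proprietary; their coefficients are not
published. The engine here is therefore an explicit, configurable
**surrogate** with the same interface (10-year probabilities of major
osteoporotic fracture, MOF, and of hip fracture, with or without BMD),
never a reproduction of FRAX output. Its structure:

* Baseline annual hazards of first MOF, first hip fracture and death,
  indexed by age on 40–100. Defaults are Gompertz laws
  $h(a) = \alpha e^{\beta a}$; age-indexed tables (linearly interpolated)
  can be supplied instead.
* Multiplicative individual risk. A profile scales the fracture hazards
  by $\exp\{\sum_j x_j \log RR_j + \gamma (\text{BMI} - \text{BMI}_0)
  + \delta(\bar T(a) - T)\}$, where $\bar T(a)$ is the age-specific
  population mean T-score. Because the BMD term is centred, a woman at
  the population-mean T-score has identical risk with and without BMD —
  a deliberate construction, documented rather than claimed faithful to
  any calculator's internals.
* The death hazard is shared across profiles: the CRFs confer no excess
  mortality here. This is the simplest defensible contract and is a
  known deviation from richer calculators.

The 10-year probability treats death as a competing risk:

$$P = \int_0^{10} h_f(t)\, \exp\!\Big(-\int_0^t [h_f(u) + h_d(u)]\,du\Big)\,dt .$$

**Integration.** The integral is evaluated on a fixed grid (default step
0.05 y) by a piecewise-exponential (actuarial) scheme: hazards are
averaged over each step and treated as constant within it, so each step
contributes the exact conditional probability
$S_k\,\frac{h_f}{h_f+h_d}\,(1 - e^{-(h_f+h_d)\Delta})$. For genuinely
constant hazards the scheme telescopes to the closed form
$\frac{\lambda_f}{\lambda_f+\lambda_d}(1-e^{-10(\lambda_f+\lambda_d)})$
to machine precision, which the test suite exploits as an oracle; for
smooth hazards the error is $O(\Delta^2)$, and halving the step moves
10-year probabilities by less than $10^{-6}$ on the probability scale. A
plain trapezoidal rule was rejected because it cannot reproduce the
constant-hazard closed form exactly and so would blur the distinction
between scheme error and implementation error. Everything is
deterministic: identical inputs give bit-identical probabilities.

**Default parameters.** Relative risks are literature-magnitude
placeholders (prior fracture 1.8, glucocorticoids 1.7, parental hip
fracture 1.5, rheumatoid arthritis and alcohol 1.4, secondary
osteoporosis 1.3, smoking 1.25; BMI log-RR −0.03 per unit above 25; BMD
RR 1.6 per SD lower T-score). Gompertz slopes use typical epidemiological
doubling times (hip $\beta$ = 0.105, MOF 0.085, death 0.092); the
intercepts are anchored so that a 62-year-old woman of BMI 23.2 with no
CRFs has 10-year probabilities of cohort-mean order (hip 2.4%, MOF
6.8%). The Malay and Indian baselines are 0.9× and 0.8× the Chinese
level — documented placeholders, replaceable through the YAML interface.
Ages outside 40–90 are clamped to that operational range with a warning;
hazards are held at their age-100 value for the tail of a long follow-up
from age 90.

## Thresholds

`build_threshold_curve()` evaluates the IT and LAT at every 5-year age
40–90 with the per-ethnicity engines (BMI set to the ethnic- and
age-specific reference mean) and averages them with the population
weights of each 5-year bin; the UAT is `uat_factor` (default 1.2) times
the **unrounded** IT. Display files round to 2 decimals but every
comparison in the pathway uses full precision — the published Singapore
table itself is only consistent with pre-rounding multiplication, which
settled the order of operations here. Off-grid ages interpolate linearly
between the 5-year nodes (the choice between interpolation and bin-wise
constants is not dictated by any guideline text; interpolation avoids
step discontinuities in triage); outside 40–90 the curve clamps to its
end node with a warning. A printed threshold table can be loaded
verbatim with `read_threshold_curve()` (the published Singapore curve
ships as `published_threshold_curve()`), so the triage pathway can run
with no engine at all. The default ethnic weights (roughly 0.76 / 0.13 /
0.11, the first share drifting up with age) and BMI references (23.5 /
26.5 / 25.5 kg/m² in mid-life, declining mildly from 65) are documented
placeholders for census values.

## Triage and tie-breaks

Prior fracture ⇒ treat, no probability computed. Otherwise, with $p_0$
the MOF probability without BMD: strictly below the LAT ⇒ discharge;
strictly above the UAT ⇒ treat; both boundary values fall into the BMD
referral band. In the band the probability is recomputed with the
T-score and treatment requires $p_1 \ge$ IT — the one inclusive rule the
pathway description states explicitly ("13% or greater" at age 65), so
the band edges were made conservative (referral) and the IT comparison
inclusive. A referred woman with no T-score gets one imputed on the spot
(flagged in her record) unless `require_bmd = TRUE`. The audit rows
mirror guidance-style reporting and deliberately overlap: "otherwise
eligible" = treated above the UAT ∪ treated after BMD; "BMD tests" =
both BMD branches; "no treatment" = discharged ∪ not treated after BMD.

## Imputation of missing risk factors

Cohorts often lack some FRAX inputs. The package carries them over from
a fully observed reference cohort by single stochastic imputation:

* Logistic regressions with fixed covariate sets — parental hip fracture
  on age and prior fracture; glucocorticoid use on age, sex and BMI;
  rheumatoid arthritis on sex, BMI and prior fracture — and a linear
  model for the T-score on age, BMI, prior fracture and smoking, whose
  root-mean-square residual is retained.
* Assignment follows the uniform-draw rule: per record, draw
  $u \sim U(0,1)$; assign positive iff $u \le \hat p$. Record order is
  draw order. Each factor has its own RNG stream derived from the base
  seed plus a stable hash of the factor name, so adding a factor never
  perturbs another factor's draws and every run is reproducible.
* T-scores are imputed as conditional mean **plus** a Gaussian residual
  by default: deterministic means would shrink the imputed T-score SD
  far below any measured distribution and distort every downstream
  quantity that depends on BMD spread. `noise = FALSE` is available for
  diagnostics.
* `prevalence_report()` compares imputed prevalences with the reference
  age-standardised to the *target's* 5-year age distribution (no
  external standard population is assumed); reference-empty bins drop
  with a warning.
* `osta_validate()` checks imputed T-scores against the OSTA body-size
  index $0.2(\text{weight} - \text{age})$. The default screen-positive
  cutoff is an index below −1, the conventional low-risk boundary;
  guideline texts sometimes print "< 1", so the cutoff is configurable
  rather than silently harmonised. Weight is reconstructed from BMI via
  height ~ Normal(1.56 m, 0.06 m) when only BMI is recorded.

A factor that is constant in the reference falls back to an
intercept-only prevalence model (with a Haldane-corrected intercept)
rather than attempting a separated logistic fit.

## Synthetic cohorts

`generate_target_cohort()` emulates a large Singaporean women's cohort
aged 50+: age 61.7 ± 7.8 (truncated at 50), BMI 23.2 ± 3.6 (truncated at
14), prevalences 6.6% prior fracture (logistic in age, slope 0.05/y),
5.4% smoking, 14.4% secondary osteoporosis, 0.058% high alcohol, 6.6%
parental hip fracture, 0.4% glucocorticoids, 1.9% rheumatoid arthritis,
and T-score −1.89 ± 0.87 (linear in age, BMI, prior fracture, smoking
plus Gaussian residual). Two calibration devices keep the realised
marginals on target: truncated-normal parent parameters are solved so the
*truncated* mean and SD equal the stated values, and each logistic
intercept is solved so the mean predicted probability over the realised
covariates equals the stated prevalence (so counts are exactly binomial
around target). The T-score residual SD is sized from a frozen
explained-variance constant calibrated once against the default
covariate structure. The columns a survey cohort would lack (parental
hip fracture, glucocorticoids, rheumatoid arthritis, T-score) are
blanked; the complete data remain in the `truth` attribute together with
the generating coefficients, making parameter-recovery tests well-posed.

`generate_reference_cohort()` uses the same structural slopes on an
age-stratified 65+ population (thirds at 65–69, 70–74, 75+, the last
spread to 90; both sexes), mimicking the elderly reference cohorts such
imputation models are fitted on in practice.

`simulate_followup()` draws administrative censoring from
Uniform(6.7, 11.5) years — mean 9.1, maximum 11.5 — and latent
first-hip-fracture and death times by inverse transform on each woman's
cumulative hazards; an event is recorded iff fracture precedes both. By
default the fracture hazard is the *without-BMD* one, so simulated
outcomes are self-consistent with the scoring used in calibration
reports; `use_bmd = TRUE` switches to the BMD-adjusted hazard.
`followup_years` is the censoring time, so person-years total
n × mean follow-up by construction.

**What the generator does not emulate.** Risk factors are conditionally
independent given age, sex and BMI (except the modelled dependencies
above); real cohorts have richer covariance, secular trends, and
informative loss to follow-up, none of which is represented. Only hip
fractures are simulated as observed outcomes. Passing tests therefore
demonstrate internal consistency of the method — engine, thresholds,
imputation and triage agreeing with their own generating assumptions —
not fidelity to any real population.

## Calibration reporting

`calibration_table()` bins baseline 10-year hip-fracture probabilities
into left-closed, right-open intervals $[k, k+w)$ — a probability
exactly on an edge belongs to the higher bin — and compares, per bin,
the expected count (sum of individual cumulative incidences truncated at
each woman's follow-up) with the observed count, plus cumulative rows.
When outcomes are simulated from the scoring engine itself, total
observed counts fall within Poisson noise of the expected total; the
test suite asserts this at the full cohort scale.

## Problem sizes and numerical choices

The test suite runs parameter recovery on a 50,000-record reference,
marginal checks and self-calibration on the full 29,323-woman cohort,
and Monte-Carlo engine validation with 10⁶ lifetimes per profile on
0.01-year steps; pipeline determinism is exercised at smaller sizes
(hundreds to thousands) where the properties checked are
size-independent. Integration uses step 0.05 y throughout; uniroot
tolerances are 10⁻¹²; truncated-normal parent parameters are solved to
relative tolerance 10⁻¹⁴. Ties at thresholds are resolved as described
under triage; degenerate inputs (empty cohorts, zero hazards,
zero-prevalence factors, constant reference factors) follow the
documented fallbacks rather than erroring where a well-defined answer
exists.

## Known limitations

* The engine is a surrogate: absolute probabilities, and therefore
  engine-derived thresholds, are not comparable to any proprietary
  calculator's output. Analyses needing the published operating curve
  should load it verbatim.
* Single imputation understates between-imputation variance; no pooling
  is attempted, and missing-not-at-random mechanisms are out of scope.
* The default parameterisation is for women; the engine accepts `sex`
  but ships no male-specific baseline.
* Ethnic weights and BMI references are placeholders pending census
  inputs.
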