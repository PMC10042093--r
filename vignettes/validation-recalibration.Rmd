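---
title: "Validating and recalibrating a non-laboratory cardiovascular risk model across regions"
author: "cvdrecal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and recalibrating a non-laboratory cardiovascular risk model across regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdrecal)
```

## The problem

Non-laboratory cardiovascular risk charts predict an individual's 10-year
risk of a first cardiovascular event from sex, age, smoking status, systolic
blood pressure and body mass index, using separate Cox-type submodels for
coronary disease and stroke. Such a model is developed in one population and
then applied elsewhere; before it can be trusted in a new territory it needs
*external validation* — measuring discrimination (can it rank who has an
event first?) and calibration (do predicted absolute risks match observed
risks?) — and, where calibration fails, *recalibration* to local incidence.

In a large, geographically diverse country, baseline hazards of coronary
disease and stroke can differ several-fold between regions while the
relative effects of the risk factors stay comparatively stable. A single
territory-wide model then underestimates risk in high-incidence regions and
overestimates it in low-incidence ones, even when its risk ordering within
each region is good. cvdrecal implements the full workflow for studying and
repairing this: scoring, region-wise recalibration, censoring-aware
validation metrics, and a synthetic multi-region cohort generator so the
whole design can be exercised and tested without access-restricted cohort
data.

## The risk model

For each sex $s$ and subtype $k \in \{\text{coronary}, \text{stroke}\}$ the
submodel is a linear predictor over centred covariates,

$$lp_{i,k} = \sum_j \beta_{j,k}\,(x_{ij} - c_j),$$

with the 10-year risk obtained on the survival scale from the reference risk
$p_{0,k}$ at the centring point:

$$p_{i,k} = 1 - (1 - p_{0,k})^{\exp(lp_{i,k})}.$$

This is exact under proportional hazards ($1 - p_{0,k}$ is the reference
10-year survival, raised to the relative hazard), strictly increasing in the
linear predictor, and reduces to $p_{0,k}$ at $lp = 0$. Subtype risks are
combined by the complement product

$$p_{i,\text{total}} = 1 - (1 - p_{i,\text{cor}})(1 - p_{i,\text{str}}),$$

i.e. survival free of any cardiovascular event is the product of the
subtype-specific survivals. This was a genuinely open design choice — the
combination rule is rarely stated in chart publications — and the complement
product is the unique rule that is symmetric, reduces to each submodel when
the other risk is zero, and preserves the survival interpretation (on the
cumulative-hazard scale the subtype hazards simply add). A capped sum is
available as `combine_subtype_risks(..., rule = "capped_sum")` for
sensitivity analyses.

Coefficients are data, not code: models are stored in a small JSON schema
(`read_risk_model()` / `write_risk_model()`) holding coefficients, centring
constants and reference risks per sex and subtype, plus a vintage label. The
built-in `default_risk_model()` is an *illustrative* coefficient set for
demonstrations and simulation studies; published chart coefficients should
be supplied as a model file. No test in the package uses the default file's
numbers as an oracle — tests use hand-set coefficients throughout.

## Recalibration

Recalibration adjusts predicted risks to a target stratum without refitting
coefficients. Strata are region × sex × age band; bands default to the
10-year bands 40–49, …, 70–79 (band width is configurable — published
recalibrations have used both 5- and 10-year bands). Each stratum $s$ and
subtype carries two parameters:

* $\bar p_s$ — the expected 10-year risk in the stratum (from local
  incidence, or estimated as the stratum's Kaplan–Meier risk);
* $\bar r_s$ — the mean relative risk $\mathrm{mean}_i\,\exp(lp_i)$ over the
  stratum's reference population.

A participant with weight $w_i = \exp(lp_i)/\bar r_s$ receives

$$p_i' = 1 - (1 - \bar p_s)^{w_i},$$

cumulative-hazard scaling: the stratum's expected cumulative hazard
$-\log(1-\bar p_s)$ is shared out in proportion to each participant's
relative hazard. The transform is monotone in $lp_i$, so the *ordering* of
participants within a stratum — and hence each submodel's discrimination
there — is exactly unchanged; what changes is the level. Across strata,
levels move to match local incidence, which both repairs calibration and,
when strata genuinely differ in baseline hazard, improves discrimination in
the pooled population (recalibrating by region is equivalent to adding
region as a predictor). Note the exact rank-preservation statement applies
per subtype; the combined total risk re-weights the two subtypes, so
total-risk orderings can shift marginally even within a stratum.

Two estimation conventions deserved explicit decisions:

* $\bar r_s$ is the **arithmetic** mean of $\exp(lp)$ (a geometric option is
  available). With the arithmetic mean, self-recalibration is an exact
  fixpoint on the hazard scale: the stratum mean recalibrated cumulative
  hazard equals $-\log(1 - \bar p_s)$ identically. The stratum mean *risk*
  then matches $\bar p_s$ only up to a Jensen gap, which grows with the
  stratum's risk level and internal dispersion (negligible below ~10% risk,
  up to ~2 percentage points in the oldest, highest-risk stroke strata).
* Strata with zero observed events get the continuity-corrected floor
  $\bar p_s = 0.5/n_s$ (with a warning) rather than 0, keeping the power
  transform defined.

`estimate_recalibration_table()` computes both parameters from a cohort;
`read_recalibration_table()` loads externally supplied parameters (e.g. a
territory-level set for the "universal model" study component). Both routes
feed the same `recalibrate()`; the two study components differ only in the
stratum scheme (one super-region versus each region).

## Validation metrics

All metrics are censoring-aware and are computed separately by sex, per
region and overall.

**Harrell's C** (`harrell_c()`): the probability that in a randomly chosen
comparable pair the participant who fails first has the higher predicted
risk. Comparable pairs require one member's observed event strictly before
the other's time (ties on time are comparable only when exactly one member
has an event; two events tied on time are not comparable); risk ties count
1/2. Pair counting delegates to `survival::concordance()`, which implements
exactly these conventions — the test suite verifies exact agreement with an
explicit all-pairs enumeration, with and without censoring and ties. The
default confidence interval uses the analytic variance estimator; a seeded
bootstrap is available.

**Kaplan–Meier 10-year risk** (`km_risk()`): $1-\hat S(t_0)$ via
`survival::survfit()` with the Greenwood variance.

**Decile calibration** (`calibration_table()`, `plot_calibration()`):
equal-size quantile groups of predicted risk (ties broken by stable input
order), mean predicted versus Kaplan–Meier observed risk per group, with
Greenwood error bars and the 45-degree ideal line.

**Predicted/observed ratio** (`po_ratio()`):
$\sum_i p_i / (n \cdot \mathrm{KM}(t_0))$; 1.0 is ideal, below 1 is
underestimation.

**Nam–D'Agostino test** (`nam_dagostino()`):
$\chi^2 = \sum_d (o_d - \bar p_d)^2 / v_d$ with Greenwood variances
$v_d$; groups with zero events are merged into the adjacent lower-risk
group first. The reference distribution defaults to $\chi^2_G$ with $G$ the
number of groups used: in external validation nothing is re-estimated on
the validation sample, so the $G$ group contributions are asymptotically
independent standard-normal squares. We verified this by simulation (500
replicates of a correctly calibrated model at $n = 5000$ under cohort-like
censoring): the $G$ rule holds the nominal 5% type-I error while the
$G{-}1$ convention inherited from internal goodness-of-fit testing is
anti-conservative. `df_rule = "groups_minus_1"` retains the traditional
convention.

**Random-effects pooling** (`pool_c_indices()`): DerSimonian–Laird pooling
of per-region C indices (via `metafor::rma(method = "DL")`), reported as the
"combined (meta)" row alongside the overall-population C. The two summaries
answer different questions: the meta-pooled C averages *within-region*
discrimination (essentially unchanged by recalibration), while the
overall-population C also credits correct *between-region* ordering (which
per-region recalibration improves).

## The synthetic cohort generator

`generate_cohort()` draws a multi-region cohort from an explicit
data-generating truth so that every downstream claim can be tested against
closed forms:

* **Covariates** per region and sex: age uniform on 40–79 (the analysis
  population's range; matching a specific empirical age distribution is not
  attempted), Bernoulli smoking, normal systolic blood pressure and body
  mass index. The default 10-region panel (`default_region_panel()`) spans the
  kind of heterogeneity reported for large East Asian cohorts — female smoking
  prevalence 0.2%–10.2%, male 39%–65%, shifted blood-pressure and adiposity
  distributions — around central values (median SBP ≈ 128–130 mmHg, BMI ≈
  23–24 kg/m²) typical of middle-aged East Asian adults.
* **Events**: for each subtype a latent time with cumulative hazard
  $\lambda_k m_{rk} e^{lp^{true}_{i,k}} t^{\gamma}$ — exponential by default
  ($\gamma = 1$), giving the closed-form 10-year risk
  $1 - \exp(-10\,\lambda_k m_{rk} e^{lp})$ used as the test oracle; Weibull
  via `weibull_shape`. Default baseline rates put the crude subtype rates
  near 0.009 (coronary) and 0.017 (stroke) events per person-year, stroke
  roughly twice coronary, as observed in East Asian cohorts; region
  multipliers $m_{rk}$ in the default panel span roughly 0.4×–2.5×.
* **Censoring**: an administrative horizon of 12 years (so the median
  follow-up is ≈ 11–12 years and the large majority of participants are
  observable at the 10-year mark) plus an independent exponential
  loss-to-follow-up time calibrated so ~1% are lost before the horizon —
  lost participants are censored, never dropped. The observed event is the
  first-occurring subtype; in subtype-specific analyses the other subtype
  does **not** censor (each participant remains at risk for their first
  coronary and first stroke event separately), which is why the cohort
  table carries the censoring time explicitly.
* **Eligibility injection**: a stated fraction of rows receive age < 40
  (15%), prior cardiovascular disease (4.5%) or missing body mass index
  (0.1%), so `apply_eligibility_filters()` is exercised; exclusion counts
  use the fixed precedence age → prior disease → missing BMI.

What the generator deliberately does *not* emulate: the empirical joint
covariate distribution of any real cohort, diagnosis-code adjudication,
competing non-CVD mortality (omitted by default; the observed-risk
estimator is therefore a net risk, and the same open question applies to
Kaplan–Meier observed risks in real validation studies), secular trends in
incidence, and within-region spatial structure. Passing tests therefore
demonstrate the *machinery* — metrics, recalibration algebra, pipeline —
under a known truth, not fidelity of any particular coefficient set to a
real population.

## Numerical and procedural choices

* Decile boundaries use stable original-order tie-breaking, so a constant
  risk vector still yields ten well-defined groups.
* Pairs with no comparable ordering raise an error rather than returning
  0.5; a zero observed case count makes the P/O ratio an error rather than
  infinity.
* All randomness flows from a single integer seed; `run_study()` is
  end-to-end deterministic and re-rendering a report reproduces
  `metrics.csv` byte-for-byte.
* Problem sizes: unit tests use cohorts of a few hundred to 50 000
  participants; the full synthetic replica in `scripts/acceptance.R` uses
  10 regions × 4 000 participants, 500 replicates for the type-I-error
  simulation and n = 100 000 for the Kaplan–Meier closed-form check —
  sizes at which Monte-Carlo error is well inside the tolerances asserted.

## Limitations

* The recalibration functional form (cumulative-hazard scaling) is the
  standard monotone choice but not the only one used in practice;
  alternatives such as re-centred linear predictors with stratum mean
  risk-factor levels are representable in the same table schema but not
  implemented.
* A recalibrated model is, in effect, a new model for each region and
  would itself require external validation before clinical use.
* Confidence intervals for C use the analytic concordance variance; the
  bootstrap option exists but is not the default for speed.
* The generator's uniform age distribution is a simplification; metrics
  that are sensitive to the age mix (absolute risks, stratum sizes) should
  be read as properties of the synthetic design, not forecasts for any
  real population.
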