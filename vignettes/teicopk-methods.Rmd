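---
title: "Population pharmacokinetics and dosing simulation of teicoplanin in sepsis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{teicopk methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teicopk)
```

## The problem

Teicoplanin is a glycopeptide antibiotic used against resistant gram-positive
organisms, MRSA in particular. It is ~90% protein bound, renally cleared, and
has a terminal half-life of roughly 100–170 h, so exposure builds over many
days: without loading doses, patients spend the critical first days of therapy
under-exposed, and septic ICU patients — with altered volumes of distribution
and widely varying renal function — are especially prone to sub-therapeutic
troughs under standard dosing. `teicopk` implements a complete
population-pharmacokinetic (PPK) dosing analysis for this setting: a
two-compartment infusion model with a renal-function covariate, a nonlinear
mixed-effects estimator with covariate selection and validation diagnostics, a
synthetic sparse-sampling cohort generator, and Monte Carlo dosing simulation
scored against trough and AUC/MIC targets.

## The model

Disposition is a two-compartment linear model parameterized by clearance
$CL$ (L/h), central volume $V_1$ (L), intercompartmental clearance $Q$ (L/h)
and peripheral volume $V_2$ (L). Concentrations under constant-rate infusions
have the usual biexponential closed form with hybrid constants
$\alpha > \beta$ ($\alpha\beta = k_{10}k_{21}$,
$\alpha + \beta = k_{10} + k_{12} + k_{21}$); multi-dose profiles are built by
superposition. The analytic solution is the production path — a thousand
replicates across many regimens must evaluate in seconds — and a stiff ODE
integration of the same system serves as an independent oracle in the test
suite (agreement to $10^{-6}$ relative on random parameter sets and
schedules).

Between-subject variability is log-normal per parameter,
$P_i = P_{TV} \cdot e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$, with
independent $\eta$ (no covariance block: none is reported for this
population). The only covariate in the final model is the glomerular
filtration rate acting on clearance as a power law,

$$CL_i = 1.03 \cdot (GFR_i / 71.88)^{0.437} \cdot e^{\eta_{CL,i}},$$

with $V_1 = 20.1$ L, $Q = 3.12$ L/h, $V_2 = 101$ L,
$\omega^2 = (0.29, 0.37, 0.29, 0.10)$ and a proportional residual error
$C_{obs} = C_{pred}(1 + \varepsilon)$, $\varepsilon \sim N(0, 0.174^2)$.
The reference value 71.88 is the covariate-model constant rather than the
rounded cohort median. The reported parameter variabilities in %CV are
interpreted as $100\sqrt{\omega^2}$ (0.29 ↔ 53.9%), which is the convention
that makes the published numbers mutually consistent. This model ships both
as `teicoplanin_sepsis_model()` and as the YAML preset in
`inst/extdata/sepsis_adult_model.yaml`.

```{r}
m <- teicoplanin_sepsis_model()
unclass(typical_params(m, list(GFR = 120)))
```

## Estimation

The marginal likelihood of each subject's sparse concentration vector is
approximated by a Laplace expansion around the conditional mode
$\hat\eta_i$ of the joint density; the proportional-error variance is
evaluated at the conditional prediction, honouring the $\eta$–$\varepsilon$
interaction of conditional estimation methods. The objective (OFV) is
$-2\sum_i \log \hat L_i$. Implementation notes that matter:

* Conditional modes are found by damped Newton iteration with
  finite-difference gradients and Hessians (step $10^{-4}$, gradient-norm
  tolerance $10^{-8}$). Under sparse trough-heavy sampling the per-subject
  joint density can be **multimodal**; each evaluation therefore solves from
  both the incumbent (warm-started) mode and the prior mode $\eta = 0$ and
  keeps the lower one. The test suite pins the approximation against direct
  quadrature of the marginal integral on single-random-effect cases
  (agreement within 0.1 OFV units).
* Population parameters are optimized on the log scale (covariate exponents
  on their natural scale) by quasi-Newton iteration with an explicit
  central-difference gradient (step $10^{-4}$) — wide enough to sit above the
  numerical noise floor of the inner solver — restarted until the OFV
  plateaus. The ten-parameter surface is multimodal for 59-subject
  trough-dominated designs; the simulation-estimation driver
  (`recovery_study()`) therefore fits the covariate model from two starts —
  chained from the base fit and from an independent generic start — and
  keeps the better optimum.
* The search is box-bounded to the plausible region: typical values within
  generous adult ranges, covariate exponents in $[-3, 3]$, IIV variances at
  most 1 (100% CV) and the proportional error SD at most 70%. With only
  4–5 observations against four random effects per subject, the
  *approximate* marginal likelihood possesses a degenerate branch — typical
  value driven toward zero while the variance inflates, letting every
  subject interpolate its own data under a nearly flat prior — that a
  modeler would reject on sight. A fit whose variance lands on its cap is
  flagged (`at_boundary`) and the stepwise and recovery drivers prefer
  interior optima over flagged ones.
* Covariate selection is forward inclusion at $\Delta\mathrm{OFV} > 3.84$
  ($P = 0.05$, $\chi^2_1$) then backward deletion at
  $\Delta\mathrm{OFV} > 10.828$ ($P = 0.001$), testing one effect at a time
  against the current model, with a full audit trail.
* Observations below the assay's lower limit of quantification
  (3.125 mg/L) are flagged and excluded from the likelihood; no censored
  (M3-type) likelihood is attempted. This is the simplest defensible default
  and is configurable at the dataset level.
* Standard errors are not computed; validation relies on the nonparametric
  bootstrap (subjects resampled with replacement, each replicate refitted,
  percentile intervals over successful fits) and on predictive checks.

## The synthetic cohort

No raw concentrations are publicly available, so estimation is validated by
simulation: `generate_dataset()` emulates the study conditions —

* 59 septic adults; GFR stratum probabilities 0.237 / 0.339 / 0.237 /
  0.085 / 0.102 for ≥90, 60–90, 30–60, 15–30 and <15 mL/min/1.73 m²,
  uniform within stratum (range 11–124 overall); weight log-normal with
  median 65 kg truncated to 35–90 kg; age uniform 28–92 y; 62.7% male;
  distractor laboratory covariates drawn independently within the observed
  ranges purely to exercise covariate screening.
* the standard regimen (400 mg q12h × 3 then 400 mg daily) with four troughs
  immediately before the 3rd–6th doses and one extra sample assigned in
  thirds (end of the 5th infusion / 1 h after its start / 1 h before the
  6th dose). "1 h after the 5th dose" is anchored at the infusion start,
  the usual TDM convention.
* proportional residual error per observation, truncated at zero only when
  writing the dataset; independent thinning at rate 46/295 so that a
  59-subject cohort yields ≈249 recorded samples, the study's yield, with
  below-LOQ values flagged.

What the generator does **not** emulate: correlated covariates, informative
dropout, occasion-to-occasion variability, assay drift. Passing recovery
tests on these cohorts therefore demonstrates estimator correctness under
the stated generative model, not robustness to every feature of real ICU
data.

## Dosing simulation and PK/PD scoring

`simulate_regimen()` draws individuals at a fixed GFR (weight fixed at the
typical 65 kg), expands a day-by-day regimen rule (days 1–3, then maintenance
from 72 h; horizon 264 h), and computes per replicate:

* `cmin72`, `cmin240`: pre-dose concentrations at 72 h and 240 h. Troughs
  are superposition values excluding any infusion starting exactly at the
  evaluation time (the analytic solution makes this the natural limit).
* `auc24`: the 24 h-normalized AUC of the **final complete maintenance
  interval** ending at or before the horizon — AUC[240, 264] for q24h
  maintenance, AUC[216, 264]/2 for q48h, AUC[216, 264] × 24/48 for q72h
  (the profile ends at 264 h). The q24h window reproduces the published
  AUC ratios cleanly; for longer intervals the published window is not
  stated and our rule is an approximation of steady-state daily exposure,
  which is why only q24h AUC values are used as quantitative references.
  The linear trapezoidal rule on a 0.1 h grid (within 0.2% of exact
  integration, verified against the closed form) matches the reported
  estimation method; residual (assay) error is not added to simulated
  exposures.

Doses are exact mg/kg × weight (975 mg for 15 mg/kg at 65 kg) rather than
the clinically rounded 1,000 mg; `round_amounts = TRUE` switches to rounded
amounts. Infusions default to 1 h (the upper end of the 30–60 min range);
with a ~100 h half-life the choice is immaterial for troughs and AUC, and
0.5 h is supported throughout.

PK/PD scoring follows the conventional targets for teicoplanin against
MRSA: $AUC_{0\text{–}24}/MIC \ge 610$, probability of target attainment
(PTA) ≥ 90% on the MIC grid {0.25, 0.5, 1, 2, 4} mg/L (inclusive
boundary), trough band 15–30 mg/L (non-complicated) or 20–40 mg/L
(complicated), and the cumulative fraction of response
$CFR = \sum_i PTA(MIC_i)\, p(MIC_i)$ classed optimal (≥90%), moderate
(80–90%) or inadequate. The MRSA MIC histogram is **not** part of the model:
CFR depends on the surveillance snapshot used, so the shipped
`mic_mrsa_synthetic.tsv` is an editable synthetic stand-in concentrated on
0.5–1 mg/L, and every CFR result echoes the distribution it used.

```{r, eval = FALSE}
s <- simulate_regimen(m, gfr = 120, recommend_regimen(120), n = 1000,
                      seed = 1)
summarize_metrics(s)
prof <- pta_profile(s$auc24)
cfr(prof, read_mic_distribution(system.file("extdata",
  "mic_mrsa_synthetic.tsv", package = "teicopk")))
```

## Validation diagnostics

`compute_diagnostics()` returns population predictions (PRED, $\eta = 0$),
individual predictions (IPRED, at $\hat\eta$) and conditional weighted
residuals from a first-order covariance linearization at $\hat\eta$.
`pc_vpc()` implements the prediction-corrected visual predictive check:
observations and simulated replicates are rescaled within time bins by the
ratio of the bin-median population prediction to the observation's own
population prediction, and the observed 2.5/50/97.5th percentiles are
compared with simulation-based confidence bands; bins with fewer than two
observations are merged. `vpc_coverage()` gives the scalar calibration
summary (fraction of observations inside the central 95% simulation band).

## Problem sizes and numerical choices

The package's own test suite runs everything at desk scale, chosen to keep a
full run in minutes on one CPU while leaving Monte Carlo error well inside
the asserted tolerances: dosing simulations use 1,000 replicates per regimen
(matching the published simulation size; median stability across seeds is
about 2–3%), the simulation-estimation recovery study uses 20 cohorts of 59
subjects, the bootstrap demonstration uses a reduced cohort and replicate
count, and predictive-check calibration uses 150–300 simulated replicates.
Quantities frozen into tests were computed from the stated oracles
(quadrature, ODE integration, enumeration) and verified before being
asserted.

Degenerate inputs are handled explicitly: empty dose lists give zero
concentration and AUC, zero variances collapse the population layer to the
typical subject (and the OFV to a weighted least-squares deviance), a
trough evaluated at a dose time excludes that dose, and a dose scheduled
exactly at the simulation horizon is dropped (it cannot affect any metric).

## Known limitations

* The estimator is a Laplace approximation, not NONMEM's FOCE-I; OFV values
  are not comparable across implementations, only OFV *differences* within
  this one are meaningful. Published standard errors are not reproduced.
* Recovery of variance components from 4–5 samples per subject is noisy;
  typical values and the covariate effect are the well-identified targets.
* CFR conclusions are only as current as the MIC snapshot supplied.
* Renal replacement therapy, time-varying renal function, weight-based
  simulation distributions and Bayesian dose individualization are out of
  scope.
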