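# teicopk

Population pharmacokinetics and dosing-regimen optimization of teicoplanin
in critically ill septic adults.

Teicoplanin is a renally cleared glycopeptide antibiotic with ~90% protein
binding and a terminal half-life of roughly 100–170 h. Under standard dosing
(400 mg q12h × 3, then 400 mg daily) septic ICU patients — whose renal
function and volumes of distribution vary widely — often spend the first
days of therapy below the efficacy targets for MRSA. `teicopk` implements
the full model-based dosing analysis for this population:

* **Structural model** — analytic two-compartment intravenous-infusion
  kinetics with multi-dose superposition and exact or trapezoidal AUC
  (`conc_at()`, `pk_auc()`).
* **Population model** — log-normal inter-individual variability, a GFR
  power covariate on clearance and proportional residual error. The final
  adult-sepsis model

  `CL = 1.03 · (GFR / 71.88)^0.437 · e^η` (L/h), `V1 = 20.1` L,
  `Q = 3.12` L/h, `V2 = 101` L, `ω² = (0.29, 0.37, 0.29, 0.10)`,
  proportional error SD 17.4%

  ships as `teicoplanin_sepsis_model()` and as a YAML preset.
* **Estimation** — Laplace-approximation nonlinear mixed-effects fitting
  with the η–ε interaction, forward/backward likelihood-ratio covariate
  selection (ΔOFV 3.84 / 10.828), nonparametric bootstrap, conditional
  weighted residuals and a prediction-corrected visual predictive check
  (`fit_model()`, `covariate_step()`, `bootstrap_fit()`, `pc_vpc()`).
* **Synthetic cohorts** — a generator emulating the study design (59
  subjects, GFR strata, sparse trough-dominated TDM sampling, LOQ
  3.125 mg/L) for simulation-estimation validation (`generate_dataset()`).
* **Dosing simulation** — Monte Carlo evaluation of loading/maintenance
  regimens against trough bands (15–30 / 20–40 mg/L), AUC₀₋₂₄/MIC ≥ 610,
  PTA ≥ 90% and CFR over an MRSA MIC distribution
  (`simulate_regimen()`, `pta()`, `cfr()`, `classify_regimen()`).

## Worked example

Simulate the regimen recommended for a patient with normal renal function
(15 mg/kg q12h × 5 loading doses, then 15 mg/kg daily) and score it:

```r
library(teicopk)

m <- teicoplanin_sepsis_model()
spec <- recommend_regimen(gfr = 120)      # 65 kg default
s <- simulate_regimen(m, gfr = 120, spec, n = 1000, seed = 1)
summarize_metrics(s)
#> # A tibble: 3 × 5
#>   metric  median     lo     hi     n
#>   <chr>    <dbl>  <dbl>  <dbl> <int>
#> 1 cmin72    16.1   4.28   34.4  1000
#> 2 cmin240   20.2   4.38   55.8  1000
#> 3 auc24    720.  255.   1616.   1000
```

The Day-4 trough (median 16.1 mg/L) sits inside the 15–30 mg/L band for
non-complicated MRSA infection, the steady-state trough (20.2 mg/L) holds
there through Day 11, and the daily exposure ratio at MIC = 1 mg/L
(median AUC₀₋₂₄/MIC ≈ 720) clears the 610 efficacy target — but the
spread across simulated patients is wide:

```r
prof <- pta_profile(s$auc24)              # PTA on the MIC grid
round(prof, 3)
#>  0.25   0.5     1     2     4
#> 0.998 0.944 0.614 0.098 0.001
dist <- read_mic_distribution(system.file("extdata",
          "mic_mrsa_synthetic.tsv", package = "teicopk"))
cfr(prof, dist)
#> [1] 0.788  (moderate at best; depends on the MIC snapshot used)
```

At MIC = 1 mg/L only ~61% of simulated patients attain the AUC target even
under the intensified regimen — the central quantitative message of the
analysis: trough-guided dosing looks adequate long before AUC/MIC-guided
dosing does.

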