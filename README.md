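# copdcea

Trial- and model-based cost-effectiveness analysis of a digital
early-warning self-management system for chronic obstructive pulmonary
disease (COPD), compared with usual care from the UK NHS perspective.

COPD patients who exacerbate frequently account for most of the
disease's hospital admissions and costs. A monitoring app that flags
deteriorations early may avert severe (hospitalised) exacerbations.
`copdcea` implements the full economic evaluation of such an
intervention for health economists and HTA analysts:

* **Within-trial cost-utility analysis** (6/12 months): QALYs by the
  area-under-the-curve method on EQ-5D utilities with linear
  interpolation, chained multiple imputation of missing follow-up data,
  covariate-adjusted incremental costs and effects (joint two-equation
  estimation), non-parametric bootstrap ICERs,
  cost-effectiveness acceptability curves (CEAC), and cost per
  hospitalisation averted.
* **5-year Markov cohort model** over the GOLD groups A–D (monthly
  cycles, three post-discharge tunnel months per admission, death on
  admission, 3.5% annual discounting), with four intervention effects:
  improved 12-month starting states, beneficial transitions under an
  annually halving relative risk (0.91 → 0.955 → 0.978 → 0.989),
  exacerbation-rate reductions of 12/6/3/1.5% in the admission-defined
  stages, and 1.278 fewer bed days per admission.
* **Probabilistic sensitivity analysis** (beta/gamma/normal/lognormal
  parameter distributions, per-iteration RNG streams), CEAC, and
  value-of-information analysis: EVPI

  `EVPI(λ) = E[max_d NB_d(θ)] − max_d E[NB_d(θ)]`, `NB = λ·QALY − cost`,

  regression-based EVPPI (GAM smoother), a nested Monte-Carlo EVPPI
  oracle, and population scaling (eligible population 626,129).
* **Synthetic trial generator** with closed-form ground truth for
  recovery testing, and a patient-level **microsimulation oracle** that
  independently validates the cohort engine.

The model's core statistic is the incremental cost-effectiveness ratio
ICER = ΔCost/ΔQALY, judged against the UK willingness-to-pay band of
£20,000–£30,000 per QALY via incremental net monetary benefit
λ·ΔQALY − ΔCost.

## Worked example

```r
library(copdcea)

ps <- load_parameters()          # packaged base-case configuration
#> default filled: usual-care transition matrix back-derived ... (placeholder)

# published costing totals, recomputed from the table
total_intervention_cost(ps$costing, "first")        # 362.57
total_intervention_cost(ps$costing, "subsequent")   # 231.23

# 6-month QALYs from the published arm-level EQ-5D means
qaly_auc(c(0.529, 0.537, 0.587), c(0, 3, 6))        # 0.27375
qaly_auc(c(0.487, 0.463, 0.490), c(0, 3, 6))        # 0.237875

# deterministic 5-year base case
deterministic_cua(ps)
#> <ce_result>
#>           arm    cost   qaly
#>    usual_care 5548.36 2.7077
#>  intervention 7313.45 2.8132
#>  incremental: cost +1765.09, effect +0.1056
#>  ICER: 16722 per unit effect

# probabilistic sensitivity analysis and value of information
psa <- run_psa(ps, n_iter = 10000, seed = 1)        # ~2 min
ceac(psa, c(20000, 30000))
#>     wtp   p_ce
#> 1 20000 0.5986
#> 2 30000 0.7387
evpi(psa, 20000)                                    # 565.40 per patient
```

Read: at point estimates the intervention yields 0.106 extra QALYs per
patient over 5 years for £1,765 extra cost (ICER ≈ £16,700/QALY, inside
the UK band); under full parameter uncertainty it is cost-effective in
60% of draws at £20,000/QALY rising to 74% at £30,000, and perfect
information would be worth about £565 per patient at £20,000/QALY.
Exact published headline values are not reproducible without
supplementary-only inputs (year-1 accruals, the usual-care transition
matrix, death-on-admission); the packaged defaults are clearly flagged
placeholders — see `vignettes/methods.Rmd`.

Within-trial analysis on synthetic data:

```r
d <- generate_trial(generator_config(), seed = 1)   # 45 per arm
pooled <- attr(impute_trial(d, n_imputations = 50, seed = 2), "pooled")
bootstrap_cea(pooled, n_reps = 5000, seed = 3)
```

End-to-end run with publication-style outputs (tables, CE plane, CEAC,
EVPI curve, manifest):

```r
run_all(out_dir = "results/full_run", seed = 1)
```

Command-line wrappers live in `inst/cli/` (`run_model.R`,
`run_trial_cea.R`, `run_psa.R`, `generate_trial.R`).

## Layout

* `R/` — parameters & distributions, intervention costing, Markov
  engine + microsimulation oracle, treatment effects, within-trial CEA,
  PSA/VoI, synthetic trial generator, orchestration.
* `inst/extdata/default_config.json` — the packaged base case: every
  model input with its point estimate and PSA distribution.
* `tests/testthat/` — unit, property and acceptance suites.
* `vignettes/methods.Rmd` — the model, its assumptions, parameter
  quirks (including documented misprint corrections), and what the
  synthetic-data tests do and do not establish.
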