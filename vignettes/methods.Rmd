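---
title: "Methods: trial- and model-based cost-effectiveness of a COPD early-warning intervention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial- and model-based cost-effectiveness of a COPD early-warning intervention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdcea)
```

## The decision problem

`copdcea` evaluates a digital early-warning self-management system for
chronic obstructive pulmonary disease (COPD) against usual care from the
UK NHS perspective. Frequent exacerbators carry most of the clinical and
economic burden of COPD; severe (hospitalised) exacerbations drive both
costs and quality-of-life loss, and an app that flags deteriorations
early may avert admissions. The package implements two linked analyses:

1. **Within-trial cost-utility / cost-effectiveness analysis** over 6 or
   12 months of follow-up: QALYs by the area-under-the-curve method on
   EQ-5D utilities, chained multiple imputation of missing follow-up
   data, covariate-adjusted incremental costs and effects, and
   non-parametric bootstrapping for the ICER and CEAC.
2. **A 5-year Markov cohort model** over the GOLD A--D groups with a
   1-month cycle, three post-discharge tunnel months after each
   hospitalised exacerbation, death attached to admissions, annual 3.5%
   discounting (from month 13), probabilistic sensitivity analysis and
   expected value of (partial) perfect information.

Because the underlying patient-level trial data are not shared, the
package ships a synthetic trial generator (`generate_trial()`) with
closed-form ground truth (`true_values()`), and the within-trial
machinery is validated by parameter recovery rather than by reproducing
the published patient-level results.

## The cohort model

States are the four GOLD groups (A: low risk / fewer symptoms, B: low
risk / more symptoms, C: high risk / fewer symptoms, D: high risk / more
symptoms), a chain of three one-month post-discharge tunnel states per
group, and an absorbing dead state. Within a cycle, stage occupants
first face the monthly exacerbation probability; the admitted fraction
either dies (probability `death_on_admission`) or enters month 1 of the
tunnel attached to its landing stage. Because GOLD membership is partly
admission-defined, admissions deteriorate A to C and B to D; C and D
land on themselves. Non-exacerbators move by the monthly transition
matrix; tunnel occupants advance one month and exit to their stage.

Cycles 1--12 are not modelled mechanistically: both arms carry their
trial-derived year-1 cost and QALY accruals, spread uniformly and
undiscounted, with the cohort held at the 12-month starting
distribution. From cycle 13 the cohort evolves as above, with costs
(stage membership, admissions, and on the intervention arm a monthly
intervention cost) and utilities (stage utility; tunnel months at the
stage utility minus 0.06) discounted by `1.035^(-t/12)`.

Four treatment effects distinguish the intervention arm:

* improved 12-month starting states (fewer patients in D);
* beneficial transition cells (A&rarr;B, A&rarr;D, C&rarr;B, C&rarr;D)
  multiplied by a relative risk that starts at 0.91 in model year 2 and
  whose risk reduction halves each year (0.955, 0.978, 0.989);
* exacerbation rates in the admission-defined stages B and D reduced by
  12%, 6%, 3% and 1.5% in years 2--5;
* 1.278 fewer bed days per admission, so intervention admissions cost
  2258.33 &minus; 1.278 &times; 260.71 = 1925.14.

Setting all four to null makes the arms identical up to the intervention
cost (a property the test suite checks indirectly through the degenerate
PSA test).

### Numerical and structural choices

* **Event ordering**: exacerbation draw first, matrix move for
  non-exacerbators second. Admissions route through tunnels regardless
  of what the matrix would have done.
* **No half-cycle correction** (the source material is silent); the
  engine accrues on start-of-cycle occupancy.
* **Admission costs** are charged for every admission, including deaths
  on admission.
* **Disutility per tunnel month**: the published "disutility for 3
  months" is read as &minus;0.06 in each tunnel month;
  `exac_disutility_per_month = false` divides it by three instead.
* **`death_on_admission` is a placeholder** (0.05, beta(5, 95)): the
  source estimates are supplementary-only. It is present in the packaged
  configuration; omitting it from a user configuration default-fills
  with a logged warning. No background mortality is modelled, matching a
  structure in which death attaches only to admissions.
* **Usual-care transition matrix is a placeholder**: the published main
  text gives only the intervention year-2 matrix, so usual care is
  back-derived by dividing the beneficial cells by 0.91 and refilling
  the row residuals. Every load logs this.
* **Merged-states variant** (`structure = "ace"`): the newer GOLD
  classification merges C and D into E. Stage-E parameters are
  occupancy-weighted pools of C and D with weights from the combined-arm
  12-month starting counts (C = 1, D = 33); pooling happens at
  model-input resolution so PSA draws pool consistently. Merging
  dilutes the modelled benefit because C is both cheaper and better
  than D, which is exactly why the variant is worth running.

### Validation oracle

`microsim_oracle()` simulates individual patients under the same
per-cycle probabilities and accrual rules. The acceptance suite requires
cohort/microsimulation agreement within 3 Monte-Carlo SE at 50,000
patients; degenerate settings (probabilities 0/1) must agree exactly.

## Parameters and their distributions

Every input is a `dist_spec`: a point estimate plus a sampling family
(beta for probabilities and utilities, gamma for costs, normal for the
admission and bed-day tariffs, lognormal for the relative risk on the
arithmetic mean/SE parameterisation). Stage A and C monthly costs are
derived as B and D minus a common decrement (33.10, gamma with shape
0.47), clamped at zero.

Three published-table quirks deserve record:

* **Starting-state points are counts, not beta means.** The published
  proportions are integer patient counts over the arm total (13/17 =
  0.765); the beta parameters add a 0.05 pseudo-alpha to empty states
  for PSA. `load_parameters()` therefore derives points by zeroing
  pseudo-count alphas and normalising the rest.
* **Some alphas carry decimal-shift misprints.** The stage-A
  exacerbation beta (4.99, 20743.01) implies a mean 10&times; below the
  printed rate, while 0.0024 &times; 20748 = 49.8 — the alpha lost a
  digit. The C&rarr;B transition cell (0.5, 95.5) against point 0.054 is
  the same defect (0.054 &times; 96 &asymp; 5). By default the PSA
  re-derives every exacerbation and transition beta by preserving the
  printed denominator `alpha + beta` (the observation count, which is
  printed consistently) and matching the printed mean; a PSA miscentred
  by an order of magnitude would invalidate any comparison with the
  deterministic base case. `recenter_betas = FALSE` restores the printed
  parameters verbatim.
* **Costing arithmetic vs printed totals.** The intervention costing
  table's printed totals (362.57 first year, 231.23 subsequent) differ
  from strict item arithmetic by up to 0.45. Printed values are the
  defaults; `strict = TRUE` recomputes and exposes the gaps.

## Probabilistic sensitivity analysis

Each PSA iteration draws a complete parameter set and runs both arms
through the cohort engine; each iteration has its own RNG stream derived
from the root seed, so results are independent of execution order.
Specific choices:

* **Starting states** are normalised independent beta draws per arm —
  the published parameters are per-state beta pairs, not a joint
  Dirichlet, and normalisation restores the sum-to-one invariant.
* **The usual-care matrix is sampled directly** around its (back-derived)
  points. Sampling the intervention cells and dividing by the sampled
  RR would inflate usual care by E[1/RR] = 1.58 (lognormal, sdlog
  0.604) — a pure Jensen artefact.
* **One RR draw drives both transition and exacerbation effects**: the
  sampled year-2 RR generates the decayed RR schedule, and the
  exacerbation-reduction schedule scales by (1 &minus; RR)/(1 &minus;
  0.91), clamped at 100% (a favourable draw can at most abolish
  exacerbations). Harmful draws (RR &gt; 1) are allowed.
* **Invalid draws** (a transition row exceeding 1 after adjustment) are
  redrawn, capped at 100 per iteration.

The deterministic base case uses point estimates, not distribution
means, following standard decision-model practice; the PSA mean will
therefore differ from the base case by genuine Jensen effects. The
acceptance suite bounds that difference by 3 Monte-Carlo SE at 10,000
iterations; the residual cost-side difference (about +20 on an
incremental cost near 1800) traces to clamping derived stage-A/C costs
at zero under the heavy-tailed decrement gamma.

## Value of information

`evpi()` is the textbook estimator: mean over iterations of the per-
iteration best net benefit, minus the net benefit of the on-average best
arm. `evppi()` is regression-based (thin-plate GAM of each arm's net
benefit on the recorded draws of the parameter group, then the same
max-of-means contrast on fitted values), clipped to [0, EVPI];
`evppi_nested()` is a generic two-level Monte-Carlo oracle used to
validate the regression estimator on toy models. `population_voi()`
multiplies per-patient value by a discounted sum over the eligible
population (default 626,129 per year).

## The synthetic trial generator

`generate_trial()` emulates the structure the within-trial analysis
assumes: 45 patients per arm across 4 sites, 87.8% in GOLD D; EQ-5D at
months 0/3/6/9/12 drawn around arm-level visit means (defaults mirror
the published arm summaries: baseline 0.529 vs 0.487, 6-month 0.587 vs
0.490) with a shared patient-level random intercept (SD 0.18) plus
visit noise (SD 0.12), clamped to [&minus;0.594, 1]; per-category
quarterly costs from gamma draws (CV 1.2) around the published
six-month category means plus a fixed 181.29 intervention cost;
hospitalisations Poisson at 0.128 vs 0.146 per six months; 10%
independent visit missingness (monotone dropout optional); 2% 12-month
mortality censoring later visits.

`true_values()` returns closed-form expectations, correcting per-visit
means for the utility clamp (clamped-normal closed form), so recovery
targets are exact. Two caveats define what a green recovery test does
and does not establish:

* The default configuration reproduces the trial's *observed* baseline
  imbalance. Because the QALY analysis adjusts for baseline EQ-5D, its
  estimand equals the marginal trapezoid difference only under
  baseline-balanced (randomised) arms — recovery tests therefore use a
  balanced configuration.
* The generator matches arm-level summaries only; it makes no claim
  about the real trial's joint distribution (cost skewness beyond a
  gamma, informative missingness, site effects), so green tests
  establish internal consistency of the pipeline, not fidelity to the
  unshared data.

## Within-trial analysis choices

* **Imputation** is linear-regression chained equations over the
  incomplete EQ-5D, cost and hospitalisation variables, predictors
  being age, gender, site, stage, arm and neighbouring observations of
  the same variable (hospitalisations additionally enter cost models);
  each missing cell is replaced by prediction plus Gaussian noise at
  the residual scale, and the point analysis uses the arithmetic mean
  of 50 imputations per cell. Patients returning no post-baseline data
  are never imputed.
* **Joint estimation**: with identical covariate sets per equation the
  SUR estimator coincides with equation-by-equation least squares, so
  the arm coefficients come from two `lm` fits and the cross-equation
  residual correlation is reported.
* **Deaths are excluded** from QALY analyses (an early death's
  near-zero QALY would dominate at these sample sizes);
  `include_deaths = TRUE` is the sensitivity switch.
* **Bootstrap** resamples patients with replacement within arm,
  preserving arm sizes (arm is a design variable); the ICER is the
  ratio of mean replicate increments; no within-trial discounting.

## Known limitations

* The published 5-year base case, trial ICERs, CEAC percentages and
  EVPI are not reproduced exactly: they depend on supplementary-only
  inputs (year-1 accruals, the usual-care matrix, death-on-admission)
  and the unshared patient data. The packaged placeholders give the
  same qualitative picture (north-east CE-plane quadrant, CEAC rising
  through the 20,000--30,000 band, EVPI of the same order) and every
  placeholder is logged on load.
* No lifetime extrapolation beyond 60 cycles, no background mortality,
  no societal perspective, no currency/price-year machinery, and the
  EQ-5D-5L crosswalk tariff itself is out of scope (utilities enter as
  numbers).
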