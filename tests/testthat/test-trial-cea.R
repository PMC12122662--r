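## small deterministic dataset builder: two arms with controllable outcomes
flat_trial <- function(n = 20, d_qaly = 0, d_cost = 0, d_hosp = 0) {
  mk <- function(arm, shift_u, shift_c, shift_h) {
    data.frame(
      id = paste0(arm, seq_len(n)), arm = arm,
      age = rep(c(65, 70, 75, 80), length.out = n),
      gender = rep(c("F", "M"), length.out = n),
      site = rep(c("S1", "S2", "S3"), length.out = n),
      gold_stage = rep(c("D", "D", "D", "B"), length.out = n),
      eq5d_m0 = 0.5, eq5d_m3 = 0.5 + shift_u, eq5d_m6 = 0.5 + shift_u,
      eq5d_m9 = 0.5 + shift_u, eq5d_m12 = 0.5 + shift_u,
      cost_p1 = 400 + shift_c / 2, cost_p2 = 400 + shift_c / 2,
      cost_p3 = 400, cost_p4 = 400,
      hosp_p1 = rep(round(c(0, 0, 1, 0) + shift_h), length.out = n),
      hosp_p2 = 0L, hosp_p3 = 0L, hosp_p4 = 0L,
      died = FALSE, death_month = NA_real_, stringsAsFactors = FALSE)
  }
  trial_dataset(rbind(mk("usual_care", 0, 0, 0),
                      mk("intervention", d_qaly * 2, d_cost, d_hosp)))
}

test_that("QALY AUC reproduces the published 6-month worked examples", {
  expect_equal(round(qaly_auc(c(0.529, 0.537, 0.587), c(0, 3, 6)), 3), 0.274)
  expect_equal(round(qaly_auc(c(0.487, 0.463, 0.490), c(0, 3, 6)), 3), 0.238)
  inc <- qaly_auc(c(0.529, 0.537, 0.587), c(0, 3, 6)) -
    qaly_auc(c(0.487, 0.463, 0.490), c(0, 3, 6))
  expect_equal(round(inc, 3), 0.036)
  expect_equal(qaly_auc(c(1, 1), c(0, 12)), 1)
  expect_error(qaly_auc(c(0.5, NA, 0.6), c(0, 3, 6)), "impute")
  expect_error(qaly_auc(c(0.5, 0.6), c(3, 0)), "increasing")
})

test_that("AUC is invariant to inserting an interpolated midpoint", {
  u <- c(0.52, 0.61, 0.47)
  tms <- c(0, 3, 6)
  mid <- (u[2] + u[3]) / 2
  expect_equal(qaly_auc(u, tms),
               qaly_auc(c(u[1], u[2], mid, u[3]), c(0, 3, 4.5, 6)))
})

test_that("dataset validation enforces the column contract", {
  d <- flat_trial()
  expect_s3_class(d, "trial_dataset")
  expect_error(trial_dataset(d[, -match("died", names(d))]), "died")
  bad <- as.data.frame(d); bad$cost_p1[1] <- -5
  expect_error(trial_dataset(bad), "nonneg")
  bad <- as.data.frame(d); bad$hosp_p1[1] <- 0.5
  expect_error(trial_dataset(bad), "integer")
  bad <- as.data.frame(d); bad$eq5d_m0[1] <- NA
  expect_error(trial_dataset(bad), "[Bb]aseline")
})

test_that("patients with no post-baseline returns are flagged excluded", {
  d <- as.data.frame(flat_trial())
  post <- c(paste0("eq5d_m", c(3, 6, 9, 12)), paste0("cost_p", 1:4),
            paste0("hosp_p", 1:4))
  d[1, post] <- NA
  d2 <- trial_dataset(d)
  expect_true(d2$excluded_imputation[1])
  expect_false(any(d2$excluded_imputation[-1]))
  imp <- impute_trial(d2, n_imputations = 2, seed = 1)
  expect_true(anyNA(attr(imp, "pooled")[1, post]))  # never imputed
})

test_that("a complete dataset passes through imputation unchanged", {
  d <- flat_trial()
  imp <- impute_trial(d, n_imputations = 3, seed = 9)
  for (m in imp) expect_equal(as.data.frame(m), as.data.frame(d))
  expect_equal(as.data.frame(attr(imp, "pooled")), as.data.frame(d))
})

test_that("imputation is seed-reproducible and fills all analysis cells", {
  set.seed(4)
  cfg <- generator_config(n_per_arm = 60, missing_prob = 0.2)
  d <- generate_trial(cfg, seed = 31)
  i1 <- impute_trial(d, n_imputations = 4, seed = 7)
  i2 <- impute_trial(d, n_imputations = 4, seed = 7)
  expect_identical(i1, i2)
  pooled <- attr(i1, "pooled")
  keep <- !pooled$excluded_imputation
  expect_false(anyNA(pooled[keep, c("eq5d_m3", "eq5d_m6",
                                    "cost_p1", "cost_p2")]))
})

## baseline-balanced configuration: with randomised (equal-mean) baselines
## the baseline-adjusted arm coefficient targets the marginal difference,
## so true_values() is the right recovery target
balanced_config <- function(...) {
  generator_config(
    visit_means = list(
      intervention = c(0.49, 0.53, 0.55, 0.55, 0.55),
      usual_care = c(0.49, 0.49, 0.49, 0.49, 0.49)),
    death_prob_12m = 0, ...)
}

test_that("imputation recovers arm means on synthetic data", {
  cfg <- balanced_config(n_per_arm = 300, missing_prob = 0.25)
  d <- generate_trial(cfg, seed = 17)
  pooled <- attr(impute_trial(d, n_imputations = 10, seed = 5), "pooled")
  inc <- adjusted_incrementals(pooled, "qaly")
  truth <- true_values(cfg)
  ## generous bound: imputation noise plus estimation SE
  expect_lt(abs(inc$d_effect - truth$d_qaly), 3 * inc$se_effect)
})

test_that("identical arms give zero adjusted increments", {
  d <- flat_trial(d_qaly = 0, d_cost = 0)
  inc <- adjusted_incrementals(d, "qaly")
  expect_equal(inc$d_cost, 0, tolerance = 1e-10)
  expect_equal(inc$d_effect, 0, tolerance = 1e-10)
})

test_that("with covariates orthogonal to arm, adjustment equals raw means", {
  d <- flat_trial(n = 24, d_qaly = 0.02, d_cost = 240)
  inc <- adjusted_incrementals(d, "qaly")
  df <- as.data.frame(d)
  per <- seq_len(2)
  raw_q <- function(a) mean(apply(
    df[df$arm == a, paste0("eq5d_m", c(0, 3, 6))], 1, qaly_auc,
    times = c(0, 3, 6)))
  raw_c <- function(a) mean(rowSums(df[df$arm == a,
                                       paste0("cost_p", per)]))
  expect_equal(inc$d_effect,
               raw_q("intervention") - raw_q("usual_care"),
               tolerance = 1e-8)
  expect_equal(inc$d_cost, raw_c("intervention") - raw_c("usual_care"),
               tolerance = 1e-8)
})

test_that("perfectly collinear covariates raise a naming error", {
  d <- as.data.frame(flat_trial())
  d$site <- ifelse(d$arm == "usual_care", "S1", "S2")
  expect_error(adjusted_incrementals(trial_dataset(d), "qaly"),
               "collinear")
})

test_that("parameter recovery on synthetic data (moderate n)", {
  cfg <- balanced_config(n_per_arm = 800, missing_prob = 0)
  d <- generate_trial(cfg, seed = 23)
  truth <- true_values(cfg)
  inc <- adjusted_incrementals(d, "qaly")
  expect_lt(abs(inc$d_effect - truth$d_qaly), 2 * inc$se_effect)
  expect_lt(abs(inc$d_cost - truth$d_cost), 2 * inc$se_cost)
  hosp <- adjusted_incrementals(d, "hospitalisations")
  expect_lt(abs(hosp$d_effect - (-truth$d_hosp)), 2 * hosp$se_effect)
})

test_that("bootstrap: degenerate data give a 0/1 CEAC and equal replicates", {
  d <- flat_trial(n = 12, d_qaly = 0.05, d_cost = 100)
  b <- bootstrap_cea(d, n_reps = 120, seed = 2)
  expect_true(all(b$ceac %in% c(0, 1)))
  expect_equal(unname(apply(b$replicates, 2, stats::sd)), c(0, 0),
               tolerance = 1e-9)
  expect_error(bootstrap_cea(d, n_reps = 50), "unstable")
})

test_that("bootstrap CEAC limits follow the replicate signs", {
  cfg <- generator_config(n_per_arm = 120, missing_prob = 0,
                          death_prob_12m = 0)
  d <- generate_trial(cfg, seed = 41)
  b <- bootstrap_cea(d, n_reps = 250, seed = 6,
                     wtp_grid = c(0, 2e4, 3e4, 1e9))
  expect_equal(b$ceac[1], mean(b$replicates$d_cost < 0))
  expect_equal(b$ceac[4], mean(b$replicates$d_effect > 0),
               tolerance = 0.01)
  ## all replicates with positive gain: CEAC non-decreasing in lambda
  if (all(b$replicates$d_effect > 0))
    expect_true(all(diff(b$ceac) >= 0))
  ## ICER consistency and reproducibility
  expect_equal(b$icer, mean(b$replicates$d_cost) /
                 mean(b$replicates$d_effect))
  b2 <- bootstrap_cea(d, n_reps = 250, seed = 6,
                      wtp_grid = c(0, 2e4, 3e4, 1e9))
  expect_identical(b$replicates, b2$replicates)
})

test_that("hospitalisation CEA uses the averted-is-gain convention", {
  cfg <- generator_config(n_per_arm = 400, missing_prob = 0,
                          death_prob_12m = 0,
                          hosp_rate_6m = c(intervention = 0.128,
                                           usual_care = 0.146))
  expect_equal(true_values(cfg)$d_hosp, -0.018)
  d <- generate_trial(cfg, seed = 13)
  b <- hospitalisation_cea(d, n_reps = 200, seed = 3)
  ## positive effect = hospitalisations averted
  expect_lt(abs(b$point$d_effect - 0.018), 2.5 * b$point$se_effect)
})
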