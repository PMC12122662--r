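make_identity_params <- function() {
  ps <- base_params()
  stages <- ps$stages
  off <- matrix(0, 4, 4, dimnames = list(stages, stages))
  ps$trans_usual <- transition_matrix(off,
                                      specs = attr(ps$trans_usual, "specs"))
  ps$exac_rates[] <- 0
  ps$death_on_admission$point <- 0
  ps
}

test_that("cycle_step conserves mass and honours the published stay rows", {
  ps <- base_params()
  sp <- state_space("abcd")
  occ <- numeric(length(sp$states))
  names(occ) <- sp$states
  occ["A"] <- 1
  ex <- ps$exac_rates * 0
  step <- cycle_step(occ, sp, as.matrix(ps$trans_intervention_year2), ex, 0.05)
  expect_equal(step$occ[["A"]], 0.978)   # 1 - (0.008 + 0.011 + 0.003)
  expect_equal(sum(step$occ), 1, tolerance = 1e-12)
})

test_that("tunnel exit and admission-driven deterioration follow the rules", {
  ps <- base_params()
  sp <- state_space("abcd")
  ## all mass in tunnel month 3 of D exits to D
  occ <- numeric(length(sp$states)); names(occ) <- sp$states
  occ[["tun_D_3"]] <- 1
  step <- cycle_step(occ, sp, as.matrix(ps$trans_usual), ps$exac_rates * 0, 0)
  expect_equal(step$occ[["D"]], 1)
  ## stage B with certain exacerbation and no death lands in tunnel of D
  occ[] <- 0; occ[["B"]] <- 1
  ex <- ps$exac_rates * 0; ex[["B"]] <- 1
  step <- cycle_step(occ, sp, as.matrix(ps$trans_usual), ex, 0)
  expect_equal(step$occ[["tun_D_1"]], 1)
  expect_equal(step$admissions, 1)
  ## death on admission routes to the absorbing state
  step <- cycle_step(occ, sp, as.matrix(ps$trans_usual), ex, 0.25)
  expect_equal(step$occ[["dead"]], 0.25)
  expect_equal(step$occ[["tun_D_1"]], 0.75)
})

test_that("identity transitions with no exacerbations give a fixed point", {
  ps <- make_identity_params()
  tr <- run_cohort(ps, "usual_care")
  for (t in 13:60)
    expect_equal(tr$occupancy[t, ], tr$occupancy[13, ], tolerance = 1e-12)
})

test_that("certain exacerbation with certain death absorbs the cohort", {
  ps <- base_params()
  ps$exac_rates[] <- 1
  ps$death_on_admission$point <- 1
  tr <- run_cohort(ps, "usual_care")
  expect_equal(unname(tr$occupancy[14, "dead"]), 1)
})

test_that("month 13 starts from the published 12-month distribution", {
  tr <- run_cohort(base_params(), "intervention")
  expect_equal(round(unname(tr$occupancy[13, "D"]), 3), 0.765)
  expect_equal(unname(tr$occupancy[13, "B"]), 3 / 17)
})

test_that("mass is conserved every cycle, including under PSA draws", {
  ps <- base_params()
  for (arm in c("usual_care", "intervention")) {
    tr <- run_cohort(ps, arm)
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, 60),
                 tolerance = 1e-9)
    expect_true(all(tr$occupancy >= -1e-12))
  }
  set.seed(5)
  for (i in 1:5) {
    dr <- sample_params(ps)
    tr <- run_cohort(dr$params, "intervention")
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, 60),
                 tolerance = 1e-9)
  }
})

test_that("discounting matches the closed form and vanishes at r = 0", {
  expect_equal(discount_factor(24), 1.035^(-2))
  expect_equal(discount_factor(24), 0.93351, tolerance = 1e-5)
  expect_equal(discount_factor(6), 1)   # trial-derived year is undiscounted
  ps <- base_params()
  ps$discount_rate_annual <- 0
  tr <- run_cohort(ps, "usual_care")
  acc <- accrue(tr)
  expect_equal(acc$total_qaly, sum(acc$qaly_undiscounted))
  expect_equal(acc$total_cost, sum(acc$cost_undiscounted))
})

test_that("uniform utilities give the closed-form discounted QALY total", {
  ps <- base_params()
  u <- 0.7
  ps$stage_params$utilities[] <- u
  ps$stage_params$exac_disutility <- 0
  ps$death_on_admission$point <- 0
  acc <- accrue(run_cohort(ps, "usual_care"))
  expected <- ps$year1$usual_care$qaly$point +
    u * sum(discount_factor(13:60)) / 12
  expect_equal(acc$total_qaly, expected, tolerance = 1e-10)
})

test_that("whole cohort in stage D accrues utility 0.59/12 per cycle", {
  ps <- make_identity_params()
  for (arm in names(ps$starting))
    ps$starting[[arm]]$point <- c(A = 0, B = 0, C = 0, D = 1)
  acc <- accrue(run_cohort(ps, "usual_care"))
  expect_equal(acc$qaly_undiscounted[20], 0.59 / 12)
})

test_that("raising death on admission never increases total QALYs", {
  ps <- base_params()
  q <- vapply(c(0, 0.05, 0.2, 0.5, 1), function(d) {
    ps$death_on_admission$point <- d
    accrue(run_cohort(ps, "intervention"))$total_qaly
  }, numeric(1))
  expect_true(all(diff(q) <= 1e-12))
})

test_that("deterministic CUA labels dominance and computes linear NMB", {
  ps <- base_params()
  res <- deterministic_cua(ps)
  expect_s3_class(res, "ce_result")
  expect_equal(res$nmb, res$wtp_grid * res$inc_effect - res$inc_cost)
  ## identical arms are indifferent
  null <- ce_result(100, 1, 100, 1)
  expect_identical(null$dominance, "indifferent")
  dom <- ce_result(100, 1, 50, 1.2)
  expect_identical(dom$dominance, "dominant")
  ## ratio arithmetic on the published trial increments
  naive <- ce_result(0, 0, 238.16, 0.020)
  expect_equal(naive$icer, 11908)
})

test_that("the merged ACE structure runs and pools C and D", {
  ps <- base_params()
  sp <- state_space("ace")
  expect_identical(sp$stages, c("A", "B", "E"))
  expect_identical(unname(sp$landing), c("E", "E", "E"))
  tr <- run_cohort(ps, "intervention", structure = "ace")
  expect_equal(unname(tr$occupancy[13, "E"]),
               unname(sum(base_params()$starting$intervention$point[c("C", "D")])))
  expect_equal(unname(rowSums(tr$occupancy)), rep(1, 60), tolerance = 1e-9)
  res <- deterministic_cua(ps, structure = "ace")
  expect_true(is.finite(res$icer) || res$dominance != "icer")
})

test_that("microsimulation matches the cohort engine", {
  ps <- base_params()
  ## degenerate probabilities: exact agreement
  psd <- make_identity_params()
  for (arm in names(psd$starting))
    psd$starting[[arm]]$point <- c(A = 0, B = 0, C = 0, D = 1)
  co <- accrue(run_cohort(psd, "usual_care"))
  ms <- microsim_oracle(psd, "usual_care", n_patients = 50, seed = 2)
  expect_equal(ms$qaly, co$total_qaly, tolerance = 1e-10)
  expect_equal(ms$cost, co$total_cost, tolerance = 1e-10)
  ## stochastic agreement at modest n (4 Monte-Carlo SE)
  co <- accrue(run_cohort(ps, "intervention"))
  ms <- microsim_oracle(ps, "intervention", n_patients = 10000, seed = 3)
  expect_lt(abs(ms$qaly - co$total_qaly), 4 * ms$se_qaly)
  expect_lt(abs(ms$cost - co$total_cost), 4 * ms$se_cost)
  ## reproducibility
  ms2 <- microsim_oracle(ps, "intervention", n_patients = 10000, seed = 3)
  expect_identical(ms, ms2)
})

test_that("trace export is tidy and complete", {
  tr <- run_cohort(base_params(), "usual_care")
  df <- trace_to_df(tr)
  expect_identical(nrow(df), 60L * ncol(tr$occupancy))
  expect_true(all(c("cycle", "state", "occupancy") %in% names(df)))
})
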