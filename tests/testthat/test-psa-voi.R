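test_that("a fully degenerate PSA reproduces the deterministic result", {
  ps <- fix_all_specs(base_params())
  det <- deterministic_cua(base_params())
  psa <- run_psa(ps, n_iter = 4, seed = 5, recenter_betas = FALSE)
  dc <- psa$cost[, 2] - psa$cost[, 1]
  dq <- psa$qaly[, 2] - psa$qaly[, 1]
  expect_equal(unname(dc), rep(det$inc_cost, 4), tolerance = 1e-9)
  expect_equal(unname(dq), rep(det$inc_effect, 4), tolerance = 1e-9)
})

test_that("PSA output is bit-identical under the same root seed", {
  ps <- base_params()
  a <- run_psa(ps, n_iter = 12, seed = 77)
  b <- run_psa(ps, n_iter = 12, seed = 77)
  expect_identical(a, b)
  d <- run_psa(ps, n_iter = 12, seed = 78)
  expect_false(identical(a$cost, d$cost))
})

test_that("CEAC enumerations match hand-computed probabilities", {
  ## two-point toy: (dC, dQ) = (100, 0.01) and (100, -0.01)
  psa <- toy_psa(cost_uc = c(0, 0), cost_int = c(100, 100),
                 qaly_uc = c(0, 0), qaly_int = c(0.01, -0.01))
  cc <- ceac(psa, wtp_grid = 20000)
  expect_equal(cc$p_ce, 0.5)
  ## every iteration favourable at 20k
  psa2 <- toy_psa(cost_uc = c(0, 0), cost_int = c(1000, 1000),
                  qaly_uc = c(0, 0), qaly_int = c(0.1, 0.1))
  expect_equal(ceac(psa2, 20000)$p_ce, 1)
  expect_equal(ceac(psa2, 0)$p_ce, 0)   # costlier at lambda = 0
})

test_that("EVPI matches the brute-force two-decision oracle", {
  ## arm NB samples d1 = {1, 3}, d2 = {2, 2}: E[max] = 2.5, max E = 2
  psa <- toy_psa(cost_uc = c(-1, -3), cost_int = c(-2, -2))
  expect_equal(evpi(psa, lambda = 0), 0.5)
  expect_equal(evpi(psa, lambda = 12345), 0.5)  # qalys are zero here
  ## dominance in every iteration gives zero EVPI
  dom <- toy_psa(cost_uc = c(5, 6), cost_int = c(1, 2))
  expect_equal(evpi(dom, 0), 0)
})

test_that("EVPI is non-negative over the whole WTP grid", {
  ps <- base_params()
  psa <- run_psa(ps, n_iter = 150, seed = 10)
  ev <- evpi(psa, seq(0, 50000, 2500))
  expect_true(all(ev >= 0))
  cc <- ceac(psa)
  expect_true(all(cc$p_ce >= 0 & cc$p_ce <= 1))
})

test_that("regression EVPPI: informative parameter recovers EVPI, null is 0", {
  set.seed(9)
  n <- 2000
  x <- rnorm(n)          # drives the incremental NB entirely
  z <- rnorm(n)          # recorded but unrelated
  psa <- toy_psa(cost_uc = rep(0, n), cost_int = -x)
  psa$params <- cbind(x = x, z = z)
  ev <- evpi(psa, 0)
  expect_equal(ev, mean(pmax(x, 0)) - max(mean(x), 0), tolerance = 1e-12)
  e_x <- evppi(psa, "x", lambda = 0)
  e_z <- evppi(psa, "z", lambda = 0)
  expect_lt(abs(e_x - ev) / ev, 0.05)
  expect_lt(e_z, 0.1 * ev)
  expect_true(e_x <= ev + 1e-12)
  expect_error(evppi(psa, "nope", 0), "not recorded")
  small <- toy_psa(rep(0, 100), rnorm(100))
  small$params <- cbind(x = rnorm(100))
  expect_error(evppi(small, "x", 0), "500")
})

test_that("nested Monte-Carlo oracle agrees with the closed form", {
  ## NB1 = theta ~ N(0,1), NB2 = 0: EVPPI(theta) = E[theta+] = 1/sqrt(2*pi)
  est <- evppi_nested(
    draw_group = function(n) rnorm(n),
    draw_rest = function(n) 0,
    nb_fun = function(g, r) c(g, 0),
    n_outer = 4000, n_inner = 1, seed = 3)
  expect_equal(est, 1 / sqrt(2 * pi), tolerance = 0.05)
  ## group with no influence: EVPPI near zero
  est0 <- evppi_nested(
    draw_group = function(n) rnorm(n),
    draw_rest = function(n) rnorm(n),
    nb_fun = function(g, r) c(r, 0),
    n_outer = 150, n_inner = 400, seed = 4)
  expect_lt(est0, 0.05)
})

test_that("population scaling multiplies and discounts correctly", {
  expect_equal(population_voi(10, population = 1, horizon_years = 1), 10)
  expect_equal(population_voi(556, 626129), 348127724)
  five <- population_voi(100, 1000, horizon_years = 5,
                         discount_rate = 0.035)
  expect_lt(five, 5 * population_voi(100, 1000))
  expect_gt(five, 4.5 * population_voi(100, 1000))
})

test_that("shrinking parameter uncertainty drives EVPI towards zero", {
  ps <- base_params()
  ev <- vapply(c(1, 8, 64), function(k) {
    psa <- run_psa(scale_uncertainty(ps, k), n_iter = 120, seed = 14)
    evpi(psa, 20000)
  }, numeric(1))
  expect_true(all(diff(ev) < 0))
  expect_lt(ev[3], 0.2 * ev[1])
})
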