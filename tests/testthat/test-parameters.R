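test_that("packaged config loads with the published starting states", {
  ps <- base_params()
  expect_equal(unname(ps$starting$usual_care$point["D"]), 20 / 23)
  expect_equal(round(ps$starting$usual_care$point[["D"]], 3), 0.870)
  expect_equal(round(ps$starting$intervention$point[["D"]], 3), 0.765)
  expect_equal(sum(ps$starting$usual_care$point), 1, tolerance = 1e-12)
  expect_equal(sum(ps$starting$intervention$point), 1, tolerance = 1e-12)
  expect_identical(ps$horizon_months, 60L)
  expect_equal(ps$discount_rate_annual, 0.035)
})

test_that("transition matrices are row-stochastic with residual diagonal", {
  ps <- base_params()
  for (m in list(ps$trans_usual, ps$trans_intervention_year2)) {
    expect_equal(unname(rowSums(as.matrix(m))), rep(1, 4), tolerance = 1e-12)
    expect_true(all(m >= 0 & m <= 1))
  }
  ## published intervention year-2 stay probabilities
  m <- as.matrix(ps$trans_intervention_year2)
  expect_equal(unname(diag(m)), c(0.978, 0.967, 0.910, 0.978))
})

test_that("an off-diagonal row sum above 1 is rejected with the row named", {
  off <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  off["A", "B"] <- 0.7
  off["A", "C"] <- 0.5
  expect_error(transition_matrix(off), "row 'A'")
})

test_that("missing optional keys are default-filled with a warning", {
  cfg <- jsonlite::read_json(default_config_path())
  cfg$death_on_admission <- NULL
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  expect_warning(
    ps <- suppressMessages(load_parameters(tmp)),
    "death_on_admission")
  expect_equal(ps$death_on_admission$point, 0.05)
  expect_true(any(grepl("death_on_admission", ps$default_filled)))
})

test_that("schema violations raise named-field errors", {
  cfg <- jsonlite::read_json(default_config_path())
  cfg$year1 <- NULL
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(suppressMessages(load_parameters(tmp)), "year1")

  cfg2 <- jsonlite::read_json(default_config_path())
  cfg2$transitions$intervention_year2$A$B$point <- 1.2
  jsonlite::write_json(cfg2, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(suppressMessages(load_parameters(tmp)))
})

test_that("published beta means agree with published points within 0.02", {
  ## documented exceptions: the exacerbation-rate betas and the C->B
  ## transition cell carry decimal-shift misprints in the alpha
  ps <- base_params()
  for (arm in names(ps$starting))
    for (s in ps$stages) {
      sp <- ps$starting[[arm]]$specs[[s]]
      expect_lt(abs(dist_mean(sp) - ps$starting[[arm]]$point[[s]]), 0.02)
    }
  specs <- attr(ps$trans_intervention_year2, "specs")
  pts <- as.matrix(ps$trans_intervention_year2)
  for (nm in setdiff(names(specs), "C->B")) {
    ft <- strsplit(nm, "->", fixed = TRUE)[[1]]
    expect_lt(abs(dist_mean(specs[[nm]]) - pts[ft[1], ft[2]]), 0.02)
  }
  for (s in ps$stages)
    expect_lt(abs(dist_mean(ps$stage_params$utility_specs[[s]]) -
                    ps$stage_params$utilities[[s]]), 0.02)
  expect_lt(abs(dist_mean(ps$stage_params$disutility_spec) -
                  ps$stage_params$exac_disutility), 0.02)
})

test_that("stage costs follow the B/D-minus-decrement structure", {
  ps <- base_params()
  mc <- ps$stage_params$monthly_costs
  expect_equal(mc[["A"]], mc[["B"]] - 33.10)
  expect_equal(mc[["C"]], mc[["D"]] - 33.10)
  expect_true(all(mc >= 0))
})

test_that("parameter serialisation round-trips bit-exactly", {
  ps <- base_params()
  tmp <- tempfile(fileext = ".json")
  params_to_json(ps, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_identical(back$discount_rate_annual, ps$discount_rate_annual)
  expect_identical(unname(unlist(back$starting$intervention$point)),
                   unname(ps$starting$intervention$point))
  expect_identical(unname(unlist(back$exac_rates)), unname(ps$exac_rates))
  expect_identical(as.vector(back$trans_usual$matrix),
                   as.vector(unclass(ps$trans_usual)))
  dg <- params_digest(ps)
  expect_true(is.numeric(dg) && !anyNA(dg))
})
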