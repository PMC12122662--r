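#' Configuration for the synthetic trial-data generator
#'
#' The defaults mirror the scale and arm-level summaries of the
#' evaluated trial: 45 patients per arm, two GOLD stages with 87.8% of
#' patients in stage D, baseline EQ-5D around 0.53 (intervention) and
#' 0.49 (usual care) with the intervention's utility rising over
#' follow-up, NHS cost components summing to roughly 1060 vs 857 per six
#' months, and 0.128 vs 0.146 hospitalisations per six months.
#'
#' @param n_per_arm Patients per arm (>= 2).
#' @param n_sites Number of recruiting sites.
#' @param stage_d_share Proportion in GOLD stage D.
#' @param visit_means List with per-arm mean utility at months 0, 3, 6,
#'   9, 12.
#' @param sd_between,sd_within Between-patient (random intercept) and
#'   within-patient residual utility SDs.
#' @param cost_means List with per-arm mean six-month cost per category
#'   (GBP); generated per category per quarter and summed.
#' @param cost_cv Coefficient of variation of cost draws.
#' @param hosp_rate_6m Named vector of expected hospitalisations per six
#'   months per arm.
#' @param missing_prob Probability each post-baseline visit is missing.
#' @param monotone_dropout If `TRUE`, a missing visit implies all later
#'   visits missing.
#' @param death_prob_12m Probability of death within 12 months.
#' @param intervention_fixed_cost Fixed per-patient intervention cost
#'   added to arm costs in period 1 (default 181.29 over six months).
#' @return A `generator_config`.
#' @export
generator_config <- function(
    n_per_arm = 45L, n_sites = 4L, stage_d_share = 0.878,
    visit_means = list(
      intervention = c(0.529, 0.537, 0.587, 0.587, 0.587),
      usual_care = c(0.487, 0.463, 0.490, 0.490, 0.490)),
    sd_between = 0.18, sd_within = 0.12,
    cost_means = list(
      intervention = c(home_visits = 125.43, primary_care = 73.41,
                       ae_attendance = 34.37, pharmaceuticals = 212.53,
                       niv_rehab = 170.40, hospitalisation = 262.26),
      usual_care = c(home_visits = 0, primary_care = 51.16,
                     ae_attendance = 34.93, pharmaceuticals = 256.33,
                     niv_rehab = 133.89, hospitalisation = 380.38)),
    cost_cv = 1.2,
    hosp_rate_6m = c(intervention = 0.128, usual_care = 0.146),
    missing_prob = 0.10, monotone_dropout = FALSE,
    death_prob_12m = 0.02,
    intervention_fixed_cost = 181.29) {
  stopifnot(n_per_arm >= 2, n_sites >= 1)
  stopifnot_prob(stage_d_share, "stage_d_share")
  stopifnot_prob(missing_prob, "missing_prob")
  stopifnot_prob(death_prob_12m, "death_prob_12m")
  vm <- lapply(visit_means, function(v) {
    if (length(v) != 5) stop("visit_means need 5 entries (months 0-12)",
                             call. = FALSE)
    if (any(v < -0.594 | v > 1))
      stop("visit mean utilities outside the feasible range", call. = FALSE)
    v
  })
  structure(list(
    n_per_arm = as.integer(n_per_arm), n_sites = as.integer(n_sites),
    stage_d_share = stage_d_share, visit_means = vm,
    sd_between = sd_between, sd_within = sd_within,
    cost_means = cost_means, cost_cv = cost_cv,
    hosp_rate_6m = hosp_rate_6m, missing_prob = missing_prob,
    monotone_dropout = monotone_dropout, death_prob_12m = death_prob_12m,
    intervention_fixed_cost = intervention_fixed_cost),
    class = "generator_config")
}

#' Closed-form ground truth implied by a generator configuration
#'
#' Expectations of the quantities the estimation pipeline targets:
#' incremental 6-month QALYs (trapezoid of the configured visit means),
#' incremental 6-month NHS cost (category means plus the fixed
#' intervention cost) and incremental 6-month hospitalisations.
#'
#' @param config A [generator_config()].
#' @param horizon_months 6 (default) or 12.
#' @return Named list `d_qaly`, `d_cost`, `d_hosp` plus per-arm values.
#' @export
true_values <- function(config, horizon_months = 6L) {
  per <- horizon_months / 3
  months <- c(0, 3 * seq_len(per))
  ## utilities are clamped to [-0.594, 1] after the draw, so the exact
  ## per-visit mean is the clamped-normal mean, not the raw mean
  s <- sqrt(config$sd_between^2 + config$sd_within^2)
  clamp_mean <- function(mu, a = -0.594, b = 1) {
    al <- (a - mu) / s; be <- (b - mu) / s
    mu + s * (stats::dnorm(al) - stats::dnorm(be)) +
      (a - mu) * stats::pnorm(al) + (b - mu) * (1 - stats::pnorm(be))
  }
  q <- vapply(config$visit_means, function(v)
    qaly_auc(clamp_mean(v[seq_len(per + 1)]), months), numeric(1))
  cost <- vapply(names(config$cost_means), function(arm) {
    base <- sum(config$cost_means[[arm]]) * (horizon_months / 6)
    base + if (arm == "intervention") config$intervention_fixed_cost *
      (horizon_months / 6) else 0
  }, numeric(1))
  hosp <- config$hosp_rate_6m * (horizon_months / 6)
  list(d_qaly = unname(q["intervention"] - q["usual_care"]),
       d_cost = unname(cost["intervention"] - cost["usual_care"]),
       d_hosp = unname(hosp[["intervention"]] - hosp[["usual_care"]]),
       qaly = q, cost = cost, hosp = hosp)
}

#' Generate a synthetic patient-level trial dataset
#'
#' Utilities are drawn per visit around the configured arm means with a
#' shared patient-level random intercept (within-patient correlation) and
#' are truncated to the EQ-5D range; per-category quarterly costs come
#' from gamma draws; hospitalisations are Poisson counts; missingness is
#' applied after generation; deaths occur uniformly over follow-up and
#' censor later measurements.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A [trial_dataset()] with the generating config and
#'   [true_values()] attached as attributes.
#' @export
generate_trial <- function(config = generator_config(), seed = 1L) {
  arms <- c("usual_care", "intervention")
  n <- config$n_per_arm
  with_seed(seed, {
    rows <- lapply(arms, function(arm) {
      vm <- config$visit_means[[arm]]
      b <- stats::rnorm(n, 0, config$sd_between)
      eq <- sapply(1:5, function(j) {
        x <- vm[j] + b + stats::rnorm(n, 0, config$sd_within)
        pmin(pmax(x, -0.594), 1)
      })
      cats <- config$cost_means[[arm]]
      ## per category per quarter; gamma moment-matched to mean/cv
      cost_q <- matrix(0, n, 4)
      for (cm in cats) {
        if (cm <= 0) next
        mq <- cm / 2
        shape <- 1 / config$cost_cv^2
        cost_q <- cost_q + matrix(
          stats::rgamma(4 * n, shape = shape, scale = mq / shape), n, 4)
      }
      if (arm == "intervention")
        cost_q[, 1] <- cost_q[, 1] + config$intervention_fixed_cost
      hosp <- matrix(stats::rpois(4 * n, config$hosp_rate_6m[[arm]] / 2),
                     n, 4)
      died <- stats::runif(n) < config$death_prob_12m
      death_month <- ifelse(died, ceiling(stats::runif(n) * 12), NA)
      data.frame(
        arm = arm, age = round(stats::rnorm(n, 70, 8)),
        gender = sample(c("F", "M"), n, replace = TRUE),
        site = sample(paste0("S", seq_len(config$n_sites)), n,
                      replace = TRUE),
        gold_stage = ifelse(stats::runif(n) < config$stage_d_share,
                            "D", "B"),
        eq5d_m0 = eq[, 1], eq5d_m3 = eq[, 2], eq5d_m6 = eq[, 3],
        eq5d_m9 = eq[, 4], eq5d_m12 = eq[, 5],
        cost_p1 = cost_q[, 1], cost_p2 = cost_q[, 2],
        cost_p3 = cost_q[, 3], cost_p4 = cost_q[, 4],
        hosp_p1 = hosp[, 1], hosp_p2 = hosp[, 2], hosp_p3 = hosp[, 3],
        hosp_p4 = hosp[, 4],
        died = died, death_month = death_month,
        stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    d$id <- sprintf("P%04d", seq_len(nrow(d)))

    ## death censors later follow-up
    visit_months <- c(3, 6, 9, 12)
    for (j in seq_along(visit_months)) {
      gone <- d$died & !is.na(d$death_month) &
        d$death_month <= visit_months[j]
      d[gone, paste0("eq5d_m", visit_months[j])] <- NA
      d[gone, paste0("cost_p", j)] <- NA
      d[gone, paste0("hosp_p", j)] <- NA
    }
    ## missingness (optionally monotone)
    if (config$missing_prob > 0) {
      drop <- matrix(stats::runif(4 * nrow(d)) < config$missing_prob,
                     nrow(d), 4)
      if (config$monotone_dropout)
        drop <- t(apply(drop, 1, cummax)) > 0
      for (j in 1:4) {
        d[drop[, j], paste0("eq5d_m", visit_months[j])] <- NA
        d[drop[, j], paste0("cost_p", j)] <- NA
        d[drop[, j], paste0("hosp_p", j)] <- NA
      }
    }
    out <- trial_dataset(d)
    attr(out, "config") <- config
    attr(out, "truth") <- true_values(config)
    out
  })
}
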