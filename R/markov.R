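#' State space of the cohort model
#'
#' Living GOLD stages, three one-month post-discharge tunnel sub-states
#' per stage (entered after a hospitalised exacerbation, exiting to the
#' stage they are attached to), and one absorbing dead state.  Mass only
#' ever enters the tunnels of the landing stages, but tunnels are laid
#' out for every stage to keep indexing uniform.
#'
#' @param structure `"abcd"` or `"ace"`.
#' @return A list with `stages`, `states` (all state labels), `landing`,
#'   and index helpers.
#' @export
state_space <- function(structure = c("abcd", "ace")) {
  structure <- match.arg(structure)
  stages <- gold_stages(structure)
  land <- landing_stage(structure)
  tun <- as.vector(outer(1:3, stages, function(k, s) paste0("tun_", s, "_", k)))
  states <- c(stages, tun, "dead")
  list(structure = structure, stages = stages, landing = land,
       states = states,
       i_stage = stats::setNames(seq_along(stages), stages),
       i_tun = matrix(length(stages) + seq_len(3 * length(stages)),
                      nrow = 3, dimnames = list(1:3, stages)),
       i_dead = length(states))
}

## Per-arm, per-year model inputs resolved from a parameter set.
## Values enter as points unless the parameter set has been replaced by a
## PSA draw (see sample_params).  For the "ace" structure the high-risk
## stages C and D are pooled with fixed occupancy weights derived from
## the combined 12-month starting counts.
model_inputs <- function(params, arm = c("usual_care", "intervention"),
                         structure = c("abcd", "ace")) {
  arm <- match.arg(arm)
  structure <- match.arg(structure)
  n_years <- params$horizon_months / 12 - 1
  eff <- params$effects

  ## year-specific transition matrices and exacerbation rates (A-D space)
  mats <- vector("list", n_years)
  rates <- matrix(NA_real_, n_years, length(params$stages),
                  dimnames = list(NULL, params$stages))
  for (k in seq_len(n_years)) {
    if (arm == "usual_care") {
      mats[[k]] <- params$trans_usual
    } else {
      mats[[k]] <- adjust_matrix(params$trans_usual, eff$rr_by_year[k],
                                 params$beneficial_cells)
    }
    for (s in params$stages)
      rates[k, s] <- effective_exac_rate(s, k + 1L, arm, params$exac_rates,
                                         eff)
  }
  start <- params$starting[[arm]]$point
  util <- params$stage_params$utilities
  cost <- params$stage_params$monthly_costs
  disutil <- params$stage_params$exac_disutility
  if (!params$stage_params$disutility_per_month) disutil <- disutil / 3

  if (structure == "ace") {
    ## pooled weights: combined starting counts across arms, pseudo-counts
    ## (zero observed patients) contributing nothing
    cc <- starting_points_from_counts(params$starting$usual_care$alphas) +
      starting_points_from_counts(params$starting$intervention$alphas)
    w <- cc[c("C", "D")] / sum(cc[c("C", "D")])
    pool_vec <- function(v) c(v[["A"]], v[["B"]],
                              w[["C"]] * v[["C"]] + w[["D"]] * v[["D"]])
    pool_mat <- function(m) {
      m <- as.matrix(m)
      erow <- w[["C"]] * m["C", ] + w[["D"]] * m["D", ]
      out <- rbind(m[c("A", "B"), ], E = erow)
      out <- cbind(out[, c("A", "B")], E = out[, "C"] + out[, "D"])
      dimnames(out) <- list(c("A", "B", "E"), c("A", "B", "E"))
      out
    }
    mats <- lapply(mats, pool_mat)
    rates <- {
      r <- t(apply(rates, 1, pool_vec))
      colnames(r) <- c("A", "B", "E"); r
    }
    start <- stats::setNames(c(start[["A"]], start[["B"]],
                               start[["C"]] + start[["D"]]),
                             c("A", "B", "E"))
    util <- stats::setNames(pool_vec(util), c("A", "B", "E"))
    cost <- stats::setNames(pool_vec(cost), c("A", "B", "E"))
  } else {
    mats <- lapply(mats, as.matrix)
  }

  list(
    arm = arm,
    space = state_space(structure),
    start = start,
    mats = mats,
    exac = rates,
    death_on_admission = params$death_on_admission$point,
    adm_cost = admission_cost(arm,
      admission_cost = params$stage_params$admission_cost$point,
      bed_day_cost = params$stage_params$bed_day_cost$point,
      bed_day_reduction = eff$bed_day_reduction),
    utilities = util,
    monthly_costs = cost,
    disutility = disutil,
    int_monthly = if (arm == "intervention")
      params$stage_params$intervention_monthly_cost$point else 0,
    year1_cost = params$year1[[arm]]$cost$point,
    year1_qaly = params$year1[[arm]]$qaly$point,
    discount_rate_annual = params$discount_rate_annual,
    horizon = params$horizon_months)
}

#' One cycle of the cohort model
#'
#' Within a cycle, stage occupants first face the exacerbation draw: the
#' exacerbating fraction is admitted, a share dies on admission and the
#' survivors enter month 1 of the landing stage's tunnel; the remaining
#' occupants transition via the matrix.  Tunnel occupants advance one
#' month, exiting to their stage after month 3.  Mass is conserved.
#'
#' @param occ Occupancy vector over the full state space (sums to 1).
#' @param space A [state_space()].
#' @param mat Living-stage transition matrix (row-stochastic).
#' @param exac_rates Named monthly exacerbation probabilities per stage.
#' @param death_on_admission Probability of dying on admission.
#' @return List with `occ` (next occupancy), `admissions` (fraction newly
#'   admitted this cycle) and `deaths` (fraction dying this cycle).
#' @export
cycle_step <- function(occ, space, mat, exac_rates, death_on_admission) {
  stages <- space$stages
  new <- numeric(length(occ))
  names(new) <- space$states
  stage_occ <- occ[stages]
  ex <- stage_occ * exac_rates[stages]
  stay <- stage_occ - ex
  if (any(ex < -1e-12) || any(stay < -1e-12))
    stop("negative intermediate mass; invalid rates or occupancy",
         call. = FALSE)
  ## matrix transitions for non-exacerbators
  new[stages] <- as.vector(stay %*% mat[stages, stages])
  ## admissions: deaths and tunnel entries
  died <- sum(ex) * death_on_admission
  surv <- ex * (1 - death_on_admission)
  for (s in stages) {
    l <- space$landing[[s]]
    new[space$i_tun[1, l]] <- new[space$i_tun[1, l]] + surv[[s]]
  }
  ## tunnel progression
  for (s in stages) {
    new[space$i_tun[2, s]] <- new[space$i_tun[2, s]] + occ[space$i_tun[1, s]]
    new[space$i_tun[3, s]] <- new[space$i_tun[3, s]] + occ[space$i_tun[2, s]]
    new[s] <- new[s] + occ[space$i_tun[3, s]]
  }
  new[space$i_dead] <- occ[space$i_dead] + died
  list(occ = new, admissions = sum(ex), deaths = died)
}

#' Run the cohort model for one arm
#'
#' Cycles 1-12 carry the trial-derived year-1 accruals (spread uniformly,
#' undiscounted) with the cohort held at its 12-month starting
#' distribution; from cycle 13 the cohort evolves monthly under the arm's
#' transition matrices and exacerbation process.
#'
#' @param params A `parameter_set` (point values, or a PSA draw).
#' @param arm `"usual_care"` or `"intervention"`.
#' @param structure `"abcd"` (default) or `"ace"`.
#' @return A `cohort_trace`: occupancy matrix (cycles x states), per-cycle
#'   admissions, and the resolved inputs.
#' @export
run_cohort <- function(params, arm = c("usual_care", "intervention"),
                       structure = c("abcd", "ace")) {
  arm <- match.arg(arm)
  structure <- match.arg(structure)
  inp <- model_inputs(params, arm, structure)
  sp <- inp$space
  H <- inp$horizon
  ns <- length(sp$states)
  occ <- matrix(0, H, ns, dimnames = list(NULL, sp$states))
  admissions <- numeric(H)

  start_full <- numeric(ns)
  names(start_full) <- sp$states
  start_full[sp$stages] <- inp$start
  for (t in 1:12) occ[t, ] <- start_full

  cur <- start_full
  for (t in 13:H) {
    occ[t, ] <- cur
    yr <- ceiling(t / 12) - 1L          # model-year index 1..4
    step <- cycle_step(cur, sp, inp$mats[[yr]], inp$exac[yr, ],
                       inp$death_on_admission)
    admissions[t] <- step$admissions
    cur <- step$occ
    if (abs(sum(cur) - 1) > 1e-9)
      stop("cohort mass not conserved", call. = FALSE)
  }
  structure(list(occupancy = occ, admissions = admissions, inputs = inp),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  H <- nrow(x$occupancy)
  cat(sprintf("<cohort_trace> arm=%s, %d cycles, %d states\n",
              x$inputs$arm, H, ncol(x$occupancy)))
  cat(sprintf(" final: dead=%.3f, admissions total=%.3f\n",
              x$occupancy[H, "dead"], sum(x$admissions)))
  invisible(x)
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Cycles 1-12 take the trial-derived arm totals as given, undiscounted.
#' For cycle t > 12 the QALY increment is occupancy-weighted utility / 12
#' (tunnel occupants at their stage utility minus the post-discharge
#' disutility) and the cost increment is stage-membership cost plus
#' admission costs for new admissions plus, on the intervention arm, the
#' monthly intervention cost for the surviving cohort; both are scaled by
#' `(1 + r)^(-t/12)`.
#'
#' @param trace A [run_cohort()] trace.
#' @return List with per-cycle increment vectors (undiscounted and
#'   discounted) and `total_cost` / `total_qaly` (discounted).
#' @export
accrue <- function(trace) {
  inp <- trace$inputs
  sp <- inp$space
  H <- inp$horizon
  occ <- trace$occupancy
  r <- inp$discount_rate_annual

  u_states <- numeric(ncol(occ))
  names(u_states) <- sp$states
  u_states[sp$stages] <- inp$utilities
  c_states <- u_states * 0
  c_states[sp$stages] <- inp$monthly_costs
  for (s in sp$stages) {
    u_states[sp$i_tun[, s]] <- inp$utilities[[s]] - inp$disutility
    c_states[sp$i_tun[, s]] <- inp$monthly_costs[[s]]
  }

  qaly_u <- numeric(H)
  cost_u <- numeric(H)
  qaly_u[1:12] <- inp$year1_qaly / 12
  cost_u[1:12] <- inp$year1_cost / 12
  alive <- 1 - occ[, "dead"]
  idx <- 13:H
  qaly_u[idx] <- as.vector(occ[idx, , drop = FALSE] %*% u_states) / 12
  cost_u[idx] <- as.vector(occ[idx, , drop = FALSE] %*% c_states) +
    trace$admissions[idx] * inp$adm_cost + alive[idx] * inp$int_monthly
  disc <- discount_factor(seq_len(H), r)
  list(qaly_undiscounted = qaly_u, cost_undiscounted = cost_u,
       qaly_discounted = qaly_u * disc, cost_discounted = cost_u * disc,
       total_qaly = sum(qaly_u * disc), total_cost = sum(cost_u * disc))
}

#' Incremental cost-effectiveness summary
#'
#' @param cost_uc,qaly_uc Usual-care totals.
#' @param cost_int,qaly_int Intervention totals.
#' @param wtp_grid Willingness-to-pay values (GBP/QALY).
#' @return A `ce_result` with increments, ICER (or a dominance label when
#'   the ratio is not interpretable) and net monetary benefit per WTP.
#' @export
ce_result <- function(cost_uc, qaly_uc, cost_int, qaly_int,
                      wtp_grid = seq(0, 50000, 5000)) {
  dc <- cost_int - cost_uc
  dq <- qaly_int - qaly_uc
  eps <- 1e-12
  label <- if (abs(dc) < eps && abs(dq) < eps) "indifferent"
    else if (dq > eps && dc < -eps) "dominant"
    else if (dq < -eps && dc > eps) "dominated"
    else "icer"
  icer <- if (label == "icer" && abs(dq) > eps) dc / dq else NA_real_
  structure(list(
    arms = data.frame(arm = c("usual_care", "intervention"),
                      cost = c(cost_uc, cost_int),
                      qaly = c(qaly_uc, qaly_int)),
    inc_cost = dc, inc_effect = dq, icer = icer, dominance = label,
    wtp_grid = wtp_grid, nmb = wtp_grid * dq - dc), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  print(transform(x$arms, cost = round(cost, 2), qaly = round(qaly, 4)),
        row.names = FALSE)
  cat(sprintf(" incremental: cost %+0.2f, effect %+0.4f\n",
              x$inc_cost, x$inc_effect))
  if (x$dominance == "icer")
    cat(sprintf(" ICER: %0.0f per unit effect\n", x$icer))
  else cat(" dominance:", x$dominance, "\n")
  invisible(x)
}

#' Deterministic base-case cost-utility analysis
#'
#' Runs both arms of the cohort model at point values and summarises
#' incremental costs, QALYs, the ICER and net monetary benefit.
#'
#' @param params A `parameter_set`.
#' @param structure `"abcd"` or `"ace"`.
#' @return A `ce_result`.
#' @examples
#' \donttest{
#' ps <- load_parameters()
#' deterministic_cua(ps)
#' }
#' @export
deterministic_cua <- function(params, structure = c("abcd", "ace")) {
  structure <- match.arg(structure)
  res <- lapply(c("usual_care", "intervention"), function(arm)
    accrue(run_cohort(params, arm, structure)))
  ce_result(res[[1]]$total_cost, res[[1]]$total_qaly,
            res[[2]]$total_cost, res[[2]]$total_qaly,
            wtp_grid = params$wtp_grid)
}

#' Export a cohort trace as a tidy table
#'
#' @param trace A [run_cohort()] trace.
#' @return Data frame with one row per cycle and state.
#' @export
trace_to_df <- function(trace) {
  acc <- accrue(trace)
  H <- nrow(trace$occupancy)
  states <- colnames(trace$occupancy)
  data.frame(
    cycle = rep(seq_len(H), times = length(states)),
    state = rep(states, each = H),
    occupancy = as.vector(trace$occupancy),
    cost_inc = rep(acc$cost_discounted, times = length(states)),
    qaly_inc = rep(acc$qaly_discounted, times = length(states)),
    discounted = rep(seq_len(H) >= 13, times = length(states)))
}

#' Patient-level microsimulation oracle
#'
#' Simulates individual trajectories under exactly the per-cycle
#' probabilities and accrual rules of the cohort engine; the mean over
#' patients converges to the cohort result, providing an independent
#' cross-check.  Simulation is vectorised over patients.
#'
#' @param params A `parameter_set`.
#' @param arm `"usual_care"` or `"intervention"`.
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed (reproducible).
#' @param structure `"abcd"` or `"ace"`.
#' @return List with mean discounted `cost` and `qaly`, their Monte-Carlo
#'   standard errors, and `n`.
#' @export
microsim_oracle <- function(params, arm = c("usual_care", "intervention"),
                            n_patients = 10000L, seed = 1L,
                            structure = c("abcd", "ace")) {
  arm <- match.arg(arm)
  structure <- match.arg(structure)
  stopifnot(n_patients >= 1)
  inp <- model_inputs(params, arm, structure)
  sp <- inp$space
  H <- inp$horizon
  ns <- length(sp$states)
  n_stage <- length(sp$stages)
  i_dead <- sp$i_dead

  u_states <- numeric(ns); c_states <- numeric(ns)
  u_states[seq_len(n_stage)] <- inp$utilities
  c_states[seq_len(n_stage)] <- inp$monthly_costs
  for (s in seq_len(n_stage)) {
    u_states[sp$i_tun[, s]] <- inp$utilities[s] - inp$disutility
    c_states[sp$i_tun[, s]] <- inp$monthly_costs[s]
  }
  land_idx <- sp$i_stage[sp$landing[sp$stages]]
  disc <- discount_factor(seq_len(H), inp$discount_rate_annual)

  with_seed(seed, {
    state <- sample.int(n_stage, n_patients, replace = TRUE,
                        prob = inp$start)
    cost <- rep(inp$year1_cost, n_patients)    # months 1-12, undiscounted
    qaly <- rep(inp$year1_qaly, n_patients)
    cum_mats <- NULL
    for (t in 13:H) {
      yr <- ceiling(t / 12) - 1L
      ## accrual on state at start of cycle
      alive <- state != i_dead
      qaly <- qaly + u_states[state] / 12 * disc[t] * alive
      cost <- cost + (c_states[state] + inp$int_monthly * alive) * disc[t] *
        alive
      ## transition
      u <- stats::runif(n_patients)
      new_state <- state
      in_stage <- which(state <= n_stage)
      if (length(in_stage)) {
        s <- state[in_stage]
        ex <- u[in_stage] < inp$exac[yr, s]
        adm <- in_stage[ex]
        if (length(adm)) {
          cost[adm] <- cost[adm] + inp$adm_cost * disc[t]
          die <- stats::runif(length(adm)) < inp$death_on_admission
          new_state[adm[die]] <- i_dead
          lv <- adm[!die]
          new_state[lv] <- sp$i_tun[1, land_idx[state[lv]]]
        }
        mv <- in_stage[!ex]
        if (length(mv)) {
          ## renormalised matrix draw given no exacerbation is NOT applied:
          ## exacerbation and matrix moves are sequential, matching the
          ## cohort engine (non-exacerbators use the full matrix row)
          m <- inp$mats[[yr]]
          cum <- t(apply(m, 1, cumsum))
          v <- stats::runif(length(mv))
          sm <- state[mv]
          dest <- integer(length(mv))
          for (j in seq_len(n_stage)) {
            sel <- sm == j
            if (any(sel))
              dest[sel] <- findInterval(v[sel], cum[j, ],
                                        left.open = TRUE) + 1L
          }
          new_state[mv] <- pmin(dest, n_stage)
        }
      }
      in_tun <- which(state > n_stage & state < i_dead)
      if (length(in_tun)) {
        st <- state[in_tun]
        k <- (st - n_stage - 1L) %% 3L + 1L       # tunnel month
        sidx <- (st - n_stage - 1L) %/% 3L + 1L   # attached stage
        new_state[in_tun] <- ifelse(k == 3L, sidx, st + 1L)
      }
      state <- new_state
    }
    list(cost = mean(cost), qaly = mean(qaly),
         se_cost = stats::sd(cost) / sqrt(n_patients),
         se_qaly = stats::sd(qaly) / sqrt(n_patients),
         n = n_patients)
  })
}
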