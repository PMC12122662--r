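#' Validate a patient-level trial dataset
#'
#' Expected one row per patient with columns `id`, `arm`
#' (`"usual_care"`/`"intervention"`), `age`, `gender`, `site`,
#' `gold_stage` (`"B"`/`"D"`), EQ-5D utilities `eq5d_m0, eq5d_m3, eq5d_m6,
#' eq5d_m9, eq5d_m12` (missable except baseline), per-period NHS costs
#' `cost_p1..cost_p4`, per-period hospitalisation counts
#' `hosp_p1..hosp_p4` (periods end at months 3, 6, 9, 12) and a `died`
#' flag with `death_month`.  Patients returning no post-baseline data are
#' flagged `excluded_imputation` and never imputed.
#'
#' @param df Data frame as above.
#' @return The data frame with class `trial_dataset` and the exclusion
#'   flag added.
#' @export
trial_dataset <- function(df) {
  need <- c("id", "arm", "age", "gender", "site", "gold_stage",
            paste0("eq5d_m", c(0, 3, 6, 9, 12)),
            paste0("cost_p", 1:4), paste0("hosp_p", 1:4), "died")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trial dataset lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(df$eq5d_m0))
    stop("baseline EQ-5D must be present for all patients", call. = FALSE)
  if (!all(df$arm %in% c("usual_care", "intervention")))
    stop("arm must be 'usual_care' or 'intervention'", call. = FALSE)
  costs <- as.matrix(df[paste0("cost_p", 1:4)])
  if (any(costs < 0, na.rm = TRUE)) stop("costs must be nonnegative",
                                         call. = FALSE)
  hosp <- as.matrix(df[paste0("hosp_p", 1:4)])
  if (any(hosp < 0, na.rm = TRUE) ||
      any(hosp != round(hosp), na.rm = TRUE))
    stop("hospitalisation counts must be nonnegative integers",
         call. = FALSE)
  post <- cbind(as.matrix(df[paste0("eq5d_m", c(3, 6, 9, 12))]), costs, hosp)
  df$excluded_imputation <- rowSums(!is.na(post)) == 0
  class(df) <- c("trial_dataset", "data.frame")
  df
}

#' QALYs by the area-under-the-curve method
#'
#' Trapezoidal integration of EQ-5D utilities over time with linear
#' interpolation between measurements; the result is in year units.
#'
#' @param utilities Numeric utilities at each time (no missing values;
#'   impute first).
#' @param times Measurement times in months, strictly increasing, first
#'   at baseline.
#' @return QALYs accrued over the observation window.
#' @examples
#' qaly_auc(c(0.529, 0.537, 0.587), c(0, 3, 6))   # 0.274 to 3 d.p.
#' @export
qaly_auc <- function(utilities, times) {
  if (length(utilities) != length(times) || length(times) < 2)
    stop("need >= 2 paired observations", call. = FALSE)
  if (anyNA(utilities))
    stop("utilities contain missing values; impute before QALY calculation",
         call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  dt <- diff(times) / 12
  sum((utilities[-length(utilities)] + utilities[-1]) / 2 * dt)
}

## variables the chained-imputation engine cycles over, with each cost
## model additionally conditioning on the period's hospitalisations
imputable_vars <- function(horizon_months) {
  per <- seq_len(horizon_months / 3)
  list(eq5d = paste0("eq5d_m", 3 * per),
       cost = paste0("cost_p", per),
       hosp = paste0("hosp_p", per))
}

#' Chained multiple imputation of trial data
#'
#' Linear-regression multiple imputation by chained equations: each
#' incomplete variable is regressed on age, gender, site, COPD stage and
#' its neighbouring observations (hospitalisations enter each cost
#' model), then missing entries are replaced by the linear prediction
#' plus residual-scale Gaussian noise.  The point analysis uses the
#' arithmetic mean of the `n_imputations` estimates for each missing
#' value, following standard trial practice.  Patients flagged as having
#' returned no post-baseline data are never imputed.
#'
#' @param dataset A [trial_dataset()].
#' @param n_imputations Number of chained imputations (default 50).
#' @param seed Integer seed; identical seeds give identical output.
#' @param horizon_months 6 or 12, the analysis window.
#' @param n_cycles Chained-equation sweeps per imputation (default 5).
#' @return List of completed datasets, with the per-cell mean dataset in
#'   attribute `"pooled"`.
#' @export
impute_trial <- function(dataset, n_imputations = 50L, seed = 1L,
                         horizon_months = 6L, n_cycles = 5L) {
  stopifnot(inherits(dataset, "trial_dataset"))
  vars <- imputable_vars(horizon_months)
  all_vars <- unlist(vars)
  keep <- !dataset$excluded_imputation
  base_covs <- c("age", "gender", "site", "gold_stage")

  neighbours <- function(v) {
    grp <- if (v %in% vars$eq5d) vars$eq5d else
      if (v %in% vars$cost) vars$cost else vars$hosp
    i <- match(v, grp)
    nb <- grp[c(i - 1, i + 1)]
    nb <- nb[!is.na(nb)]
    if (v %in% vars$eq5d && i == 1) nb <- c("eq5d_m0", nb)
    extra <- if (v %in% vars$cost) vars$hosp[match(v, vars$cost)] else NULL
    c(nb, extra)
  }

  seeds <- derive_seeds(seed, n_imputations)
  bounds <- function(v, x) {
    if (startsWith(v, "eq5d")) pmin(pmax(x, -0.594), 1)
    else if (startsWith(v, "cost")) pmax(x, 0)
    else pmax(round(x), 0)
  }

  run_one <- function(sd_i) with_seed(sd_i, {
    d <- as.data.frame(dataset)
    miss <- lapply(all_vars, function(v) which(is.na(d[[v]]) & keep))
    names(miss) <- all_vars
    ## initialise with observed means
    for (v in all_vars)
      if (length(miss[[v]]))
        d[[v]][miss[[v]]] <- mean(d[[v]][keep], na.rm = TRUE)
    for (cyc in seq_len(n_cycles)) {
      for (v in all_vars) {
        idx <- miss[[v]]
        if (!length(idx)) next
        preds <- c(base_covs, "arm", neighbours(v))
        obs <- which(keep & !is.na(dataset[[v]]))
        if (length(obs) < length(preds) + 2)
          stop(sprintf("too few complete records to model '%s'", v),
               call. = FALSE)
        fml <- stats::reformulate(preds, response = v)
        fit <- stats::lm(fml, data = d[obs, , drop = FALSE])
        sig <- sqrt(max(mean(stats::residuals(fit)^2), 1e-12))
        pr <- stats::predict(fit, newdata = d[idx, , drop = FALSE])
        d[[v]][idx] <- bounds(v, pr + stats::rnorm(length(idx), 0, sig))
      }
    }
    d
  })

  out <- lapply(seeds, run_one)
  pooled <- out[[1]]
  if (n_imputations > 1)
    for (v in all_vars) {
      vals <- vapply(out, function(d) d[[v]], numeric(nrow(pooled)))
      pooled[[v]] <- rowMeans(vals)
      pooled[[v]] <- bounds(v, pooled[[v]])
    }
  class(pooled) <- class(dataset)
  attr(out, "pooled") <- pooled
  out
}

## per-patient analysis outcomes over the horizon
patient_outcomes <- function(d, horizon_months = 6L,
                             include_deaths = FALSE) {
  per <- seq_len(horizon_months / 3)
  months <- c(0, 3 * per)
  eq <- as.matrix(d[paste0("eq5d_m", months)])
  qaly <- apply(eq, 1, function(u)
    if (anyNA(u)) NA_real_ else qaly_auc(u, months))
  cost <- rowSums(as.matrix(d[paste0("cost_p", per)]))
  hosp <- rowSums(as.matrix(d[paste0("hosp_p", per)]))
  out <- data.frame(d[c("id", "arm", "age", "gender", "site", "gold_stage")],
                    eq5d_m0 = d$eq5d_m0, qaly = qaly, cost = cost,
                    hosp = hosp, died = d$died)
  if (!include_deaths) out <- out[!out$died, , drop = FALSE]
  out[stats::complete.cases(out[c("qaly", "cost", "hosp")]), , drop = FALSE]
}

## joint two-equation fit; with a common covariate set the SUR estimator
## coincides with equation-by-equation least squares, so coefficients come
## from lm and the cross-equation residual correlation is reported
sur_fit <- function(po, effect = c("qaly", "hospitalisations")) {
  effect <- match.arg(effect)
  po$arm <- factor(po$arm, levels = c("usual_care", "intervention"))
  covs <- c("age", "gender", "site", "gold_stage")
  covs <- covs[vapply(covs, function(v) length(unique(po[[v]])) > 1,
                      logical(1))]
  X <- stats::model.matrix(
    stats::reformulate(c("arm", covs)), data = po)
  if (qr(X)$rank < ncol(X)) {
    alias <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("collinear covariates: ", paste(alias, collapse = ", "),
         call. = FALSE)
  }
  eff_col <- if (effect == "qaly") po$qaly else -po$hosp  # averted = gain
  Xe <- if (effect == "qaly" && stats::sd(po$eq5d_m0) > 1e-12)
    cbind(X, eq5d_m0 = po$eq5d_m0) else X
  fit_c <- stats::lm.fit(X, po$cost)
  fit_e <- stats::lm.fit(Xe, eff_col)
  se_of <- function(fit, M) {
    s2 <- sum(fit$residuals^2) / fit$df.residual
    sqrt(diag(chol2inv(qr.R(fit$qr)) * s2))
  }
  i_c <- match("armintervention", colnames(X))
  i_e <- match("armintervention", colnames(Xe))
  list(d_cost = unname(fit_c$coefficients[i_c]),
       d_effect = unname(fit_e$coefficients[i_e]),
       se_cost = se_of(fit_c)[i_c],
       se_effect = se_of(fit_e)[i_e],
       resid_cor = stats::cor(fit_c$residuals, fit_e$residuals),
       n = nrow(po))
}

#' Covariate-adjusted incremental cost and effect
#'
#' Cost and effect equations estimated jointly on treatment arm plus
#' baseline covariates (age, gender, site, COPD stage; baseline EQ-5D
#' additionally in the QALY equation).  The arm coefficients are the
#' adjusted increments.  Deceased patients are excluded by default.
#'
#' @param dataset A completed [trial_dataset()] (no missing analysis
#'   values) or the pooled output of [impute_trial()].
#' @param effect `"qaly"` or `"hospitalisations"` (hospitalisations
#'   averted count as gains).
#' @param horizon_months 6 or 12.
#' @param include_deaths Include deceased patients (sensitivity switch).
#' @return List with `d_cost`, `d_effect`, standard errors, residual
#'   correlation and `n`.
#' @export
adjusted_incrementals <- function(dataset,
                                  effect = c("qaly", "hospitalisations"),
                                  horizon_months = 6L,
                                  include_deaths = FALSE) {
  effect <- match.arg(effect)
  po <- patient_outcomes(dataset, horizon_months, include_deaths)
  sur_fit(po, effect)
}

#' Bootstrap cost-effectiveness analysis
#'
#' Patient-level non-parametric bootstrap, resampling with replacement
#' within arm (arm sizes preserved), re-estimating the covariate-adjusted
#' increments in each replicate.  The ICER is the ratio of mean replicate
#' increments; the probability of cost-effectiveness at willingness to
#' pay `lambda` is the fraction of replicates with positive incremental
#' net monetary benefit `lambda * dE - dC`.
#'
#' @param dataset A completed [trial_dataset()].
#' @param n_reps Bootstrap replicates (>= 100; default 5000).
#' @param wtp_grid Willingness-to-pay grid (GBP per effect unit).
#' @param effect `"qaly"` or `"hospitalisations"`.
#' @param seed Integer seed.
#' @param horizon_months 6 or 12.
#' @param include_deaths Passed to the adjustment.
#' @return A `boot_ce` with replicate draws, point estimates, ICER and
#'   the CEAC.
#' @export
bootstrap_cea <- function(dataset, n_reps = 5000L,
                          wtp_grid = seq(0, 50000, 2500),
                          effect = c("qaly", "hospitalisations"),
                          seed = 1L, horizon_months = 6L,
                          include_deaths = FALSE) {
  effect <- match.arg(effect)
  if (n_reps < 100) stop("n_reps below 100 gives unstable probabilities",
                         call. = FALSE)
  po <- patient_outcomes(dataset, horizon_months, include_deaths)
  point <- sur_fit(po, effect)
  arms <- split(seq_len(nrow(po)), po$arm)
  reps <- with_seed(seed, {
    t(vapply(seq_len(n_reps), function(i) {
      idx <- unlist(lapply(arms, function(a)
        a[sample.int(length(a), length(a), replace = TRUE)]))
      f <- tryCatch(sur_fit(po[idx, , drop = FALSE], effect),
                    error = function(e) NULL)
      if (is.null(f)) c(NA_real_, NA_real_) else c(f$d_cost, f$d_effect)
    }, numeric(2)))
  })
  colnames(reps) <- c("d_cost", "d_effect")
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  mdc <- mean(reps[, "d_cost"]); mde <- mean(reps[, "d_effect"])
  ceac <- vapply(wtp_grid, function(l)
    mean(l * reps[, "d_effect"] - reps[, "d_cost"] > 0), numeric(1))
  structure(list(
    effect = effect, replicates = as.data.frame(reps),
    point = point,
    boot_mean = c(d_cost = mdc, d_effect = mde),
    icer = if (abs(mde) > 1e-12) mdc / mde else NA_real_,
    dominance = if (mde > 0 && mdc < 0) "dominant"
      else if (mde < 0 && mdc > 0) "dominated" else "icer",
    wtp_grid = wtp_grid, ceac = ceac, n_reps = nrow(reps)),
    class = "boot_ce")
}

#' @export
print.boot_ce <- function(x, ...) {
  cat(sprintf("<boot_ce> effect=%s, %d replicates\n", x$effect, x$n_reps))
  cat(sprintf(" adjusted increments: cost %+0.2f (SE %.2f), effect %+0.4f (SE %.4f)\n",
              x$point$d_cost, x$point$se_cost, x$point$d_effect,
              x$point$se_effect))
  if (x$dominance == "icer")
    cat(sprintf(" ICER %0.0f; P(CE) at 20k = %.2f, at 30k = %.2f\n",
                x$icer, x$ceac[which.min(abs(x$wtp_grid - 20000))],
                x$ceac[which.min(abs(x$wtp_grid - 30000))]))
  invisible(x)
}

#' Cost per hospitalisation averted
#'
#' [bootstrap_cea()] with hospitalisations averted as the effect measure.
#'
#' @inheritParams bootstrap_cea
#' @return A `boot_ce`.
#' @export
hospitalisation_cea <- function(dataset, n_reps = 5000L, seed = 1L,
                                wtp_grid = seq(0, 50000, 2500),
                                horizon_months = 6L) {
  bootstrap_cea(dataset, n_reps = n_reps, wtp_grid = wtp_grid,
                effect = "hospitalisations", seed = seed,
                horizon_months = horizon_months)
}
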