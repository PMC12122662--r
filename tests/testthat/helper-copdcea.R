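## shared fixtures, built in code

# packaged base case, loaded once (default-fill messages silenced)
base_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(load_parameters())
    cache
  }
})

# parameter set with every sampling distribution pinned to a point value;
# starting-state spec points are pinned to the count-based proportions so
# a degenerate PSA reproduces the deterministic run exactly
fix_all_specs <- function(ps) {
  fix <- function(sp) { sp$family <- "fixed"; sp }
  ps$effects$rr_spec <- fix(ps$effects$rr_spec)
  ps$effects$bed_spec <- fix(ps$effects$bed_spec)
  attr(ps$trans_usual, "specs") <-
    lapply(attr(ps$trans_usual, "specs"), fix)
  for (a in names(ps$starting)) {
    ps$starting[[a]]$specs <- lapply(names(ps$starting[[a]]$specs),
      function(s) {
        sp <- fix(ps$starting[[a]]$specs[[s]])
        sp$point <- ps$starting[[a]]$point[[s]]
        sp
      })
    names(ps$starting[[a]]$specs) <- ps$stages
  }
  ps$stage_params$utility_specs <-
    lapply(ps$stage_params$utility_specs, fix)
  ps$stage_params$disutility_spec <- fix(ps$stage_params$disutility_spec)
  ps$exac_specs <- lapply(ps$exac_specs, fix)
  ps$death_on_admission <- fix(ps$death_on_admission)
  ps$stage_params$cost_specs <- lapply(ps$stage_params$cost_specs, fix)
  ps$stage_params$admission_cost <- fix(ps$stage_params$admission_cost)
  ps$stage_params$bed_day_cost <- fix(ps$stage_params$bed_day_cost)
  ps$stage_params$intervention_monthly_cost <-
    fix(ps$stage_params$intervention_monthly_cost)
  for (a in names(ps$year1)) {
    ps$year1[[a]]$cost <- fix(ps$year1[[a]]$cost)
    ps$year1[[a]]$qaly <- fix(ps$year1[[a]]$qaly)
  }
  ps
}

# hand-made minimal psa_output for the VoI operations
toy_psa <- function(cost_uc, cost_int, qaly_uc = NULL, qaly_int = NULL) {
  n <- length(cost_uc)
  qaly_uc <- qaly_uc %||% rep(0, n)
  qaly_int <- qaly_int %||% rep(0, n)
  structure(list(
    cost = cbind(usual_care = cost_uc, intervention = cost_int),
    qaly = cbind(usual_care = qaly_uc, intervention = qaly_int),
    params = matrix(numeric(0), n, 0),
    n_iter = n, seed = 0L, structure = "abcd", resamples = 0L,
    wtp_grid = seq(0, 50000, 10000)), class = "psa_output")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
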