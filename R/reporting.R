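#' End-to-end analysis run
#'
#' Orchestrates the full evaluation: synthetic trial generation (or a
#' user-supplied patient-level CSV), within-trial cost-utility and
#' cost-per-hospitalisation-averted analyses, the deterministic 5-year
#' cohort model, probabilistic sensitivity analysis and value of
#' information.  Publication-style summary tables, the CE-plane scatter,
#' CEAC and EVPI curve are written as CSV/JSON (and optionally PNG), and
#' a run manifest records the configuration hash, seeds and every output
#' file.
#'
#' All randomness flows from the single `seed`.  Simulation sizes default
#' to publication scale; reduce `n_psa`/`n_boot` for smoke runs.
#'
#' @param config_path Model configuration JSON (packaged default).
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed.
#' @param trial_data Optional patient-level data frame or CSV path; if
#'   `NULL` a synthetic trial is generated.
#' @param structure `"abcd"` or `"ace"`.
#' @param n_psa PSA iterations (default 10000).
#' @param n_boot Bootstrap replicates (default 5000).
#' @param n_imputations Chained imputations (default 50).
#' @param plots Write PNG figures (default `TRUE`).
#' @return A `run_manifest` (invisibly the same list written to
#'   `manifest.json`).
#' @export
run_all <- function(config_path = default_config_path(), out_dir,
                    seed = 1L, trial_data = NULL,
                    structure = c("abcd", "ace"),
                    n_psa = 10000L, n_boot = 5000L, n_imputations = 50L,
                    plots = TRUE) {
  structure <- match.arg(structure)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 4L)
  outputs <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  emit_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, name)
  }
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    outputs <<- c(outputs, name)
  }
  emit_png <- function(name, fun) {
    if (!plots) return(invisible())
    path <- file.path(out_dir, name)
    grDevices::png(path, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    fun()
    outputs <<- c(outputs, name)
  }

  params <- stage("parameters", load_parameters(config_path))
  stage("parameters", params_to_json(params,
    file.path(out_dir, "parameter_set.json")))
  outputs <- c(outputs, "parameter_set.json")

  emit_csv(intervention_cost_breakdown(params$costing),
           "intervention_costing.csv")

  dataset <- stage("trial_data", {
    if (is.null(trial_data)) {
      generate_trial(generator_config(), seed = seeds[1])
    } else if (is.character(trial_data)) {
      trial_dataset(utils::read.csv(trial_data, stringsAsFactors = FALSE))
    } else trial_dataset(trial_data)
  })
  emit_csv(as.data.frame(dataset), "trial_data.csv")

  trial <- stage("trial_cea", {
    imp <- impute_trial(dataset, n_imputations = n_imputations,
                        seed = seeds[2])
    pooled <- attr(imp, "pooled")
    cua <- bootstrap_cea(pooled, n_reps = n_boot, seed = seeds[3],
                         wtp_grid = params$wtp_grid)
    cea <- hospitalisation_cea(pooled, n_reps = n_boot, seed = seeds[3],
                               wtp_grid = params$wtp_grid)
    list(pooled = pooled, cua = cua, cea = cea)
  })
  emit_csv(trial$cua$replicates, "trial_ce_plane.csv")
  emit_csv(data.frame(wtp = trial$cua$wtp_grid, p_ce = trial$cua$ceac),
           "trial_ceac.csv")
  emit_json(list(
    cost_utility = list(
      d_qaly = trial$cua$point$d_effect, d_cost = trial$cua$point$d_cost,
      se_qaly = trial$cua$point$se_effect, se_cost = trial$cua$point$se_cost,
      icer = trial$cua$icer,
      p_ce_20k = trial$cua$ceac[which.min(abs(trial$cua$wtp_grid - 20000))]),
    cost_effectiveness = list(
      d_hosp_averted = trial$cea$point$d_effect,
      d_cost = trial$cea$point$d_cost, icer = trial$cea$icer)),
    "trial_summary.json")

  det <- stage("deterministic_model", deterministic_cua(params, structure))
  emit_json(list(arms = det$arms, inc_cost = det$inc_cost,
                 inc_qaly = det$inc_effect, icer = det$icer,
                 dominance = det$dominance),
            "model_base_case.json")
  tr <- run_cohort(params, "intervention", structure)
  emit_csv(trace_to_df(tr), "trace_intervention.csv")

  psa <- stage("psa", run_psa(params, n_iter = n_psa, seed = seeds[4],
                              structure = structure))
  dc <- psa$cost[, 2] - psa$cost[, 1]
  dq <- psa$qaly[, 2] - psa$qaly[, 1]
  emit_csv(data.frame(d_cost = dc, d_qaly = dq), "model_ce_plane.csv")
  cc <- ceac(psa)
  emit_csv(cc, "model_ceac.csv")
  lam <- params$wtp_grid
  ev <- evpi(psa, lam)
  emit_csv(data.frame(wtp = lam, evpi = ev,
                      population_evpi = population_voi(ev,
                        params$population_eligible)),
           "evpi_curve.csv")

  emit_png("ce_plane.png", function() {
    graphics::plot(dq, dc, pch = 16, cex = 0.4, col = "grey40",
         xlab = "Incremental QALYs", ylab = "Incremental cost (GBP)",
         main = "Cost-utility plane (PSA)")
    graphics::abline(h = 0, v = 0, lty = 2)
    graphics::abline(a = 0, b = 20000, col = "red3")
  })
  emit_png("ceac.png", function() {
    graphics::plot(cc$wtp, cc$p_ce, type = "b", pch = 16, ylim = c(0, 1),
         xlab = "Willingness to pay (GBP/QALY)",
         ylab = "P(cost-effective)", main = "CEAC")
    graphics::abline(v = c(20000, 30000), lty = 3)
  })
  emit_png("evpi.png", function() {
    graphics::plot(lam, ev, type = "b", pch = 16,
         xlab = "Willingness to pay (GBP/QALY)",
         ylab = "EVPI per patient (GBP)", main = "EVPI")
  })

  manifest <- structure(list(
    config = config_path,
    config_md5 = unname(tools::md5sum(config_path)),
    structure = structure,
    seed = seed, stage_seeds = seeds,
    n_psa = n_psa, n_boot = n_boot, n_imputations = n_imputations,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    default_filled = params$default_filled,
    outputs = outputs), class = "run_manifest")
  emit_json(unclass(manifest)[names(manifest) != "timestamp"],
            "manifest.json")
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed=%d, %d outputs, config md5 %s\n",
              x$seed, length(x$outputs), x$config_md5))
  invisible(x)
}
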