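#' GOLD stage labels for a model structure
#'
#' The base structure uses the four GOLD 2017 groups A-D
#' (A low risk / fewer symptoms, B low risk / more symptoms,
#' C high risk / fewer symptoms, D high risk / more symptoms).
#' The variant structure follows the newer classification in which the
#' high-risk groups C and D are merged into a single group E.
#'
#' @param structure `"abcd"` (default) or `"ace"`.
#' @return Character vector of living-stage labels.
#' @export
gold_stages <- function(structure = c("abcd", "ace")) {
  structure <- match.arg(structure)
  if (structure == "abcd") c("A", "B", "C", "D") else c("A", "B", "E")
}

#' Post-discharge landing stage after a hospitalised exacerbation
#'
#' GOLD membership is partly admission-defined, so a hospitalised
#' exacerbation moves low-risk patients into the corresponding high-risk
#' stage: A to C and B to D (A or B to E in the merged structure);
#' high-risk patients remain where they are.
#'
#' @param structure `"abcd"` or `"ace"`.
#' @return Named character vector mapping each stage to its landing stage.
#' @export
landing_stage <- function(structure = c("abcd", "ace")) {
  structure <- match.arg(structure)
  if (structure == "abcd") c(A = "C", B = "D", C = "C", D = "D")
  else c(A = "E", B = "E", E = "E")
}

#' Construct and validate a monthly transition matrix
#'
#' Off-diagonal cells hold move probabilities; the diagonal is the
#' residual stay probability filling each row to 1.  Rows whose
#' off-diagonal sum exceeds 1 are rejected.
#'
#' @param offdiag Square numeric matrix (dimnames = stages) with zero
#'   diagonal, holding monthly move probabilities.
#' @param specs Optional named list of [dist_spec()]s, names `"A->B"` etc.,
#'   used when the matrix is sampled in PSA.
#' @return A `transition_matrix`: the row-stochastic point matrix with
#'   `specs` attached as an attribute.
#' @export
transition_matrix <- function(offdiag, specs = NULL) {
  stages <- rownames(offdiag)
  if (is.null(stages) || !identical(stages, colnames(offdiag)))
    stop("transition matrix needs matching stage dimnames", call. = FALSE)
  if (any(diag(offdiag) != 0))
    stop("supply off-diagonal moves only; the diagonal is residual-filled",
         call. = FALSE)
  if (any(offdiag < 0) || any(offdiag > 1))
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  rs <- rowSums(offdiag)
  if (any(rs > 1 + 1e-12)) {
    bad <- stages[which.max(rs)]
    stop(sprintf("off-diagonal row sum exceeds 1 for row '%s' (%.4f)",
                 bad, max(rs)), call. = FALSE)
  }
  m <- offdiag
  diag(m) <- 1 - rs
  structure(m, specs = specs, class = c("transition_matrix", "matrix", "array"))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> monthly, rows sum to 1\n")
  print(unclass(x)[,, drop = FALSE])
  invisible(x)
}

## Point starting-state proportions from beta count parameters.
## Alphas at the pseudo-count floor represent zero observed patients and
## contribute a zero count; the remaining alphas are trial counts, so the
## printed proportions are counts over the total patient number.
starting_points_from_counts <- function(alphas, pseudo = 0.05) {
  counts <- ifelse(alphas <= pseudo + 1e-12, 0, alphas)
  counts / sum(counts)
}

#' Path to the packaged base-case configuration
#' @return File path of the default JSON configuration.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.json", package = "copdcea",
              mustWork = TRUE)
}

#' Load and validate a model configuration
#'
#' Reads a JSON configuration holding every model input (starting-state
#' proportions with beta parameters, transition matrices, exacerbation
#' rates, treatment effects, utilities, costs, first-year trial accruals,
#' intervention costing items) and returns a validated `parameter_set`.
#' Optional keys (`death_on_admission`, the usual-care transition matrix)
#' are default-filled with a logged warning; everything else is mandatory.
#'
#' @param config_path Path to a JSON configuration file; defaults to the
#'   packaged base case.
#' @return A `parameter_set` object.
#' @examples
#' ps <- load_parameters()
#' ps$starting$usual_care$point[["D"]]   # 0.870
#' @export
load_parameters <- function(config_path = default_config_path()) {
  if (!file.exists(config_path))
    stop(sprintf("config file '%s' not found", config_path), call. = FALSE)
  cfg <- jsonlite::read_json(config_path, simplifyVector = FALSE)

  need <- function(key) {
    if (is.null(cfg[[key]]))
      stop(sprintf("config field '%s' is missing", key), call. = FALSE)
    cfg[[key]]
  }
  num <- function(x, key) {
    x <- unlist(x)
    if (!is.numeric(x)) stop(sprintf("config field '%s' must be numeric", key),
                             call. = FALSE)
    x
  }

  stages <- c("A", "B", "C", "D")
  horizon <- num(need("horizon_months"), "horizon_months")
  if (horizon %% 12 != 0)
    stop("horizon_months must be divisible by 12", call. = FALSE)
  disc <- num(need("discount_rate_annual"), "discount_rate_annual")
  wtp <- num(need("wtp_grid"), "wtp_grid")

  ## --- starting states -------------------------------------------------
  st_cfg <- need("starting_states")
  pseudo <- st_cfg$pseudo_alpha %||% 0.05
  starting <- lapply(c(usual_care = "usual_care", intervention = "intervention"),
    function(arm) {
      entries <- st_cfg[[arm]]
      if (is.null(entries)) stop(sprintf("starting_states.%s missing", arm),
                                 call. = FALSE)
      alphas <- vapply(stages, function(s) num(entries[[s]]$alpha,
        sprintf("starting_states.%s.%s.alpha", arm, s)), numeric(1))
      betas <- vapply(stages, function(s) num(entries[[s]]$beta,
        sprintf("starting_states.%s.%s.beta", arm, s)), numeric(1))
      point <- starting_points_from_counts(alphas, pseudo)
      if (abs(sum(point) - 1) > 1e-9)
        stop(sprintf("starting proportions for arm '%s' do not sum to 1", arm),
             call. = FALSE)
      specs <- mapply(function(a, b) dist_spec("beta", point = a / (a + b),
                                               alpha = a, beta = b,
                                               lower = 0, upper = 1),
                      alphas, betas, SIMPLIFY = FALSE)
      names(specs) <- stages
      list(point = point, alphas = alphas, specs = specs)
    })

  ## --- transition matrices --------------------------------------------
  tr_cfg <- need("transitions")
  int_cfg <- tr_cfg$intervention_year2
  if (is.null(int_cfg)) stop("transitions.intervention_year2 missing",
                             call. = FALSE)
  off <- matrix(0, 4, 4, dimnames = list(stages, stages))
  tspecs <- list()
  for (from in stages) for (to in setdiff(stages, from)) {
    cell <- int_cfg[[from]][[to]]
    if (is.null(cell))
      stop(sprintf("transition cell %s->%s missing", from, to), call. = FALSE)
    sp <- spec_from_config(cell, "probability", sprintf("trans %s->%s", from, to))
    off[from, to] <- sp$point
    tspecs[[paste0(from, "->", to)]] <- sp
  }
  trans_int_y2 <- transition_matrix(off, specs = tspecs)

  ben_raw <- tr_cfg$beneficial_cells %||%
    list(c("A", "B"), c("A", "D"), c("C", "B"), c("C", "D"))
  beneficial <- do.call(rbind, lapply(ben_raw, function(p)
    data.frame(from = p[[1]], to = p[[2]], stringsAsFactors = FALSE)))

  filled <- character()
  eff_cfg <- need("treatment_effect")
  rr_spec <- spec_from_config(eff_cfg$base_rr_year2, "rr", "base_rr_year2")
  decay <- num(eff_cfg$decay %||% 0.5, "treatment_effect.decay")

  if (is.null(tr_cfg$usual_care)) {
    ## back-derive: the packaged intervention year-2 matrix already has the
    ## beneficial cells scaled by the year-2 RR, so divide them back out.
    trans_uc <- adjust_matrix(trans_int_y2, rr = 1 / rr_spec$point,
                              beneficial_cells = beneficial)
    attr(trans_uc, "specs") <- tspecs
    filled <- c(filled,
      "usual-care transition matrix back-derived from the intervention year-2 matrix (placeholder, not ground truth)")
  } else {
    off_uc <- matrix(0, 4, 4, dimnames = list(stages, stages))
    for (from in stages) for (to in setdiff(stages, from)) {
      cell <- tr_cfg$usual_care[[from]][[to]]
      if (is.null(cell))
        stop(sprintf("usual-care transition cell %s->%s missing", from, to),
             call. = FALSE)
      off_uc[from, to] <- spec_from_config(cell, "probability",
        sprintf("uc trans %s->%s", from, to))$point
    }
    trans_uc <- transition_matrix(off_uc, specs = tspecs)
  }

  ## --- exacerbations ---------------------------------------------------
  ex_cfg <- need("exacerbations")
  exac_specs <- lapply(stages, function(s)
    spec_from_config(ex_cfg$rates[[s]], "rate", sprintf("exac rate %s", s)))
  names(exac_specs) <- stages
  ## printed means drive the deterministic base case; the printed
  ## alpha/beta pairs (internally inconsistent with the means) drive PSA
  exac_rates <- vapply(stages, function(s)
    num(ex_cfg$rates[[s]]$point, sprintf("exac rate %s", s)), numeric(1))
  effect_stages <- unlist(ex_cfg$effect_stages %||% list("B", "D"))
  reduction <- num(ex_cfg$reduction_schedule %||% c(0.12, 0.06, 0.03, 0.015),
                   "reduction_schedule")
  if (any(diff(reduction) > 0))
    stop("exacerbation reduction schedule must be non-increasing", call. = FALSE)

  bed_spec <- spec_from_config(eff_cfg$bed_day_reduction, "other",
                               "bed_day_reduction")

  ## --- stage parameters ------------------------------------------------
  sp_cfg <- need("stage_params")
  util_specs <- lapply(stages, function(s)
    spec_from_config(sp_cfg$utilities[[s]], "utility", sprintf("utility %s", s)))
  names(util_specs) <- stages
  utilities <- vapply(util_specs, function(s) s$point, numeric(1))
  if (any(utilities < -0.594 | utilities > 1))
    stop("stage utilities must lie in [-0.594, 1]", call. = FALSE)
  disutil_spec <- spec_from_config(sp_cfg$exac_disutility, "probability",
                                   "exac_disutility")

  cost_b <- spec_from_config(sp_cfg$monthly_costs$B, "cost", "cost B")
  cost_d <- spec_from_config(sp_cfg$monthly_costs$D, "cost", "cost D")
  decr <- spec_from_config(sp_cfg$monthly_costs$ac_decrement, "cost",
                           "cost A/C decrement")
  monthly_costs <- c(A = cost_b$point - decr$point, B = cost_b$point,
                     C = cost_d$point - decr$point, D = cost_d$point)
  if (any(monthly_costs < 0)) stop("negative stage cost", call. = FALSE)

  stage_params <- list(
    utilities = utilities, utility_specs = util_specs,
    exac_disutility = disutil_spec$point, disutility_spec = disutil_spec,
    disutility_per_month = isTRUE(sp_cfg$exac_disutility_per_month %||% TRUE),
    monthly_costs = monthly_costs,
    cost_specs = list(B = cost_b, D = cost_d, ac_decrement = decr),
    admission_cost = spec_from_config(sp_cfg$admission_cost, "cost",
                                      "admission_cost"),
    bed_day_cost = spec_from_config(sp_cfg$bed_day_cost, "cost",
                                    "bed_day_cost"),
    intervention_monthly_cost = spec_from_config(
      sp_cfg$intervention_monthly_cost, "cost", "intervention_monthly_cost"))

  ## --- first-year trial accruals --------------------------------------
  y1_cfg <- need("year1")
  year1 <- lapply(c(usual_care = "usual_care", intervention = "intervention"),
    function(arm) list(
      cost = spec_from_config(y1_cfg[[arm]]$cost, "cost",
                              sprintf("year1.%s.cost", arm)),
      qaly = spec_from_config(y1_cfg[[arm]]$qaly, "other",
                              sprintf("year1.%s.qaly", arm))))

  ## --- optional keys ---------------------------------------------------
  if (is.null(cfg$death_on_admission)) {
    death_spec <- dist_spec("beta", point = 0.05, alpha = 5, beta = 95,
                            lower = 0, upper = 1)
    filled <- c(filled,
      "death_on_admission defaulted to placeholder 0.05 (beta(5, 95)); source estimates are not in the public domain")
    warning("death_on_admission missing from config; using placeholder 0.05",
            call. = FALSE)
  } else {
    death_spec <- spec_from_config(cfg$death_on_admission, "probability",
                                   "death_on_admission")
  }

  effects <- treatment_effect_schedule(
    base_rr_year2 = rr_spec$point, decay = decay,
    n_years = horizon / 12 - 1,
    exac_reduction_schedule = reduction,
    bed_day_reduction = bed_spec$point,
    effect_stages = effect_stages)
  effects$rr_spec <- rr_spec
  effects$bed_spec <- bed_spec

  ps <- structure(list(
    stages = stages,
    structure = "abcd",
    starting = starting,
    trans_usual = trans_uc,
    trans_intervention_year2 = trans_int_y2,
    beneficial_cells = beneficial,
    exac_rates = exac_rates,
    exac_specs = exac_specs,
    effects = effects,
    stage_params = stage_params,
    year1 = year1,
    death_on_admission = death_spec,
    discount_rate_annual = disc,
    horizon_months = as.integer(horizon),
    wtp_grid = wtp,
    population_eligible = num(cfg$population_eligible %||% 626129,
                              "population_eligible"),
    costing = cfg$intervention_costing,
    trial_summaries = cfg$trial_summaries,
    default_filled = filled,
    config_path = config_path
  ), class = "parameter_set")
  for (msg in filled) message("default filled: ", msg)
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %s structure, horizon %d months, discount %.1f%%\n",
              x$structure, x$horizon_months, 100 * x$discount_rate_annual))
  cat(" starting (usual care):   ",
      paste(sprintf("%s=%.3f", x$stages, x$starting$usual_care$point),
            collapse = " "), "\n")
  cat(" starting (intervention): ",
      paste(sprintf("%s=%.3f", x$stages, x$starting$intervention$point),
            collapse = " "), "\n")
  cat(" stage utilities:", paste(sprintf("%s=%.2f", x$stages,
                                         x$stage_params$utilities),
                                 collapse = " "), "\n")
  if (length(x$default_filled))
    cat(" default-filled:", length(x$default_filled), "field(s)\n")
  invisible(x)
}

#' Serialise a parameter set to JSON for provenance
#'
#' Writes every numeric input (full precision) so a run can be audited and
#' reproduced; [params_digest()] round-trips through this representation.
#'
#' @param params A `parameter_set`.
#' @param path Output file; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
params_to_json <- function(params, path = NULL) {
  strip <- function(x) {
    if (inherits(x, "dist_spec")) return(unclass(x))
    if (inherits(x, "transition_matrix")) {
      m <- unclass(x)
      attributes(m) <- list(dim = dim(x), dimnames = dimnames(x))
      return(list(matrix = m, specs = lapply(attr(x, "specs"), unclass)))
    }
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  ## I(17) significant digits so doubles survive the round trip bit-exactly
  js <- jsonlite::toJSON(strip(unclass(params)), auto_unbox = TRUE,
                         digits = I(17), null = "null", force = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Flat numeric digest of a parameter set
#'
#' Used by round-trip tests and the PSA iteration log: every scalar model
#' input as a named numeric vector.
#'
#' @param params A `parameter_set`.
#' @return Named numeric vector.
#' @export
params_digest <- function(params) {
  m <- as.matrix(params$trans_usual)
  out <- c(
    stats::setNames(params$starting$usual_care$point,
                    paste0("start_uc_", params$stages)),
    stats::setNames(params$starting$intervention$point,
                    paste0("start_int_", params$stages)),
    stats::setNames(as.vector(m), paste0("uc_", rep(rownames(m), 4), "_",
                                         rep(colnames(m), each = 4))),
    stats::setNames(params$exac_rates, paste0("exac_", params$stages)),
    stats::setNames(params$stage_params$utilities,
                    paste0("util_", params$stages)),
    stats::setNames(params$stage_params$monthly_costs,
                    paste0("cost_", params$stages)),
    disutility = params$stage_params$exac_disutility,
    admission_cost = params$stage_params$admission_cost$point,
    bed_day_cost = params$stage_params$bed_day_cost$point,
    intervention_monthly_cost =
      params$stage_params$intervention_monthly_cost$point,
    rr_year2 = params$effects$base_rr_year2,
    bed_day_reduction = params$effects$bed_day_reduction,
    death_on_admission = params$death_on_admission$point,
    year1_cost_uc = params$year1$usual_care$cost$point,
    year1_cost_int = params$year1$intervention$cost$point,
    year1_qaly_uc = params$year1$usual_care$qaly$point,
    year1_qaly_int = params$year1$intervention$qaly$point,
    discount_rate_annual = params$discount_rate_annual,
    horizon_months = params$horizon_months)
  out
}
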