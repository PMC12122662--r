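#' Annually decaying relative-risk schedule
#'
#' The intervention's benefit on exacerbation-related transitions is
#' assumed to wane: the year-2 risk reduction (1 - RR) halves each year
#' to the end of the horizon, i.e. `RR[k+1] = 1 - (1 - RR[k]) * decay`.
#'
#' @param base_rr Relative risk in the first modelled year (model year 2),
#'   in (0, 1].
#' @param decay Fraction of the risk reduction retained each subsequent
#'   year (default 0.5).
#' @param n_years Number of modelled years (default 4, model years 2-5).
#' @return Numeric vector of per-year relative risks.
#' @examples
#' rr_schedule(0.91)          # 0.91 0.955 0.9775 0.98875
#' @export
rr_schedule <- function(base_rr, decay = 0.5, n_years = 4L) {
  if (!is.finite(base_rr) || base_rr <= 0 || base_rr > 1)
    stop("base_rr must lie in (0, 1]", call. = FALSE)
  if (decay < 0 || decay > 1) stop("decay must lie in [0, 1]", call. = FALSE)
  reduction <- (1 - base_rr) * decay^(seq_len(n_years) - 1)
  1 - reduction
}

#' Bundle the intervention's four treatment effects
#'
#' The intervention acts through (1) improved 12-month starting states
#' (held in the parameter set), (2) a beneficial transition-matrix
#' adjustment whose relative risk decays annually, (3) reduced
#' exacerbation rates in the admission-defined stages, and (4) fewer bed
#' days per hospitalised exacerbation.
#'
#' @param base_rr_year2 Year-2 relative risk on beneficial transitions.
#' @param decay Annual retention of the risk reduction.
#' @param n_years Modelled years after year 1.
#' @param exac_reduction_schedule Per-year proportional reduction in
#'   exacerbation rates (default 12%, 6%, 3%, 1.5%).
#' @param bed_day_reduction Bed days saved per hospitalised exacerbation.
#' @param effect_stages Stages receiving the exacerbation-rate effect
#'   (default B and D, the admission-defined stages).
#' @return A `treatment_effect_schedule` list.
#' @export
treatment_effect_schedule <- function(base_rr_year2 = 0.91, decay = 0.5,
                                      n_years = 4L,
                                      exac_reduction_schedule =
                                        c(0.12, 0.06, 0.03, 0.015),
                                      bed_day_reduction = 1.278,
                                      effect_stages = c("B", "D")) {
  rrs <- rr_schedule(base_rr_year2, decay, n_years)
  if (length(exac_reduction_schedule) != n_years)
    stop("exac_reduction_schedule must have one entry per modelled year",
         call. = FALSE)
  structure(list(
    base_rr_year2 = base_rr_year2, decay = decay,
    rr_by_year = rrs,
    exac_reduction_schedule = exac_reduction_schedule,
    bed_day_reduction = bed_day_reduction,
    effect_stages = effect_stages), class = "treatment_effect_schedule")
}

#' Apply a relative risk to the beneficial cells of a transition matrix
#'
#' Multiplies the designated beneficial-cell probabilities by `rr` and
#' restores row-stochasticity through the residual stay probabilities.
#' `rr = 1` returns the input unchanged; `rr` above 1 is allowed (used to
#' back-derive the usual-care matrix and in PSA draws).
#'
#' @param usual A [transition_matrix()].
#' @param rr Relative risk applied to the beneficial cells.
#' @param beneficial_cells Data frame with columns `from`, `to`.
#' @return Adjusted `transition_matrix`.
#' @export
adjust_matrix <- function(usual, rr, beneficial_cells) {
  if (!is.finite(rr) || rr < 0) stop("rr must be nonnegative", call. = FALSE)
  off <- as.matrix(unclass(usual))
  diag(off) <- 0
  for (i in seq_len(nrow(beneficial_cells))) {
    f <- beneficial_cells$from[i]; t <- beneficial_cells$to[i]
    if (!(f %in% rownames(off)) || !(t %in% colnames(off)))
      stop(sprintf("beneficial cell %s->%s outside the stage set", f, t),
           call. = FALSE)
    off[f, t] <- off[f, t] * rr
  }
  out <- transition_matrix(off, specs = attr(usual, "specs"))
  out
}

#' Effective monthly exacerbation rate by stage, year and arm
#'
#' Usual care keeps the base rates; the intervention multiplies the rates
#' of the admission-defined effect stages by `1 - reduction(year)` from
#' the decaying schedule.
#'
#' @param stage Stage label.
#' @param model_year Model year, 2 to horizon/12.
#' @param arm `"usual_care"` or `"intervention"`.
#' @param base_rates Named vector of monthly base rates per stage.
#' @param schedule A [treatment_effect_schedule()].
#' @return Monthly probability of a hospitalised exacerbation.
#' @examples
#' sched <- treatment_effect_schedule()
#' effective_exac_rate("D", 2, "intervention", c(B = 0.0078, D = 0.0157), sched)
#' @export
effective_exac_rate <- function(stage, model_year,
                                arm = c("usual_care", "intervention"),
                                base_rates, schedule) {
  arm <- match.arg(arm)
  if (!stage %in% names(base_rates))
    stop(sprintf("no base exacerbation rate for stage '%s'", stage),
         call. = FALSE)
  rate <- base_rates[[stage]]
  if (arm == "usual_care" || !(stage %in% schedule$effect_stages))
    return(rate)
  k <- model_year - 1L
  if (k < 1L || k > length(schedule$exac_reduction_schedule))
    stop("model_year outside the modelled range", call. = FALSE)
  rate * (1 - schedule$exac_reduction_schedule[k])
}

#' Cost per hospitalised exacerbation by arm
#'
#' Usual care pays the full admission tariff; the intervention's
#' admissions are cheaper by the bed-day saving times the bed-day cost.
#'
#' @param arm `"usual_care"` or `"intervention"`.
#' @param admission_cost Full admission cost (GBP).
#' @param bed_day_cost Cost per hospital bed day (GBP).
#' @param bed_day_reduction Bed days saved per admission on the
#'   intervention.
#' @return Cost in GBP; errors if the reduction exceeds the tariff.
#' @examples
#' admission_cost("intervention")   # 2258.33 - 1.278 * 260.71
#' @export
admission_cost <- function(arm = c("usual_care", "intervention"),
                           admission_cost = 2258.33,
                           bed_day_cost = 260.71,
                           bed_day_reduction = 1.278) {
  arm <- match.arg(arm)
  if (arm == "usual_care") return(admission_cost)
  out <- admission_cost - bed_day_reduction * bed_day_cost
  if (out < 0)
    stop("bed-day saving exceeds the admission cost; check configuration",
         call. = FALSE)
  out
}
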