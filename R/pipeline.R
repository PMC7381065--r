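#' Per-participant costs and QALYs from ODI trajectories
#'
#' Maps each participant's week-4 and week-8 ODI scores to SF-6D utilities,
#' builds the QALY over the trial horizon, and attaches the
#' protocol-determined arm cost where the cohort does not already carry a
#' `cost_naira` column.
#'
#' @param cohort Data frame with columns `arm`, `odi_week4`, `odi_week8`
#'   (and optionally `id`, `cost_naira`).
#' @param cost_model A [cost_model()]; ignored for rows that already have a
#'   cost.
#' @param coeffs ODI to SF-6D mapping coefficients.
#' @param convention QALY convention, see [qaly()].
#' @return The cohort with added columns `sf6d_week4`, `sf6d_week8`, `qaly`
#'   (and `cost_naira` if absent).
#' @export
participant_costs_qalys <- function(cohort, cost_model = default_cost_model(),
                                    coeffs = sf6d_coefficients(),
                                    convention = "mean_utility") {
  need <- c("arm", "odi_week4", "odi_week8")
  if (!all(need %in% names(cohort)))
    stop("cohort needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  out <- cohort
  out$sf6d_week4 <- map_odi_to_sf6d(cohort$odi_week4, coeffs)
  out$sf6d_week8 <- map_odi_to_sf6d(cohort$odi_week8, coeffs)
  out$qaly <- qaly(out$sf6d_week4, out$sf6d_week8,
                   horizon_weeks = cost_model$horizon_weeks,
                   convention = convention)
  if (is.null(out$cost_naira))
    out$cost_naira <- vapply(out$arm, arm_total_cost_naira, numeric(1),
                             model = cost_model)
  out
}

#' Point-estimate cost-utility analysis of a cohort
#'
#' Runs the full deterministic pipeline: utilities and QALYs per
#' participant, arm means, incremental cost and effect, and the ICER /
#' dominance ruling, returned with an incremental-analysis table in the
#' familiar cost / incremental cost / effect / incremental effect / ICER
#' layout.
#'
#' @inheritParams participant_costs_qalys
#' @param new,ref Labels of the new and reference arm.
#' @return A list of class `cua_analysis`: `arms` (per-arm n, mean cost in
#'   naira and USD, mean QALY), `delta_cost`, `delta_effect`, `icer`
#'   (an `icer_result`), and `table` (one row per arm).
#' @export
analyze_cohort <- function(cohort, cost_model = default_cost_model(),
                           coeffs = sf6d_coefficients(),
                           convention = "mean_utility",
                           new = "TBMT", ref = "CBMT") {
  pc <- participant_costs_qalys(cohort, cost_model, coeffs, convention)
  summ <- function(a) {
    d <- pc[pc$arm == a, ]
    if (nrow(d) == 0L) stop(sprintf("arm '%s' has no participants", a), call. = FALSE)
    list(arm = a, n = nrow(d),
         mean_cost_naira = mean(d$cost_naira),
         mean_cost_usd = naira_to_usd(mean(d$cost_naira), cost_model$exchange_rate),
         mean_qaly = mean(d$qaly))
  }
  s_new <- summ(new); s_ref <- summ(ref)
  inc <- incremental(s_new, s_ref)
  ic <- icer(inc[["delta_cost"]], inc[["delta_effect"]])
  tab <- data.frame(
    arm = c(s_ref$arm, s_new$arm),
    n = c(s_ref$n, s_new$n),
    mean_cost_naira = c(s_ref$mean_cost_naira, s_new$mean_cost_naira),
    mean_cost_usd = c(s_ref$mean_cost_usd, s_new$mean_cost_usd),
    mean_qaly = c(s_ref$mean_qaly, s_new$mean_qaly),
    delta_cost = c(NA, inc[["delta_cost"]]),
    delta_effect = c(NA, inc[["delta_effect"]]),
    icer = c(NA_character_,
             if (is.na(ic$icer)) ic$label else sprintf("%.0f", ic$icer))
  )
  structure(list(arms = list(new = s_new, ref = s_ref),
                 delta_cost = inc[["delta_cost"]],
                 delta_effect = inc[["delta_effect"]],
                 icer = ic, table = tab,
                 participants = pc),
            class = "cua_analysis")
}

#' @export
print.cua_analysis <- function(x, ...) {
  cat("Cost-utility analysis (point estimates)\n")
  print(x$table, row.names = FALSE, digits = 6)
  invisible(x)
}
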