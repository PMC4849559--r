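# Value-based pricing of hypothetical CVD-risk-reducing treatments.
#
# The maximum annual price p* is the price at which the incremental net
# benefit at threshold lambda is exactly zero:
#   p* = (lambda * dQALY - dCost_disease) / discounted treatment years,
# floored at zero. Disease costs exclude the treatment price itself; the
# price is paid per discounted life-year alive (or event-free, by config).

#' Incremental deltas between a treated and an untreated run
#'
#' @param base \code{scad_outputs} of the untreated run.
#' @param treated \code{scad_outputs} of the treated run.
#' @return List with \code{d_qaly} (discounted), \code{d_cost_disease}
#'   (discounted, excluding treatment price) and \code{exposure}
#'   (discounted treatment years of the treated run).
#' @export
incremental <- function(base, treated) {
  stopifnot(inherits(base, "scad_outputs"), inherits(treated, "scad_outputs"))
  list(d_qaly = treated$disc_qalys - base$disc_qalys,
       d_cost_disease = treated$disc_total_costs - base$disc_total_costs,
       exposure = treated$disc_exposure_years)
}

#' Maximum cost-effective annual treatment price
#'
#' @param deltas Result of \code{\link{incremental}}.
#' @param lambda Cost-effectiveness threshold, GBP per QALY (> 0).
#' @return Maximum annual price in GBP per year (floored at 0).
#' @export
max_price <- function(deltas, lambda) {
  stopifnot(lambda > 0)
  if (deltas$exposure <= 0) {
    stop("treatment exposure is zero; maximum price undefined", call. = FALSE)
  }
  max(0, (lambda * deltas$d_qaly - deltas$d_cost_disease) / deltas$exposure)
}

#' Pricing grid across risk groups, effect sizes and thresholds
#'
#' Runs the cohort model untreated and under each hazard reduction for each
#' group-mean profile, then evaluates the maximum price on the full
#' (group, rho, lambda) grid.
#'
#' @param groups Result of \code{\link{assign_risk_groups}}.
#' @param set,cost_model,utilities Model inputs (see \code{\link{run_cohort}}).
#' @param rhos Hazard reductions (default 0.10, 0.20, 0.30, 0.40).
#' @param lambdas Thresholds in GBP/QALY (default 10,000 to 40,000 by 10,000).
#' @param discount_rate Annual discount rate.
#' @param ... Passed to \code{\link{treatment_scenario}}.
#' @return Data frame (group, mean_risk, rho, lambda, d_qaly,
#'   d_cost_disease, exposure, max_price).
#' @export
price_grid <- function(groups, set, cost_model, utilities,
                       rhos = c(0.10, 0.20, 0.30, 0.40),
                       lambdas = seq(10000, 40000, by = 10000),
                       discount_rate = 0.035, ...) {
  rows <- list()
  for (g in groups) {
    base <- run_cohort(g$mean_covariates, set, cost_model, utilities,
                       discount_rate = discount_rate)$outputs
    for (rho in rhos) {
      tr <- treatment_scenario(rho, ...)
      treated <- run_cohort(g$mean_covariates, set, cost_model, utilities,
                            discount_rate = discount_rate,
                            treatment = tr)$outputs
      d <- incremental(base, treated)
      for (lam in lambdas) {
        rows[[length(rows) + 1]] <- data.frame(
          group = g$index, mean_risk = g$mean_risk, rho = rho, lambda = lam,
          d_qaly = d$d_qaly, d_cost_disease = d$d_cost_disease,
          exposure = d$exposure, max_price = max_price(d, lam))
      }
    }
  }
  do.call(rbind, rows)
}
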