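# Risk stratification into tenths and probabilistic sensitivity analysis.

#' Assign patients to baseline-risk groups
#'
#' Ranks patients by predicted 5-year composite CVD risk (stable sort, ties
#' broken by patient id) and splits them into k contiguous equally sized
#' groups (sizes differ by at most one).
#'
#' @param cohort Profile table.
#' @param set \code{scad_eqset}.
#' @param k Number of groups (default 10).
#' @param risk Optional precomputed risk vector (same order as cohort).
#' @return List of \code{k} groups, each with \code{index}, \code{member_ids},
#'   \code{mean_risk}, \code{risk_at_mean}, \code{mean_covariates} (one-row
#'   design matrix) and \code{mean_age}, \code{mean_female}.
#' @export
assign_risk_groups <- function(cohort, set, k = 10L, risk = NULL) {
  n <- nrow(cohort)
  if (k > n) stop("more groups than patients", call. = FALSE)
  if (is.null(risk)) risk <- cohort_composite_risk(set, cohort)
  ord <- order(risk, cohort$patient_id, method = "radix")
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  X <- profile_model_matrix(cohort)
  lapply(seq_len(k), function(g) {
    idx <- ord[starts[g]:stops[g]]
    xm <- matrix(colMeans(X[idx, , drop = FALSE]), nrow = 1,
                 dimnames = list(NULL, colnames(X)))
    fem <- unname(xm[1, "female"])
    age <- (unname(xm[1, "age10"]) + .CENTRES[["age10"]]) * 10
    list(index = g,
         member_ids = cohort$patient_id[idx],
         member_risk = risk[idx],
         mean_risk = mean(risk[idx]),
         risk_at_mean = predict_5yr_composite_risk(set, xm, fem, age),
         mean_covariates = xm,
         mean_age = age, mean_female = fem)
  })
}

#' Representative patient of a risk group
#'
#' The member whose predicted risk is the group median (the lower of the two
#' central members for even group sizes).
#'
#' @param group One element of \code{\link{assign_risk_groups}}'s result.
#' @param cohort The profile table the group was built from.
#' @return One-row profile data frame.
#' @export
representative_patient <- function(group, cohort) {
  stopifnot(length(group$member_ids) >= 1)
  ord <- order(group$member_risk, group$member_ids, method = "radix")
  pick <- ord[ceiling(length(ord) / 2)]  # lower-median for even sizes
  cohort[cohort$patient_id == group$member_ids[pick], , drop = FALSE]
}

# ---------------------------------------------------------------------------
# PSA

# Draw multivariate normal given mean and covariance; non-PD covariance is
# repaired by clipping negative eigenvalues (with a warning).
rmvn <- function(n, mean, sigma) {
  p <- length(mean)
  if (all(sigma == 0)) return(matrix(rep(mean, each = n), n))
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  # numeric-Hessian inverses routinely carry eigenvalues a hair below zero;
  # clip those silently, warn only when the matrix is materially indefinite
  if (any(ev$values < -1e-4 * max(abs(ev$values)))) {
    warning("vcov not positive semi-definite; nearest-PSD repair applied")
  }
  lam <- pmax(ev$values, 0)
  L <- ev$vectors %*% diag(sqrt(lam), p)
  matrix(rep(mean, each = n), n) + matrix(rnorm(n * p), n) %*% t(L)
}

# Beta perturbation with given mean in (0, 1] and sd; sd = 0 or mean = 1
# returns the mean unchanged.
rbeta_mean_sd <- function(n, mean, sd) {
  if (sd <= 0 || mean >= 1 || mean <= 0) return(rep(mean, n))
  v <- sd^2
  v <- min(v, mean * (1 - mean) * 0.99)
  a <- mean * (mean * (1 - mean) / v - 1)
  b <- (1 - mean) * (mean * (1 - mean) / v - 1)
  rbeta(n, a, b)
}

# Perturb a fitted survival equation set using each fit's vcov.
draw_equation_set <- function(set) {
  perturb <- function(fit) {
    if (is.null(fit$par) || all(fit$vcov == 0) || anyNA(fit$vcov)) return(fit)
    th <- drop(rmvn(1, fit$par, fit$vcov))
    # a shift of 30 on the log-time scale already means "immediately" or
    # "never"; clamping keeps draws from non-identified coefficients
    # (zero-event sparse indicators) numerically sane
    th <- pmin(pmax(th, fit$par - 30), fit$par + 30)
    p <- aft_unpack(th, length(fit$coef), fit$family, fit$fixed)
    fit$coef[] <- p$beta
    fit$sigma <- p$sigma
    fit$Q <- p$Q
    fit$par[] <- th
    fit
  }
  set$primary <- lapply(set$primary, perturb)
  set$post <- lapply(set$post, function(x) lapply(x, perturb))
  set
}

draw_cost_model <- function(cm) {
  if (!all(cm$vcov_cvd == 0)) {
    cm$coef_cvd[] <- drop(rmvn(1, cm$coef_cvd, cm$vcov_cvd))
  }
  if (!all(cm$vcov_other == 0)) {
    cm$coef_other[] <- drop(rmvn(1, cm$coef_other, cm$vcov_other))
  }
  cm
}

draw_utilities <- function(cat, sd = 0.02) {
  cat$bands$base_utility <- vapply(cat$bands$base_utility,
                                   function(m) rbeta_mean_sd(1, m, sd),
                                   numeric(1))
  cat$multipliers[] <- vapply(cat$multipliers,
                              function(m) rbeta_mean_sd(1, m, sd),
                              numeric(1))
  cat
}

#' Probabilistic sensitivity analysis for one profile
#'
#' Each iteration draws survival and cost coefficients from multivariate
#' normal distributions on their estimation scales and utilities from beta
#' perturbations, re-runs the cohort model, and collects every lifetime
#' output. Zero variance on every input reproduces the point estimate in
#' every draw.
#'
#' @inheritParams run_cohort
#' @param n_iter Number of Monte Carlo iterations (default 1000).
#' @param seed Integer seed.
#' @param utility_sd Beta-perturbation standard deviation (default 0.02).
#' @return List of class \code{scad_psa}: \code{point} (scad_outputs),
#'   \code{draws} (data frame, one row per iteration), \code{ci} (2.5/97.5
#'   percentiles per output).
#' @export
run_psa <- function(profile, set, cost_model, utilities, n_iter = 1000L,
                    seed = 1L, discount_rate = 0.035, treatment = NULL,
                    utility_sd = 0.02, subdiv = 64L) {
  point <- run_cohort(profile, set, cost_model, utilities,
                      discount_rate = discount_rate, treatment = treatment,
                      subdiv = subdiv)$outputs
  draws <- with_seed(seed, {
    out <- vector("list", n_iter)
    for (i in seq_len(n_iter)) {
      s_i <- draw_equation_set(set)
      c_i <- draw_cost_model(cost_model)
      u_i <- draw_utilities(utilities, utility_sd)
      r <- run_cohort(profile, s_i, c_i, u_i, discount_rate = discount_rate,
                      treatment = treatment, subdiv = subdiv)$outputs
      out[[i]] <- as.data.frame(r)
    }
    do.call(rbind, out)
  })
  ci <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  rownames(ci) <- c("lower", "upper")
  structure(list(point = point, draws = draws, ci = ci, n_iter = n_iter),
            class = "scad_psa")
}

#' @export
print.scad_psa <- function(x, ...) {
  cat(sprintf("PSA with %d iterations\n", x$n_iter))
  sel <- c("disc_qalys", "disc_total_costs", "cvd_mortality_pct")
  for (f in sel) {
    cat(sprintf("  %-18s %10.2f (95%% CI %10.2f to %10.2f)\n", f,
                x$point[[f]], x$ci["lower", f], x$ci["upper", f]))
  }
  invisible(x)
}
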