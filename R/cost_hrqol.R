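# Per-cycle costs and health-related quality of life.
#
# Costs are modelled as two non-negative components — CVD-attributable and
# other — each with a log-link mean over baseline covariates, model state,
# an acute-cycle indicator, a time-since-event band and current age. Their
# sum is the total cost, so "CVD cost <= total cost" holds by construction.
# Utilities come from a catalogue of sex/age-band EQ-5D-style baseline
# values combined multiplicatively with condition and event multipliers.

# Baseline covariates entering the cost model (subset of the primary design).
COST_COVARIATES <- c("female", "heart_failure", "diabetes", "copd", "cancer",
                     "ckd", "depression", "previous_mi")

# Design columns added on top of the baseline covariates.
cost_design <- function(X_primary, state, cycles_since_event, current_age) {
  n <- length(state)
  post_mi <- as.numeric(state == "post_mi")
  post_is <- as.numeric(state == "post_is")
  post_hs <- as.numeric(state == "post_hs")
  cse <- ifelse(is.na(cycles_since_event), -1L, cycles_since_event)
  acute <- as.numeric(state %in% c("post_mi", "post_is", "post_hs") & cse == 0)
  recent <- as.numeric(state %in% c("post_mi", "post_is", "post_hs") &
                         cse >= 1 & cse <= 3)
  cbind(
    intercept = rep(1, n),
    X_primary[, COST_COVARIATES, drop = FALSE],
    age10 = current_age / 10 - 6.5,
    post_mi = post_mi, post_is = post_is, post_hs = post_hs,
    acute = acute, recent = recent
  )
}

cost_design_names <- function() {
  c("intercept", COST_COVARIATES, "age10",
    "post_mi", "post_is", "post_hs", "acute", "recent")
}

#' Default ground-truth cost model (GBP per 90 days, 2011/12 prices)
#'
#' Two log-linear components. The CVD component carries the event uplifts
#' (a large acute-cycle multiplier, a smaller first-year multiplier) while
#' the other component is dominated by age and non-CVD comorbidity.
#' Dispersion is the gamma noise dispersion (variance = dispersion * mean^2).
#'
#' @return A list of class \code{scad_costmodel}.
#' @export
default_true_cost_model <- function() {
  nm <- cost_design_names()
  mk <- function(...) {
    g <- setNames(numeric(length(nm)), nm)
    v <- c(...)
    g[names(v)] <- v
    g
  }
  structure(list(
    coef_cvd = mk(intercept = log(250), age10 = 0.10, heart_failure = 0.30,
                  diabetes = 0.15, previous_mi = 0.10,
                  post_mi = 0.45, post_is = 0.55, post_hs = 0.60,
                  acute = 2.60, recent = 0.35),
    coef_other = mk(intercept = log(400), age10 = 0.25, copd = 0.30,
                    cancer = 0.50, ckd = 0.20, depression = 0.15,
                    post_mi = 0.10, post_is = 0.15, post_hs = 0.15,
                    acute = 0.70),
    vcov_cvd = matrix(0, length(nm), length(nm), dimnames = list(nm, nm)),
    vcov_other = matrix(0, length(nm), length(nm), dimnames = list(nm, nm)),
    dispersion = 0.5
  ), class = "scad_costmodel")
}

# Component means for arbitrary rows (vectorised). Returns list(cvd, other).
cost_linear_predictors <- function(model, X_primary, state, cycles_since_event,
                                   current_age) {
  D <- cost_design(X_primary, state, cycles_since_event, current_age)
  list(cvd = drop(exp(D %*% model$coef_cvd[colnames(D)])),
       other = drop(exp(D %*% model$coef_other[colnames(D)])))
}

#' Fit the two-component per-cycle cost model
#'
#' Quasi-Poisson (log link) mean models for the CVD-attributable and other
#' cost components, with cluster-by-patient sandwich variance estimates
#' (costs within a patient are serially correlated).
#'
#' @param panel Cost panel with columns \code{cost_cvd} and \code{cost_other}
#'   (as produced by \code{\link{simulate_cost_panel}}).
#' @param cohort Profile table the panel rows join to.
#' @return Fitted \code{scad_costmodel} with coefficient vectors, robust
#'   vcov matrices and the estimated dispersion.
#' @export
fit_cost_model <- function(panel, cohort) {
  stopifnot(nrow(panel) > 0)
  if (any(panel$observed_cost < 0, na.rm = TRUE)) {
    stop("panel contains negative costs", call. = FALSE)
  }
  ridx <- match(panel$patient_id, cohort$patient_id)
  if (anyNA(ridx)) stop("panel rows exist without a matching profile", call. = FALSE)
  Xp <- profile_model_matrix(cohort)[ridx, , drop = FALSE]
  age_now <- cohort$age_entry[ridx] + panel$cycle_index * CYCLE_YEARS
  D <- cost_design(Xp, panel$state_at_cycle, panel$cycles_since_event, age_now)
  if (all(panel$observed_cost == 0)) {
    warning("all observed costs are zero; cost model is degenerate")
  }
  fit_one <- function(y) {
    g <- glm.fit(D, y, family = quasipoisson(link = "log"))
    beta <- setNames(coef(g), colnames(D))
    if (anyNA(beta)) {
      # rank deficiency: a state/band never observed in this panel; its
      # column is all zero so a zero coefficient reproduces the fit
      warning("cost design is rank deficient; unidentified coefficients set to 0")
      beta[is.na(beta)] <- 0
    }
    mu <- drop(exp(D %*% beta))
    # cluster sandwich: B = (X'WX)^-1, meat = sum over patients of score sums
    W <- mu                                  # quasi-Poisson working weights
    XtWX <- crossprod(D * sqrt(W))
    bread <- safe_solve(XtWX, ncol(D))       # pseudo-inverse if rank deficient
    sc <- D * (y - mu)
    meat <- crossprod(rowsum(sc, panel$patient_id))
    vc <- bread %*% meat %*% bread
    dimnames(vc) <- list(colnames(D), colnames(D))
    disp <- sum((y - mu)^2 / pmax(mu, 1e-12)) / (length(y) - ncol(D))
    list(beta = beta, vcov = vc, dispersion = disp)
  }
  f_cvd <- fit_one(panel$cost_cvd)
  f_other <- fit_one(panel$cost_other)
  structure(list(
    coef_cvd = f_cvd$beta, coef_other = f_other$beta,
    vcov_cvd = f_cvd$vcov, vcov_other = f_other$vcov,
    dispersion = (f_cvd$dispersion + f_other$dispersion) / 2
  ), class = "scad_costmodel")
}

#' Per-cycle cost for a profile in a given state
#'
#' @param model \code{scad_costmodel}.
#' @param x_primary One-row primary design matrix (see
#'   \code{\link{profile_model_matrix}}); fractional group means allowed.
#' @param state One of the live model states.
#' @param cycles_since_event Integer (0 = the cycle in which the event
#'   occurred) or \code{NA} for the stable state.
#' @param current_age Attained age in years.
#' @return List with \code{total}, \code{cvd} and \code{other} GBP per 90 days.
#' @export
cycle_cost <- function(model, x_primary, state, cycles_since_event, current_age) {
  if (!all(state %in% c("stable", "post_mi", "post_is", "post_hs"))) {
    stop("cycle_cost is defined for live states only", call. = FALSE)
  }
  n <- max(length(state), length(current_age), length(cycles_since_event))
  Xr <- x_primary[rep(1, n), , drop = FALSE]
  lp <- cost_linear_predictors(model, Xr, rep_len(state, n),
                               rep_len(cycles_since_event, n),
                               rep_len(current_age, n))
  list(total = lp$cvd + lp$other, cvd = lp$cvd, other = lp$other)
}

# ---------------------------------------------------------------------------
# Utilities

#' Default synthetic utility catalogue
#'
#' Sex/age-band baseline utilities shaped like UK general-population EQ-5D
#' norms, a stable-CAD condition multiplier, post-event multipliers and
#' acute-cycle multipliers. The numbers are synthetic stand-ins (the package
#' ships no licensed value set); the structure matches published catalogues.
#'
#' @return A list of class \code{scad_utilities} with \code{bands} (data
#'   frame sex/age_lo/age_hi/base_utility) and \code{multipliers}.
#' @export
default_utility_catalogue <- function() {
  bands <- expand.grid(sex = c("male", "female"),
                       lo = c(18, 25, 35, 45, 55, 65, 75, 85),
                       stringsAsFactors = FALSE)
  bands <- bands[order(bands$sex, bands$lo), ]
  base_m <- c(0.94, 0.93, 0.91, 0.85, 0.80, 0.78, 0.75, 0.68)
  base_f <- c(0.94, 0.93, 0.90, 0.85, 0.81, 0.76, 0.71, 0.65)
  bands$age_lo <- bands$lo
  # terminal band runs past the age cap so the engine's short run-out
  # (age cap + 2 years) stays inside the catalogue
  bands$age_hi <- c(24, 34, 44, 54, 64, 74, 84, 120)[match(bands$lo, c(18, 25, 35, 45, 55, 65, 75, 85))]
  bands$base_utility <- ifelse(bands$sex == "male",
                               base_m[match(bands$lo, c(18, 25, 35, 45, 55, 65, 75, 85))],
                               base_f[match(bands$lo, c(18, 25, 35, 45, 55, 65, 75, 85))])
  bands$lo <- NULL
  rownames(bands) <- NULL
  structure(list(
    bands = bands,
    multipliers = c(condition_cad = 0.93,
                    post_mi = 0.88, post_is = 0.82, post_hs = 0.76,
                    acute_mi = 0.85, acute_is = 0.80, acute_hs = 0.75)
  ), class = "scad_utilities")
}

validate_utility_catalogue <- function(cat) {
  b <- cat$bands
  stopifnot(all(c("sex", "age_lo", "age_hi", "base_utility") %in% names(b)))
  if (any(b$base_utility < -0.594 | b$base_utility > 1)) {
    stop("base utilities must lie in the EQ-5D UK range [-0.594, 1]", call. = FALSE)
  }
  m <- cat$multipliers
  if (any(m <= 0 | m > 1)) stop("utility multipliers must lie in (0, 1]", call. = FALSE)
  invisible(cat)
}

# Vectorised base-utility lookup with nearest-band fallback.
base_utility <- function(cat, female, age) {
  b <- cat$bands
  n <- max(length(female), length(age))
  female <- rep_len(sex_indicator(female), n)
  age <- rep_len(age, n)
  u <- numeric(n)
  for (sx in c("male", "female")) {
    bb <- b[b$sex == sx, ]
    idx <- findInterval(age, bb$age_lo)
    out_of_range <- idx == 0 | age > max(bb$age_hi)
    if (any(out_of_range)) {
      warning("age outside utility catalogue range; nearest band used")
      idx <- pmin(pmax(idx, 1L), nrow(bb))
    }
    uv <- bb$base_utility[idx]
    w <- if (sx == "female") female else 1 - female
    u <- u + w * uv
  }
  u
}

#' Per-cycle utility
#'
#' Base utility for the profile's sex and attained-age band, multiplied by
#' the stable-CAD condition multiplier, the post-event multiplier for the
#' occupied state, and the acute multiplier in the event cycle itself
#' (\code{cycles_since_event == 0}).
#'
#' @param catalogue \code{scad_utilities} object.
#' @param female Female indicator (fractional group means allowed).
#' @param state Live model state(s).
#' @param cycles_since_event Integer or \code{NA} (stable state).
#' @param current_age Attained age, years.
#' @return Utility value(s) in the EQ-5D range.
#' @export
cycle_utility <- function(catalogue, female, state, cycles_since_event,
                          current_age) {
  n <- max(length(state), length(current_age), length(cycles_since_event))
  state <- rep_len(state, n)
  cse <- rep_len(ifelse(is.na(cycles_since_event), -1L, cycles_since_event), n)
  u <- base_utility(catalogue, female, rep_len(current_age, n))
  m <- catalogue$multipliers
  u <- u * m[["condition_cad"]]
  post_key <- c(post_mi = "post_mi", post_is = "post_is", post_hs = "post_hs")
  acute_key <- c(post_mi = "acute_mi", post_is = "acute_is", post_hs = "acute_hs")
  for (st in names(post_key)) {
    sel <- state == st
    if (any(sel)) {
      u[sel] <- u[sel] * m[[post_key[[st]]]]
      ac <- sel & cse == 0
      u[ac] <- u[ac] * m[[acute_key[[st]]]]
    }
  }
  u
}
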