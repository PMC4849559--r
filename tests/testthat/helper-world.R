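# Shared test fixtures, built in code.

DL <- cycle_length_years()

# Truth object with constant (exponential, intercept-only) primary hazards.
# `h` is a named list over the five primary endpoints; missing/zero entries
# get an effectively-zero hazard. Post-event hazards are constant too
# (`post_cvd`, `post_ncvd`, per year). Censoring off by default.
const_hazard_truth <- function(h = list(), post_cvd = 0, post_ncvd = 0,
                               censoring = 0) {
  tr <- default_true_parameters()
  eps_mu <- 50  # hazard e^-50: effectively zero
  for (ep in names(tr$primary)) {
    b <- tr$primary[[ep]]$beta * 0
    hv <- h[[ep]] %||% 0
    b["intercept"] <- if (hv > 0) -log(hv) else eps_mu
    tr$primary[[ep]] <- list(family = "exponential", sigma = 1, beta = b)
  }
  for (st in names(tr$post)) {
    for (oc in c("cvd_death", "noncvd_death")) {
      hv <- if (oc == "cvd_death") post_cvd else post_ncvd
      tr$post[[st]][[oc]] <- list(
        family = "exponential", sigma = 1,
        beta = c(intercept = if (hv > 0) -log(hv) else eps_mu,
                 female = 0, age_event10 = 0))
    }
  }
  tr$censoring_rate <- censoring
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reference profile: 65-year-old male with reference-level covariates.
reference_profile <- function(age = 65, sex = "male") {
  p <- generate_cohort(1, 1)
  p$age_entry <- age
  p$sex <- sex
  p$cad_subtype <- "stable_angina"
  p$smoking <- "never"
  for (v in c("pci_6m", "cabg_6m", "previous_mi", "nitrates", "hypertension",
              "diabetes", "heart_failure", "pad", "af", "prior_stroke",
              "ckd", "copd", "cancer", "liver_disease", "depression",
              "anxiety")) {
    p[[v]] <- 0
  }
  p$deprived_quintile <- 3
  p$total_chol <- 4.8; p$hdl <- 1.37; p$heart_rate <- 72
  p$creatinine <- 100; p$wcc <- 7.5; p$haemoglobin <- 1.36
  p
}

# Random-but-sane truth for oracle-equivalence draws. All eleven hazards
# are non-degenerate so every output field has Monte Carlo variance.
random_truth <- function(seed) {
  tr <- default_true_parameters()
  set.seed(seed)
  fams <- c("exponential", "weibull", "lognormal")
  jit <- function(x, s) x + rnorm(length(x), 0, s)
  for (ep in names(tr$primary)) {
    eq <- tr$primary[[ep]]
    eq$family <- sample(fams, 1)
    eq$sigma <- runif(1, 0.7, 1.3)
    eq$beta["intercept"] <- jit(eq$beta[["intercept"]], 0.3)
    eq$beta["age10"] <- jit(eq$beta[["age10"]], 0.1)
    tr$primary[[ep]] <- eq
  }
  for (st in names(tr$post)) {
    for (oc in c("cvd_death", "noncvd_death")) {
      eq <- tr$post[[st]][[oc]]
      eq$sigma <- runif(1, 0.8, 1.2)
      eq$beta["intercept"] <- jit(eq$beta[["intercept"]], 0.3)
      tr$post[[st]][[oc]] <- eq
    }
  }
  tr
}

# Lazily-built medium fitted world shared across test files.
.world <- new.env()

fitted_world <- function(n = 6000, seed = 2024) {
  key <- sprintf("w_%d_%d", n, seed)
  if (is.null(.world[[key]])) {
    cohort <- generate_cohort(n, seed)
    truth <- default_true_parameters()
    histories <- simulate_event_histories(cohort, truth, seed + 1)
    panel <- simulate_cost_panel(cohort, histories, truth, seed + 2)
    # gengamma excluded here purely for test runtime; the smoke pipeline in
    # the acceptance suite exercises the default four-family selection
    set <- suppressWarnings(fit_risk_equations(
      cohort, histories,
      families = c("exponential", "weibull", "lognormal")))
    cost_model <- fit_cost_model(panel, cohort)
    .world[[key]] <- list(cohort = cohort, truth = truth,
                          histories = histories, panel = panel,
                          set = set, cost_model = cost_model,
                          utilities = default_utility_catalogue())
  }
  .world[[key]]
}

# Tolerance for cohort-vs-microsim comparisons: 3 Monte Carlo SEs, with a
# binomial fallback for percentage fields whose microsim count is zero
# (an event so rare that n draws saw none still bounds the cohort value).
equivalence_tol <- function(field, cohort_value, ms) {
  tol <- 3 * ms$se[[field]]
  if (grepl("_pct$|^p_first", field)) {
    p <- min(max(cohort_value / 100, 0), 1)
    tol <- max(tol, 3 * 100 * sqrt(p * (1 - p) / ms$n))
  }
  max(tol, 1e-9)
}
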