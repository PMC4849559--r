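# Cohort engine and microsimulation oracle.

test_that("zero hazards: the horizon cap binds and QALYs equal utility-time", {
  tr <- const_hazard_truth(list())
  set <- equation_set_from_truth(tr, splice_time = Inf)
  p <- reference_profile(age = 40)
  cm <- default_true_cost_model()
  uc <- default_utility_catalogue()
  r <- suppressWarnings(run_cohort(p, set, cm, uc, discount_rate = 0,
                                   horizon_years = 60, age_cap = 1e6))
  expect_equal(r$outputs$life_years, 60, tolerance = DL)
  expect_equal(r$outputs$cvd_mortality_pct + r$outputs$noncvd_mortality_pct, 0)
  expect_equal(r$outputs$time_to_first_event, r$outputs$life_years)
  # deterministic degenerate case: microsim equals the cohort value exactly
  ms <- suppressWarnings(microsim_oracle(p, set, cm, uc, n = 1000, seed = 1,
                                         discount_rate = 0,
                                         horizon_years = 60, age_cap = 1e6))
  expect_equal(ms$outputs$qalys, r$outputs$qalys, tolerance = 1e-9)
  expect_equal(ms$outputs$life_years, r$outputs$life_years, tolerance = 1e-9)
})

test_that("constant-hazard life expectancy matches closed forms", {
  tr <- const_hazard_truth(list(cvd_death = 0.10, noncvd_death = 0.05))
  set <- equation_set_from_truth(tr, splice_time = Inf)
  p <- reference_profile(age = 65)
  cm <- default_true_cost_model()
  uc <- default_utility_catalogue()
  r <- suppressWarnings(run_cohort(p, set, cm, uc, discount_rate = 0,
                                   horizon_years = 150, age_cap = 1e6))
  expect_lt(abs(r$outputs$life_years - 1 / 0.15) * 0.15, 0.005)
  r2 <- suppressWarnings(run_cohort(p, set, cm, uc, discount_rate = 0.035,
                                    horizon_years = 150, age_cap = 1e6))
  target <- 1 / (0.15 + log(1.035))
  expect_lt(abs(r2$outputs$disc_life_years - target) / target, 0.01)
  # cause split of lifetime mortality
  expect_equal(r$outputs$cvd_mortality_pct, 100 * 2 / 3, tolerance = 0.01)
})

test_that("occupancy sums to one each cycle and death states absorb", {
  w <- fitted_world()
  g <- assign_risk_groups(w$cohort, w$set, 10)
  r <- run_cohort(g[[7]]$mean_covariates, w$set, w$cost_model, w$utilities)
  occ <- r$trace$stable + r$trace$post_mi + r$trace$post_is +
    r$trace$post_hs + r$trace$cvd_death + r$trace$noncvd_death
  expect_lt(max(abs(occ - 1)), 1e-10)
  expect_true(all(diff(r$trace$cvd_death) >= -1e-12))
  expect_true(all(diff(r$trace$noncvd_death) >= -1e-12))
  expect_lt(r$outputs$residual_live_mass, 1e-9)
  expect_equal(r$outputs$cvd_mortality_pct + r$outputs$noncvd_mortality_pct,
               100, tolerance = 1e-6)
  # first-endpoint probabilities close the probability ledger
  ledger <- r$outputs$p_first_mi + r$outputs$p_first_is +
    r$outputs$p_first_hs +
    unname(r$cifs$F[nrow(r$cifs$F), "cvd_death"]) * 100 +
    unname(r$cifs$F[nrow(r$cifs$F), "noncvd_death"]) * 100
  expect_equal(ledger, 100, tolerance = 1e-6)
})

test_that("discounting lowers every output and is monotone in the rate", {
  w <- fitted_world()
  x <- mean_covariate_row(w$cohort)
  rates <- c(0, 0.035, 0.07)
  runs <- lapply(rates, function(r) {
    run_cohort(x, w$set, w$cost_model, w$utilities, discount_rate = r)$outputs
  })
  for (r in runs) {
    expect_lte(r$disc_life_years, r$life_years)
    expect_lte(r$disc_qalys, r$qalys)
    expect_lte(r$disc_total_costs, r$total_costs)
    expect_lte(r$disc_cvd_costs, r$cvd_costs)
  }
  dq <- vapply(runs, `[[`, 0, "disc_qalys")
  expect_true(all(diff(dq) < 0))
  # undiscounted quantities are unaffected by the rate
  expect_equal(runs[[1]]$life_years, runs[[3]]$life_years)
})

test_that("cohort expectations equal microsimulation means (3 SE)", {
  # light check on two random worlds; the acceptance suite scales this up
  cm <- default_true_cost_model()
  uc <- default_utility_catalogue()
  for (s in c(101, 202)) {
    tr <- random_truth(s)
    set <- equation_set_from_truth(tr, splice_time = 10)
    p <- reference_profile(age = 62 + (s %% 7))
    p$heart_failure <- as.numeric(s %% 2 == 0)
    r <- run_cohort(p, set, cm, uc)$outputs
    ms <- microsim_oracle(p, set, cm, uc, n = 30000, seed = s + 1)
    for (f in stablecad:::OUTPUT_FIELDS) {
      tol <- equivalence_tol(f, r[[f]], ms)
      expect_lt(abs(r[[f]] - ms$outputs[[f]]), tol + 1e-12,
                label = sprintf("field %s (seed %d): |%g - %g|", f, s,
                                r[[f]], ms$outputs[[f]]))
    }
  }
})

test_that("microsimulation is reproducible under a fixed seed", {
  tr <- random_truth(7)
  set <- equation_set_from_truth(tr, splice_time = 10)
  p <- reference_profile()
  cm <- default_true_cost_model()
  uc <- default_utility_catalogue()
  a <- microsim_oracle(p, set, cm, uc, n = 2000, seed = 5)
  b <- microsim_oracle(p, set, cm, uc, n = 2000, seed = 5)
  expect_identical(a, b)
  expect_error(microsim_oracle(p, set, cm, uc, n = 10, seed = 1), "1000")
})

test_that("a free effective treatment never reduces discounted QALYs", {
  w <- fitted_world()
  g <- assign_risk_groups(w$cohort, w$set, 5)
  for (gi in c(1, 3, 5)) {
    base <- run_cohort(g[[gi]]$mean_covariates, w$set, w$cost_model,
                       w$utilities)$outputs
    qal <- base$disc_qalys
    for (rho in c(0.1, 0.3)) {
      tr <- run_cohort(g[[gi]]$mean_covariates, w$set, w$cost_model,
                       w$utilities, treatment = treatment_scenario(rho))$outputs
      expect_gte(tr$disc_qalys, qal - 1e-9)
      expect_lte(tr$cvd_mortality_pct, base$cvd_mortality_pct + 1e-9)
      qal <- tr$disc_qalys
    }
  }
})
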