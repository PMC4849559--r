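# Cohort generator, event-history simulation and cost panel.

test_that("generation is reproducible and marginals track the config", {
  a <- generate_cohort(10, seed = 1)
  b <- generate_cohort(10, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(10, seed = 2)))

  big <- generate_cohort(50000, seed = 5)
  expect_lt(abs(mean(big$hypertension) - 0.76), 0.01)
  expect_lt(abs(mean(big$sex == "female") - 0.44), 0.01)
  expect_lt(abs(mean(big$cad_subtype == "stable_angina") - 0.47), 0.01)
  expect_lt(abs(mean(big$total_chol) - 4.79), 0.03)
  # hard invariants
  expect_true(all(big$age_entry >= 18 & big$age_entry <= 110))
  for (v in c("total_chol", "hdl", "heart_rate", "creatinine", "wcc",
              "haemoglobin")) {
    expect_true(all(big[[v]] > 0))
  }
  expect_true(all(big$deprived_quintile %in% 1:5))
})

test_that("invalid generator proportions are rejected", {
  cfg <- default_cohort_config()
  cfg$binary_probs["diabetes"] <- 1.2
  expect_error(generate_cohort(10, 1, cfg), "\\[0, 1\\]")
  cfg2 <- default_cohort_config()
  cfg2$subtype_probs <- cfg2$subtype_probs * 2
  expect_error(generate_cohort(10, 1, cfg2), "sum to 1")
})

test_that("degenerate competing-risk worlds behave as closed forms say", {
  co <- generate_cohort(4000, 3)
  # single cause: constant non-CVD hazard only
  tr <- const_hazard_truth(list(noncvd_death = 0.1))
  h <- simulate_event_histories(co, tr, seed = 4)
  expect_true(all(h$first_event == "noncvd_death"))
  expect_true(all(h$post_event_outcome == "none"))

  # two causes: MI 0.10 vs non-CVD death 0.05 -> cause split 2/3
  tr2 <- const_hazard_truth(list(mi = 0.10, noncvd_death = 0.05))
  co2 <- generate_cohort(100000, 6)
  h2 <- simulate_event_histories(co2, tr2, seed = 7)
  p_mi <- mean(h2$first_event == "mi")
  expect_lt(abs(p_mi - 2 / 3), 3 * sqrt((2 / 3) * (1 / 3) / nrow(co2)))
  # mean first-event time 1/0.15
  m <- mean(h2$time_first_event)
  se <- sd(h2$time_first_event) / sqrt(nrow(co2))
  expect_lt(abs(m - 1 / 0.15), 3 * se)
})

test_that("empirical CIFs converge to the analytic competing-risk law", {
  tr <- const_hazard_truth(list(mi = 0.08, cvd_death = 0.04,
                                noncvd_death = 0.06))
  co <- generate_cohort(50000, 8)
  h <- simulate_event_histories(co, tr, seed = 9)
  htot <- 0.18
  tgrid <- seq(0.5, 8, by = 0.5)
  for (ep in c("mi", "cvd_death")) {
    hk <- c(mi = 0.08, cvd_death = 0.04)[[ep]]
    F_emp <- vapply(tgrid, function(u) {
      mean(h$first_event == ep & h$time_first_event <= u)
    }, numeric(1))
    F_th <- (hk / htot) * (1 - exp(-htot * tgrid))
    expect_lt(max(abs(F_emp - F_th)), 0.006)
  }
})

test_that("event histories never contain a second non-fatal event", {
  w <- fitted_world()
  h <- w$histories
  nf <- h$first_event %in% c("mi", "ischaemic_stroke", "haemorrhagic_stroke")
  expect_true(all(h$post_event_outcome[nf] %in%
                    c("cvd_death", "noncvd_death", "censored")))
  expect_true(all(h$post_event_outcome[!nf] == "none"))
  expect_true(all(is.na(h$time_post_event[!nf])))
  expect_true(all(h$time_post_event[nf] >= 0))
  expect_true(all(h$time_first_event >= 0))
})

test_that("cost panel truncates at death and is exact when noiseless", {
  co <- reference_profile()
  # death at a known time: constant cvd_death hazard, huge -> dies early
  tr <- const_hazard_truth(list(cvd_death = 1e-9))
  tr$cost$dispersion <- 0
  hi <- data.frame(patient_id = co$patient_id, first_event = "cvd_death",
                   time_first_event = 3.5 * DL,  # dies during cycle 3
                   post_event_outcome = "none", time_post_event = NA_real_)
  panel <- simulate_cost_panel(co, hi, tr, seed = 1)
  expect_identical(panel$cycle_index, 0:3)
  expect_true(all(panel$state_at_cycle == "stable"))
  # noiseless: observed equals the deterministic predictor
  x <- profile_model_matrix(co)
  pred <- cycle_cost(tr$cost, x, "stable", NA, co$age_entry + panel$cycle_index * DL)
  expect_equal(panel$observed_cost, pred$total)
  expect_equal(panel$cost_cvd + panel$cost_other, panel$observed_cost)
})

test_that("acute-cycle cost uplift is recovered from simulated panels", {
  # reference patients, truth tuned so acute uplift is exactly +2000 GBP
  co <- reference_profile()[rep(1, 4000), ]
  co$patient_id <- sprintf("P%06d", seq_len(nrow(co)))
  rownames(co) <- NULL
  tr <- const_hazard_truth(list(mi = 0.25, noncvd_death = 0.02),
                           post_cvd = 0.02, post_ncvd = 0.02)
  g <- tr$cost$coef_cvd * 0
  g["intercept"] <- log(300)
  tr$cost$coef_cvd <- g
  go <- tr$cost$coef_other * 0
  go["intercept"] <- log(200)
  tr$cost$coef_other <- go
  # stable total = 500; acute cycle adds 2000 via the CVD component
  tr$cost$coef_cvd["acute"] <- log((300 + 2000) / 300)
  tr$cost$dispersion <- 0.3
  hi <- simulate_event_histories(co, tr, seed = 21)
  panel <- simulate_cost_panel(co, hi, tr, seed = 22)
  acute <- panel$state_at_cycle == "post_mi" & panel$cycles_since_event == 0
  stable <- panel$state_at_cycle == "stable"
  dd <- mean(panel$observed_cost[acute]) - mean(panel$observed_cost[stable])
  se <- sqrt(var(panel$observed_cost[acute]) / sum(acute) +
               var(panel$observed_cost[stable]) / sum(stable))
  expect_lt(abs(dd - 2000), 3 * se)
})
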