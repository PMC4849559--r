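# Risk stratification and probabilistic sensitivity analysis.

test_that("risk groups partition the cohort into ordered equal tenths", {
  w <- fitted_world()
  g <- assign_risk_groups(w$cohort, w$set, 10)
  sizes <- vapply(g, function(x) length(x$member_ids), integer(1))
  expect_true(max(sizes) - min(sizes) <= 1)
  ids <- unlist(lapply(g, `[[`, "member_ids"))
  expect_setequal(ids, w$cohort$patient_id)
  expect_equal(length(ids), nrow(w$cohort))  # pairwise disjoint
  risks <- vapply(g, `[[`, 0, "mean_risk")
  expect_true(all(diff(risks) > 0))
  # exact split for n divisible by k
  co <- w$cohort[1:100, ]
  g100 <- assign_risk_groups(co, w$set, 10)
  expect_true(all(vapply(g100, function(x) length(x$member_ids), 1L) == 10))
  expect_error(assign_risk_groups(co, w$set, 101), "more groups")
})

test_that("risk at group-mean covariates sits below the group mean risk", {
  # convexity pattern: cohort-mean risk exceeds risk at the mean covariates
  w <- fitted_world()
  risk <- cohort_composite_risk(w$set, w$cohort)
  xm <- mean_covariate_row(w$cohort)
  fem <- unname(xm[1, "female"])
  age <- (unname(xm[1, "age10"]) + 6.5) * 10
  r_at_mean <- predict_5yr_composite_risk(w$set, xm, fem, age)
  expect_lt(r_at_mean, mean(risk))
})

test_that("the representative patient is the group median by risk", {
  w <- fitted_world()
  g3 <- list(index = 1,
             member_ids = c("A", "B", "C"),
             member_risk = c(0.1, 0.2, 0.9))
  co <- w$cohort[1:3, ]
  co$patient_id <- c("A", "B", "C")
  rep3 <- representative_patient(g3, co)
  expect_equal(rep3$patient_id, "B")
  g1 <- list(index = 1, member_ids = "A", member_risk = 0.5)
  expect_equal(representative_patient(g1, co)$patient_id, "A")
  # even size: lower of the two central members
  g4 <- list(index = 1, member_ids = c("A", "B", "C", "D"),
             member_risk = c(0.4, 0.1, 0.3, 0.2))
  co4 <- w$cohort[1:4, ]; co4$patient_id <- c("A", "B", "C", "D")
  expect_equal(representative_patient(g4, co4)$patient_id, "D")
  # representative risk lies within the group range
  g <- assign_risk_groups(w$cohort[1:200, ], w$set, 4)
  for (gr in g) {
    rp <- representative_patient(gr, w$cohort)
    r <- cohort_composite_risk(w$set, rp)
    expect_gte(r, min(gr$member_risk) - 1e-12)
    expect_lte(r, max(gr$member_risk) + 1e-12)
  }
})

test_that("PSA with zero variance reproduces the point estimate", {
  tr <- default_true_parameters()
  set <- equation_set_from_truth(tr, splice_time = 10)  # vcov all zero
  p <- reference_profile()
  cm <- default_true_cost_model()                        # vcov all zero
  psa <- run_psa(p, set, cm, tr$utility, n_iter = 8, seed = 3,
                 utility_sd = 0)
  for (f in c("disc_qalys", "disc_total_costs", "life_years")) {
    expect_true(all(abs(psa$draws[[f]] - psa$point[[f]]) < 1e-9))
    expect_equal(unname(psa$ci["lower", f]), psa$point[[f]], tolerance = 1e-9)
  }
})

test_that("PSA is reproducible and its intervals cover the point estimate", {
  w <- fitted_world()
  g <- assign_risk_groups(w$cohort, w$set, 10)
  x <- g[[5]]$mean_covariates
  a <- run_psa(x, w$set, w$cost_model, w$utilities, n_iter = 30, seed = 9)
  b <- run_psa(x, w$set, w$cost_model, w$utilities, n_iter = 30, seed = 9)
  expect_identical(a$ci, b$ci)
  expect_false(identical(
    a$ci, run_psa(x, w$set, w$cost_model, w$utilities, n_iter = 30,
                  seed = 10)$ci))
  # point estimates inside the percentile intervals for the key outputs
  for (f in c("disc_qalys", "disc_total_costs", "cvd_mortality_pct")) {
    expect_gte(psa_margin <- a$point[[f]] - a$ci["lower", f], 0)
    expect_gte(a$ci["upper", f] - a$point[[f]], 0)
  }
})

test_that("PSA intervals tighten when the cohort is larger", {
  # 4x the estimation data should roughly halve the CI width
  co_small <- generate_cohort(1500, 61)
  co_big <- generate_cohort(6000, 62)
  tr <- default_true_parameters()
  width <- function(co, seed) {
    hi <- simulate_event_histories(co, tr, seed)
    set <- suppressWarnings(fit_risk_equations(co, hi))
    pa <- simulate_cost_panel(co, hi, tr, seed + 1)
    cmod <- fit_cost_model(pa, co)
    x <- mean_covariate_row(co)
    # small cohorts produce materially indefinite numeric Hessians, so the
    # PSD-repair warnings are expected here
    p <- suppressWarnings(run_psa(x, set, cmod, tr$utility, n_iter = 60,
                                  seed = 77, utility_sd = 0))
    unname(p$ci["upper", "disc_qalys"] - p$ci["lower", "disc_qalys"])
  }
  w_small <- width(co_small, 63)
  w_big <- width(co_big, 65)
  expect_lt(w_big, w_small)
})

test_that("non-PSD covariance matrices are repaired with a warning", {
  sig <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_warning(stablecad:::rmvn(5, c(0, 0), sig), "PSD")
  ok <- stablecad:::rmvn(5, c(1, 2), diag(0, 2))
  expect_true(all(ok[, 1] == 1 & ok[, 2] == 2))
})
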