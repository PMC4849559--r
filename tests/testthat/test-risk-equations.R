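# Parametric fitting, AIC selection, life-table splice.

test_that("exponential MLE equals the closed form D/T", {
  set.seed(1)
  n <- 500
  tt <- rexp(n, 0.2)
  cens <- rexp(n, 0.1)
  time <- pmin(tt, cens); status <- as.numeric(tt <= cens)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  f <- fit_parametric(time, status, X, "exponential")
  expect_equal(exp(-unname(f$coef)), sum(status) / sum(time), tolerance = 1e-7)
  expect_equal(f$AIC, 2 * f$npar - 2 * f$loglik, tolerance = 1e-9)
})

test_that("Weibull and lognormal fits match survreg and recover truth", {
  skip_if_not_installed("survival")
  set.seed(2)
  n <- 10000
  X <- cbind(intercept = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  beta <- c(2.0, -0.5, 0.3); sigma <- 0.8
  mu <- drop(X %*% beta)
  for (fam in c("weibull", "lognormal")) {
    tt <- aft_rtime(fam, n, mu, sigma)
    cens <- rexp(n, 0.15)
    time <- pmin(tt, cens); status <- as.numeric(tt <= cens)
    f <- fit_parametric(time, status, X, fam)
    sr <- survival::survreg(
      survival::Surv(time, status) ~ x1 + x2,
      data = data.frame(x1 = X[, 2], x2 = X[, 3]), dist = fam)
    expect_equal(unname(f$coef), unname(coef(sr)), tolerance = 1e-4)
    expect_equal(f$sigma, sr$scale, tolerance = 1e-4)
    # truth within 3 Wald standard errors
    se <- sqrt(diag(f$vcov))[seq_along(beta)]
    expect_true(all(abs(f$coef - beta) < 3 * se))
  }
})

test_that("generalised gamma honours its nesting structure", {
  set.seed(3)
  n <- 4000
  X <- cbind(intercept = 1, x = rnorm(n))
  mu <- drop(X %*% c(1.8, -0.4))
  tt <- aft_rtime("weibull", n, mu, 0.8)
  cens <- rexp(n, 0.2)
  time <- pmin(tt, cens); status <- as.numeric(tt <= cens)
  fw <- fit_parametric(time, status, X, "weibull")
  fl <- fit_parametric(time, status, X, "lognormal")
  fg1 <- fit_parametric(time, status, X, "gengamma", fixed = list(Q = 1))
  expect_equal(fg1$loglik, fw$loglik, tolerance = 1e-6)
  fg <- fit_parametric(time, status, X, "gengamma")
  expect_gte(fg$loglik, fw$loglik - 1e-6)
  expect_gte(fg$loglik, fl$loglik - 1e-6)
})

test_that("errors: zero events, too few events, positive times", {
  X <- matrix(1, 20, 1, dimnames = list(NULL, "intercept"))
  expect_error(fit_parametric(rexp(20), rep(0, 20), X, "weibull"),
               "no events")
  expect_error(fit_parametric(rexp(20), c(1, rep(0, 19)), X, "weibull"),
               "events")
  expect_error(fit_parametric(c(-1, rexp(19)), rep(1, 20), X, "weibull"),
               "positive")
})

test_that("AIC selection picks the minimum and breaks ties to fewer params", {
  mk <- function(aic, npar, fp = "fp") {
    structure(list(AIC = aic, npar = npar, fingerprint = fp,
                   family = "weibull"), class = "scad_survfit")
  }
  fits <- list(mk(100.0, 3), mk(98.2, 4), mk(103.5, 5))
  expect_equal(select_best_family(fits)$AIC, 98.2)
  ties <- list(mk(98.2, 5), mk(98.2, 4))
  expect_equal(select_best_family(ties)$npar, 4)
  single <- list(mk(42, 2))
  expect_identical(select_best_family(single), single[[1]])
  expect_error(select_best_family(list(mk(1, 2, "a"), mk(2, 2, "b"))),
               "same data")
})

test_that("AIC selection recovers the generating family", {
  # a light version; the acceptance suite runs the full 20-replicate study
  set.seed(4)
  n <- 5000
  X <- cbind(intercept = 1, x = rnorm(n))
  mu <- drop(X %*% c(2.2, -0.5))
  hits <- 0
  reps <- 5
  for (r in seq_len(reps)) {
    tt <- aft_rtime("weibull", n, mu, 0.6)
    cens <- rexp(n, 0.12)
    time <- pmin(tt, cens); status <- as.numeric(tt <= cens)
    fits <- lapply(c("exponential", "weibull", "lognormal", "gengamma"),
                   function(f) fit_parametric(time, status, X, f))
    best <- select_best_family(fits)
    if (best$family %in% c("weibull", "gengamma")) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("life-table splice switches hazards at the splice boundary", {
  lt <- make_life_table()
  tr <- const_hazard_truth(list(noncvd_death = 0.05))
  set <- equation_set_from_truth(tr, lt, splice_time = 10)
  p <- reference_profile(age = 60)
  x <- profile_model_matrix(p)
  h_before <- spliced_noncvd_hazard(set, x, 0, 60, 9.99)
  h_after <- spliced_noncvd_hazard(set, x, 0, 60, 10.01)
  expect_equal(h_before, 0.05, tolerance = 1e-9)
  q70 <- lt$qx[lt$sex == "male" & lt$age == 70]
  expect_equal(h_after, -log(1 - q70), tolerance = 1e-12)
  # closed form -log(1 - q)
  lt2 <- lt; lt2$qx[lt2$sex == "male" & lt2$age == 70] <- 0.02
  set2 <- equation_set_from_truth(tr, lt2, splice_time = 10)
  expect_equal(spliced_noncvd_hazard(set2, x, 0, 60, 10.01),
               -log(0.98), tolerance = 1e-12)
  expect_equal(-log(0.98), 0.020203, tolerance = 1e-4)
  # terminal row: certain death within the year, handled as a capped rate
  h_term <- spliced_noncvd_hazard(set, x, 0, 60, 55)
  expect_gt(h_term, 20)
  expect_true(is.finite(h_term))
})

test_that("life table validation catches gaps and bad terminal rows", {
  lt <- make_life_table()
  expect_silent(stablecad:::validate_life_table(lt))
  gap <- lt[!(lt$sex == "male" & lt$age == 60), ]
  expect_error(stablecad:::validate_life_table(gap), "contiguous")
  noterm <- lt
  noterm$qx[noterm$sex == "female" & noterm$age == 110] <- 0.5
  expect_error(stablecad:::validate_life_table(noterm), "terminal")
})

test_that("fitted equation sets contain exactly 11 equations and sane fits", {
  w <- fitted_world()
  set <- w$set
  expect_s3_class(set, "scad_eqset")
  expect_length(set$primary, 5)
  expect_equal(sum(lengths(set$post)), 6)
  for (f in set$primary) {
    expect_true(f$sigma > 0)
    ev <- eigen(f$vcov, only.values = TRUE)$values
    expect_true(all(ev > -1e-8 * max(abs(ev))))
    expect_equal(f$AIC, 2 * f$npar - 2 * f$loglik, tolerance = 1e-9)
  }
  # post-event fits use only sex and age at event
  for (st in set$post) {
    for (f in st) {
      expect_true(all(names(f$coef) %in%
                        c("intercept", "female", "age_event10")))
    }
  }
})

test_that("survival curves from fits are monotone with S(0) = 1", {
  w <- fitted_world()
  x <- mean_covariate_row(w$cohort)
  tgrid <- seq(0, 40, length.out = 1000)
  for (ep in names(w$set$primary)) {
    fit <- w$set$primary[[ep]]
    mu <- stablecad:::fit_mu(fit, x)
    H <- aft_cumhaz(fit$family, tgrid, rep(mu, length(tgrid)), fit$sigma, fit$Q)
    S <- exp(-H)
    expect_equal(S[1], 1)
    expect_true(all(diff(S) <= 1e-12))
    expect_true(all(aft_hazard(fit$family, tgrid[-1], rep(mu, 999),
                               fit$sigma, fit$Q) >= 0))
  }
})

test_that("composite 5-year risk follows the exponential closed form", {
  tr <- const_hazard_truth(list(cvd_death = 0.10, noncvd_death = 0.05))
  set <- equation_set_from_truth(tr, splice_time = Inf)
  p <- reference_profile()
  x <- profile_model_matrix(p)
  expect_equal(predict_5yr_composite_risk(set, x, 0, 65),
               (0.10 / 0.15) * (1 - exp(-0.75)), tolerance = 1e-6)
  tr0 <- const_hazard_truth(list(noncvd_death = 0.05))
  set0 <- equation_set_from_truth(tr0, splice_time = Inf)
  expect_lt(predict_5yr_composite_risk(set0, x, 0, 65), 1e-10)
})
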