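# CIF composition, per-cycle transitions, treatment effects.

const_cumhaz <- function(h) function(t) h * t

test_that("CIFs match the exponential closed form and conserve mass", {
  ch <- list(mi = const_cumhaz(0.10), noncvd_death = const_cumhaz(0.05))
  nc <- ceiling(6 / DL)
  cifs <- build_cifs(ch, nc, DL, subdiv = 8)
  F_th <- (0.10 / 0.15) * (1 - exp(-0.15 * cifs$t))
  expect_lt(max(abs(cifs$F[, "mi"] - F_th)), 1e-6)
  expect_lt(max(abs(cifs$S - exp(-0.15 * cifs$t))), 1e-6)
  expect_lt(max(abs(cifs$S + rowSums(cifs$F) - 1)), 1e-8)
  expect_equal(cifs$S[1], 1)
  expect_true(all(diff(cifs$S) <= 0))
  expect_true(all(apply(cifs$F, 2, function(x) all(diff(x) >= 0))))
})

test_that("single cause gives F = 1 - S; zero hazards give S = 1", {
  ch <- list(mi = function(t) 0.2 * t^1.3)   # non-constant hazard
  cifs <- build_cifs(ch, 20, DL, subdiv = 16)
  expect_equal(cifs$F[, "mi"], 1 - cifs$S, tolerance = 1e-12)
  ch0 <- list(mi = function(t) rep(0, length(t)))
  cifs0 <- build_cifs(ch0, 20, DL)
  expect_true(all(cifs0$S == 1))
  expect_true(all(cifs0$F == 0))
})

test_that("halving the quadrature step changes no CIF by more than 1e-7", {
  ch <- list(mi = function(t) (t * exp(-2))^(1 / 0.8),
             cvd = function(t) (t * exp(-2.6))^(1 / 1.2),
             ncvd = function(t) -pnorm((log(pmax(t, 1e-300)) - 2.4) / 0.9,
                                       lower.tail = FALSE, log.p = TRUE) * (t > 0))
  # 64 is the engine default; halving the step must not move any CIF
  a <- build_cifs(ch, 40, DL, subdiv = 64)
  b <- build_cifs(ch, 40, DL, subdiv = 128)
  expect_lt(max(abs(a$F - b$F)), 1e-7)
})

test_that("negative hazards abort CIF construction", {
  ch <- list(mi = function(t) -0.1 * t)
  expect_error(build_cifs(ch, 10, DL), "negative")
})

test_that("stable-state per-cycle transitions match the exponential formula", {
  ch <- list(mi = const_cumhaz(0.10), ischaemic_stroke = const_cumhaz(0),
             haemorrhagic_stroke = const_cumhaz(0),
             cvd_death = const_cumhaz(0), noncvd_death = const_cumhaz(0.05))
  cifs <- build_cifs(ch, 10, DL, subdiv = 8)
  tp <- stable_state_transitions(cifs, 0)
  expect_equal(unname(tp["stable"]), exp(-0.15 * DL), tolerance = 1e-9)
  expect_equal(unname(tp["post_mi"]), (2 / 3) * (1 - exp(-0.15 * DL)),
               tolerance = 1e-9)
  expect_equal(sum(tp), 1, tolerance = 1e-12)
  # spec's rounded cycle length: 0.2465 y gives the printed 0.9637 / 0.0242
  expect_equal(round(exp(-0.15 * 0.2465), 4), 0.9637)
})

test_that("transition rows are probabilities summing to one, for random draws", {
  set.seed(10)
  for (r in 1:40) {
    h <- runif(5, 0, 0.5)
    ch <- setNames(lapply(h, const_cumhaz),
                   c("mi", "ischaemic_stroke", "haemorrhagic_stroke",
                     "cvd_death", "noncvd_death"))
    cifs <- build_cifs(ch, 8, DL, subdiv = 4)
    for (j in c(0, 3, 6)) {
      tp <- stable_state_transitions(cifs, j)
      expect_true(all(tp >= 0 & tp <= 1))
      expect_equal(sum(tp), 1, tolerance = 1e-12)
    }
  }
})

test_that("post-event transitions split deaths by cause and respect age", {
  tr <- const_hazard_truth(list(mi = 0.1), post_cvd = 0.2, post_ncvd = 0.1)
  set <- equation_set_from_truth(tr, splice_time = Inf)
  tp <- post_event_transitions(set, "post_mi", 0, 70, 0)
  p_die <- 1 - exp(-0.3 * DL)
  expect_equal(unname(tp["cvd_death"]), p_die * 2 / 3, tolerance = 1e-9)
  expect_equal(unname(tp["noncvd_death"]), p_die * 1 / 3, tolerance = 1e-9)
  expect_equal(unname(tp["post_mi"]), 1 - p_die, tolerance = 1e-9)

  # zero post hazards: stay forever
  tr0 <- const_hazard_truth(list(mi = 0.1))
  set0 <- equation_set_from_truth(tr0, splice_time = Inf)
  tp0 <- post_event_transitions(set0, "post_mi", 0, 70, 5)
  expect_equal(unname(tp0["post_mi"]), 1, tolerance = 1e-10)

  # positive age coefficient on log-hazard scale: death risk rises with age
  tr2 <- const_hazard_truth(list(mi = 0.1), post_cvd = 0.05, post_ncvd = 0.05)
  for (st in names(tr2$post)) {
    tr2$post[[st]]$cvd_death$beta["age_event10"] <- -0.5  # AFT: shorter times
  }
  set2 <- equation_set_from_truth(tr2, splice_time = Inf)
  ages <- c(55, 65, 75, 85)
  p <- vapply(ages, function(a) {
    unname(post_event_transitions(set2, "post_mi", 0, a, 0)["cvd_death"])
  }, numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("treatment scales CVD hazards only, with config switches", {
  h <- c(mi = 0.10, ischaemic_stroke = 0.05, haemorrhagic_stroke = 0.01,
         cvd_death = 0.08, noncvd_death = 0.20)
  expect_identical(apply_treatment(h, 0), h)
  treated <- apply_treatment(h, 0.2)
  expect_equal(unname(treated["mi"]), 0.08)
  expect_equal(unname(treated["noncvd_death"]), 0.20)
  expect_equal(unname(treated["haemorrhagic_stroke"]), 0.008)
  no_hs <- apply_treatment(h, 0.2, include_haemorrhagic = FALSE)
  expect_equal(unname(no_hs["haemorrhagic_stroke"]), 0.01)
  expect_error(apply_treatment(h, 1), "rho")
  expect_error(treatment_scenario(-0.1), "rho")
})

test_that("CVD CIFs fall and the non-CVD CIF rises with the hazard reduction", {
  tr <- default_true_parameters()
  set <- equation_set_from_truth(tr, splice_time = 10)
  p <- reference_profile(age = 70)
  p$heart_failure <- 1
  x <- profile_model_matrix(p)
  rhos <- c(0, 0.1, 0.2, 0.3, 0.4)
  F_cvd <- F_ncvd <- numeric(length(rhos))
  for (i in seq_along(rhos)) {
    trmt <- if (rhos[i] > 0) treatment_scenario(rhos[i]) else NULL
    ch <- stablecad:::profile_cumhaz_set(set, x, 0, 70, trmt)
    cifs <- build_cifs(ch, 80, DL, subdiv = 4)
    iend <- nrow(cifs$F)
    F_cvd[i] <- sum(cifs$F[iend, c("mi", "ischaemic_stroke",
                                   "haemorrhagic_stroke", "cvd_death")])
    F_ncvd[i] <- cifs$F[iend, "noncvd_death"]
  }
  expect_true(all(diff(F_cvd) < 0))
  expect_true(all(diff(F_ncvd) > 0))
})
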