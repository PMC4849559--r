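# Six-state Markov cohort engine and its individual-level microsimulation
# oracle.
#
# States: stable, post-MI, post-ischaemic-stroke, post-haemorrhagic-stroke,
# CVD death, non-CVD death. Cycles are 90 days. Post-event mortality depends
# on age at event and time since event, so occupancy of each post-event
# state is tracked by entry cycle (a semi-Markov cohort trace). Costs accrue
# per full cycle to the cycle-start state (panel-billing convention);
# person-time (life years, QALYs, treatment exposure) uses the within-cycle
# trapezoid — mass transitioning to death accrues half a cycle — which
# removes the half-cycle bias from life expectancy. Both engines share the
# same per-cycle transition probabilities and accrual conventions, so the
# cohort expectations equal the microsimulation means up to Monte Carlo
# error.

# Canonical internal profile: one-row design matrix + female fraction +
# entry age. Accepts a one-row profile data frame or a design row.
as_profile_row <- function(profile) {
  if (is.list(profile) && !is.null(profile$x_primary)) return(profile)
  if (is.matrix(profile)) {
    x <- profile[1, , drop = FALSE]
    return(list(x_primary = x,
                female = unname(x[1, "female"]),
                age_entry = (unname(x[1, "age10"]) + .CENTRES[["age10"]]) * 10))
  }
  stopifnot(is.data.frame(profile), nrow(profile) == 1)
  list(x_primary = profile_model_matrix(profile),
       female = sex_indicator(profile$sex),
       age_entry = profile$age_entry)
}

#' Run the cohort model for one patient profile
#'
#' Propagates a cohort of identical patients through the six-state model in
#' 90-day cycles until the living mass is extinct (or an attained-age /
#' horizon cap binds), accruing discounted and undiscounted life years,
#' QALYs, and total/CVD costs.
#'
#' @param profile One-row profile data frame, or a one-row design matrix
#'   (e.g. a risk-group mean from \code{\link{mean_covariate_row}}).
#' @param set \code{scad_eqset} of the 11 risk equations.
#' @param cost_model \code{scad_costmodel}.
#' @param utilities \code{scad_utilities}.
#' @param discount_rate Annual discount rate (default 0.035).
#' @param treatment Optional \code{scad_treatment}.
#' @param horizon_years Optional cap on model time (default: run to the
#'   attained-age cap of 110 plus a short run-out).
#' @param subdiv Within-cycle subdivisions for the CIF composition
#'   (default 64; halving the step at this resolution moves no CIF by more
#'   than 1e-7).
#' @param age_cap Attained-age cap in years (default 110).
#' @return List with \code{trace} (per-cycle occupancy and accruals) and
#'   \code{outputs} (a \code{scad_outputs} list of lifetime summaries).
#' @export
run_cohort <- function(profile, set, cost_model, utilities,
                       discount_rate = 0.035, treatment = NULL,
                       horizon_years = Inf, subdiv = 64L, age_cap = 110) {
  pr <- as_profile_row(profile)
  dl <- CYCLE_YEARS
  # run-out past the age cap lets the terminal life-table row absorb
  # residual mass (q = 1 means near-certain death per cycle)
  run_years <- min(horizon_years, age_cap - pr$age_entry + 2)
  n_cycles <- max(1L, ceiling(run_years / dl))
  lt_fun <- if (!is.infinite(set$splice_time)) {
    lt_cumhaz_fun(set$life_table, pr$female, pr$age_entry)
  } else {
    NULL
  }
  ch <- profile_cumhaz_set(set, pr$x_primary, pr$female, pr$age_entry,
                           treatment, lt_fun)
  cifs <- build_cifs(ch, n_cycles, dl, subdiv)
  tgrid <- cifs$t
  v <- (1 + discount_rate)^(-tgrid[-length(tgrid)])  # cycle-start discount

  post_states <- c("post_mi", "post_is", "post_hs")
  cause_of <- c(post_mi = "mi", post_is = "ischaemic_stroke",
                post_hs = "haemorrhagic_stroke")

  # precompute per-entry-cycle post-event death probabilities as matrices
  # indexed [entry cycle e, s + 1]; entrants during cycle e arrive at e+1
  # and the event age is mid-cycle
  age_event <- pr$age_entry + tgrid[-length(tgrid)] + dl / 2
  t_event <- tgrid[-length(tgrid)] + dl / 2
  pp_cvd <- pp_ncvd <- lapply(post_states, function(st) {
    matrix(0, n_cycles, n_cycles)
  })
  names(pp_cvd) <- names(pp_ncvd) <- post_states
  for (st in post_states) {
    for (e in seq_len(max(n_cycles - 1L, 0L))) {
      smax <- n_cycles - e
      prb <- post_event_cycle_probs(set, st, pr$female, age_event[e],
                                    0:(smax - 1), t_event[e], treatment,
                                    lt_fun, dl)
      pp_cvd[[st]][e, seq_len(smax)] <- prb$p_cvd
      pp_ncvd[[st]][e, seq_len(smax)] <- prb$p_noncvd
    }
  }

  # occupancy bookkeeping
  stable <- cifs$S[-length(cifs$S)]                    # S at cycle starts
  entrants <- sapply(post_states, function(st) {
    diff(cifs$F[, cause_of[[st]]])                     # mass arriving at e+1
  })
  entrants <- matrix(entrants, ncol = 3, dimnames = list(NULL, post_states))

  occ_post <- matrix(0, n_cycles, 3, dimnames = list(NULL, post_states))
  dead_cvd_post <- 0; dead_ncvd_post <- 0
  cost_tot <- cost_cvd <- qaly <- ly <- numeric(n_cycles)
  d_cost_tot <- d_cost_cvd <- d_qaly <- d_ly <- numeric(n_cycles)
  exposure <- d_exposure <- numeric(n_cycles)          # treatment-price time

  age_now <- pr$age_entry + tgrid[-length(tgrid)]
  cst_stable <- cycle_cost(cost_model, pr$x_primary, "stable", NA, age_now)
  u_stable <- cycle_utility(utilities, pr$female, "stable", NA, age_now)
  # post-event cost/utility depend on cycles-since-event only through the
  # acute (s = 0) / recent (1..3) / late bands of the cost design and the
  # acute utility multiplier, so precompute one vector over cycles per band
  cost_band <- util_band <- list()
  for (st in post_states) {
    cost_band[[st]] <- list(
      acute = cycle_cost(cost_model, pr$x_primary, st, 0L, age_now),
      recent = cycle_cost(cost_model, pr$x_primary, st, 1L, age_now),
      late = cycle_cost(cost_model, pr$x_primary, st, 4L, age_now))
    util_band[[st]] <- list(
      acute = cycle_utility(utilities, pr$female, st, 0L, age_now),
      late = cycle_utility(utilities, pr$female, st, 4L, age_now))
  }

  # per-post-state slice ledgers: mass[e] alive in state entered at cycle e
  slice <- list(post_mi = numeric(n_cycles), post_is = numeric(n_cycles),
                post_hs = numeric(n_cycles))
  occ_cvd_dead <- occ_ncvd_dead <- numeric(n_cycles)
  for (j in seq_len(n_cycles)) {
    # accrue stable state (occupancy at cycle start); person-time uses the
    # within-cycle trapezoid: mass dying during the cycle accrues half a
    # cycle at its starting state's utility
    m_st <- stable[j]
    live_mass <- m_st
    d_stable <- (cifs$F[j + 1, "cvd_death"] - cifs$F[j, "cvd_death"]) +
      (cifs$F[j + 1, "noncvd_death"] - cifs$F[j, "noncvd_death"])
    pt_j <- (m_st - d_stable / 2) * dl          # person-time
    cost_j <- m_st * cst_stable$total[j]
    costc_j <- m_st * cst_stable$cvd[j]
    qaly_j <- (m_st - d_stable / 2) * u_stable[j] * dl
    expo_j <- (m_st - d_stable / 2) * dl
    occ_cvd_dead[j] <- cifs$F[j, "cvd_death"] + dead_cvd_post
    occ_ncvd_dead[j] <- cifs$F[j, "noncvd_death"] + dead_ncvd_post
    # accrue and transition post-event slices
    for (si in seq_along(post_states)) {
      st <- post_states[si]
      occ_post[j, st] <- sum(slice[[st]])
      es <- which(slice[[st]] > 0)
      if (length(es)) {
        mass <- slice[[st]][es]
        s_idx <- j - es - 1L                    # cycles since event
        cb <- cost_band[[st]]
        cc_tot <- ifelse(s_idx == 0L, cb$acute$total[j],
                         ifelse(s_idx <= 3L, cb$recent$total[j], cb$late$total[j]))
        cc_cvd <- ifelse(s_idx == 0L, cb$acute$cvd[j],
                         ifelse(s_idx <= 3L, cb$recent$cvd[j], cb$late$cvd[j]))
        uu <- ifelse(s_idx == 0L, util_band[[st]]$acute[j],
                     util_band[[st]]$late[j])
        live_mass <- live_mass + sum(mass)
        idx <- cbind(es, j - es)
        pc <- pp_cvd[[st]][idx]
        pn <- pp_ncvd[[st]][idx]
        dying <- mass * (pc + pn)
        pt_j <- pt_j + sum(mass - dying / 2) * dl
        cost_j <- cost_j + sum(mass * cc_tot)
        costc_j <- costc_j + sum(mass * cc_cvd)
        qaly_j <- qaly_j + sum((mass - dying / 2) * uu) * dl
        if (is.null(treatment) || !treatment$until_first_event) {
          expo_j <- expo_j + sum(mass - dying / 2) * dl
        }
        dead_cvd_post <- dead_cvd_post + sum(mass * pc)
        dead_ncvd_post <- dead_ncvd_post + sum(mass * pn)
        slice[[st]][es] <- mass - dying
      }
      # entrants from the stable state arrive at cycle j+1
      if (j < n_cycles) slice[[st]][j] <- slice[[st]][j] + entrants[j, st]
    }
    ly[j] <- pt_j
    cost_tot[j] <- cost_j; cost_cvd[j] <- costc_j; qaly[j] <- qaly_j
    exposure[j] <- expo_j
    d_ly[j] <- v[j] * ly[j]; d_qaly[j] <- v[j] * qaly_j
    d_cost_tot[j] <- v[j] * cost_j; d_cost_cvd[j] <- v[j] * costc_j
    d_exposure[j] <- v[j] * expo_j
    if (live_mass < 1e-9) {
      keep <- seq_len(j)
      ly <- ly[keep]; qaly <- qaly[keep]; cost_tot <- cost_tot[keep]
      cost_cvd <- cost_cvd[keep]; d_ly <- d_ly[keep]; d_qaly <- d_qaly[keep]
      d_cost_tot <- d_cost_tot[keep]; d_cost_cvd <- d_cost_cvd[keep]
      exposure <- exposure[keep]; d_exposure <- d_exposure[keep]
      occ_post <- occ_post[keep, , drop = FALSE]
      occ_cvd_dead <- occ_cvd_dead[keep]; occ_ncvd_dead <- occ_ncvd_dead[keep]
      n_cycles <- j
      break
    }
  }

  Fend <- cifs$F[n_cycles + 1, ]
  residual_live <- cifs$S[n_cycles + 1] + sum(vapply(slice, sum, numeric(1)))
  if (residual_live > 1e-6) {
    warning(sprintf("horizon cap reached with %.2e live mass remaining",
                    residual_live))
  }
  p_cvd_death <- unname(Fend["cvd_death"] + dead_cvd_post)
  p_ncvd_death <- unname(Fend["noncvd_death"] + dead_ncvd_post)

  # expected time to first departure from the stable state
  ttfe <- sum(cifs$S[seq_len(n_cycles)]) * dl

  trace <- data.frame(
    cycle = seq_len(n_cycles) - 1L,
    time = tgrid[seq_len(n_cycles)],
    stable = stable[seq_len(n_cycles)],
    occ_post,
    cvd_death = occ_cvd_dead,
    noncvd_death = occ_ncvd_dead,
    discount = v[seq_len(n_cycles)],
    cost = cost_tot, cost_cvd = cost_cvd, qaly = qaly,
    check.names = FALSE
  )
  outputs <- structure(list(
    life_years = sum(ly),
    disc_life_years = sum(d_ly),
    qalys = sum(qaly),
    disc_qalys = sum(d_qaly),
    total_costs = sum(cost_tot),
    disc_total_costs = sum(d_cost_tot),
    cvd_costs = sum(cost_cvd),
    disc_cvd_costs = sum(d_cost_cvd),
    time_to_first_event = ttfe,
    p_first_mi = 100 * unname(Fend["mi"]),
    p_first_is = 100 * unname(Fend["ischaemic_stroke"]),
    p_first_hs = 100 * unname(Fend["haemorrhagic_stroke"]),
    cvd_mortality_pct = 100 * p_cvd_death,
    noncvd_mortality_pct = 100 * p_ncvd_death,
    exposure_years = sum(exposure),
    disc_exposure_years = sum(d_exposure),
    residual_live_mass = residual_live
  ), class = "scad_outputs")
  list(trace = trace, outputs = outputs, cifs = cifs)
}

#' @export
print.scad_outputs <- function(x, ...) {
  cat("Lifetime model outputs\n")
  cat(sprintf("  life years      %8.2f (disc %8.2f)\n", x$life_years, x$disc_life_years))
  cat(sprintf("  QALYs           %8.2f (disc %8.2f)\n", x$qalys, x$disc_qalys))
  cat(sprintf("  total costs   GBP %8.0f (disc %8.0f)\n", x$total_costs, x$disc_total_costs))
  cat(sprintf("  CVD costs     GBP %8.0f (disc %8.0f)\n", x$cvd_costs, x$disc_cvd_costs))
  cat(sprintf("  time to first event %6.2f years\n", x$time_to_first_event))
  cat(sprintf("  first endpoint: MI %.2f%%  IS %.2f%%  HS %.2f%%\n",
              x$p_first_mi, x$p_first_is, x$p_first_hs))
  cat(sprintf("  lifetime mortality: CVD %.2f%%  non-CVD %.2f%%\n",
              x$cvd_mortality_pct, x$noncvd_mortality_pct))
  invisible(x)
}

#' Convert model outputs to a one-row data frame
#'
#' @param x \code{scad_outputs}.
#' @param ... Unused.
#' @return One-row data frame.
#' @export
as.data.frame.scad_outputs <- function(x, ...) {
  as.data.frame(unclass(x)[OUTPUT_FIELDS], check.names = FALSE)
}

OUTPUT_FIELDS <- c("life_years", "disc_life_years", "qalys", "disc_qalys",
                   "total_costs", "disc_total_costs", "cvd_costs",
                   "disc_cvd_costs", "time_to_first_event", "p_first_mi",
                   "p_first_is", "p_first_hs", "cvd_mortality_pct",
                   "noncvd_mortality_pct", "exposure_years",
                   "disc_exposure_years")

#' Individual-level microsimulation oracle
#'
#' Simulates n individual trajectories by sampling the same per-cycle
#' transition probabilities the cohort engine uses, and returns the mean and
#' Monte Carlo standard error of every lifetime output. Serves as the
#' brute-force cross-check of the deterministic cohort expectations.
#'
#' @inheritParams run_cohort
#' @param n Number of simulated individuals (>= 1000).
#' @param seed Integer seed.
#' @return List with \code{outputs} (means, class \code{scad_outputs}) and
#'   \code{se} (standard errors for each field).
#' @export
microsim_oracle <- function(profile, set, cost_model, utilities, n, seed,
                            discount_rate = 0.035, treatment = NULL,
                            horizon_years = Inf, subdiv = 64L, age_cap = 110) {
  stopifnot(n >= 1000)
  pr <- as_profile_row(profile)
  dl <- CYCLE_YEARS
  run_years <- min(horizon_years, age_cap - pr$age_entry + 2)
  n_cycles <- max(1L, ceiling(run_years / dl))
  lt_fun <- if (!is.infinite(set$splice_time)) {
    lt_cumhaz_fun(set$life_table, pr$female, pr$age_entry)
  } else {
    NULL
  }
  ch <- profile_cumhaz_set(set, pr$x_primary, pr$female, pr$age_entry,
                           treatment, lt_fun)
  cifs <- build_cifs(ch, n_cycles, dl, subdiv)
  tgrid <- cifs$t
  v <- (1 + discount_rate)^(-tgrid[-length(tgrid)])
  age_now <- pr$age_entry + tgrid[-length(tgrid)]
  cst_stable <- cycle_cost(cost_model, pr$x_primary, "stable", NA, age_now)
  u_stable <- cycle_utility(utilities, pr$female, "stable", NA, age_now)
  age_event <- pr$age_entry + tgrid[-length(tgrid)] + dl / 2
  t_event <- tgrid[-length(tgrid)] + dl / 2
  post_states <- c("post_mi", "post_is", "post_hs")
  cause_col <- c(post_mi = "mi", post_is = "ischaemic_stroke",
                 post_hs = "haemorrhagic_stroke")

  with_seed(seed, {
    state <- rep(1L, n)           # index into MODEL_STATES
    entry_cycle <- rep(NA_integer_, n)
    ly <- qaly <- ctot <- ccvd <- dly <- dqaly <- dctot <- dccvd <-
      expo <- dexpo <- tfe <- numeric(n)
    first_ep <- rep(NA_character_, n)
    pay_all_states <- is.null(treatment) || !treatment$until_first_event

    for (j in seq_len(n_cycles)) {
      alive <- which(state <= 4L)
      if (!length(alive)) break
      st_j <- state[alive]
      # accrual at cycle start
      ly[alive] <- ly[alive] + dl
      dly[alive] <- dly[alive] + v[j] * dl
      in_stable <- alive[st_j == 1L]
      if (length(in_stable)) {
        tfe[in_stable] <- tfe[in_stable] + dl
        qaly[in_stable] <- qaly[in_stable] + u_stable[j] * dl
        dqaly[in_stable] <- dqaly[in_stable] + v[j] * u_stable[j] * dl
        ctot[in_stable] <- ctot[in_stable] + cst_stable$total[j]
        dctot[in_stable] <- dctot[in_stable] + v[j] * cst_stable$total[j]
        ccvd[in_stable] <- ccvd[in_stable] + cst_stable$cvd[j]
        dccvd[in_stable] <- dccvd[in_stable] + v[j] * cst_stable$cvd[j]
        expo[in_stable] <- expo[in_stable] + dl
        dexpo[in_stable] <- dexpo[in_stable] + v[j] * dl
        # stable-state transitions
        tp <- stable_state_transitions(cifs, j - 1L)
        u <- runif(length(in_stable))
        cp <- cumsum(tp)
        newst <- 1L + findInterval(u, cp[-6], left.open = FALSE)
        moved <- newst != 1L
        if (any(moved)) {
          state[in_stable[moved]] <- newst[moved]
          entered_post <- moved & newst >= 2L & newst <= 4L
          if (any(entered_post)) entry_cycle[in_stable[entered_post]] <- j
          fe <- c(NA, "mi", "ischaemic_stroke", "haemorrhagic_stroke",
                  "cvd_death", "noncvd_death")[newst[moved]]
          first_ep[in_stable[moved]] <- fe
          # deaths accrue only half this cycle's person-time
          died <- in_stable[newst >= 5L]
          if (length(died)) {
            ly[died] <- ly[died] - dl / 2
            dly[died] <- dly[died] - v[j] * dl / 2
            qaly[died] <- qaly[died] - u_stable[j] * dl / 2
            dqaly[died] <- dqaly[died] - v[j] * u_stable[j] * dl / 2
            expo[died] <- expo[died] - dl / 2
            dexpo[died] <- dexpo[died] - v[j] * dl / 2
          }
        }
      }
      for (si in 1:3) {
        in_post <- alive[st_j == si + 1L]
        if (!length(in_post)) next
        st <- post_states[si]
        e <- entry_cycle[in_post]
        s_idx <- j - e - 1L       # 0 in the first cycle occupied post-event
        cc <- cycle_cost(cost_model, pr$x_primary, st, s_idx, age_now[j])
        uu <- cycle_utility(utilities, pr$female, st, s_idx, age_now[j])
        qaly[in_post] <- qaly[in_post] + uu * dl
        dqaly[in_post] <- dqaly[in_post] + v[j] * uu * dl
        ctot[in_post] <- ctot[in_post] + cc$total
        dctot[in_post] <- dctot[in_post] + v[j] * cc$total
        ccvd[in_post] <- ccvd[in_post] + cc$cvd
        dccvd[in_post] <- dccvd[in_post] + v[j] * cc$cvd
        if (pay_all_states) {
          expo[in_post] <- expo[in_post] + dl
          dexpo[in_post] <- dexpo[in_post] + v[j] * dl
        }
        pr_move <- post_event_cycle_probs(set, st, pr$female, age_event[e],
                                          s_idx, t_event[e], treatment,
                                          lt_fun, dl)
        u <- runif(length(in_post))
        die_cvd <- u < pr_move$p_cvd
        die_ncvd <- !die_cvd & u < pr_move$p_cvd + pr_move$p_noncvd
        state[in_post[die_cvd]] <- 5L
        state[in_post[die_ncvd]] <- 6L
        died <- in_post[die_cvd | die_ncvd]
        if (length(died)) {
          udied <- uu[die_cvd | die_ncvd]
          ly[died] <- ly[died] - dl / 2
          dly[died] <- dly[died] - v[j] * dl / 2
          qaly[died] <- qaly[died] - udied * dl / 2
          dqaly[died] <- dqaly[died] - v[j] * udied * dl / 2
          if (pay_all_states) {
            expo[died] <- expo[died] - dl / 2
            dexpo[died] <- dexpo[died] - v[j] * dl / 2
          }
        }
      }
    }
    vals <- list(
      life_years = ly, disc_life_years = dly, qalys = qaly, disc_qalys = dqaly,
      total_costs = ctot, disc_total_costs = dctot, cvd_costs = ccvd,
      disc_cvd_costs = dccvd, time_to_first_event = tfe,
      p_first_mi = 100 * as.numeric(!is.na(first_ep) & first_ep == "mi"),
      p_first_is = 100 * as.numeric(!is.na(first_ep) & first_ep == "ischaemic_stroke"),
      p_first_hs = 100 * as.numeric(!is.na(first_ep) & first_ep == "haemorrhagic_stroke"),
      cvd_mortality_pct = 100 * as.numeric(state == 5L),
      noncvd_mortality_pct = 100 * as.numeric(state == 6L),
      exposure_years = expo, disc_exposure_years = dexpo
    )
    means <- lapply(vals, mean)
    ses <- vapply(vals, function(x) sd(x) / sqrt(n), numeric(1))
    means$residual_live_mass <- mean(state <= 4L)
    list(outputs = structure(means, class = "scad_outputs"),
         se = ses, n = n)
  })
}

# microsim entry semantics: an individual in stable at cycle start j-1
# (0-based j-1) who transitions is in the post state from cycle j onwards;
# entry_cycle records j, so cycles_since_event = current - entry. The cohort
# engine indexes entrants the same way (arrival one cycle after the event
# cycle), keeping the two engines probabilistically identical.
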