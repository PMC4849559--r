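# Competing-risks composition: cause-specific hazards -> cumulative
# incidence functions -> per-cycle transition probabilities.
#
# Within each (sub-)interval the exact survival drop S(t1) - S(t2) is split
# between causes in proportion to their cumulative-hazard increments. This
# composition conserves S + sum(F_k) = 1 to machine precision, is exact for
# constant hazards, and is second-order accurate otherwise (no within-cycle
# event-ordering assumption is needed).

#' Hypothetical risk-reducing treatment scenario
#'
#' @param rho Proportional hazard reduction in [0, 1) applied to the CVD
#'   cause-specific hazards (MI, ischaemic stroke, haemorrhagic stroke, CVD
#'   death). Non-CVD mortality is never touched.
#' @param annual_price Treatment price, GBP per year.
#' @param include_haemorrhagic Whether haemorrhagic stroke counts as a
#'   treated CVD endpoint (default TRUE).
#' @param treat_post_event Whether the post-event CVD-death hazards are also
#'   reduced (default TRUE).
#' @param until_first_event If TRUE the price is paid only while event-free;
#'   default FALSE (paid in all live states).
#' @return List of class \code{scad_treatment}.
#' @export
treatment_scenario <- function(rho, annual_price = 0,
                               include_haemorrhagic = TRUE,
                               treat_post_event = TRUE,
                               until_first_event = FALSE) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (annual_price < 0) stop("annual_price must be >= 0", call. = FALSE)
  structure(list(rho = rho, annual_price = annual_price,
                 include_haemorrhagic = include_haemorrhagic,
                 treat_post_event = treat_post_event,
                 until_first_event = until_first_event),
            class = "scad_treatment")
}

# Per-cause multiplicative factors for the primary hazards.
treatment_factors <- function(treatment) {
  f <- setNames(rep(1, 5), PRIMARY_ENDPOINTS)
  if (is.null(treatment)) return(f)
  r <- 1 - treatment$rho
  f[c("mi", "ischaemic_stroke", "cvd_death")] <- r
  if (treatment$include_haemorrhagic) f["haemorrhagic_stroke"] <- r
  f
}

#' Apply a proportional CVD hazard reduction
#'
#' Multiplies the CVD cause-specific hazards by \code{1 - rho}, leaving
#' non-CVD mortality untouched.
#'
#' @param hazards Named numeric vector of cause-specific hazards (names from
#'   \code{mi, ischaemic_stroke, haemorrhagic_stroke, cvd_death,
#'   noncvd_death}).
#' @param rho Hazard reduction in [0, 1).
#' @param include_haemorrhagic Include haemorrhagic stroke (default TRUE).
#' @return The treated hazard vector.
#' @export
apply_treatment <- function(hazards, rho, include_haemorrhagic = TRUE) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  tr <- treatment_scenario(rho, include_haemorrhagic = include_haemorrhagic)
  f <- treatment_factors(tr)
  out <- hazards
  common <- intersect(names(hazards), names(f))
  out[common] <- hazards[common] * f[common]
  out
}

# Cumulative-hazard closures for the five primary causes of one profile.
# Returns a named list of vectorised functions H_k(t). `lt_fun` is the
# precomputed life-table cumulative hazard on cohort time (NULL = no splice).
profile_cumhaz_set <- function(set, x_primary, female, age_entry,
                               treatment = NULL, lt_fun = NULL) {
  fac <- treatment_factors(treatment)
  ts <- set$splice_time
  if (is.null(lt_fun) && !is.infinite(ts)) {
    lt_fun <- lt_cumhaz_fun(set$life_table, female, age_entry)
  }
  out <- list()
  for (ep in PRIMARY_ENDPOINTS) {
    fit <- set$primary[[ep]]
    mu <- fit_mu(fit, x_primary)
    fam <- fit$family; sg <- fit$sigma; Qv <- fit$Q
    f <- fac[[ep]]
    if (ep == "noncvd_death" && !is.infinite(ts)) {
      out[[ep]] <- local({
        mu0 <- mu; fam0 <- fam; sg0 <- sg; Q0 <- Qv
        function(t) {
          H <- aft_cumhaz(fam0, pmin(t, ts), rep_len(mu0, length(t)), sg0, Q0)
          after <- t > ts
          if (any(after)) H[after] <- H[after] + lt_fun(t[after]) - lt_fun(ts)
          H
        }
      })
    } else {
      out[[ep]] <- local({
        mu0 <- mu; fam0 <- fam; sg0 <- sg; Q0 <- Qv; f0 <- f
        function(t) f0 * aft_cumhaz(fam0, t, rep_len(mu0, length(t)), sg0, Q0)
      })
    }
  }
  out
}

# Piecewise-linear cumulative life-table hazard on cohort time, blended over
# sex for fractional female indicators. Exact (rates are piecewise constant).
lt_cumhaz_fun <- function(lt, female, age_entry, t_max = 130) {
  brk <- c(0, (ceiling(age_entry + 1e-9):floor(age_entry + t_max)) - age_entry,
           t_max)
  brk <- sort(unique(brk[brk >= 0 & brk <= t_max]))
  mid <- age_entry + (brk[-length(brk)] + brk[-1]) / 2
  rates <- lt_rate_blend(lt, female, mid)
  Hk <- c(0, cumsum(rates * diff(brk)))
  approxfun(brk, Hk, rule = 2)
}

#' Build cumulative incidence functions on the cycle grid
#'
#' @param cumhaz Named list of vectorised cumulative-hazard functions, one
#'   per cause (any number of causes). Cumulative hazards are used rather
#'   than hazards so that singular hazards (e.g. Weibull with sigma > 1 at
#'   t = 0) integrate exactly.
#' @param n_cycles Number of 90-day cycles to cover.
#' @param cycle_length Cycle length in years (default 90/365.25).
#' @param subdiv Within-cycle subdivisions for the composition (default 8).
#' @return Object of class \code{scad_cifs}: \code{t} (cycle boundaries),
#'   \code{S} (event-free survival) and \code{F} (matrix of per-cause CIFs).
#' @export
build_cifs <- function(cumhaz, n_cycles, cycle_length = CYCLE_YEARS,
                       subdiv = 8L) {
  stopifnot(n_cycles >= 1, subdiv >= 1, cycle_length > 0)
  causes <- names(cumhaz)
  fine <- seq(0, n_cycles * cycle_length, length.out = n_cycles * subdiv + 1)
  dH <- sapply(causes, function(k) {
    f <- cumhaz[[k]]
    H <- f(fine)
    if (any(is.nan(H)) || any(H < -1e-12)) {
      stop("non-finite or negative cumulative hazard for cause '", k, "'",
           call. = FALSE)
    }
    d <- diff(H)
    if (any(d < -1e-9, na.rm = TRUE)) {
      stop("negative hazard increment for cause '", k, "'", call. = FALSE)
    }
    # increments above ~700 mean certain transition already; capping keeps
    # Inf (and Inf - Inf) out of the cause-split arithmetic, which matters
    # for extreme PSA coefficient draws
    d[!is.finite(d)] <- 700
    pmin(pmax(d, 0), 700)
  })
  dH <- matrix(dH, ncol = length(causes), dimnames = list(NULL, causes))
  dtot <- rowSums(dH)
  Sf <- exp(-cumsum(dtot))               # survival at fine grid (excl. t=0)
  Sprev <- c(1, Sf[-length(Sf)])
  drop_mass <- Sprev - Sf                # exact survival drop per fine step
  w <- dH / ifelse(dtot > 0, dtot, 1)    # cause split of each drop
  dF <- w * drop_mass
  Ff <- apply(dF, 2, cumsum)
  pick <- seq(1, length(fine), by = subdiv)  # cycle boundaries
  Fmat <- rbind(0, matrix(Ff, ncol = length(causes)))[pick, , drop = FALSE]
  colnames(Fmat) <- causes
  structure(list(t = fine[pick], S = c(1, Sf)[pick], F = Fmat,
                 cycle_length = cycle_length, subdiv = subdiv),
            class = "scad_cifs")
}

#' @export
print.scad_cifs <- function(x, ...) {
  cat(sprintf("CIF bundle: %d cycles of %.4f years, causes: %s\n",
              length(x$t) - 1, x$cycle_length,
              paste(colnames(x$F), collapse = ", ")))
  invisible(x)
}

#' Tidy data frame of a CIF bundle
#'
#' @param x \code{scad_cifs}.
#' @param ... Unused.
#' @return Data frame with time, S and one column per cause CIF.
#' @export
as.data.frame.scad_cifs <- function(x, ...) {
  data.frame(time = x$t, S = x$S, x$F, check.names = FALSE)
}

#' Per-cycle transition probabilities out of the stable state
#'
#' @param cifs \code{scad_cifs} for the five primary causes.
#' @param j Cycle index (0-based).
#' @return Named probability vector over the six model states.
#' @export
stable_state_transitions <- function(cifs, j) {
  stopifnot(j >= 0, j + 2 <= length(cifs$t))
  Sj <- cifs$S[j + 1]
  out <- setNames(numeric(6), MODEL_STATES)
  if (Sj <= 0) {
    warning("stable state unreachable at cycle ", j, "; absorbing self-loop used")
    out["stable"] <- 1
    return(out)
  }
  dF <- (cifs$F[j + 2, ] - cifs$F[j + 1, ]) / Sj
  out["stable"] <- cifs$S[j + 2] / Sj
  out["post_mi"] <- dF[["mi"]]
  out["post_is"] <- dF[["ischaemic_stroke"]]
  out["post_hs"] <- dF[["haemorrhagic_stroke"]]
  out["cvd_death"] <- dF[["cvd_death"]]
  out["noncvd_death"] <- dF[["noncvd_death"]]
  out / sum(out)
}

# Vectorised two-cause post-event per-cycle probabilities.
#
# For patients who entered post-event state `st` at cohort time `t_event`
# aged `age_at_event`, returns P(cvd death) and P(non-CVD death) during
# post-event cycle s (i.e. between s and s+1 cycles after the event).
# The post-event clock drives the parametric fits; the non-CVD hazard is
# spliced to the life table once cohort time exceeds the splice time, and
# `lt_fun` must then be the profile's life-table cumulative hazard.
post_event_cycle_probs <- function(set, st, female, age_at_event, s,
                                   t_event, treatment = NULL, lt_fun = NULL,
                                   cycle_length = CYCLE_YEARS) {
  n <- max(length(s), length(age_at_event), length(t_event))
  s <- rep_len(s, n); age_at_event <- rep_len(age_at_event, n)
  t_event <- rep_len(t_event, n)
  tau1 <- s * cycle_length; tau2 <- (s + 1) * cycle_length
  Xp <- post_event_design(female, age_at_event)

  fit_c <- set$post[[st]]$cvd_death
  mu_c <- fit_mu(fit_c, Xp)
  dHc <- aft_cumhaz(fit_c$family, tau2, mu_c, fit_c$sigma, fit_c$Q) -
    aft_cumhaz(fit_c$family, tau1, mu_c, fit_c$sigma, fit_c$Q)
  if (!is.null(treatment) && treatment$treat_post_event) {
    dHc <- dHc * (1 - treatment$rho)
  }

  fit_n <- set$post[[st]]$noncvd_death
  mu_n <- fit_mu(fit_n, Xp)
  ts <- set$splice_time
  ct1 <- t_event + tau1; ct2 <- t_event + tau2
  # parametric part on the post-event clock, only while cohort time < splice
  p1 <- pmin(tau1, pmax(ts - t_event, 0))
  p2 <- pmin(tau2, pmax(ts - t_event, 0))
  dHn <- aft_cumhaz(fit_n$family, p2, mu_n, fit_n$sigma, fit_n$Q) -
    aft_cumhaz(fit_n$family, p1, mu_n, fit_n$sigma, fit_n$Q)
  if (!is.infinite(ts)) {
    over <- ct2 > ts
    if (any(over)) {
      if (is.null(lt_fun)) {
        lt_fun <- lt_cumhaz_fun(set$life_table, female,
                                age_at_event[1] - t_event[1])
      }
      lo <- pmax(ct1[over], ts)
      dHn[over] <- dHn[over] + lt_fun(ct2[over]) - lt_fun(lo)
    }
  }
  # cap against Inf - Inf from pathological draws (see build_cifs)
  dHc[!is.finite(dHc)] <- 700; dHn[!is.finite(dHn)] <- 700
  dHc <- pmin(pmax(dHc, 0), 700); dHn <- pmin(pmax(dHn, 0), 700)
  dH <- dHc + dHn
  pdie <- -expm1(-dH)
  wc <- ifelse(dH > 0, dHc / dH, 0)
  list(p_cvd = pdie * wc, p_noncvd = pdie * (1 - wc))
}

#' Per-cycle transition probabilities from a post-event state
#'
#' @param set \code{scad_eqset}.
#' @param state One of \code{"post_mi"}, \code{"post_is"}, \code{"post_hs"}.
#' @param female Female indicator (fractional allowed).
#' @param age_at_event Age when the non-fatal event occurred, years.
#' @param cycles_since_event Post-event cycle index (0-based).
#' @param t_event Cohort time of the event, years (drives the life-table
#'   splice; default 0).
#' @param treatment Optional \code{scad_treatment}.
#' @return Named probability vector over the six model states.
#' @export
post_event_transitions <- function(set, state, female, age_at_event,
                                   cycles_since_event, t_event = 0,
                                   treatment = NULL) {
  stopifnot(state %in% c("post_mi", "post_is", "post_hs"),
            cycles_since_event >= 0)
  pr <- post_event_cycle_probs(set, state, female, age_at_event,
                               cycles_since_event, t_event, treatment)
  out <- setNames(numeric(6), MODEL_STATES)
  out["cvd_death"] <- pr$p_cvd
  out["noncvd_death"] <- pr$p_noncvd
  out[state] <- 1 - pr$p_cvd - pr$p_noncvd
  out
}
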