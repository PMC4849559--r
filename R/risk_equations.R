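# Parametric competing-risk survival equations.
#
# Five primary endpoints (non-fatal MI, ischaemic stroke, haemorrhagic
# stroke, CVD death, non-CVD death) are fitted on the full covariate vector;
# six post-event mortality equations (CVD / non-CVD death after each
# non-fatal event) use only sex and age at event. For each endpoint the
# candidate AFT families are fitted by maximum likelihood and the best is
# selected by AIC. Non-CVD mortality beyond the follow-up horizon (10 years)
# is spliced to an age/sex life table.

#' Fit a parametric AFT survival model
#'
#' Maximises the right-censored log-likelihood for one of the four families.
#' Initial values come from the closed-form-flavoured exponential fit; the
#' generalised gamma is multi-started from the Weibull (Q = 1) and lognormal
#' (Q = 0) solutions.
#'
#' @param time Follow-up times (> 0), years.
#' @param status Event indicator (1 = event, 0 = right-censored).
#' @param X Design matrix (include an intercept column).
#' @param family One of \code{"exponential"}, \code{"weibull"},
#'   \code{"lognormal"}, \code{"gengamma"}.
#' @param fixed Optional named list fixing \code{log_sigma} and/or \code{Q}
#'   (e.g. \code{list(Q = 1)} to constrain the generalised gamma to Weibull).
#' @param min_events Minimum number of events required (default 10).
#' @param endpoint Optional endpoint label stored on the fit.
#' @return Object of class \code{scad_survfit}: coefficients, ancillary
#'   parameters, full vcov (observed information), log-likelihood, AIC.
#' @export
fit_parametric <- function(time, status, X, family,
                           fixed = list(), min_events = 10L,
                           endpoint = NA_character_) {
  family <- match.arg(family, FAMILIES)
  X <- as.matrix(X)
  stopifnot(length(time) == length(status), nrow(X) == length(time))
  if (any(time <= 0)) stop("all times must be positive", call. = FALSE)
  n_events <- sum(status == 1)
  if (n_events == 0) stop("no events observed; cannot fit ", family, call. = FALSE)
  if (n_events < min_events) {
    stop(sprintf("only %d events (< %d required) for endpoint '%s'",
                 n_events, min_events, endpoint), call. = FALSE)
  }
  k <- ncol(X)

  # exponential starting values: intercept = log(total time / events)
  beta0 <- numeric(k)
  icol <- which(colnames(X) == "intercept")[1]
  if (is.na(icol)) icol <- 1L
  beta0[icol] <- log(sum(time) / n_events)

  negll <- function(th) -aft_loglik(th, time, status, X, family, fixed)
  neggr <- if (family %in% c("exponential", "weibull", "lognormal")) {
    function(th) -aft_grad(th, time, status, X, family, fixed)
  } else {
    NULL
  }
  run_optim <- function(start) {
    optim(start, negll, gr = neggr, method = "BFGS",
          control = list(maxit = 1000, reltol = 1e-12))
  }

  starts <- list()
  if (family == "exponential") {
    starts[[1]] <- beta0
  } else if (family %in% c("weibull", "lognormal")) {
    st <- beta0
    if (is.null(fixed$log_sigma)) st <- c(st, 0)
    starts[[1]] <- st
  } else {
    # gengamma: start from fitted weibull and lognormal if Q is free
    wb <- tryCatch(fit_parametric(time, status, X, "weibull",
                                  min_events = min_events, endpoint = endpoint),
                   error = function(e) NULL)
    ln <- tryCatch(fit_parametric(time, status, X, "lognormal",
                                  min_events = min_events, endpoint = endpoint),
                   error = function(e) NULL)
    mk_start <- function(fit, Qv) {
      b <- if (is.null(fit)) beta0 else fit$coef
      ls <- if (is.null(fit)) 0 else log(fit$sigma)
      st <- b
      if (is.null(fixed$log_sigma)) st <- c(st, ls)
      if (is.null(fixed$Q)) st <- c(st, Qv)
      st
    }
    starts[[1]] <- mk_start(wb, 1)
    if (is.null(fixed$Q)) starts[[2]] <- mk_start(ln, 0.05)
  }

  best <- NULL
  for (st in starts) {
    res <- tryCatch(run_optim(st), error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("optimisation failed for family ", family, call. = FALSE)
  gnorm <- max(abs(numeric_gradient(negll, best$par)))
  if (best$convergence != 0 && gnorm > 1e-3) {
    stop(sprintf("non-convergence for family %s (gradient norm %.3e)",
                 family, gnorm), call. = FALSE)
  }
  H <- tryCatch(optimHess(best$par, negll, gr = neggr), error = function(e) NULL)
  vc <- safe_solve(H, length(best$par))
  p <- aft_unpack(best$par, k, family, fixed)
  pn <- c(colnames(X) %||% paste0("x", seq_len(k)))
  parnames <- pn[seq_len(k)]
  if (family != "exponential" && is.null(fixed$log_sigma)) parnames <- c(parnames, "log_sigma")
  if (family == "gengamma" && is.null(fixed$Q)) parnames <- c(parnames, "Q")
  dimnames(vc) <- list(parnames, parnames)
  ll <- -best$value
  npar <- length(best$par)
  structure(list(
    endpoint = endpoint, family = family,
    coef = setNames(p$beta, pn[seq_len(k)]),
    sigma = p$sigma, Q = p$Q,
    par = setNames(best$par, parnames),
    fixed = fixed,
    vcov = vc, loglik = ll, AIC = 2 * npar - 2 * ll,
    npar = npar, n = length(time), n_events = n_events,
    gradient_norm = gnorm,
    fingerprint = data_fingerprint(time, status, X)
  ), class = "scad_survfit")
}

# Zero-hazard equation for an endpoint with no observed events (the
# exponential MLE of the rate is exactly 0; e^-50/yr stands in for it).
null_fit <- function(endpoint) {
  structure(list(
    endpoint = paste0(endpoint, "_no_events"), family = "exponential",
    coef = c(intercept = 50), sigma = 1, Q = 1,
    par = c(intercept = 50), fixed = list(),
    vcov = matrix(0, 1, 1, dimnames = list("intercept", "intercept")),
    loglik = 0, AIC = NA_real_, npar = 1L, n = NA_integer_, n_events = 0L,
    gradient_norm = 0, fingerprint = "no_events"), class = "scad_survfit")
}

numeric_gradient <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  vapply(seq_along(x), function(i) {
    xi <- x; xi[i] <- xi[i] + eps * max(1, abs(x[i]))
    (f(xi) - f0) / (eps * max(1, abs(x[i])))
  }, numeric(1))
}

# Invert the observed information; fall back to an eigen pseudo-inverse
# when it is numerically singular.
safe_solve <- function(H, p) {
  if (is.null(H)) return(matrix(NA_real_, p, p))
  out <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(out)) {
    e <- eigen((H + t(H)) / 2, symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-12
    out <- e$vectors[, pos, drop = FALSE] %*%
      (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
  }
  (out + t(out)) / 2
}

#' @export
print.scad_survfit <- function(x, ...) {
  cat(sprintf("Parametric survival fit [%s] endpoint=%s\n", x$family, x$endpoint))
  cat(sprintf("  n=%d events=%d loglik=%.2f AIC=%.2f sigma=%.4f Q=%.4f\n",
              x$n, x$n_events, x$loglik, x$AIC, x$sigma, x$Q))
  invisible(x)
}

#' Select the best-fitting family by AIC
#'
#' @param fits List of \code{scad_survfit} objects on the same data.
#' @return The minimum-AIC fit; ties (difference < 1e-6) go to the fit with
#'   fewer parameters.
#' @export
select_best_family <- function(fits) {
  stopifnot(length(fits) >= 1)
  if (length(fits) == 1) return(fits[[1]])
  fp <- vapply(fits, `[[`, "", "fingerprint")
  if (length(unique(fp)) > 1) {
    stop("candidate fits were not estimated on the same data", call. = FALSE)
  }
  aic <- vapply(fits, `[[`, 0, "AIC")
  npar <- vapply(fits, `[[`, 0, "npar")
  best <- min(aic)
  cand <- which(aic - best < 1e-6)
  fits[[cand[which.min(npar[cand])]]]
}

# ---------------------------------------------------------------------------
# Life table

#' Build a synthetic national life table for non-CVD mortality
#'
#' Gompertz–Makeham annual probabilities of death by sex and single year of
#' age, with q = 1 at the terminal age. A synthetic stand-in for a national
#' life table with the same layout.
#'
#' @param ages Integer ages covered (default 18..110).
#' @param makeham,b,c Gompertz–Makeham parameters (female rates are scaled
#'   down by \code{female_factor}).
#' @param female_factor Multiplier on female rates.
#' @return Data frame (sex, age, qx) of class \code{scad_lifetable}.
#' @export
make_life_table <- function(ages = 18:110, makeham = 4e-4, b = 1.8e-5,
                            c = 0.096, female_factor = 0.75) {
  build <- function(sex, scale) {
    rate <- makeham + scale * b * exp(c * ages)
    qx <- 1 - exp(-rate)
    qx[length(qx)] <- 1
    data.frame(sex = sex, age = ages, qx = pmin(qx, 1))
  }
  out <- rbind(build("male", 1), build("female", female_factor))
  class(out) <- c("scad_lifetable", "data.frame")
  out
}

validate_life_table <- function(lt) {
  stopifnot(all(c("sex", "age", "qx") %in% names(lt)))
  stop_if_not_prob(lt$qx, "life table qx")
  for (sx in unique(lt$sex)) {
    a <- sort(lt$age[lt$sex == sx])
    if (any(diff(a) != 1)) {
      gap <- a[which(diff(a) != 1)[1]]
      stop(sprintf("life table ages for sex '%s' are not contiguous after age %d",
                   sx, gap), call. = FALSE)
    }
    if (lt$qx[lt$sex == sx & lt$age == max(a)] < 1) {
      stop("life table must end with qx = 1 at the terminal age", call. = FALSE)
    }
  }
  invisible(lt)
}

# Annual non-CVD mortality rate at integer age (vectorised); beyond the
# terminal age the terminal rate applies. q = 1 maps to a large finite rate
# so that discrete transitions give "certain death within the year" without
# Inf arithmetic.
.RATE_CAP <- -log(1e-12)

lt_rate <- function(lt, sex, age) {
  n <- max(length(sex), length(age))
  sex <- rep_len(sex, n); age <- rep_len(floor(age), n)
  r <- numeric(n)
  for (sx in unique(sex)) {
    sub <- lt[lt$sex == sx, ]
    idx <- pmin(pmax(age[sex == sx] - min(sub$age) + 1L, 1L), nrow(sub))
    q <- sub$qx[idx]
    r[sex == sx] <- ifelse(q >= 1, .RATE_CAP, -log(1 - q))
  }
  r
}

# For fractional sex (group-mean profiles): female-weighted blend of rates.
lt_rate_blend <- function(lt, female, age) {
  female <- rep_len(female, length(age))
  (1 - female) * lt_rate(lt, "male", age) + female * lt_rate(lt, "female", age)
}

# Integral of the life-table rate from cohort time t1 to t2 for a patient
# entering at age_entry (piecewise-constant by integer attained age).
lt_cumhaz_segment <- function(lt, female, age_entry, t1, t2) {
  if (t2 <= t1) return(0)
  # breakpoints where attained age crosses an integer
  a1 <- age_entry + t1; a2 <- age_entry + t2
  brk <- if (ceiling(a1) <= floor(a2)) ceiling(a1):floor(a2) else numeric(0)
  ts <- unique(c(t1, brk - age_entry, t2))
  ts <- sort(ts[ts >= t1 & ts <= t2])
  mid_age <- age_entry + (ts[-length(ts)] + ts[-1]) / 2
  sum(lt_rate_blend(lt, female, mid_age) * diff(ts))
}

# ---------------------------------------------------------------------------
# Equation sets

new_equation_set <- function(primary, post, life_table, splice_time,
                             aic_table = NULL) {
  stopifnot(identical(sort(names(primary)), sort(PRIMARY_ENDPOINTS)))
  stopifnot(identical(sort(names(post)), sort(c("post_mi", "post_is", "post_hs"))))
  n_eq <- length(primary) + sum(lengths(post))
  if (n_eq != 11L) stop("an equation set must contain exactly 11 equations",
                        call. = FALSE)
  if (!is.infinite(splice_time)) validate_life_table(life_table)
  structure(list(primary = primary, post = post, life_table = life_table,
                 splice_time = splice_time, aic_table = aic_table),
            class = "scad_eqset")
}

#' @export
print.scad_eqset <- function(x, ...) {
  cat("Risk equation set: 11 equations, splice at", x$splice_time, "years\n")
  for (ep in names(x$primary)) {
    f <- x$primary[[ep]]
    cat(sprintf("  %-20s %-12s events=%s\n", ep, f$family,
                f$n_events %||% "truth"))
  }
  invisible(x)
}

#' Fit the 11 risk equations from a cohort and its event histories
#'
#' Each primary endpoint is fitted cause-specifically (competing events are
#' censored at their occurrence) over the candidate families and selected by
#' AIC. Post-event equations use sex and age at event only. When a post-event
#' stratum has too few deaths to support its own equation the three
#' post-event strata are pooled for that outcome (small-sample fallback,
#' reported in the returned AIC table).
#'
#' @param cohort Profile table.
#' @param histories Event-history table.
#' @param families Candidate families (default all four).
#' @param life_table Life table for the non-CVD splice.
#' @param splice_time Years after which non-CVD mortality follows the life
#'   table (default 10).
#' @param min_events Minimum events per equation before pooling (default 10).
#' @param gengamma_min_events Events needed before the generalised gamma is
#'   attempted (default 30; it is poorly identified below that).
#' @return A \code{scad_eqset}.
#' @export
fit_risk_equations <- function(cohort, histories,
                               families = FAMILIES,
                               life_table = make_life_table(),
                               splice_time = 10,
                               min_events = 10L,
                               gengamma_min_events = 30L) {
  X <- profile_model_matrix(cohort)
  h <- histories[match(cohort$patient_id, histories$patient_id), ]
  aic_rows <- list()

  fit_endpoint <- function(time, status, XX, label,
                           fams = families, min_ev = min_events) {
    fits <- list()
    for (fam in fams) {
      if (fam == "gengamma" && sum(status) < gengamma_min_events) next
      f <- tryCatch(
        fit_parametric(time, status, XX, fam, min_events = min_ev,
                       endpoint = label),
        error = function(e) NULL)
      if (!is.null(f)) fits[[fam]] <- f
    }
    if (!length(fits)) {
      stop("no family could be fitted for endpoint '", label, "'", call. = FALSE)
    }
    for (f in fits) {
      aic_rows[[length(aic_rows) + 1]] <<- data.frame(
        endpoint = label, family = f$family, loglik = f$loglik,
        AIC = f$AIC, n_events = f$n_events, selected = FALSE)
    }
    best <- select_best_family(fits)
    for (i in seq_along(aic_rows)) {
      if (aic_rows[[i]]$endpoint == label && aic_rows[[i]]$family == best$family) {
        aic_rows[[i]]$selected <<- TRUE
      }
    }
    best
  }

  # Small-sample fallback ladder for a sparse endpoint (e.g. haemorrhagic
  # stroke in a small cohort): full covariates -> (intercept, age, sex)
  # exponential -> intercept-only exponential. The reduced fits are flagged
  # in the AIC table by their endpoint label.
  fit_primary <- function(time, status, label) {
    d <- sum(status)
    if (d >= min_events) return(fit_endpoint(time, status, X, label))
    if (d >= 3) {
      Xr <- X[, c("intercept", "age10", "female"), drop = FALSE]
      return(fit_endpoint(time, status, Xr, paste0(label, "_reduced"),
                          fams = "exponential", min_ev = 3L))
    }
    if (d >= 1) {
      return(fit_endpoint(time, status, X[, "intercept", drop = FALSE],
                          paste0(label, "_intercept_only"),
                          fams = "exponential", min_ev = 1L))
    }
    # zero events: the exponential MLE rate is 0; use an effectively
    # zero-hazard equation rather than refusing to build the set
    warning("no events observed for endpoint '", label,
            "'; zero-hazard equation used")
    null_fit(label)
  }

  primary <- list()
  for (ep in PRIMARY_ENDPOINTS) {
    status <- as.numeric(h$first_event == ep)
    primary[[ep]] <- fit_primary(h$time_first_event, status, ep)
  }

  nf_state <- c(mi = "post_mi", ischaemic_stroke = "post_is",
                haemorrhagic_stroke = "post_hs")
  idx_nf <- which(h$first_event %in% names(nf_state))
  age_ev <- cohort$age_entry[idx_nf] + h$time_first_event[idx_nf]
  Xp_all <- post_event_design(cohort$sex[idx_nf], age_ev)
  st_all <- nf_state[h$first_event[idx_nf]]
  tp_all <- h$time_post_event[idx_nf]

  post <- list()
  for (st in c("post_mi", "post_is", "post_hs")) {
    post[[st]] <- list()
    for (oc in c("cvd_death", "noncvd_death")) {
      sel <- st_all == st
      status <- as.numeric(h$post_event_outcome[idx_nf] == oc)
      label <- paste(st, oc, sep = "_")
      if (sum(status[sel]) >= min_events) {
        post[[st]][[oc]] <- fit_endpoint(tp_all[sel], status[sel],
                                         Xp_all[sel, , drop = FALSE], label)
      } else if (sum(status) >= min_events) {
        # pooled fallback across the three post-event strata
        post[[st]][[oc]] <- fit_endpoint(tp_all, status, Xp_all,
                                         paste0(label, "_pooled"))
      } else if (sum(status) >= 3) {
        post[[st]][[oc]] <- fit_endpoint(tp_all, status, Xp_all,
                                         paste0(label, "_pooled_reduced"),
                                         fams = "exponential", min_ev = 3L)
      } else if (sum(status) >= 1) {
        post[[st]][[oc]] <- fit_endpoint(tp_all, status,
                                         Xp_all[, "intercept", drop = FALSE],
                                         paste0(label, "_pooled_intercept"),
                                         fams = "exponential", min_ev = 1L)
      } else {
        warning("no events observed for '", label,
                "'; zero-hazard equation used")
        post[[st]][[oc]] <- null_fit(label)
      }
    }
  }
  aic_table <- do.call(rbind, aic_rows)
  new_equation_set(primary, post, life_table, splice_time, aic_table)
}

#' Build an equation set directly from ground-truth parameters
#'
#' Wraps a \code{scad_truth} object into the same structure as a fitted
#' equation set (with zero variance), so the decision engine can be run on
#' the known data-generating process.
#'
#' @param truth \code{scad_truth}.
#' @param life_table Life table (default synthetic); ignored when
#'   \code{splice_time} is infinite.
#' @param splice_time Splice time in years; \code{Inf} disables the splice.
#' @return A \code{scad_eqset}.
#' @export
equation_set_from_truth <- function(truth = default_true_parameters(),
                                    life_table = make_life_table(),
                                    splice_time = 10) {
  as_fit <- function(eq, endpoint) {
    k <- length(eq$beta)
    npar <- k + (eq$family != "exponential") + (eq$family == "gengamma")
    structure(list(
      endpoint = endpoint, family = eq$family, coef = eq$beta,
      sigma = eq$sigma %||% 1, Q = eq$Q %||% if (eq$family == "lognormal") 0 else 1,
      par = NULL, fixed = list(),
      vcov = matrix(0, npar, npar), loglik = NA_real_, AIC = NA_real_,
      npar = npar, n = NA_integer_, n_events = NA_integer_,
      fingerprint = "truth"), class = "scad_survfit")
  }
  primary <- lapply(setNames(PRIMARY_ENDPOINTS, PRIMARY_ENDPOINTS),
                    function(ep) as_fit(truth$primary[[ep]], ep))
  post <- lapply(setNames(names(truth$post), names(truth$post)), function(st) {
    lapply(setNames(c("cvd_death", "noncvd_death"), c("cvd_death", "noncvd_death")),
           function(oc) as_fit(truth$post[[st]][[oc]], paste(st, oc, sep = "_")))
  })
  new_equation_set(primary, post, life_table, splice_time)
}

# Location linear predictor of a fit for design row(s).
fit_mu <- function(fit, X) {
  nm <- names(fit$coef)
  drop(as.matrix(X)[, nm, drop = FALSE] %*% fit$coef)
}

#' Spliced non-CVD mortality hazard
#'
#' Parametric fitted hazard before the splice time, life-table rate
#' \eqn{-\log(1 - q_x)} at the attained integer age afterwards.
#'
#' @param set \code{scad_eqset}.
#' @param x_primary One-row primary design matrix for the profile.
#' @param female Female indicator (fractional allowed).
#' @param age_entry Age at cohort entry, years.
#' @param t Time(s) since entry, years.
#' @return Hazard per year at each \code{t}.
#' @export
spliced_noncvd_hazard <- function(set, x_primary, female, age_entry, t) {
  fit <- set$primary$noncvd_death
  mu <- fit_mu(fit, x_primary)
  h <- aft_hazard(fit$family, t, rep_len(mu, length(t)), fit$sigma, fit$Q)
  after <- t >= set$splice_time
  if (any(after)) {
    h[after] <- lt_rate_blend(set$life_table, female, age_entry + t[after])
  }
  h
}

# Cumulative spliced non-CVD hazard from 0 to t (vectorised over sorted or
# unsorted t).
spliced_noncvd_cumhaz <- function(set, x_primary, female, age_entry, t) {
  fit <- set$primary$noncvd_death
  mu <- fit_mu(fit, x_primary)
  ts <- set$splice_time
  H <- aft_cumhaz(fit$family, pmin(t, ts), rep_len(mu, length(t)), fit$sigma, fit$Q)
  after <- which(t > ts)
  for (i in after) {
    H[i] <- H[i] + lt_cumhaz_segment(set$life_table, female, age_entry, ts, t[i])
  }
  H
}
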