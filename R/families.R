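# Accelerated-failure-time survival families.
#
# All four families share the location parameter mu (the linear predictor
# x'beta on the log-time scale). The generalised gamma uses the Prentice
# (mu, sigma, Q) parameterisation, which nests the Weibull at Q = 1 and the
# lognormal as Q -> 0. Functions are vectorised over t and mu.

FAMILIES <- c("exponential", "weibull", "lognormal", "gengamma")

# Treat |Q| below this as the lognormal limit.
.Q_EPS <- 1e-8

#' Cumulative hazard of an AFT family
#'
#' @param family One of \code{"exponential"}, \code{"weibull"},
#'   \code{"lognormal"}, \code{"gengamma"}.
#' @param t Time(s), non-negative, years.
#' @param mu Location linear predictor(s) on the log-time scale.
#' @param sigma Scale parameter (> 0); ignored for the exponential.
#' @param Q Generalised-gamma shape; ignored for other families.
#' @return Cumulative hazard H(t), same length as \code{t} (recycled
#'   against \code{mu}).
#' @export
aft_cumhaz <- function(family, t, mu, sigma = 1, Q = 1) {
  t <- pmax(t, 0)
  switch(family,
    exponential = {
      # exp(log t - mu) rather than t * exp(-mu): avoids 0 * Inf when a
      # degenerate coefficient draw sends the rate to infinity
      H <- exp(log(t) - rep_len(mu, max(length(t), length(mu))))
      H[rep_len(t, length(H)) == 0] <- 0
      H
    },
    weibull = {
      H <- exp(log(t) / sigma - rep_len(mu, max(length(t), length(mu))) / sigma)
      H[rep_len(t, length(H)) == 0] <- 0
      H
    },
    lognormal = {
      H <- numeric(length(t) * 0 + max(length(t), length(mu)))
      tt <- rep_len(t, length(H)); mm <- rep_len(mu, length(H))
      pos <- tt > 0
      H[pos] <- -pnorm((log(tt[pos]) - mm[pos]) / sigma,
                       lower.tail = FALSE, log.p = TRUE)
      H
    },
    gengamma = {
      n <- max(length(t), length(mu))
      tt <- rep_len(t, n); mm <- rep_len(mu, n)
      H <- numeric(n)
      pos <- tt > 0
      if (abs(Q) < .Q_EPS) {
        H[pos] <- -pnorm((log(tt[pos]) - mm[pos]) / sigma,
                         lower.tail = FALSE, log.p = TRUE)
      } else {
        a <- Q^-2
        w <- (log(tt[pos]) - mm[pos]) / sigma
        u <- a * exp(Q * w)
        if (Q > 0) {
          H[pos] <- -pgamma(u, shape = a, lower.tail = FALSE, log.p = TRUE)
        } else {
          H[pos] <- -pgamma(u, shape = a, lower.tail = TRUE, log.p = TRUE)
        }
      }
      H
    },
    stop("unknown family: ", family)
  )
}

#' Hazard function of an AFT family
#'
#' @inheritParams aft_cumhaz
#' @return Instantaneous hazard h(t) per year.
#' @export
aft_hazard <- function(family, t, mu, sigma = 1, Q = 1) {
  n <- max(length(t), length(mu))
  tt <- rep_len(t, n); mm <- rep_len(mu, n)
  switch(family,
    exponential = rep_len(exp(-mm), n),
    weibull = {
      h <- numeric(n); pos <- tt > 0
      h[pos] <- exp((1 / sigma - 1) * log(tt[pos]) - mm[pos] / sigma) / sigma
      if (any(!pos)) h[!pos] <- if (sigma < 1) 0 else if (sigma == 1) exp(-mm[!pos]) else Inf
      h
    },
    lognormal = {
      h <- numeric(n); pos <- tt > 0
      z <- (log(tt[pos]) - mm[pos]) / sigma
      logS <- pnorm(z, lower.tail = FALSE, log.p = TRUE)
      h[pos] <- exp(dnorm(z, log = TRUE) - logS) / (sigma * tt[pos])
      h
    },
    gengamma = {
      h <- numeric(n); pos <- tt > 0
      logf <- gengamma_logdens(tt[pos], mm[pos], sigma, Q)
      logS <- -aft_cumhaz("gengamma", tt[pos], mm[pos], sigma, Q)
      h[pos] <- exp(logf - logS)
      h
    },
    stop("unknown family: ", family)
  )
}

# Log density of the generalised gamma (Prentice form), vectorised; t > 0.
gengamma_logdens <- function(t, mu, sigma, Q) {
  w <- (log(t) - mu) / sigma
  if (abs(Q) < .Q_EPS) {
    dnorm(w, log = TRUE) - log(sigma) - log(t)
  } else {
    a <- Q^-2
    a * log(a) + log(abs(Q)) - lgamma(a) + a * (Q * w - exp(Q * w)) -
      log(sigma) - log(t)
  }
}

#' Random times from an AFT family
#'
#' @inheritParams aft_cumhaz
#' @param n Number of draws; \code{mu} is recycled to length \code{n}.
#' @return Vector of event times in years.
#' @export
aft_rtime <- function(family, n, mu, sigma = 1, Q = 1) {
  mu <- rep_len(mu, n)
  switch(family,
    exponential = rexp(n) * exp(mu),
    weibull = exp(mu) * (-log(runif(n)))^sigma,
    lognormal = exp(mu + sigma * rnorm(n)),
    gengamma = {
      if (abs(Q) < .Q_EPS) {
        exp(mu + sigma * rnorm(n))
      } else {
        a <- Q^-2
        g <- rgamma(n, shape = a, rate = 1)
        w <- log(g / a) / Q
        exp(mu + sigma * w)
      }
    },
    stop("unknown family: ", family)
  )
}

# Log-likelihood of right-censored AFT data.
# theta layout: c(beta[k], log_sigma (if used), Q (if gengamma)), with any
# parameters named in `fixed` removed from theta and taken from there.
aft_loglik <- function(theta, time, status, X, family, fixed = list()) {
  p <- aft_unpack(theta, ncol(X), family, fixed)
  mu <- drop(X %*% p$beta)
  logS <- -aft_cumhaz(family, time, mu, p$sigma, p$Q)
  d <- status == 1
  ll <- logS
  if (any(d)) {
    logf <- switch(family,
      exponential = -mu[d] + logS[d],
      weibull = {
        w <- (log(time[d]) - mu[d]) / p$sigma
        -log(p$sigma) - log(time[d]) + w - exp(w)
      },
      lognormal = {
        w <- (log(time[d]) - mu[d]) / p$sigma
        dnorm(w, log = TRUE) - log(p$sigma) - log(time[d])
      },
      gengamma = gengamma_logdens(time[d], mu[d], p$sigma, p$Q)
    )
    ll[d] <- logf
  }
  sum(ll)
}

# Analytic gradient for exponential / weibull / lognormal (gengamma uses a
# numeric gradient; its Q-derivatives involve incomplete-gamma derivatives).
aft_grad <- function(theta, time, status, X, family, fixed = list()) {
  p <- aft_unpack(theta, ncol(X), family, fixed)
  mu <- drop(X %*% p$beta)
  sigma <- p$sigma
  d <- status == 1
  if (family == "exponential") {
    ez <- time * exp(-mu)          # = e^w
    dmu <- ez - as.numeric(d)      # event: -1 + e^w ; censored: e^w
    g <- drop(crossprod(X, dmu))
    names(g) <- colnames(X)
    return(g[!(names(g) %in% names(fixed))] * 1)  # no aux params
  }
  w <- (log(time) - mu) / sigma
  if (family == "weibull") {
    ew <- exp(w)
    dmu <- ifelse(d, (ew - 1) / sigma, ew / sigma)
    dls <- ifelse(d, -1 - w * (1 - ew), w * ew)
  } else if (family == "lognormal") {
    lam <- exp(dnorm(w, log = TRUE) - pnorm(w, lower.tail = FALSE, log.p = TRUE))
    dmu <- ifelse(d, w / sigma, lam / sigma)
    dls <- ifelse(d, -1 + w^2, lam * w)
  } else {
    stop("analytic gradient not implemented for ", family)
  }
  gb <- drop(crossprod(X, dmu))
  g <- c(gb, sum(dls))
  names(g) <- c(colnames(X), "log_sigma")
  if ("log_sigma" %in% names(fixed)) g <- g[names(g) != "log_sigma"]
  g
}

# Split the free-parameter vector into beta / sigma / Q given fixings.
aft_unpack <- function(theta, k, family, fixed = list()) {
  beta <- theta[seq_len(k)]
  idx <- k
  if (family == "exponential") {
    sigma <- 1
  } else if (!is.null(fixed$log_sigma)) {
    sigma <- exp(fixed$log_sigma)
  } else {
    idx <- idx + 1
    sigma <- exp(theta[idx])
  }
  if (family != "gengamma") {
    Q <- if (family == "weibull" || family == "exponential") 1 else 0
  } else if (!is.null(fixed$Q)) {
    Q <- fixed$Q
  } else {
    idx <- idx + 1
    Q <- theta[idx]
  }
  list(beta = beta, sigma = sigma, Q = Q)
}

# Number of free parameters for a family with k location coefficients.
aft_npar <- function(family, k, fixed = list()) {
  n <- k
  if (family != "exponential" && is.null(fixed$log_sigma)) n <- n + 1
  if (family == "gengamma" && is.null(fixed$Q)) n <- n + 1
  n
}
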