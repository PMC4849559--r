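# Shared internal helpers: seeding, cycle-length constant, small validators.

# One 90-day cycle expressed in years. Used everywhere so the time unit
# cannot drift between modules.
CYCLE_YEARS <- 90 / 365.25

#' Number of years in one 90-day model cycle
#'
#' @return A single numeric, \code{90/365.25}.
#' @export
cycle_length_years <- function() CYCLE_YEARS

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls do not clobber user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a reproducible sub-seed for stage `k` from a master seed, kept
# below 2^31 so it is always a valid R integer.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483647L)
}

stop_if_not_prob <- function(p, what) {
  bad <- !is.finite(p) | p < 0 | p > 1
  if (any(bad)) {
    stop(sprintf("%s must lie in [0, 1]; got %s", what,
                 paste(format(p[bad][seq_len(min(3, sum(bad)))]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Cheap data fingerprint used to detect AIC comparisons across different
# datasets. Not cryptographic; collision risk is irrelevant here.
data_fingerprint <- function(time, status, X) {
  sprintf("n%d_d%d_t%.6e_x%.6e",
          length(time), sum(status), sum(time), sum(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
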