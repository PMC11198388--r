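#' Calibrate a constant hazard rate to a survival anchor
#'
#' Solves `exp(-lambda * horizon) = surv_frac` for the rate `lambda` of an
#' exponential survival model, i.e. the constant per-year hazard under which
#' survival passes through `surv_frac` at time `horizon`. Used to anchor
#' simulated subgroup hazards to published survival fractions (for example
#' 85% survival at 6 years for the most favourable subgroup).
#'
#' @param surv_frac Survival probability in (0, 1] at `horizon`.
#' @param horizon Positive time in years.
#' @return Hazard rate per year (>= 0).
#' @examples
#' calibrate_exponential(0.85, 6)
#' @export
calibrate_exponential <- function(surv_frac, horizon) {
  if (!is.numeric(surv_frac) || length(surv_frac) != 1 || !is.finite(surv_frac) ||
      surv_frac <= 0 || surv_frac > 1) {
    stop("`surv_frac` must be a single number in (0, 1]")
  }
  if (!is.numeric(horizon) || length(horizon) != 1 || !is.finite(horizon) ||
      horizon <= 0) {
    stop("`horizon` must be a single positive number")
  }
  -log(surv_frac) / horizon
}

#' Calibrate a two-piece exponential hazard to two survival anchors
#'
#' Constructs rates `(rate1, rate2)` such that a piecewise-exponential model
#' with hazard `rate1` on `[0, t1]` and `rate2` on `(t1, t2]` (and beyond)
#' satisfies `S(t1) = s1` and `S(t2) = s2`. This reproduces survival curves
#' with a steep early decline followed by a different late slope, such as the
#' worst-prognosis subgroup's 48% one-year and 11% six-year survival.
#'
#' @param s1,s2 Survival probabilities at `t1` and `t2`; requires
#'   `0 < s2 <= s1 <= 1`.
#' @param t1,t2 Anchor times in years, `0 < t1 < t2`.
#' @return Numeric vector `c(rate1, rate2)` of per-year hazard rates.
#' @examples
#' calibrate_piecewise(0.48, 1, 0.11, 6)
#' @export
calibrate_piecewise <- function(s1, t1, s2, t2) {
  if (t1 <= 0 || t2 <= t1) stop("need 0 < t1 < t2")
  if (s1 <= 0 || s1 > 1 || s2 <= 0) stop("survival anchors must be in (0, 1]")
  if (s2 > s1) stop("survival cannot increase: need s2 <= s1")
  c(-log(s1) / t1, (log(s1) - log(s2)) / (t2 - t1))
}

#' Piecewise-exponential leaf hazard
#'
#' Hazard model attached to one terminal leaf of a truth tree: a step hazard
#' with `rates[j]` on the interval between consecutive `cuts`, the final
#' piece open-ended.
#'
#' @param leaf_id Integer leaf identifier.
#' @param rates Non-negative per-year rates, one per piece.
#' @param cuts Strictly increasing interior breakpoints (years); length
#'   `length(rates) - 1`.
#' @return Object of class `leaf_hazard`.
#' @examples
#' leaf_hazard(5, calibrate_piecewise(0.48, 1, 0.11, 6), cuts = 1)
#' @export
leaf_hazard <- function(leaf_id, rates, cuts = numeric(0)) {
  if (length(rates) != length(cuts) + 1) {
    stop("need length(rates) == length(cuts) + 1")
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("hazard rates must be finite and non-negative")
  }
  if (length(cuts) && (any(cuts <= 0) || any(diff(cuts) <= 0) || any(!is.finite(cuts)))) {
    stop("`cuts` must be finite, positive and strictly increasing")
  }
  structure(
    list(leaf_id = as.integer(leaf_id), rates = as.numeric(rates),
         cuts = as.numeric(cuts)),
    class = "leaf_hazard"
  )
}

#' Cumulative hazard of a piecewise-exponential model
#'
#' @param hazard A [leaf_hazard()].
#' @param t Non-negative times (years).
#' @return Cumulative hazard at each `t`.
#' @export
cumulative_hazard <- function(hazard, t) {
  stopifnot(inherits(hazard, "leaf_hazard"))
  if (any(t < 0)) stop("`t` must be non-negative")
  starts <- c(0, hazard$cuts)
  ends <- c(hazard$cuts, Inf)
  H <- numeric(length(t))
  for (j in seq_along(hazard$rates)) {
    H <- H + hazard$rates[j] * pmax(0, pmin(t, ends[j]) - starts[j])
  }
  H
}

#' Survival function of a piecewise-exponential model
#'
#' `S(t) = exp(-H(t))`; non-increasing with `S(0) = 1`.
#'
#' @inheritParams cumulative_hazard
#' @return Survival probability at each `t`.
#' @export
hazard_survival <- function(hazard, t) {
  exp(-cumulative_hazard(hazard, t))
}

#' Draw event times from a piecewise-exponential hazard
#'
#' Inverse-transform sampling: a unit exponential deviate is inverted through
#' the piecewise-linear cumulative hazard. Times beyond the support of a
#' hazard whose total mass is finite (trailing zero rate) are `Inf` and are
#' expected to be administratively censored downstream.
#'
#' @param hazard A [leaf_hazard()].
#' @param n Number of draws.
#' @return Numeric vector of event times (years), possibly infinite.
#' @export
sample_event_times <- function(hazard, n) {
  stopifnot(inherits(hazard, "leaf_hazard"), n >= 0)
  if (n == 0) return(numeric(0))
  starts <- c(0, hazard$cuts)
  ends <- c(hazard$cuts, Inf)
  r <- hazard$rates
  k <- length(r)
  h_start <- c(0, cumsum(r[-k] * (ends[-k] - starts[-k])))
  h_end <- h_start + r * (ends - starts)
  h_end[r == 0] <- h_start[r == 0]  # 0 * Inf guard on open-ended zero rate
  u <- stats::rexp(n)
  j <- findInterval(u, h_end, left.open = TRUE) + 1L
  out <- rep(Inf, n)
  ok <- j <= k
  out[ok] <- starts[j[ok]] + (u[ok] - h_start[j[ok]]) / r[j[ok]]
  out
}

#' Censoring model for cohort simulation
#'
#' Staggered uniform study entry over `entry_window` years, administrative
#' censoring at `study_end` (calendar time since the start of enrolment), and
#' an independent exponential dropout process.
#'
#' @param entry_window Width of the uniform entry window in years.
#' @param study_end Calendar end of follow-up in years (> 0).
#' @param dropout_rate Per-year dropout hazard (>= 0).
#' @return Object of class `censoring_spec`.
#' @export
censoring_spec <- function(entry_window = 10, study_end = 10,
                           dropout_rate = 0.02) {
  if (study_end <= 0) stop("`study_end` must be positive")
  if (entry_window < 0) stop("`entry_window` must be non-negative")
  if (dropout_rate < 0) stop("`dropout_rate` must be non-negative")
  structure(
    list(entry_window = entry_window, study_end = study_end,
         dropout_rate = dropout_rate),
    class = "censoring_spec"
  )
}
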