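#' @keywords internal
check_survival_data <- function(time, event) {
  if (length(time) == 0) stop("empty survival data")
  if (length(time) != length(event)) {
    stop("`time` and `event` must have equal length")
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("`time` must be finite and positive")
  }
  if (!all(event %in% c(0, 1))) stop("`event` must be 0/1")
  invisible(TRUE)
}

# shared risk-set bookkeeping: distinct times, events and at-risk counts.
# At-risk at t counts everyone with time >= t, so subjects censored at an
# event time are still at risk for that event (events precede censorings).
risk_table <- function(time, event) {
  n <- length(time)
  tt <- sort(unique(time))
  f <- factor(time, levels = tt)
  d <- as.vector(rowsum(as.numeric(event), f))
  removed <- tabulate(f)
  nrisk <- n - c(0, cumsum(removed)[-length(removed)])
  list(time = tt, n.event = d, n.risk = nrisk, n = n)
}

#' Nelson-Aalen cumulative hazard estimator
#'
#' Step estimator of the cumulative hazard:
#' `Lambda(t) = sum over event times t_j <= t of d_j / n_j`, where `d_j`
#' counts events at `t_j` and `n_j` the subjects still at risk (time
#' `>= t_j`).
#'
#' @param time Positive follow-up times (years).
#' @param event Event indicators (1 = event, 0 = censored).
#' @return Object of class `hazard_step` with fields `time`, `cumhaz`,
#'   `n.risk`, `n.event`, `n`; a right-continuous step function starting
#'   at 0.
#' @examples
#' na <- nelson_aalen(c(1, 2, 3), c(1, 1, 1))
#' na$cumhaz  # 1/3, 1/3 + 1/2, 1/3 + 1/2 + 1
#' @export
nelson_aalen <- function(time, event) {
  check_survival_data(time, event)
  rt <- risk_table(time, event)
  keep <- rt$n.event > 0
  structure(
    list(time = rt$time[keep],
         cumhaz = cumsum(rt$n.event[keep] / rt$n.risk[keep]),
         n.risk = rt$n.risk[keep], n.event = rt$n.event[keep], n = rt$n),
    class = "hazard_step"
  )
}

#' Evaluate a cumulative-hazard step function
#'
#' @param fit A [nelson_aalen()] fit.
#' @param t Non-negative evaluation times.
#' @return `Lambda(t)`, right-continuous.
#' @export
cumhaz_at <- function(fit, t) {
  stopifnot(inherits(fit, "hazard_step"))
  if (any(t < 0)) stop("`t` must be non-negative")
  c(0, fit$cumhaz)[findInterval(t, fit$time) + 1L]
}

#' Log-rank scores
#'
#' Per-subject residuals `a_i = event_i - Lambda(time_i)` of the event
#' indicator against the Nelson-Aalen cumulative hazard evaluated at the
#' subject's own follow-up time. Group sums of these scores form
#' log-rank-type statistics; the scores always sum to zero.
#'
#' @inheritParams nelson_aalen
#' @return Numeric vector of scores.
#' @export
logrank_scores <- function(time, event) {
  check_survival_data(time, event)
  if (!any(event == 1)) return(numeric(length(time)))
  event - cumhaz_at(nelson_aalen(time, event), time)
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod over event times t_j <= t of (1 - d_j / n_j)`, with the
#' Greenwood variance `S(t)^2 * sum d_j / (n_j (n_j - d_j))`.
#'
#' @inheritParams nelson_aalen
#' @return Object of class `km_curve` with fields `time`, `surv`, `var`
#'   (Greenwood), `n.risk`, `n.event`, `n`.
#' @export
kaplan_meier <- function(time, event) {
  check_survival_data(time, event)
  rt <- risk_table(time, event)
  keep <- rt$n.event > 0
  d <- rt$n.event[keep]
  r <- rt$n.risk[keep]
  surv <- cumprod(1 - d / r)
  gw_terms <- ifelse(r > d, d / (r * (r - d)), NA_real_)
  structure(
    list(time = rt$time[keep], surv = surv,
         var = surv^2 * cumsum(gw_terms),
         n.risk = r, n.event = d, n = rt$n,
         max_time = max(time)),
    class = "km_curve"
  )
}

#' Evaluate a Kaplan-Meier curve
#'
#' Right-continuous step lookup; `S(t) = 1` before the first event and the
#' last value is carried forward beyond the final event time.
#'
#' @param curve A [kaplan_meier()] curve.
#' @param t Non-negative evaluation times.
#' @return Survival probabilities.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(t < 0)) stop("`t` must be non-negative")
  c(1, curve$surv)[findInterval(t, curve$time) + 1L]
}

#' Median survival time of a Kaplan-Meier curve
#'
#' Smallest observed event time at which the curve drops to 0.5 or below;
#' `NA` when the curve never reaches 0.5.
#'
#' @param curve A [kaplan_meier()] curve.
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- which(curve$surv <= 0.5 + 1e-9)  # cumprod rounding at exact halves
  if (!length(idx)) return(NA_real_)
  curve$time[idx[1]]
}

#' Export a Kaplan-Meier curve as a data frame
#'
#' @param x A [kaplan_meier()] curve.
#' @param ... Unused.
#' @return `data.frame` with time, survival, Greenwood variance and at-risk
#'   counts, suitable for TSV export.
#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, surv = x$surv, var = x$var,
             n.risk = x$n.risk, n.event = x$n.event)
}
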