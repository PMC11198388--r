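#' Univariate Cox screening
#'
#' Fits one single-covariate Cox model per variable and reports the per-unit
#' hazard ratio with confidence interval and Wald p-value, plus the per-SD
#' hazard ratio for continuous variables. Variables whose fit fails (for
#' example constant columns or separation) are returned as flagged rows
#' rather than aborting the screen. Factors are screened through their
#' one-hot contrasts and report the smallest contrast p-value.
#'
#' @param data Data frame with outcome and covariates.
#' @param variables Variable names to screen.
#' @param time_col,event_col Outcome column names.
#' @param ties Tie handling for [cox_fit()].
#' @return `data.frame` of class `screen_table`: one row per variable with
#'   `hr`, `ci_lower`, `ci_upper`, `p`, `hr_per_sd`, `n`, `events`, `note`.
#' @export
univariate_screen <- function(data, variables, time_col = "time_years",
                              event_col = "event", ties = "efron") {
  time <- data[[time_col]]
  event <- data[[event_col]]
  check_survival_data(time, event)
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    res <- data.frame(variable = v, hr = NA_real_, ci_lower = NA_real_,
                      ci_upper = NA_real_, p = NA_real_,
                      hr_per_sd = NA_real_, n = length(time),
                      events = sum(event), note = "ok",
                      stringsAsFactors = FALSE)
    fit <- tryCatch({
      g <- if (is.factor(x)) {
        stats::model.matrix(~z, data.frame(z = droplevels(x)))[, -1, drop = FALSE]
      } else {
        matrix(as.numeric(x), dimnames = list(NULL, v))
      }
      cox_fit(g, time, event, ties = ties)
    }, error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      res$note <- fit
      return(res)
    }
    j <- which.min(fit$p)
    res$hr <- fit$hr[j]
    res$ci_lower <- fit$ci_lower[j]
    res$ci_upper <- fit$ci_upper[j]
    res$p <- fit$p[j]
    if (!is.factor(x) && length(unique(x)) > 2) {
      res$hr_per_sd <- exp(fit$coef[j] * stats::sd(as.numeric(x)))
    }
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("screen_table", class(out))
  out
}

#' Forward/backward stepwise Cox selection
#'
#' Iterates forward addition (the candidate with the smallest Wald p-value
#' in the augmented model enters when `p < p_enter`) and backward
#' elimination (any included variable with `p > p_remove` is dropped, worst
#' first) until the model is stable or the iteration cap is reached.
#' Deterministic given the data; ties are broken by candidate order.
#' Candidates whose augmented fit fails to converge are skipped in that
#' iteration.
#'
#' @param data Data frame with outcome and covariates.
#' @param candidates Candidate variable names.
#' @param p_enter Entry threshold (default 0.05); must be `<= p_remove`.
#' @param p_remove Removal threshold (default 0.10).
#' @param time_col,event_col Outcome column names.
#' @param ties Tie handling for [cox_fit()].
#' @param max_iter Cap on forward/backward sweeps.
#' @return Character vector of selected variable names (possibly empty).
#' @export
stepwise_cox <- function(data, candidates, p_enter = 0.05, p_remove = 0.10,
                         time_col = "time_years", event_col = "event",
                         ties = "efron", max_iter = 50) {
  if (p_enter > p_remove) stop("need p_enter <= p_remove")
  if (!length(candidates)) return(character(0))
  time <- data[[time_col]]
  event <- data[[event_col]]
  check_survival_data(time, event)
  xmat <- function(vars) {
    m <- as.matrix(as.data.frame(lapply(data[vars], as.numeric),
                                 optional = TRUE))
    colnames(m) <- vars
    m
  }
  fit_p <- function(vars) {
    fit <- tryCatch(cox_fit(xmat(vars), time, event, ties = ties),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    stats::setNames(fit$p, vars)
  }
  current <- character(0)
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    # forward step
    remaining <- setdiff(candidates, current)
    if (length(remaining)) {
      entry_p <- rep(NA_real_, length(remaining))
      for (j in seq_along(remaining)) {
        pv <- fit_p(c(current, remaining[j]))
        if (!is.null(pv)) entry_p[j] <- pv[remaining[j]]
      }
      if (any(!is.na(entry_p))) {
        jbest <- which.min(entry_p)     # first index wins ties
        if (entry_p[jbest] < p_enter) {
          current <- c(current, remaining[jbest])
          changed <- TRUE
        }
      }
    }
    # backward step
    repeat {
      if (length(current) < 1) break
      pv <- fit_p(current)
      if (is.null(pv)) break
      worst <- which.max(pv)
      if (pv[worst] > p_remove) {
        current <- current[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  current
}

#' Bootstrap stability selection within variable domains
#'
#' For each variable domain (clinical, echocardiographic, laboratory), draws
#' `B` bootstrap resamples of the cohort (same n, with replacement), runs
#' [stepwise_cox()] on each, and records the per-variable inclusion
#' frequency. Variables selected in at least `threshold` of the repeats are
#' retained; the final covariate set is the union of the per-domain retained
#' sets. A repeat whose stepwise fails entirely counts as an empty
#' selection.
#'
#' @param data Data frame with outcome and covariates.
#' @param domain_map Named list of variable names per domain, as from
#'   [cohort_domain_map()].
#' @param B Number of bootstrap repeats per domain (default 500).
#' @param threshold Retention threshold on the inclusion frequency (default
#'   0.85).
#' @param p_enter,p_remove Stepwise thresholds.
#' @param seed Integer seed making the resamples reproducible.
#' @param time_col,event_col,ties Passed through.
#' @return Object of class `selection_report`: `$frequencies` (data frame of
#'   domain, variable, frequency, retained), `$retained` (union across
#'   domains), `$B`, `$threshold`, `$failures` (failed repeats per domain).
#' @export
bootstrap_selection <- function(data, domain_map, B = 500, threshold = 0.85,
                                p_enter = 0.05, p_remove = 0.10, seed = 1,
                                time_col = "time_years", event_col = "event",
                                ties = "efron") {
  stopifnot(B >= 1, threshold >= 0, threshold <= 1)
  domain_map <- domain_map[vapply(domain_map, length, integer(1)) > 0]
  if (!length(domain_map)) stop("empty domain map")
  n <- nrow(data)
  set.seed(seed)
  freq_rows <- list()
  failures <- stats::setNames(integer(length(domain_map)), names(domain_map))
  for (dom in names(domain_map)) {
    vars <- domain_map[[dom]]
    counts <- stats::setNames(numeric(length(vars)), vars)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      sel <- tryCatch(
        stepwise_cox(data[idx, , drop = FALSE], vars,
                     p_enter = p_enter, p_remove = p_remove,
                     time_col = time_col, event_col = event_col, ties = ties),
        error = function(e) {
          failures[dom] <<- failures[dom] + 1L
          character(0)
        }
      )
      counts[sel] <- counts[sel] + 1
    }
    freq_rows[[dom]] <- data.frame(
      domain = dom, variable = vars, frequency = as.vector(counts) / B,
      retained = as.vector(counts) / B >= threshold,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  freq <- do.call(rbind, freq_rows)
  row.names(freq) <- NULL
  structure(
    list(frequencies = freq,
         retained = freq$variable[freq$retained],
         B = as.integer(B), threshold = threshold, seed = seed,
         failures = failures),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Bootstrap stability selection: B =", x$B,
      ", threshold =", x$threshold, "\n")
  print(x$frequencies[order(x$frequencies$domain,
                            -x$frequencies$frequency), ],
        row.names = FALSE)
  cat("Retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
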