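#' Cox proportional hazards regression
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with step-halving,
#' starting from `beta = 0`, with the Efron (default) or Breslow correction
#' for tied event times. Standard errors come from the inverse observed
#' information; confidence intervals and p-values use the Wald normal
#' reference.
#'
#' @param x Covariate matrix (n x p), vector, or data frame of numeric
#'   columns.
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param ties `"efron"` or `"breslow"`.
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param conf_level Confidence level for the hazard-ratio intervals.
#' @return Object of class `cox_fit` with coefficients, standard errors,
#'   hazard ratios with confidence bounds, Wald p-values, the maximized log
#'   partial likelihood, convergence diagnostics and the variance matrix.
#' @examples
#' fit <- cox_fit(c(1, 0, 1, 0), time = c(1, 2, 3, 4), event = rep(1, 4))
#' fit$coef
#' @export
cox_fit <- function(x, time, event, ties = c("efron", "breslow"),
                    max_iter = 50, tol = 1e-9, conf_level = 0.95) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  check_survival_data(time, event)
  n <- nrow(x)
  p <- ncol(x)
  if (length(time) != n) stop("`x` and `time` dimensions disagree")
  if (p < 1 || n <= p) stop("need n > p >= 1")
  if (!any(event == 1)) stop("no events: partial likelihood is undefined")
  const <- apply(x, 2, function(col) diff(range(col)) == 0)
  if (any(const)) {
    stop("constant covariate(s): ", paste(colnames(x)[const], collapse = ", "))
  }

  pr <- cox_prep(x, time, event)
  beta <- rep(0, p)
  ev <- cox_eval(beta, pr, ties)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(ev$grad)) < tol) {
      converged <- TRUE
      break
    }
    info <- -ev$hess
    delta <- tryCatch(solve(info, ev$grad), error = function(e) NULL)
    if (is.null(delta)) {
      stop("singular information matrix; covariates may be collinear or ",
           "constant within risk sets")
    }
    step <- 1
    repeat {
      cand <- beta + step * delta
      ev_new <- cox_eval(cand, pr, ties)
      if (is.finite(ev_new$loglik) && ev_new$loglik >= ev$loglik - 1e-12) break
      step <- step / 2
      if (step < 2^-20) {
        stop("step-halving failed to improve the partial likelihood")
      }
    }
    beta <- beta + step * delta
    ev <- ev_new
    # increment below floating-point resolution: the gradient cannot be
    # reduced further even though its max-norm may sit above `tol` when the
    # log likelihood is large in magnitude
    if (max(abs(step * delta)) < 1e-10 * max(1, max(abs(beta)))) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 20) {
      worst <- colnames(x)[which.max(abs(beta))]
      stop("monotone partial likelihood (perfect separation) for covariate: ",
           worst)
    }
  }
  if (!converged && max(abs(ev$grad)) < tol) converged <- TRUE
  if (!converged) {
    stop("Cox fit did not converge in ", max_iter, " iterations")
  }

  info <- -ev$hess
  vmat <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vmat)) {
    stop("singular information matrix at the optimum")
  }
  se <- sqrt(diag(as.matrix(vmat)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- beta / se
  structure(
    list(coef = stats::setNames(beta, colnames(x)),
         se = stats::setNames(se, colnames(x)),
         hr = exp(beta),
         ci_lower = exp(beta - zq * se),
         ci_upper = exp(beta + zq * se),
         p = 2 * stats::pnorm(-abs(z)),
         loglik = ev$loglik,
         gradient_norm = max(abs(ev$grad)),
         var = vmat,
         converged = converged, iter = iter, ties = ties,
         n = n, nevent = sum(event == 1), conf_level = conf_level),
    class = "cox_fit"
  )
}

# sort once per fit; risk sets become suffix sums over ascending time
cox_prep <- function(x, time, event) {
  ord <- order(time)
  ts <- time[ord]
  xs <- x[ord, , drop = FALSE]
  ev <- event[ord] == 1
  p <- ncol(x)
  first <- !duplicated(ts)
  gidx <- cumsum(first)
  firstpos <- which(first)
  ei <- which(ev)
  eg <- gidx[ei]                         # distinct-time group of each event
  ug <- unique(eg)
  d <- tabulate(factor(eg, levels = ug)) # tied-event multiplicities
  # row in the suffix-sum arrays holding each event's risk-set totals
  rowsel <- firstpos[ug][rep(seq_along(ug), d)]
  frac <- (sequence(d) - 1) / rep(d, d)  # Efron within-tie fractions k/d
  gi <- rep(seq_along(ug), d)
  x2cols <- cbind(rep(seq_len(p), times = p), rep(seq_len(p), each = p))
  list(x = xs, time = ts, ev = ev, ei = ei, d = d, gi = gi,
       rowsel = rowsel, frac = frac, p = p, x2cols = x2cols)
}

suffix_cumsum <- function(m) {
  if (is.null(dim(m))) return(rev(cumsum(rev(m))))
  apply(m, 2, function(col) rev(cumsum(rev(col))))
}

cox_eval <- function(beta, pr, ties) {
  x <- pr$x
  p <- pr$p
  eta <- drop(x %*% beta)
  eta <- eta - max(eta)                  # overflow guard; cancels in loglik
  w <- exp(eta)
  wx <- w * x
  x2 <- x[, pr$x2cols[, 1], drop = FALSE] * x[, pr$x2cols[, 2], drop = FALSE]
  wx2 <- w * x2

  s0 <- suffix_cumsum(w)
  s1 <- suffix_cumsum(wx)
  s2 <- suffix_cumsum(wx2)

  ei <- pr$ei
  gi <- pr$gi
  f <- if (ties == "efron") pr$frac else rep(0, length(pr$frac))
  t0 <- rowsum(w[ei], pr$gi)[, 1]
  t1 <- rowsum(wx[ei, , drop = FALSE], pr$gi)
  t2 <- rowsum(wx2[ei, , drop = FALSE], pr$gi)

  s0e <- s0[pr$rowsel]
  s1e <- s1[pr$rowsel, , drop = FALSE]
  s2e <- s2[pr$rowsel, , drop = FALSE]

  denom <- s0e - f * t0[gi]
  m <- (s1e - f * t1[gi, , drop = FALSE]) / denom
  s2eff <- (s2e - f * t2[gi, , drop = FALSE]) / denom

  loglik <- sum(eta[ei]) - sum(log(denom))
  grad <- colSums(x[ei, , drop = FALSE] - m)
  hess <- crossprod(m) - matrix(colSums(s2eff), p, p)
  list(loglik = loglik, grad = grad, hess = hess)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$nevent, "\n", sep = "")
  tab <- data.frame(coef = x$coef, se = x$se, HR = x$hr,
                    lower = x$ci_lower, upper = x$ci_upper, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Per-subgroup hazard-ratio table
#'
#' One-hot codes subgroup (leaf) membership against a reference leaf and
#' fits a single Cox model, yielding the hazard ratio, confidence interval
#' and Wald p-value of every subgroup versus the reference. Rows are sorted
#' by ascending hazard ratio; the reference row has HR 1 by construction.
#'
#' @param leaf Subgroup labels (factor or coercible).
#' @param time,event Survival outcome.
#' @param reference Reference leaf label.
#' @param ties,conf_level Passed to [cox_fit()].
#' @return `data.frame` with columns `leaf`, `n`, `events`, `hr`,
#'   `ci_lower`, `ci_upper`, `p`, `reference`.
#' @export
cox_hr_table <- function(leaf, time, event, reference,
                         ties = "efron", conf_level = 0.95) {
  leaf <- factor(leaf)
  check_survival_data(time, event)
  if (!as.character(reference) %in% levels(leaf)) {
    stop("reference leaf not present: ", reference)
  }
  if (nlevels(droplevels(leaf)) < 2) {
    stop("need at least two subgroups with observations")
  }
  leaf <- stats::relevel(droplevels(leaf), ref = as.character(reference))
  ev_per_leaf <- tapply(event, leaf, sum)
  if (any(ev_per_leaf == 0)) {
    stop("subgroup(s) without events: ",
         paste(names(ev_per_leaf)[ev_per_leaf == 0], collapse = ", "),
         " (remove or flag before fitting)")
  }
  mm <- stats::model.matrix(~leaf)[, -1, drop = FALSE]
  colnames(mm) <- levels(leaf)[-1]
  fit <- cox_fit(mm, time, event, ties = ties, conf_level = conf_level)
  tab <- data.frame(
    leaf = c(levels(leaf)[1], colnames(mm)),
    n = as.vector(table(leaf)[c(levels(leaf)[1], colnames(mm))]),
    events = as.vector(ev_per_leaf[c(levels(leaf)[1], colnames(mm))]),
    hr = c(1, fit$hr),
    ci_lower = c(NA, fit$ci_lower),
    ci_upper = c(NA, fit$ci_upper),
    p = c(NA, fit$p),
    reference = c(TRUE, rep(FALSE, ncol(mm))),
    row.names = NULL
  )
  tab[order(tab$hr), , drop = FALSE]
}
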