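#' Permutation linear statistic
#'
#' Linear association statistic `T = sum(g_i * a_i)` between a transformed
#' covariate `g` (numeric vector, or one-hot matrix for a categorical
#' covariate) and scores `a` (here: log-rank scores), standardized by its
#' exact permutation-null moments. Under random permutation of the scores
#' against the covariate,
#' `mu = sum(g) * mean(a)` and, for scalar `g`,
#' `variance = sum((g - mean(g))^2) * sum((a - mean(a))^2) / (n - 1)`.
#' Scalar statistics are referred to the two-sided normal distribution; for
#' matrix `g` a quadratic form with the Moore-Penrose pseudo-inverse of the
#' permutation covariance is referred to chi-squared with df equal to the
#' covariance rank.
#'
#' @param g Numeric vector, or numeric matrix with one column per category.
#' @param a Numeric score vector of the same length.
#' @return Object of class `linear_statistic`: fields `statistic` (`T`),
#'   `mu`, `variance` (scalar or covariance matrix), `z` (scalar case),
#'   `quad` (quadratic form, matrix case), `df`, `p`, `degenerate`.
#' @export
linear_statistic <- function(g, a) {
  if (is.data.frame(g)) g <- as.matrix(g)
  n <- length(a)
  if (n < 2) stop("need n >= 2")
  if ((is.matrix(g) && nrow(g) != n) || (!is.matrix(g) && length(g) != n)) {
    stop("`g` and `a` lengths disagree")
  }
  abar <- mean(a)
  va <- sum((a - abar)^2)
  if (!is.matrix(g)) {
    gbar <- mean(g)
    vg <- sum((g - gbar)^2)
    T_obs <- sum(g * a)
    mu <- sum(g) * abar
    variance <- va * vg / (n - 1)
    if (variance <= 1e-14 * max(1, abs(T_obs))) {
      return(structure(
        list(statistic = T_obs, mu = mu, variance = variance, z = 0,
             quad = 0, df = 1L, p = 1, degenerate = TRUE),
        class = "linear_statistic"
      ))
    }
    z <- (T_obs - mu) / sqrt(variance)
    structure(
      list(statistic = T_obs, mu = mu, variance = variance, z = z,
           quad = z^2, df = 1L, p = 2 * stats::pnorm(-abs(z)),
           degenerate = FALSE),
      class = "linear_statistic"
    )
  } else {
    T_obs <- drop(crossprod(g, a))
    mu <- colSums(g) * abar
    gbar <- colMeans(g)
    sigma <- (va / (n - 1)) * (crossprod(g) - n * tcrossprod(gbar))
    eg <- eigen(sigma, symmetric = TRUE)
    pos <- eg$values > 1e-8 * max(eg$values, 0)
    if (!any(pos)) {
      return(structure(
        list(statistic = T_obs, mu = mu, variance = sigma, z = NA_real_,
             quad = 0, df = 0L, p = 1, degenerate = TRUE),
        class = "linear_statistic"
      ))
    }
    v <- eg$vectors[, pos, drop = FALSE]
    quad <- sum((crossprod(v, T_obs - mu))^2 / eg$values[pos])
    df <- sum(pos)
    structure(
      list(statistic = T_obs, mu = mu, variance = sigma, z = NA_real_,
           quad = quad, df = df,
           p = stats::pchisq(quad, df, lower.tail = FALSE),
           degenerate = FALSE),
      class = "linear_statistic"
    )
  }
}

# all permutations of 1..n as an (n! x n) index matrix
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- perm_matrix(n - 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(rep(i, nrow(sub)),
                      matrix(rest[sub], nrow(sub), n - 1))
  }
  do.call(rbind, out)
}

# all n! values of T under permutation of a; chunked above n = 8
perm_stat_values <- function(g, a) {
  n <- length(g)
  if (n <= 8) {
    pm <- perm_matrix(n)
    return(drop(matrix(a[pm], nrow(pm)) %*% g))
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- g[1] * a[i] + perm_stat_values(g[-1], a[-i])
  }
  unlist(out, use.names = FALSE)
}

#' Exact permutation p-value of the linear statistic
#'
#' Enumerates all `n!` rearrangements of the scores and counts those whose
#' statistic is at least as far from the permutation mean as the observed
#' one: `p = #{pi : |T(pi) - mu| >= |T_obs - mu|} / n!`. Intended as a
#' small-sample oracle for the asymptotic p-value of [linear_statistic()].
#'
#' @param g Numeric covariate vector.
#' @param a Numeric score vector.
#' @param limit Largest `n` to enumerate (default 10).
#' @return Exact two-sided permutation p-value.
#' @export
exact_permutation_p <- function(g, a, limit = 10) {
  n <- length(g)
  stopifnot(length(a) == n, n >= 2)
  if (n > limit) {
    stop("n = ", n, " exceeds the enumeration limit (", limit,
         "); use the asymptotic p-value from linear_statistic()")
  }
  mu <- sum(g) * mean(a)
  t_obs <- abs(sum(g * a) - mu)
  vals <- abs(perm_stat_values(g, a) - mu)
  tol <- 1e-9 * (1 + t_obs)
  mean(vals >= t_obs - tol)
}
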