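test_that("the worked 3-point example reproduces the permutation moments", {
  a <- logrank_scores(c(1, 2, 3), c(1, 1, 1))
  ls <- linear_statistic(c(1, 2, 3), a)
  expect_equal(ls$statistic, -1.5, tolerance = 1e-10)
  expect_equal(ls$mu, 0, tolerance = 1e-10)
  expect_equal(ls$variance, 7 / 6, tolerance = 1e-4)
  expect_equal(ls$z, -1.3887, tolerance = 1e-4)
  expect_equal(ls$p, 0.165, tolerance = 1e-3)
  # brute-force enumeration over all 3! rearrangements agrees exactly
  oracle <- perm_enum_oracle(c(1, 2, 3), a)
  expect_equal(ls$mu, oracle$mean, tolerance = 1e-10)
  expect_equal(ls$variance, oracle$var, tolerance = 1e-10)
})

test_that("moment formulas equal brute-force enumeration on random fixtures", {
  set.seed(701)
  for (r in 1:20) {
    n <- sample(3:7, 1)
    g <- sample(c(rnorm(n), rbinom(n, 1, 0.5)), n)
    a <- rnorm(n)
    ls <- linear_statistic(g, a)
    oracle <- perm_enum_oracle(g, a)
    expect_equal(ls$mu, oracle$mean, tolerance = 1e-10)
    expect_equal(ls$variance, oracle$var, tolerance = 1e-10)
  }
})

test_that("degenerate inputs yield p = 1 with a flag, never an error", {
  ls <- linear_statistic(c(1, 2, 3, 4), rep(0, 4))
  expect_true(ls$degenerate)
  expect_equal(ls$p, 1)
  expect_equal(ls$statistic, 0)
  ls2 <- linear_statistic(rep(2, 5), rnorm(5))
  expect_true(ls2$degenerate)
  expect_equal(ls2$p, 1)
})

test_that("categorical covariates use a chi-squared quadratic form", {
  set.seed(702)
  x <- factor(sample(c("a", "b", "c"), 60, replace = TRUE))
  a <- rnorm(60)
  g <- stats::model.matrix(~x - 1)
  ls <- linear_statistic(g, a)
  expect_equal(ls$df, 2)
  expect_true(ls$p >= 0 && ls$p <= 1)
  # one-hot of a binary factor collapses to the scalar statistic's p
  xb <- factor(rep(c("u", "v"), 15))
  ab <- rnorm(30)
  p_quad <- linear_statistic(stats::model.matrix(~xb - 1), ab)$p
  p_scal <- linear_statistic(as.numeric(xb == "v"), ab)$p
  expect_equal(p_quad, p_scal, tolerance = 1e-9)
})

test_that("exact permutation p matches hand enumeration and bounds the asymptotic p", {
  a <- logrank_scores(c(1, 2, 3), c(1, 1, 1))
  expect_equal(exact_permutation_p(c(1, 2, 3), a), 1 / 3, tolerance = 1e-12)
  expect_equal(exact_permutation_p(c(1, 2, 3), rep(0.5, 3)), 1)
  expect_error(exact_permutation_p(rnorm(12), rnorm(12)), "limit")
  # Monte-Carlo permutation agrees with exact enumeration within 3 sigma
  set.seed(703)
  g <- rnorm(7)
  a7 <- logrank_scores(rexp(7), rbinom(7, 1, 0.8))
  p_exact <- exact_permutation_p(g, a7)
  mu <- sum(g) * mean(a7)
  t_obs <- abs(sum(g * a7) - mu)
  draws <- replicate(1e5, abs(sum(g * sample(a7)) - mu))
  p_mc <- mean(draws >= t_obs - 1e-9 * (1 + t_obs))
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 1e5))
})

test_that("asymptotic and exact p agree in order and within the documented gap", {
  set.seed(704)
  pairs <- list()
  for (r in 1:12) {
    n <- sample(5:8, 1)
    d <- random_censored_sample(n, event_rate = 0.5)
    a <- logrank_scores(d$time, d$event)
    if (all(a == 0)) next
    g <- rnorm(n)
    ls <- linear_statistic(g, a)
    if (ls$degenerate) next
    pe <- exact_permutation_p(g, a)
    expect_lt(abs(ls$p - pe), 0.15)
    pairs[[length(pairs) + 1]] <- c(ls$p, pe)
  }
  m <- do.call(rbind, pairs)
  # ordering agreement across fixtures (asymptotic ranks track exact ranks)
  expect_gt(cor(rank(m[, 1]), rank(m[, 2])), 0.9)
})
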