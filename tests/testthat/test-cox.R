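test_that("label-swap symmetry forces a zero coefficient under either ties method", {
  for (tie in c("efron", "breslow")) {
    fit <- cox_fit(c(1, 0, 1, 0), c(1, 1, 2, 2), c(1, 1, 1, 1), ties = tie)
    expect_equal(unname(fit$coef), 0, tolerance = 1e-9)
    expect_true(fit$converged)
  }
})

test_that("the 4-subject worked example matches the brute-force likelihood maximum", {
  x <- c(1, 0, 1, 0)
  tm <- c(1, 2, 3, 4)
  ev <- rep(1, 4)
  fit <- cox_fit(x, tm, ev)
  oracle <- optimize(function(b) cox_ll_bruteforce(b, x, tm, ev),
                     c(-5, 5), maximum = TRUE)$maximum
  expect_equal(unname(fit$coef), oracle, tolerance = 1e-5)
  expect_equal(unname(fit$coef), 0.941, tolerance = 1e-3)
  expect_lt(fit$gradient_norm, 1e-9)
  # the fit's likelihood equals the brute-force evaluation at beta-hat
  expect_equal(fit$loglik, cox_ll_bruteforce(fit$coef, x, tm, ev),
               tolerance = 1e-10)
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(cox_fit(c(1, 0, 1), c(1, 2, 3), c(0, 0, 0)), "no events")
  expect_error(cox_fit(cbind(k = rep(1, 5)), 1:5, rep(1, 5)), "constant")
  # monotone likelihood: every x = 1 subject dies before any x = 0 event
  x <- rep(c(1, 0), each = 10)
  tm <- c(1:10, 21:30)
  ev <- rep(1, 20)
  expect_error(cox_fit(x, tm, ev), "separation")
})

test_that("efron and breslow agree exactly when there are no ties", {
  set.seed(601)
  for (r in 1:5) {
    n <- 40
    x <- matrix(rnorm(2 * n), n, 2)
    tm <- rexp(n)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) < 4) next
    fe <- cox_fit(x, tm, ev, ties = "efron")
    fb <- cox_fit(x, tm, ev, ties = "breslow")
    expect_lt(max(abs(fe$coef - fb$coef)), 1e-8)
  }
})

test_that("coefficients, standard errors and p-values match coxph to 1e-6", {
  library(survival)
  set.seed(602)
  worst <- 0
  for (r in 1:16) {
    n <- sample(15:50, 1)
    p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), n, p)
    tm <- if (r %% 2 == 0) ceiling(rexp(n, 0.5) * 5) / 5 else rexp(n, 0.5)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) < p + 3) next
    for (tie in c("efron", "breslow")) {
      mine <- tryCatch(cox_fit(x, tm, ev, ties = tie),
                       error = function(e) NULL)
      if (is.null(mine)) next  # separation on tiny samples: skip instance
      ref <- coxph(Surv(tm, ev) ~ x, ties = tie)
      worst <- max(worst,
                   max(abs(mine$coef - unname(coef(ref)))),
                   max(abs(mine$se - unname(sqrt(diag(vcov(ref)))))))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("large samples recover the true log hazard ratio with ~95% CI coverage", {
  set.seed(603)
  beta_true <- 0.5
  big <- simulate_ph_cohort(4000, c(x = beta_true), seed = 604)
  fit <- cox_fit(big$x, big$time_years, big$event)
  expect_lt(abs(fit$coef - beta_true), 3 * fit$se)
  expect_lt(fit$se, 0.05)
  covered <- replicate(200, {
    d <- simulate_ph_cohort(150, c(x = beta_true))
    f <- tryCatch(cox_fit(d$x, d$time_years, d$event),
                  error = function(e) NULL)
    if (is.null(f)) return(NA)
    beta_true >= log(f$ci_lower) && beta_true <= log(f$ci_upper)
  })
  cov_rate <- mean(covered, na.rm = TRUE)
  expect_gt(cov_rate, 0.90)   # binomial band around 0.95 at 200 replicates
  expect_lt(cov_rate, 0.99)
})

test_that("per-leaf HR tables recover proportional-hazards ground truth", {
  set.seed(605)
  # equal hazards: HR ~ 1 with CI covering 1
  n <- 1000
  tm <- rexp(2 * n, 0.1)
  cc <- runif(2 * n, 0, 15)
  leaf <- rep(c("A", "B"), each = n)
  tab <- cox_hr_table(leaf, pmin(tm, cc), as.integer(tm <= cc), reference = "A")
  row_b <- tab[tab$leaf == "B", ]
  expect_lt(abs(log(row_b$hr)), 0.2)
  expect_true(row_b$ci_lower < 1 && row_b$ci_upper > 1)
  # rate ratio 10 recovered
  tm2 <- c(rexp(2500, 0.027), rexp(2500, 0.27))
  leaf2 <- rep(c("ref", "high"), each = 2500)
  cc2 <- runif(5000, 0, 20)
  tab2 <- cox_hr_table(leaf2, pmin(tm2, cc2), as.integer(tm2 <= cc2),
                       reference = "ref")
  row_h <- tab2[tab2$leaf == "high", ]
  expect_true(row_h$ci_lower < 10 && row_h$ci_upper > 10)
  expect_equal(row_h$hr, 10, tolerance = 0.15)
  # ordering and reference conventions
  expect_equal(tab2$hr[1], 1)
  expect_true(all(diff(tab2$hr) >= 0))
  expect_error(cox_hr_table(rep("only", 10), rexp(10), rbinom(10, 1, 0.5),
                            reference = "only"), "two subgroups")
  expect_error(cox_hr_table(leaf, pmin(tm, cc), as.integer(tm <= cc),
                            reference = "missing"), "reference")
})
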