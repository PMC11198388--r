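test_that("cutpoint search maximizes |z| over admissible thresholds", {
  a <- logrank_scores(c(1, 2, 3), c(1, 1, 1))
  bc <- best_cutpoint(c(1, 2, 3), a, minbucket = 1)
  expect_equal(bc$threshold, 2)
  expect_equal(bc$z_abs, 1.3363, tolerance = 1e-4)
  # the rejected candidate c = 1 has |z| = 1.069
  z1 <- abs(linear_statistic(as.numeric(c(1, 2, 3) <= 1), a)$z)
  expect_equal(z1, 1.069, tolerance = 1e-3)
  expect_lt(z1, bc$z_abs)
  # minbucket too large for n = 3: no admissible cutpoint
  expect_null(best_cutpoint(c(1, 2, 3), a, minbucket = 2))
  # binary covariate admits exactly its single cut
  set.seed(801)
  x <- rbinom(40, 1, 0.5)
  a40 <- logrank_scores(rexp(40), rbinom(40, 1, 0.8))
  bc2 <- best_cutpoint(x, a40, minbucket = 5)
  expect_equal(bc2$threshold, 0)
})

test_that("cutpoint ties break toward the smallest threshold", {
  # symmetric configuration: cut after position 1 and after position 3
  # give identical |z|; the smaller threshold must win
  a <- c(1, -0.5, -0.5, 1) - 0.25
  x <- c(1, 2, 3, 4)
  bc <- best_cutpoint(x, a, minbucket = 1)
  z_first <- abs(linear_statistic(as.numeric(x <= 1), a)$z)
  z_last <- abs(linear_statistic(as.numeric(x <= 3), a)$z)
  expect_equal(z_first, z_last, tolerance = 1e-12)
  expect_equal(bc$threshold, 1)
})

test_that("variable selection applies Bonferroni across tested covariates", {
  set.seed(802)
  n <- 600
  d <- data.frame(time_years = rexp(n, 0.2), event = rbinom(n, 1, 0.7))
  d$signal <- rnorm(n)
  d$time_years <- rexp(n, 0.2 * exp(0.8 * d$signal))
  d$noise1 <- rnorm(n)
  d$noise2 <- rnorm(n)
  d$constant <- 1
  a <- logrank_scores(d$time_years, d$event)
  sel <- select_split_variable(d, c("signal", "noise1", "noise2", "constant"),
                               a, split_config(minbucket = 50, minsplit = 100))
  expect_equal(sel$var, "signal")
  # constant covariate is degenerate: only 3 candidates count for Bonferroni
  expect_equal(sel$p_adj, min(1, 3 * min(sel$p_values, na.rm = TRUE)))
  expect_true(is.na(sel$p_values["constant"]))
  # all-degenerate candidate set is a stop signal
  expect_null(select_split_variable(d, "constant", a,
                                    split_config(minbucket = 50,
                                                 minsplit = 100)))
})

test_that("a single informative covariate is selected in almost all replicates", {
  set.seed(803)
  hits <- replicate(20, {
    n <- 1000
    alb <- rnorm(n, 37.9, 6)
    rate <- ifelse(alb <= 40.6, 0.25, 0.05)
    tm <- rexp(n) / rate
    cc <- runif(n, 0, 12)
    d <- data.frame(time_years = pmin(tm, cc),
                    event = as.integer(tm <= cc),
                    albumin = alb, n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n), n4 = rbinom(n, 1, 0.4))
    a <- logrank_scores(d$time_years, d$event)
    sel <- select_split_variable(d, c("albumin", paste0("n", 1:4)), a,
                                 split_config())
    !is.null(sel) && sel$var == "albumin"
  })
  expect_gte(sum(hits), 19)
})

test_that("trees respect size constraints and partition the sample", {
  coh <- generate_cohort(default_generator_spec(n = 1317, seed = 21))
  covs <- unname(unlist(cohort_domain_map(coh)))
  tree <- grow_tree(coh, covs, split_config())
  lv <- tree_leaves(tree)
  expect_true(all(lv$n >= 95))
  expect_equal(sum(lv$n), nrow(coh))
  expect_equal(lv$id, seq_len(nrow(lv)))   # left-to-right numbering
  # every internal node is significant at alpha after adjustment
  check_nodes <- function(node) {
    if (node$type == "leaf") return(invisible())
    expect_lt(node$p_adj, 0.05)
    expect_equal(node$n, node$left$n + node$right$n)
    check_nodes(node$left)
    check_nodes(node$right)
  }
  check_nodes(tree$root)
  # routing the training data reproduces the leaf sizes
  pl <- predict_leaf(tree, coh)
  expect_equal(as.vector(table(pl)), lv$n)
})

test_that("a two-leaf truth is recovered with its threshold", {
  set.seed(804)
  n <- 900
  alb <- rnorm(n, 37.9, 6)
  rate <- ifelse(alb <= 40.6, 0.30, 0.04)
  tm <- rexp(n) / rate
  cc <- runif(n, 0, 12)
  d <- data.frame(time_years = pmin(tm, cc), event = as.integer(tm <= cc),
                  albumin = alb, noise = rnorm(n))
  tree <- grow_tree(d, c("albumin", "noise"),
                    split_config(minbucket = 95))
  expect_equal(tree$root$var, "albumin")
  expect_lt(abs(tree$root$threshold - 40.6), 1)
})

test_that("the root stays a leaf under the global null and tiny nodes never split", {
  set.seed(805)
  null_roots <- replicate(20, {
    n <- 1000
    d <- data.frame(time_years = rexp(n, 0.2), event = rbinom(n, 1, 0.6),
                    x1 = rnorm(n), x2 = rnorm(n), x3 = rbinom(n, 1, 0.5))
    tree <- grow_tree(d, c("x1", "x2", "x3"), split_config())
    nrow(tree_leaves(tree)) == 1
  })
  expect_gte(sum(null_roots), 18)
  # n below minsplit: single leaf regardless of signal
  d2 <- data.frame(time_years = rexp(50, 0.2), event = rbinom(50, 1, 0.6),
                   x = rnorm(50))
  expect_equal(nrow(tree_leaves(grow_tree(d2, "x", split_config()))), 1)
})

test_that("categorical splits partition levels and route correctly", {
  set.seed(806)
  n <- 800
  grp <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  rate <- ifelse(grp == "c", 0.5, 0.05)
  tm <- rexp(n) / rate
  cc <- runif(n, 0, 10)
  d <- data.frame(time_years = pmin(tm, cc), event = as.integer(tm <= cc),
                  grp = grp)
  tree <- grow_tree(d, "grp", split_config(minbucket = 50, minsplit = 100))
  expect_equal(tree$root$var, "grp")
  sides <- list(tree$root$levels_left, tree$root$levels_right)
  expect_true(any(vapply(sides, function(s) identical(sort(s), "c"),
                         logical(1))))
  pl <- predict_leaf(tree, d)
  expect_equal(length(unique(pl[grp == "c"])), 1)
  # > 5 levels rejected
  d$many <- factor(sample(letters[1:6], n, replace = TRUE))
  expect_error(grow_tree(d, "many", split_config(minbucket = 50,
                                                 minsplit = 100)),
               "5 levels")
})

test_that("prediction is deterministic, boundary-left, and strict about missing data", {
  coh <- generate_cohort(default_generator_spec(n = 1500, seed = 22))
  covs <- unname(unlist(cohort_domain_map(coh)))
  tree <- grow_tree(coh, covs, split_config())
  thr <- tree$root$threshold
  v <- tree$root$var
  probe <- coh[1, , drop = FALSE]
  probe[[v]] <- thr                      # exactly at the threshold
  collect_ids <- function(node) {
    if (node$type == "leaf") node$id else c(collect_ids(node$left),
                                            collect_ids(node$right))
  }
  expect_true(predict_leaf(tree, probe) %in% collect_ids(tree$root$left))
  probe2 <- probe
  probe2[[v]] <- NA
  expect_error(predict_leaf(tree, probe2), "missing values")
  expect_error(predict_leaf(tree, probe[, setdiff(names(probe), v)]),
               "missing split variable")
})

test_that("trees serialize to JSON and indented text", {
  coh <- generate_cohort(default_generator_spec(n = 1000, seed = 23))
  tree <- grow_tree(coh, c("albumin", "age", "ntprobnp"), split_config())
  js <- jsonlite::fromJSON(tree_to_json(tree), simplifyVector = FALSE)
  expect_equal(js$n, 1000)
  expect_equal(js$root$type, "split")
  txt <- format(tree)
  expect_match(txt, "leaf 1")
  expect_match(txt, "p.adj", fixed = TRUE)
  paths <- leaf_paths(tree)
  expect_equal(length(paths), nrow(tree_leaves(tree)))
  expect_match(paths[["1"]], "<=")
  # JSON round trip preserves routing and leaf summaries
  f <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tree, f)
  back <- tree_from_json(f)
  expect_equal(predict_leaf(back, coh), predict_leaf(tree, coh))
  expect_equal(tree_leaves(back)[, c("id", "n", "events")],
               tree_leaves(tree)[, c("id", "n", "events")])
})

test_that("split_config validates its invariants", {
  expect_error(split_config(alpha = 0), "alpha")
  expect_error(split_config(minbucket = 0), "minbucket")
  expect_error(split_config(minbucket = 95, minsplit = 100), "minsplit")
})
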