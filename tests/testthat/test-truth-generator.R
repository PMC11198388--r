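test_that("default truth tree routes the published subgroup profiles", {
  tt <- default_truth_tree()
  expect_equal(truth_leaf_ids(tt), 1:8)
  expect_setequal(truth_tree_variables(tt),
                  c("albumin", "age", "bun", "ntprobnp", "hemoglobin"))
  row7 <- data.frame(albumin = 42, hemoglobin = 13.5, age = 60,
                     bun = 20, ntprobnp = 3000)
  expect_equal(assign_true_leaf(row7, tt), 7L)
  row5 <- data.frame(albumin = 35, hemoglobin = 12, age = 70,
                     bun = 20, ntprobnp = 12000)
  expect_equal(assign_true_leaf(row5, tt), 5L)
  # boundary convention: value == threshold goes left
  boundary <- data.frame(albumin = 40.6, hemoglobin = 13, age = 60,
                         bun = 20, ntprobnp = 3000)
  expect_equal(assign_true_leaf(boundary, tt), 1L)
  expect_error(assign_true_leaf(data.frame(albumin = 42), tt), "missing")
  row_na <- row7
  row_na$age <- NA
  expect_error(assign_true_leaf(row_na, tt), "missing values")
})

test_that("truth-tree construction rejects malformed trees", {
  expect_error(truth_tree(tree_split("x", 1, tree_leaf(1), tree_leaf(1))),
               "unique")
  expect_error(truth_tree(tree_split("x", 1, tree_leaf(1), tree_leaf(3))),
               "contiguous")
  expect_error(tree_split("x", Inf, tree_leaf(1), tree_leaf(2)))
})

test_that("generated cohorts are reproducible and internally consistent", {
  spec <- default_generator_spec(n = 1500, seed = 42)
  coh <- generate_cohort(spec)
  expect_identical(coh, generate_cohort(spec))
  expect_false(identical(coh, generate_cohort(spec, seed = 43)))
  expect_true(all(coh$time_years > 0))
  expect_true(all(coh$event %in% 0:1))
  expect_equal(assign_true_leaf(coh, spec$truth), coh$true_leaf)
  expect_true(all(coh$inclusion_year %in% 2010:2019))
  expect_setequal(levels(coh$hf_subtype), c("HFpEF", "HFmrEF", "HFrEF"))
  # domain map covers every covariate exactly once
  dm <- cohort_domain_map(coh)
  expect_setequal(unlist(dm), setdiff(names(coh),
    c("patient_id", "time_years", "event", "inclusion_year",
      "hf_subtype", "true_leaf")))
})

test_that("single-leaf cohort reproduces its calibrated survival", {
  # everyone routed to one leaf with the reference rate, no censoring
  spec <- generator_spec(
    marginals = list(normal_marginal("x", 0, -1, 1, "lab")),
    truth = truth_tree(tree_leaf(1)),
    hazards = list(leaf_hazard(1, calibrate_exponential(0.85, 6))),
    censoring = censoring_spec(entry_window = 0, study_end = 1e6,
                               dropout_rate = 0),
    n = 10000, seed = 8
  )
  coh <- generate_cohort(spec)
  expect_true(all(coh$event == 1))
  s6 <- mean(coh$time_years > 6)
  expect_lt(abs(s6 - 0.85), 0.011)   # 3 binomial sigma at n = 10,000
})

test_that("immediate study end censors everyone; event fraction matches closed form", {
  spec <- default_generator_spec(n = 400, seed = 5)
  spec$censoring <- censoring_spec(entry_window = 0, study_end = 1e-9,
                                   dropout_rate = 0)
  coh <- generate_cohort(spec)
  expect_true(all(coh$event == 0))
  expect_true(all(coh$time_years > 0))

  # pure administrative censoring at fixed C: P(event) = 1 - exp(-lambda C)
  lam <- 0.2
  spec2 <- generator_spec(
    marginals = list(normal_marginal("x", 0, -1, 1, "lab")),
    truth = truth_tree(tree_leaf(1)),
    hazards = list(leaf_hazard(1, lam)),
    censoring = censoring_spec(entry_window = 0, study_end = 5,
                               dropout_rate = 0),
    n = 20000, seed = 9
  )
  coh2 <- generate_cohort(spec2)
  p_true <- 1 - exp(-lam * 5)
  expect_lt(abs(mean(coh2$event) - p_true),
            3 * sqrt(p_true * (1 - p_true) / 20000))
})

test_that("cohort CSV round-trips with its domain sidecar", {
  coh <- generate_cohort(default_generator_spec(n = 50, seed = 3))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "cohort.csv")
  write_cohort(coh, f)
  expect_true(file.exists(file.path(dir, "cohort.meta.json")))
  back <- read_cohort(f)
  expect_equal(nrow(back), 50)
  expect_equal(attr(back, "domains"), attr(coh, "domains"))
  expect_equal(back$time_years, coh$time_years, tolerance = 1e-12)
})
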