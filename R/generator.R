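#' Cohort generator specification
#'
#' Bundles everything needed to simulate a cohort with known structure:
#' covariate marginals, a truth tree, one piecewise-exponential hazard per
#' leaf, a censoring model, subtype mix and sample size. Every truth-tree
#' leaf must have exactly one hazard.
#'
#' @param marginals List of [marginal_spec()] objects.
#' @param truth A [truth_tree()]; its split variables must all appear among
#'   the marginals.
#' @param hazards List of [leaf_hazard()] objects covering every leaf id.
#' @param censoring A [censoring_spec()].
#' @param n Default cohort size.
#' @param seed Default integer seed.
#' @param subtype_probs Named probabilities of the heart-failure subtype
#'   labels (must sum to 1).
#' @param year_start First inclusion calendar year.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(marginals, truth, hazards, censoring,
                           n = 1317, seed = 1,
                           subtype_probs = c(HFpEF = 331, HFmrEF = 330,
                                             HFrEF = 656) / 1317,
                           year_start = 2010) {
  stopifnot(inherits(truth, "truth_tree"), inherits(censoring, "censoring_spec"))
  cov_names <- vapply(marginals, `[[`, character(1), "name")
  missing_vars <- setdiff(truth_tree_variables(truth), cov_names)
  if (length(missing_vars)) {
    stop("truth tree uses variables without a marginal: ",
         paste(missing_vars, collapse = ", "))
  }
  hz_ids <- vapply(hazards, `[[`, integer(1), "leaf_id")
  if (!setequal(hz_ids, truth_leaf_ids(truth)) || anyDuplicated(hz_ids)) {
    stop("`hazards` must contain exactly one hazard per truth-tree leaf")
  }
  if (abs(sum(subtype_probs) - 1) > 1e-12 || is.null(names(subtype_probs))) {
    stop("`subtype_probs` must be named and sum to 1")
  }
  structure(
    list(marginals = marginals, truth = truth,
         hazards = hazards[order(hz_ids)], censoring = censoring,
         n = as.integer(n), seed = as.integer(seed),
         subtype_probs = subtype_probs, year_start = year_start),
    class = "generator_spec"
  )
}

#' Default leaf hazards: proportional-hazards ladder
#'
#' The reference leaf (subgroup 7) gets the exponential rate calibrated to
#' 85% survival at 6 years; every other leaf multiplies that rate by its
#' published hazard ratio. Optionally the worst leaf (subgroup 5) is replaced
#' by the two-piece hazard calibrated to 48% one-year and 11% six-year
#' survival, which reproduces its printed early/late survival shape exactly
#' at the cost of exact proportionality.
#'
#' @param ladder Named HR ladder as from [default_hr_ladder()].
#' @param reference_rate Reference per-year rate; default
#'   `calibrate_exponential(0.85, 6)`.
#' @param worst_leaf_two_piece If `TRUE`, use the two-piece calibration for
#'   leaf 5.
#' @return List of [leaf_hazard()] objects.
#' @export
default_leaf_hazards <- function(ladder = default_hr_ladder(),
                                 reference_rate = calibrate_exponential(0.85, 6),
                                 worst_leaf_two_piece = FALSE) {
  hz <- lapply(seq_along(ladder), function(i) {
    id <- as.integer(names(ladder)[i])
    leaf_hazard(id, reference_rate * ladder[[i]])
  })
  if (worst_leaf_two_piece) {
    worst <- as.integer(names(ladder)[which.max(ladder)])
    hz[[which(vapply(hz, `[[`, integer(1), "leaf_id") == worst)]] <-
      worst_leaf_hazard(worst)
  }
  hz
}

#' Two-piece hazard of the worst-survival subgroup
#'
#' Calibrated to the printed 48% one-year and 11% six-year survival.
#'
#' @param leaf_id Leaf id to attach the hazard to (default 5).
#' @export
worst_leaf_hazard <- function(leaf_id = 5) {
  leaf_hazard(leaf_id, calibrate_piecewise(0.48, 1, 0.11, 6), cuts = 1)
}

#' Default generator specification
#'
#' Cohort of 1,317 patients with the published covariate marginals, the
#' 8-leaf truth tree, the proportional-hazards leaf ladder anchored at 85%
#' six-year reference survival, uniform staggered entry over 10 years with
#' administrative censoring at study end and 0.02/year dropout.
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param worst_leaf_two_piece Passed to [default_leaf_hazards()].
#' @return A [generator_spec()].
#' @export
default_generator_spec <- function(n = 1317, seed = 1,
                                   worst_leaf_two_piece = FALSE) {
  generator_spec(
    marginals = default_marginals(),
    truth = default_truth_tree(),
    hazards = default_leaf_hazards(worst_leaf_two_piece = worst_leaf_two_piece),
    censoring = censoring_spec(entry_window = 10, study_end = 10,
                               dropout_rate = 0.02),
    n = n, seed = seed
  )
}

#' Generate a synthetic survival cohort
#'
#' Draws covariates from the marginals, routes each patient to their true
#' leaf, samples an event time from that leaf's hazard, and right-censors by
#' the minimum of administrative follow-up (study end minus uniform entry)
#' and exponential dropout. Observed time is the minimum of event and
#' censoring time; the event indicator is 1 when the event came first.
#'
#' @param spec A [generator_spec()].
#' @param n Cohort size (defaults to `spec$n`).
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return `data.frame` with columns `patient_id`, `time_years`, `event`,
#'   `inclusion_year`, `hf_subtype`, `true_leaf`, then one column per
#'   covariate; domain tags in the `"domains"` attribute.
#' @export
generate_cohort <- function(spec, n = spec$n, seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"), n >= 0)
  set.seed(seed)
  covs <- sample_covariates(spec$marginals, n)
  true_leaf <- if (n > 0) assign_true_leaf(covs, spec$truth) else integer(0)

  event_time <- numeric(n)
  for (hz in spec$hazards) {
    idx <- which(true_leaf == hz$leaf_id)
    event_time[idx] <- sample_event_times(hz, length(idx))
  }

  cs <- spec$censoring
  entry <- stats::runif(n, 0, min(cs$entry_window, cs$study_end))
  admin <- cs$study_end - entry
  dropout <- if (cs$dropout_rate > 0) stats::rexp(n, cs$dropout_rate) else rep(Inf, n)
  cens_time <- pmin(admin, dropout)
  obs_time <- pmin(event_time, cens_time)
  event <- as.integer(event_time <= cens_time)

  subtype <- factor(
    sample(names(spec$subtype_probs), n, replace = TRUE,
           prob = spec$subtype_probs),
    levels = names(spec$subtype_probs)
  )

  out <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    time_years = obs_time,
    event = event,
    inclusion_year = spec$year_start + floor(entry),
    hf_subtype = subtype,
    true_leaf = true_leaf
  )
  out <- cbind(out, covs)
  attr(out, "domains") <- attr(covs, "domains")
  out
}

#' Domain map of a cohort or generator spec
#'
#' Named list splitting covariate names into the clinical, echocardiographic
#' and laboratory domains used by the three selection models.
#'
#' @param x A `generator_spec` or a cohort `data.frame` carrying a
#'   `"domains"` attribute.
#' @return Named list of character vectors.
#' @export
cohort_domain_map <- function(x) {
  tags <- if (inherits(x, "generator_spec")) {
    stats::setNames(vapply(x$marginals, `[[`, character(1), "domain"),
                    vapply(x$marginals, `[[`, character(1), "name"))
  } else {
    attr(x, "domains")
  }
  if (is.null(tags)) stop("no domain tags found")
  split(names(tags), factor(tags, levels = c("clinical", "echo", "lab")))
}

#' Write a cohort to CSV with a metadata sidecar
#'
#' @param cohort Cohort `data.frame` from [generate_cohort()].
#' @param file Output CSV path.
#' @param metadata_file Optional JSON sidecar path recording the domain tag
#'   of every covariate (defaults to `file` with a `.meta.json` suffix).
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, file, metadata_file = NULL) {
  utils::write.csv(cohort, file, row.names = FALSE)
  if (is.null(metadata_file)) {
    metadata_file <- paste0(sub("\\.csv$", "", file), ".meta.json")
  }
  domains <- attr(cohort, "domains")
  meta <- list(
    n = nrow(cohort),
    columns = names(cohort),
    domains = as.list(domains)
  )
  jsonlite::write_json(meta, metadata_file, auto_unbox = TRUE, pretty = TRUE)
  invisible(cohort)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param file CSV path.
#' @param metadata_file Optional sidecar path; when found, domain tags are
#'   re-attached.
#' @export
read_cohort <- function(file, metadata_file = NULL) {
  out <- utils::read.csv(file, stringsAsFactors = TRUE)
  if (is.null(metadata_file)) {
    metadata_file <- paste0(sub("\\.csv$", "", file), ".meta.json")
  }
  if (file.exists(metadata_file)) {
    meta <- jsonlite::read_json(metadata_file, simplifyVector = TRUE)
    attr(out, "domains") <- unlist(meta$domains)
  }
  out
}

#' Simulate a plain proportional-hazards cohort
#'
#' Independent standard-normal covariates, exponential baseline hazard and
#' uniform administrative censoring; used to study the operating
#' characteristics of screening and stability selection under a known log
#' hazard ratio vector.
#'
#' @param n Number of subjects.
#' @param beta Named numeric vector of log hazard ratios per covariate
#'   (covariates are iid standard normal).
#' @param baseline_rate Baseline per-year rate.
#' @param censor_max Administrative censoring drawn uniform on
#'   `(0, censor_max)`.
#' @param seed Optional integer seed.
#' @return `data.frame` with `time_years`, `event` and the covariates.
#' @export
simulate_ph_cohort <- function(n, beta, baseline_rate = 0.2, censor_max = 10,
                               seed = NULL) {
  stopifnot(n >= 1, length(beta) >= 1)
  if (is.null(names(beta))) names(beta) <- paste0("x", seq_along(beta))
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(stats::rnorm(n * length(beta)), n, length(beta),
              dimnames = list(NULL, names(beta)))
  rate <- baseline_rate * exp(drop(x %*% beta))
  t_event <- stats::rexp(n) / rate
  cens <- stats::runif(n, 0, censor_max)
  out <- data.frame(time_years = pmin(t_event, cens),
                    event = as.integer(t_event <= cens))
  cbind(out, as.data.frame(x))
}
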