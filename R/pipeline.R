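#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end stratification analysis. The
#' defaults mirror the published protocol: 70/30 derivation/validation split
#' stratified by heart-failure subtype, 500 bootstrap repeats with an 85%
#' retention threshold, tree growth at alpha 0.05 with at least 95 patients
#' per terminal leaf, and 1- and 6-year Kaplan-Meier landmarks.
#'
#' @param alpha Split significance level.
#' @param minbucket Minimum terminal-leaf size.
#' @param minsplit Minimum node size to attempt a split.
#' @param bootstrap_B Bootstrap repeats per domain model.
#' @param selection_threshold Retention threshold on inclusion frequency.
#' @param p_enter,p_remove Stepwise entry/removal p-values.
#' @param split_fraction Derivation fraction of the stratified split.
#' @param ties Cox tie handling.
#' @param landmark_years Kaplan-Meier landmark times.
#' @param seed Integer master seed.
#' @param domain_map Optional named list of covariates per domain; when
#'   `NULL` it is read from the cohort's `"domains"` attribute.
#' @param subtype_column,year_column,time_column,event_column Column names.
#' @param adjustment Multiplicity adjustment at tree nodes.
#' @param max_depth Optional tree depth cap.
#' @param subtype_minbucket Optional per-subtype minbucket override; by
#'   default scaled as `ceiling(minbucket * n_subtype / n_total)`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05, minbucket = 95,
                            minsplit = 2 * minbucket, bootstrap_B = 500,
                            selection_threshold = 0.85, p_enter = 0.05,
                            p_remove = 0.10, split_fraction = 0.7,
                            ties = "efron", landmark_years = c(1, 6),
                            seed = 1, domain_map = NULL,
                            subtype_column = "hf_subtype",
                            year_column = "inclusion_year",
                            time_column = "time_years",
                            event_column = "event",
                            adjustment = "bonferroni", max_depth = Inf,
                            subtype_minbucket = NULL) {
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("`split_fraction` must be in (0, 1)")
  }
  cfg <- list(alpha = alpha, minbucket = minbucket, minsplit = minsplit,
              bootstrap_B = bootstrap_B,
              selection_threshold = selection_threshold,
              p_enter = p_enter, p_remove = p_remove,
              split_fraction = split_fraction, ties = ties,
              landmark_years = landmark_years, seed = seed,
              domain_map = domain_map, subtype_column = subtype_column,
              year_column = year_column, time_column = time_column,
              event_column = event_column, adjustment = adjustment,
              max_depth = max_depth, subtype_minbucket = subtype_minbucket)
  # validate the tree part eagerly
  split_config(alpha = alpha, minbucket = minbucket, minsplit = minsplit,
               adjustment = adjustment, max_depth = max_depth,
               landmark_years = landmark_years)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON or YAML file
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the `yaml` package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: ", path)
  }
  do.call(pipeline_config, vals)
}

tree_config_of <- function(config) {
  split_config(alpha = config$alpha, minbucket = config$minbucket,
               minsplit = config$minsplit, adjustment = config$adjustment,
               max_depth = config$max_depth,
               landmark_years = config$landmark_years)
}

#' Stratified derivation/validation split
#'
#' Within each stratum, `ceiling(fraction * n_stratum)` patients are drawn
#' without replacement into the derivation cohort and the remainder form the
#' validation cohort. With strata of 331, 330 and 656 patients at fraction
#' 0.7 this yields exactly 923 derivation and 394 validation patients.
#'
#' @param data Cohort data frame.
#' @param fraction Derivation fraction in (0, 1).
#' @param stratum_col Name of the stratification column.
#' @param seed Integer seed.
#' @return Object of class `split_result`: `$derivation`/`$validation` row
#'   indices, `$counts` per-stratum table, `$fraction`, `$seed`.
#' @export
stratified_split <- function(data, fraction = 0.7,
                             stratum_col = "hf_subtype", seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  if (!stratum_col %in% names(data)) {
    stop("stratum column not found: ", stratum_col)
  }
  strata <- factor(data[[stratum_col]])
  if (any(table(strata) == 0) || anyNA(strata)) {
    stop("empty or missing stratum levels")
  }
  set.seed(seed)
  deriv <- integer(0)
  for (lv in levels(strata)) {
    idx <- which(strata == lv)
    k <- ceiling(fraction * length(idx))
    deriv <- c(deriv, sort(sample(idx, k)))
  }
  deriv <- sort(deriv)
  valid <- setdiff(seq_len(nrow(data)), deriv)
  counts <- data.frame(
    stratum = levels(strata),
    n = as.vector(table(strata)),
    derivation = as.vector(table(strata[deriv])),
    validation = as.vector(table(strata[valid]))
  )
  structure(
    list(derivation = deriv, validation = valid, counts = counts,
         fraction = fraction, seed = seed),
    class = "split_result"
  )
}

#' Temporal split by alternating inclusion years
#'
#' Sorts the distinct inclusion years and assigns patients from the 1st,
#' 3rd, 5th, ... year to cohort A and the 2nd, 4th, ... to cohort B.
#'
#' @param data Cohort data frame.
#' @param year_col Name of the inclusion-year column.
#' @return `list(a =, b =)` of row indices, with the year assignment in
#'   attributes `years_a` / `years_b`.
#' @export
temporal_split <- function(data, year_col = "inclusion_year") {
  if (!year_col %in% names(data)) stop("year column not found: ", year_col)
  years <- data[[year_col]]
  yy <- sort(unique(years))
  if (length(yy) < 2) stop("temporal split needs at least 2 distinct years")
  years_a <- yy[seq(1, length(yy), by = 2)]
  years_b <- yy[seq(2, length(yy), by = 2)]
  out <- list(a = which(years %in% years_a), b = which(years %in% years_b))
  attr(out, "years_a") <- years_a
  attr(out, "years_b") <- years_b
  out
}

#' Per-subgroup Kaplan-Meier / Cox summary
#'
#' Routes every patient through a fitted tree, summarizes each terminal leaf
#' (n, events, Kaplan-Meier survival at the landmark years, criteria string
#' of its root-to-leaf path) and reports Cox hazard ratios versus the
#' reference leaf, defined as the leaf with the highest Kaplan-Meier
#' survival at the last landmark (falling back to the largest follow-up time
#' common to all leaves when the landmark exceeds it). Leaves without events
#' get a flagged, non-estimable hazard ratio. Rows are ordered by ascending
#' hazard ratio.
#'
#' @param tree A [grow_tree()] fit.
#' @param data Cohort data frame (derivation, validation, or temporal).
#' @param time_col,event_col Outcome columns.
#' @param landmark_years Landmark times; defaults to the tree's config.
#' @param ties Cox tie handling.
#' @return `data.frame` of class `subgroup_summary`.
#' @export
subgroup_report <- function(tree, data, time_col = tree$time_col,
                            event_col = tree$event_col,
                            landmark_years = tree$config$landmark_years,
                            ties = "efron") {
  leaf <- predict_leaf(tree, data)
  time <- data[[time_col]]
  event <- data[[event_col]]
  check_survival_data(time, event)
  paths <- leaf_paths(tree)
  ids <- sort(unique(leaf))
  km_landmark <- matrix(NA_real_, length(ids), length(landmark_years),
                        dimnames = list(ids, paste0("s", landmark_years, "y")))
  max_follow <- numeric(length(ids))
  for (i in seq_along(ids)) {
    sel <- leaf == ids[i]
    curve <- kaplan_meier(time[sel], event[sel])
    km_landmark[i, ] <- survival_at(curve, landmark_years)
    max_follow[i] <- max(time[sel])
  }
  ref_time <- landmark_years[length(landmark_years)]
  if (ref_time > min(max_follow)) ref_time <- min(max_follow)
  ref_surv <- vapply(seq_along(ids), function(i) {
    sel <- leaf == ids[i]
    survival_at(kaplan_meier(time[sel], event[sel]), ref_time)
  }, numeric(1))
  reference <- ids[which.max(ref_surv)]

  n_leaf <- as.vector(table(factor(leaf, levels = ids)))
  ev_leaf <- as.vector(tapply(event, factor(leaf, levels = ids), sum))
  estimable <- ids[ev_leaf > 0]
  hr_tab <- NULL
  if (length(estimable) >= 2 && reference %in% estimable) {
    sel <- leaf %in% estimable
    hr_tab <- cox_hr_table(leaf[sel], time[sel], event[sel],
                           reference = reference, ties = ties)
  }
  out <- data.frame(
    leaf = ids,
    criteria = unname(paths[as.character(ids)]),
    n = n_leaf, events = ev_leaf,
    km_landmark,
    hr = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_, p = NA_real_,
    reference = ids == reference,
    note = ifelse(ev_leaf == 0, "no events: HR non-estimable", ""),
    row.names = NULL, check.names = FALSE
  )
  if (!is.null(hr_tab)) {
    m <- match(out$leaf, as.integer(hr_tab$leaf))
    out$hr <- hr_tab$hr[m]
    out$ci_lower <- hr_tab$ci_lower[m]
    out$ci_upper <- hr_tab$ci_upper[m]
    out$p <- hr_tab$p[m]
  }
  out <- out[order(is.na(out$hr), out$hr), , drop = FALSE]
  row.names(out) <- NULL
  class(out) <- c("subgroup_summary", class(out))
  out
}

validate_cohort <- function(data, config, covariates) {
  problems <- character(0)
  need <- c(config$time_column, config$event_column, config$subtype_column,
            config$year_column, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    problems <- c(problems, paste("missing column(s):",
                                  paste(miss, collapse = ", ")))
  }
  if (config$time_column %in% names(data)) {
    tm <- data[[config$time_column]]
    if (any(!is.finite(tm)) || any(tm <= 0)) {
      problems <- c(problems, "follow-up times must be finite and positive")
    }
  }
  if (config$event_column %in% names(data)) {
    if (!all(data[[config$event_column]] %in% c(0, 1))) {
      problems <- c(problems, "event indicator must be 0/1")
    }
  }
  for (v in intersect(covariates, names(data))) {
    nbad <- sum(is.na(data[[v]]))
    if (nbad > 0) {
      problems <- c(problems,
                    sprintf("covariate `%s` has %d missing value(s)", v, nbad))
    }
  }
  if (length(problems)) {
    stop("cohort schema violations:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  invisible(TRUE)
}

#' Run the full stratification analysis
#'
#' End-to-end orchestration on one cohort: stratified derivation/validation
#' split, univariate Cox screen and bootstrap stability selection on the
#' derivation cohort, survival-tree growth on the derivation cohort using
#' the union of retained variables, subgroup reporting on derivation and
#' (with the frozen tree) validation, and a temporal-consistency check
#' applying the frozen tree to two alternating-year cohorts. Fully
#' reproducible from the config seed.
#'
#' @param data Cohort data frame (schema validated before any computation).
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_report`.
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  domain_map <- config$domain_map
  if (is.null(domain_map)) domain_map <- cohort_domain_map(data)
  covariates <- unlist(domain_map, use.names = FALSE)
  validate_cohort(data, config, covariates)

  split <- stratified_split(data, fraction = config$split_fraction,
                            stratum_col = config$subtype_column,
                            seed = config$seed)
  deriv <- data[split$derivation, , drop = FALSE]
  valid <- data[split$validation, , drop = FALSE]

  screen <- univariate_screen(deriv, covariates,
                              time_col = config$time_column,
                              event_col = config$event_column,
                              ties = config$ties)
  selection <- bootstrap_selection(
    deriv, domain_map, B = config$bootstrap_B,
    threshold = config$selection_threshold,
    p_enter = config$p_enter, p_remove = config$p_remove,
    seed = config$seed + 1L,
    time_col = config$time_column, event_col = config$event_column,
    ties = config$ties
  )
  tree_vars <- selection$retained
  single_leaf <- length(tree_vars) == 0
  if (single_leaf) {
    # nothing retained: the tree degenerates to a single leaf; grow on a
    # constant pseudo-covariate that can never split
    deriv$.null_covariate <- 0
    tree_vars <- ".null_covariate"
  }
  tree <- grow_tree(deriv, tree_vars, config = tree_config_of(config),
                    time_col = config$time_column,
                    event_col = config$event_column)
  if (single_leaf) deriv$.null_covariate <- NULL

  sub_deriv <- subgroup_report(tree, deriv, ties = config$ties)
  sub_valid <- subgroup_report(tree, valid, ties = config$ties)
  tsplit <- temporal_split(data, year_col = config$year_column)
  temporal <- list(
    a = subgroup_report(tree, data[tsplit$a, , drop = FALSE],
                        ties = config$ties),
    b = subgroup_report(tree, data[tsplit$b, , drop = FALSE],
                        ties = config$ties)
  )
  structure(
    list(split = split, screen = screen, selection = selection, tree = tree,
         subgroups_derivation = sub_deriv, subgroups_validation = sub_valid,
         temporal = temporal, temporal_years = attributes(tsplit),
         config = config, n = nrow(data),
         version = as.character(utils::packageVersion("treestrat"))),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Stratification pipeline report (treestrat ", x$version, ")\n",
      sep = "")
  cat("Cohort: n =", x$n, "; derivation", length(x$split$derivation),
      "/ validation", length(x$split$validation), "\n")
  cat("Retained covariates:",
      if (length(x$selection$retained))
        paste(x$selection$retained, collapse = ", ") else "(none)", "\n\n")
  print(x$tree)
  cat("\nDerivation subgroups:\n")
  print(format_subgroups(x$subgroups_derivation), row.names = FALSE)
  cat("\nValidation subgroups:\n")
  print(format_subgroups(x$subgroups_validation), row.names = FALSE)
  invisible(x)
}

format_subgroups <- function(tab) {
  out <- as.data.frame(tab)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(col) round(col, 3))
  out
}

#' Per-subtype stratification analyses
#'
#' Applies stability selection and tree growth to each heart-failure
#' subtype separately, on the full subtype subset without an internal
#' derivation/validation split (subtype subsets are too small to split).
#' The minimum leaf size is scaled to the subset (configurable through
#' `config$subtype_minbucket`). Subsets smaller than the scaled `minsplit`
#' are reported as a single leaf.
#'
#' @param data Cohort data frame.
#' @param config A [pipeline_config()].
#' @return Named list (one entry per subtype level) of lists with elements
#'   `n`, `selection`, `tree`, `subgroups`.
#' @export
subtype_analysis <- function(data, config = pipeline_config()) {
  domain_map <- config$domain_map
  if (is.null(domain_map)) domain_map <- cohort_domain_map(data)
  covariates <- unlist(domain_map, use.names = FALSE)
  validate_cohort(data, config, covariates)
  subtype <- factor(data[[config$subtype_column]])
  out <- list()
  for (lv in levels(subtype)) {
    sub <- data[subtype == lv, , drop = FALSE]
    mb <- config$subtype_minbucket
    if (is.null(mb)) mb <- max(1L, ceiling(config$minbucket * nrow(sub) / nrow(data)))
    cfg_tree <- split_config(alpha = config$alpha, minbucket = mb,
                             minsplit = 2 * mb, adjustment = config$adjustment,
                             max_depth = config$max_depth,
                             landmark_years = config$landmark_years)
    selection <- bootstrap_selection(
      sub, domain_map, B = config$bootstrap_B,
      threshold = config$selection_threshold,
      p_enter = config$p_enter, p_remove = config$p_remove,
      seed = config$seed + 1L,
      time_col = config$time_column, event_col = config$event_column,
      ties = config$ties
    )
    tree_vars <- selection$retained
    if (!length(tree_vars)) {
      sub$.null_covariate <- 0
      tree_vars <- ".null_covariate"
    }
    tree <- grow_tree(sub, tree_vars, config = cfg_tree,
                      time_col = config$time_column,
                      event_col = config$event_column)
    out[[lv]] <- list(
      n = nrow(sub), selection = selection, tree = tree,
      subgroups = subgroup_report(tree, sub, ties = config$ties)
    )
  }
  out
}
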