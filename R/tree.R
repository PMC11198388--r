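#' Tree-growing configuration
#'
#' Controls for conditional-inference survival-tree growth: nodes are split
#' only when the smallest multiplicity-adjusted permutation p-value across
#' candidate covariates falls below `alpha`, every terminal leaf must keep at
#' least `minbucket` patients, and nodes smaller than `minsplit` are not
#' considered for splitting.
#'
#' @param alpha Significance level for the adjusted split test (default
#'   0.05).
#' @param minbucket Minimum terminal-leaf size (default 95).
#' @param minsplit Minimum node size to attempt a split; must be at least
#'   `2 * minbucket` (default exactly that).
#' @param adjustment Multiplicity adjustment across covariates at a node:
#'   `"bonferroni"` (default) or `"none"`.
#' @param max_depth Optional depth cap (root has depth 0).
#' @param landmark_years Landmark times (years) reported per leaf.
#' @return Object of class `split_config`.
#' @export
split_config <- function(alpha = 0.05, minbucket = 95,
                         minsplit = 2 * minbucket,
                         adjustment = c("bonferroni", "none"),
                         max_depth = Inf, landmark_years = c(1, 6)) {
  adjustment <- match.arg(adjustment)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (minbucket < 1) stop("`minbucket` must be >= 1")
  if (minsplit < 2 * minbucket) stop("`minsplit` must be >= 2 * minbucket")
  structure(
    list(alpha = alpha, minbucket = as.integer(minbucket),
         minsplit = as.integer(minsplit), adjustment = adjustment,
         max_depth = max_depth, landmark_years = landmark_years),
    class = "split_config"
  )
}

covariate_to_g <- function(x) {
  if (is.factor(x)) {
    lv <- levels(droplevels(x))
    if (length(lv) < 2) return(NULL)
    stats::model.matrix(~z - 1, data.frame(z = droplevels(x)))
  } else {
    as.numeric(x)
  }
}

#' Select the split variable at a node
#'
#' Computes, for every candidate covariate, the permutation-test p-value of
#' its association with the node-local log-rank scores ([linear_statistic()];
#' quadratic-form statistic for categorical covariates), applies the
#' multiplicity adjustment across candidates, and selects the most
#' significant covariate. Returns `NULL` (a stop signal) when no candidate
#' is non-degenerate or the adjusted p-value is not below `alpha`.
#'
#' @param data Data frame holding the node's rows.
#' @param covariates Candidate covariate names.
#' @param a Node-local log-rank scores.
#' @param config A [split_config()].
#' @return `list(var, p_adj, p_values)` or `NULL`.
#' @export
select_split_variable <- function(data, covariates, a, config) {
  p <- rep(NA_real_, length(covariates))
  names(p) <- covariates
  for (v in covariates) {
    g <- covariate_to_g(data[[v]])
    if (is.null(g)) next
    ls <- linear_statistic(g, a)
    if (!ls$degenerate) p[v] <- ls$p
  }
  tested <- which(!is.na(p))
  if (!length(tested)) return(NULL)
  m <- length(tested)
  i <- tested[which.min(p[tested])]
  p_adj <- if (config$adjustment == "bonferroni") min(1, m * p[i]) else p[i]
  if (p_adj >= config$alpha) return(NULL)
  list(var = covariates[i], p_adj = p_adj, p_values = p)
}

#' Best binary cutpoint for a numeric covariate
#'
#' Over all observed values `c` of `x` that leave at least `minbucket`
#' subjects on each side of the split `x <= c`, maximizes the absolute
#' standardized linear statistic of the split indicator against the scores.
#' Ties are broken toward the smallest threshold.
#'
#' @param x Numeric covariate at the node.
#' @param a Node-local log-rank scores.
#' @param minbucket Minimum child size.
#' @return `list(threshold, z_abs)` or `NULL` when no admissible cutpoint
#'   exists.
#' @export
best_cutpoint <- function(x, a, minbucket = 1) {
  n <- length(x)
  stopifnot(length(a) == n, minbucket >= 1)
  abar <- mean(a)
  va <- sum((a - abar)^2)
  if (va <= 0) return(NULL)
  ord <- order(x)
  xs <- x[ord]
  sa <- cumsum(a[ord])
  k <- which(diff(xs) > 0)                      # last index of each distinct value
  k <- k[k >= minbucket & (n - k) >= minbucket]
  if (!length(k)) return(NULL)
  vark <- va / (n - 1) * (k * (n - k) / n)
  z <- abs((sa[k] - k * abar) / sqrt(vark))
  zmax <- max(z)
  if (!is.finite(zmax) || zmax == 0) return(NULL)
  i <- which(z >= zmax * (1 - 1e-10))[1]        # smallest threshold on ties
  list(threshold = xs[k[i]], z_abs = z[i])
}

# exhaustive binary partitions of factor levels (<= 5 levels)
best_partition <- function(x, a, minbucket = 1) {
  x <- droplevels(x)
  lv <- levels(x)
  L <- length(lv)
  if (L < 2) return(NULL)
  if (L > 5) stop("categorical covariates with more than 5 levels are not supported")
  abar <- mean(a)
  va <- sum((a - abar)^2)
  if (va <= 0) return(NULL)
  n <- length(x)
  best <- NULL
  # subsets of levels 2..L, each unioned with level 1 (dedupes complements)
  for (m in 0:(2^(L - 1) - 1)) {
    left <- c(lv[1], lv[-1][bitwAnd(m, 2^(seq_len(L - 1) - 1)) > 0])
    if (length(left) == L) next
    g <- as.numeric(x %in% left)
    k <- sum(g)
    if (k < minbucket || n - k < minbucket) next
    z <- abs((sum(g * a) - k * abar) /
               sqrt(va / (n - 1) * (k * (n - k) / n)))
    if (is.finite(z) && (is.null(best) || z > best$z_abs * (1 + 1e-10))) {
      best <- list(levels_left = left, levels_right = setdiff(lv, left),
                   z_abs = z)
    }
  }
  best
}

make_leaf <- function(tm, evv, config) {
  curve <- kaplan_meier(tm, evv)
  landmarks <- survival_at(curve, config$landmark_years)
  names(landmarks) <- paste0("s", config$landmark_years, "y")
  list(type = "leaf", id = NA_integer_, n = length(tm), events = sum(evv),
       km_landmarks = landmarks, median_survival = km_median(curve),
       max_time = max(tm))
}

#' Grow a conditional-inference survival tree
#'
#' Recursive partitioning of right-censored survival data: at every node the
#' log-rank scores are recomputed from the node's own subjects, the covariate
#' most associated with them is selected by a multiplicity-adjusted
#' permutation test, and the split maximizing the standardized survival
#' difference is applied. A node becomes a terminal leaf when it is smaller
#' than `minsplit`, no adjusted p-value is below `alpha`, no admissible
#' cutpoint respects `minbucket`, or the depth cap is reached. Leaf ids are
#' assigned left-to-right.
#'
#' @param data Data frame containing the outcome and covariates; complete
#'   cases required for all `covariates`.
#' @param covariates Candidate covariate names (numeric, binary, or factors
#'   with at most 5 levels).
#' @param config A [split_config()].
#' @param time_col,event_col Outcome column names.
#' @return Object of class `survival_tree`.
#' @export
grow_tree <- function(data, covariates, config = split_config(),
                      time_col = "time_years", event_col = "event") {
  stopifnot(inherits(config, "split_config"), nrow(data) >= 1,
            length(covariates) >= 1)
  missing_cols <- setdiff(c(time_col, event_col, covariates), names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (v in covariates) {
    if (anyNA(data[[v]])) {
      stop("missing values in covariate `", v,
           "`; complete cases are required at fit time")
    }
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) > 5) {
      stop("categorical covariate `", v, "` has more than 5 levels")
    }
  }
  time <- data[[time_col]]
  event <- data[[event_col]]
  check_survival_data(time, event)

  grow <- function(idx, depth) {
    tm <- time[idx]
    evv <- event[idx]
    if (length(idx) < config$minsplit || depth >= config$max_depth) {
      return(make_leaf(tm, evv, config))
    }
    a <- logrank_scores(tm, evv)
    sel <- select_split_variable(data[idx, , drop = FALSE], covariates, a,
                                 config)
    if (is.null(sel)) return(make_leaf(tm, evv, config))
    x <- data[[sel$var]][idx]
    cut <- if (is.factor(x)) best_partition(x, a, config$minbucket)
           else best_cutpoint(x, a, config$minbucket)
    if (is.null(cut)) return(make_leaf(tm, evv, config))
    goes_left <- if (is.factor(x)) x %in% cut$levels_left
                 else x <= cut$threshold
    node <- list(type = "split", var = sel$var, p_adj = sel$p_adj,
                 n = length(idx), events = sum(evv))
    if (is.factor(x)) {
      node$levels_left <- cut$levels_left
      node$levels_right <- cut$levels_right
    } else {
      node$threshold <- cut$threshold
    }
    node$left <- grow(idx[goes_left], depth + 1)
    node$right <- grow(idx[!goes_left], depth + 1)
    node
  }

  root <- grow(seq_along(time), 0)
  root <- number_leaves(root)$node
  structure(
    list(root = root, config = config, covariates = covariates,
         n = length(time), time_col = time_col, event_col = event_col),
    class = "survival_tree"
  )
}

number_leaves <- function(node, next_id = 1L) {
  if (node$type == "leaf") {
    node$id <- next_id
    return(list(node = node, next_id = next_id + 1L))
  }
  l <- number_leaves(node$left, next_id)
  r <- number_leaves(node$right, l$next_id)
  node$left <- l$node
  node$right <- r$node
  list(node = node, next_id = r$next_id)
}

#' Terminal-leaf summary of a fitted tree
#'
#' @param tree A [grow_tree()] fit.
#' @return `data.frame` with one row per leaf: id, n, events, Kaplan-Meier
#'   landmark survival, median survival.
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "survival_tree"))
  rows <- list()
  walk <- function(node) {
    if (node$type == "leaf") {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = node$id, n = node$n, events = node$events,
        t(node$km_landmarks), median_survival = node$median_survival
      )
    } else {
      walk(node$left)
      walk(node$right)
    }
  }
  walk(tree$root)
  do.call(rbind, rows)
}

split_condition <- function(node, side) {
  if (!is.null(node$threshold)) {
    thr <- formatC(node$threshold, format = "g", digits = 6)
    if (side == "left") paste0(node$var, " <= ", thr)
    else paste0(node$var, " > ", thr)
  } else {
    lv <- if (side == "left") node$levels_left else node$levels_right
    paste0(node$var, " in {", paste(lv, collapse = ", "), "}")
  }
}

#' Root-to-leaf criteria strings
#'
#' @param tree A [grow_tree()] fit.
#' @return Named character vector mapping leaf id to the conjunction of
#'   split conditions along its path (conditions joined by "/").
#' @export
leaf_paths <- function(tree) {
  stopifnot(inherits(tree, "survival_tree"))
  out <- character(0)
  walk <- function(node, path) {
    if (node$type == "leaf") {
      out[as.character(node$id)] <<- paste(path, collapse = "/")
    } else {
      walk(node$left, c(path, split_condition(node, "left")))
      walk(node$right, c(path, split_condition(node, "right")))
    }
  }
  walk(tree$root, character(0))
  out
}

#' Route new records to terminal leaves
#'
#' Deterministic routing with the `value <= threshold` goes-left convention;
#' there are no surrogate splits, so every split variable must be present
#' and non-missing.
#'
#' @param tree A [grow_tree()] fit.
#' @param newdata Data frame of covariates.
#' @return Integer vector of leaf ids.
#' @export
predict_leaf <- function(tree, newdata) {
  stopifnot(inherits(tree, "survival_tree"))
  used <- character(0)
  gather <- function(node) {
    if (node$type == "split") {
      used <<- c(used, node$var)
      gather(node$left)
      gather(node$right)
    }
  }
  gather(tree$root)
  used <- unique(used)
  missing_vars <- setdiff(used, names(newdata))
  if (length(missing_vars)) {
    stop("missing split variable(s): ", paste(missing_vars, collapse = ", "))
  }
  for (v in used) {
    if (anyNA(newdata[[v]])) stop("missing values in split variable: ", v)
  }
  out <- integer(nrow(newdata))
  route <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (node$type == "leaf") {
      out[idx] <<- node$id
      return(invisible())
    }
    x <- newdata[[node$var]][idx]
    goes_left <- if (!is.null(node$threshold)) x <= node$threshold
                 else x %in% node$levels_left
    route(node$left, idx[goes_left])
    route(node$right, idx[!goes_left])
  }
  route(tree$root, seq_len(nrow(newdata)))
  out
}

#' @export
format.survival_tree <- function(x, ...) {
  lines <- character(0)
  walk <- function(node, indent, label) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      lm <- paste(sprintf("%s=%.3f", names(node$km_landmarks),
                          node$km_landmarks), collapse = ", ")
      lines <<- c(lines, sprintf("%s%sleaf %d: n=%d, events=%d, %s",
                                 pad, label, node$id, node$n, node$events, lm))
    } else {
      lines <<- c(lines, sprintf("%s%s[%s] (p.adj=%.4g, n=%d)",
                                 pad, label, node$var, node$p_adj, node$n))
      walk(node$left, indent + 1,
           paste0(split_condition(node, "left"), " -> "))
      walk(node$right, indent + 1,
           paste0(split_condition(node, "right"), " -> "))
    }
  }
  walk(x$root, 0, "")
  paste(lines, collapse = "\n")
}

#' @export
print.survival_tree <- function(x, ...) {
  cat("Conditional-inference survival tree: n =", x$n, "\n")
  cat(format(x), "\n")
  invisible(x)
}

node_to_list <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf", id = node$id, n = node$n, events = node$events,
         km_landmarks = as.list(node$km_landmarks),
         median_survival = node$median_survival)
  } else {
    out <- list(type = "split", var = node$var, p_adj = node$p_adj,
                n = node$n, events = node$events)
    if (!is.null(node$threshold)) out$threshold <- node$threshold
    else {
      out$levels_left <- node$levels_left
      out$levels_right <- node$levels_right
    }
    out$left <- node_to_list(node$left)
    out$right <- node_to_list(node$right)
    out
  }
}

#' Serialize a fitted tree to JSON
#'
#' @param tree A [grow_tree()] fit.
#' @param file Optional output path; when `NULL` the JSON string is
#'   returned.
#' @export
tree_to_json <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "survival_tree"))
  obj <- list(n = tree$n, covariates = tree$covariates,
              config = unclass(tree$config), root = node_to_list(tree$root))
  # I(17) significant digits: thresholds must round-trip bit-exactly so that
  # routing through a deserialized tree matches the original fit
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE, null = "null")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

list_to_node <- function(obj) {
  if (obj$type == "leaf") {
    list(type = "leaf", id = as.integer(obj$id), n = obj$n,
         events = obj$events,
         km_landmarks = unlist(obj$km_landmarks),
         median_survival = if (is.null(obj$median_survival)) NA_real_
                           else obj$median_survival)
  } else {
    node <- list(type = "split", var = obj$var, p_adj = obj$p_adj,
                 n = obj$n, events = obj$events)
    if (!is.null(obj$threshold)) node$threshold <- obj$threshold
    else {
      node$levels_left <- unlist(obj$levels_left)
      node$levels_right <- unlist(obj$levels_right)
    }
    node$left <- list_to_node(obj$left)
    node$right <- list_to_node(obj$right)
    node
  }
}

#' Reconstruct a fitted tree from its JSON serialization
#'
#' Inverse of [tree_to_json()]: the returned object routes records and
#' reports identically to the original fit.
#'
#' @param file Path to a `tree.json` file (or a JSON string).
#' @return Object of class `survival_tree`.
#' @export
tree_from_json <- function(file) {
  obj <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  cfg <- obj$config
  config <- split_config(alpha = cfg$alpha, minbucket = cfg$minbucket,
                         minsplit = cfg$minsplit,
                         adjustment = cfg$adjustment,
                         max_depth = if (is.null(cfg$max_depth)) Inf
                                     else cfg$max_depth,
                         landmark_years = unlist(cfg$landmark_years))
  structure(
    list(root = list_to_node(obj$root), config = config,
         covariates = unlist(obj$covariates), n = obj$n,
         time_col = "time_years", event_col = "event"),
    class = "survival_tree"
  )
}
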