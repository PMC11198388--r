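#' Truth-tree constructors
#'
#' A truth tree is the known recursive binary partition a synthetic cohort is
#' generated from: internal nodes carry a split variable and threshold
#' (routing convention: `value <= threshold` goes left), terminal leaves
#' carry integer ids. [truth_tree()] validates the assembled structure.
#'
#' @param var Split variable name.
#' @param threshold Finite numeric split threshold.
#' @param left,right Child nodes (`tree_split()` or `tree_leaf()`).
#' @param id Integer leaf id.
#' @return Nodes of class `truth_split` / `truth_leaf`; [truth_tree()]
#'   returns an object of class `truth_tree`.
#' @examples
#' tt <- truth_tree(tree_split("age", 65, tree_leaf(1), tree_leaf(2)))
#' truth_leaf_ids(tt)
#' @export
tree_split <- function(var, threshold, left, right) {
  stopifnot(is.character(var), length(var) == 1,
            is.numeric(threshold), is.finite(threshold))
  structure(list(var = var, threshold = as.numeric(threshold),
                 left = left, right = right),
            class = "truth_split")
}

#' @rdname tree_split
#' @export
tree_leaf <- function(id) {
  structure(list(id = as.integer(id)), class = "truth_leaf")
}

#' @rdname tree_split
#' @param root Root node of the tree.
#' @export
truth_tree <- function(root) {
  ids <- collect_leaf_ids(root)
  if (anyDuplicated(ids)) stop("leaf ids must be unique")
  if (!identical(sort(ids), seq_along(ids))) {
    stop("leaf ids must be contiguous 1..L")
  }
  structure(list(root = root, leaf_ids = ids), class = "truth_tree")
}

collect_leaf_ids <- function(node) {
  if (inherits(node, "truth_leaf")) return(node$id)
  c(collect_leaf_ids(node$left), collect_leaf_ids(node$right))
}

collect_split_vars <- function(node) {
  if (inherits(node, "truth_leaf")) return(character(0))
  unique(c(node$var, collect_split_vars(node$left),
           collect_split_vars(node$right)))
}

#' Split variables used by a truth tree
#' @param truth A [truth_tree()].
#' @export
truth_tree_variables <- function(truth) {
  collect_split_vars(truth$root)
}

#' @rdname truth_tree_variables
#' @export
truth_leaf_ids <- function(truth) {
  truth$leaf_ids
}

#' Route records through a truth tree
#'
#' Assigns each record its true leaf by recursive routing with the
#' `value <= threshold -> left` convention. All split variables must be
#' present and non-missing.
#'
#' @param newdata Data frame of covariates.
#' @param truth A [truth_tree()].
#' @return Integer vector of leaf ids, one per row.
#' @export
assign_true_leaf <- function(newdata, truth) {
  stopifnot(inherits(truth, "truth_tree"))
  vars <- truth_tree_variables(truth)
  missing_vars <- setdiff(vars, names(newdata))
  if (length(missing_vars)) {
    stop("missing split variable(s): ", paste(missing_vars, collapse = ", "))
  }
  for (v in vars) {
    if (anyNA(newdata[[v]])) stop("missing values in split variable: ", v)
  }
  out <- integer(nrow(newdata))
  route <- function(node, idx) {
    if (!length(idx)) return(invisible())
    if (inherits(node, "truth_leaf")) {
      out[idx] <<- node$id
      return(invisible())
    }
    goes_left <- newdata[[node$var]][idx] <= node$threshold
    route(node$left, idx[goes_left])
    route(node$right, idx[!goes_left])
  }
  route(truth$root, seq_len(nrow(newdata)))
  out
}

#' Default 8-leaf truth tree for the severe-sMR cohort generator
#'
#' The published derivation-cohort partition: root split on albumin at
#' 40.6 g/L; the low-albumin side splits on age at 68 years, then blood urea
#' nitrogen at 24.1 mg/dL (younger) or NT-proBNP at 9,570 pg/mL and albumin
#' again at 34.5 g/L (older); the high-albumin side splits on hemoglobin at
#' 12.7 g/dL and age at 66 years. Left-to-right leaf numbering reproduces the
#' published subgroup ids 1 through 8, with subgroup 7 (young, high
#' hemoglobin, high albumin) the best-survival reference and subgroup 5
#' (older, hypoalbuminemic, very high NT-proBNP) the worst.
#'
#' @return A [truth_tree()].
#' @export
default_truth_tree <- function() {
  truth_tree(
    tree_split("albumin", 40.6,
      left = tree_split("age", 68,
        left = tree_split("bun", 24.1, tree_leaf(1), tree_leaf(2)),
        right = tree_split("ntprobnp", 9570,
          left = tree_split("albumin", 34.5, tree_leaf(3), tree_leaf(4)),
          right = tree_leaf(5))),
      right = tree_split("hemoglobin", 12.7,
        left = tree_leaf(6),
        right = tree_split("age", 66, tree_leaf(7), tree_leaf(8))))
  )
}

#' Published hazard-ratio ladder of the default truth tree
#'
#' Derivation-cohort hazard ratios of each subgroup versus the reference
#' subgroup 7, used as proportional-hazards offsets by the default generator.
#'
#' @return Named numeric vector indexed by leaf id ("1".."8").
#' @export
default_hr_ladder <- function() {
  c(`1` = 3.14, `2` = 8.27, `3` = 13.12, `4` = 5.74,
    `5` = 20.38, `6` = 4.68, `7` = 1.00, `8` = 2.72)
}
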