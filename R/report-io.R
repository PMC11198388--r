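#' Write a pipeline report to a directory
#'
#' Emits the standard output files: `tree.json`, `tree.txt`, `screen.tsv`,
#' `selection.tsv`, `subgroups_derivation.tsv`, `subgroups_validation.tsv`,
#' `temporal_a.tsv`, `temporal_b.tsv` and `run.log` (config echo, seed and
#' package version as JSON).
#'
#' @param report A [run_pipeline()] report.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_pipeline_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, file) {
    utils::write.table(as.data.frame(x), file.path(dir, file),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  tree_to_json(report$tree, file.path(dir, "tree.json"))
  writeLines(format(report$tree), file.path(dir, "tree.txt"))
  tsv(report$screen, "screen.tsv")
  tsv(report$selection$frequencies, "selection.tsv")
  tsv(report$subgroups_derivation, "subgroups_derivation.tsv")
  tsv(report$subgroups_validation, "subgroups_validation.tsv")
  tsv(report$temporal$a, "temporal_a.tsv")
  tsv(report$temporal$b, "temporal_b.tsv")
  cfg <- report$config
  cfg$domain_map <- NULL
  jsonlite::write_json(
    list(version = report$version, n = report$n, config = unclass(cfg),
         derivation_n = length(report$split$derivation),
         validation_n = length(report$split$validation)),
    file.path(dir, "run.log"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, null = "null", force = TRUE
  )
  invisible(dir)
}

#' Export a Kaplan-Meier curve as TSV
#'
#' @param curve A [kaplan_meier()] curve.
#' @param file Output path.
#' @export
write_km_tsv <- function(curve, file) {
  utils::write.table(as.data.frame(curve), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
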