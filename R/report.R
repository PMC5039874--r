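#' Write a reproducibility manifest next to a set of outputs
#'
#' Records what produced the files in an output directory: the command
#' label, configuration path, seed, package version and timestamp. Given the
#' same package version, the manifest is sufficient to reproduce the outputs
#' bit for bit.
#'
#' @param dir output directory (created if missing).
#' @param command short label for the analysis stage (e.g. `"base_case"`).
#' @param seed integer seed used, or `NA` for deterministic stages.
#' @param config path or description of the parameter configuration.
#' @param extra optional named list of additional fields to record.
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(dir, command, seed = NA, config = NA,
                               extra = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- c(list(
    command = command,
    config = config,
    seed = seed,
    package = "anginacua",
    version = as.character(utils::packageVersion("anginacua")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    output_dir = normalizePath(dir)), extra)
  path <- file.path(dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Write the tables of an analysis stage as CSV
#'
#' Thin wrappers over [utils::write.csv()] so every exported table goes
#' through one code path and parses back with [utils::read.csv()].
#'
#' @param x a data.frame (or an object with an `as.data.frame` method, e.g. a
#'   `cohort_trace` or `owsa_result`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
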