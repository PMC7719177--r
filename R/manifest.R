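# Run manifests: enough provenance to replay a command-line run.

#' Write a run manifest
#'
#' Records the configuration snapshot, seeds, MD5 digests of every input
#' and output file, and a timestamp, as JSON next to the run's
#' artifacts. Re-running with the recorded config and seed reproduces
#' the listed digests.
#'
#' @param path destination `.json` path.
#' @param command the subcommand or function that produced the run.
#' @param config configuration list or [pipeline_config()] snapshot.
#' @param seed integer seed(s) used.
#' @param inputs,outputs character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, config = NULL, seed = NULL,
                               inputs = character(0),
                               outputs = character(0)) {
  digest <- function(files) {
    files <- files[file.exists(files)]
    as.list(tools::md5sum(files))
  }
  obj <- list(
    command = command,
    config = config,
    seed = seed,
    inputs = digest(inputs),
    outputs = digest(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
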