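#' Write a reproducibility manifest next to an output
#'
#' Records the command line (or calling description), the effective
#' configuration, the seed, the package version, checksums of the input files
#' and a timestamp, as `manifest.json` in `dir`. Re-running a deterministic
#' command with an identical manifest (ignoring the timestamp) reproduces its
#' outputs byte-identically.
#'
#' @param dir Output directory (created if missing).
#' @param command Character description of the invocation.
#' @param seed The seed used, or `NULL`.
#' @param config A named list of effective settings.
#' @param inputs Character vector of input file paths to checksum.
#' @return The manifest path, invisibly.
#' @export
run_manifest <- function(dir, command, seed = NULL, config = list(),
                         inputs = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- inputs[file.exists(inputs)]
  checksums <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs))
  } else {
    stats::setNames(list(), character())
  }
  config <- config[!vapply(config, is.null, logical(1))]
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(
      command = paste(command, collapse = " "),
      seed = seed,
      config = config,
      package_version = as.character(utils::packageVersion("abbrex")),
      input_checksums = checksums,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
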