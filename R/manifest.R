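#' Write a machine-readable run manifest
#'
#' Records, as JSON, everything needed to reproduce a run: the subcommand or
#' function, its parameters (including the seed), input files, package and R
#' versions, and the filtering counters accumulated while loading data
#' (sites dropped by MAF/phasing/multiallelic/missing filters, windows removed
#' by masks).
#'
#' @param path output JSON file.
#' @param command name of the operation.
#' @param params named list of parameters.
#' @param inputs named list or character vector of input files.
#' @param counts named list of filtering counters.
#' @return \code{path}, invisibly.
#' @export
writeRunManifest <- function(path, command, params = list(), inputs = list(),
                             counts = list()) {
  manifest <- list(
    command = command,
    params = params,
    inputs = inputs,
    counts = counts,
    package = list(name = "genonet",
                   version = as.character(utils::packageVersion("genonet"))),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Re-exported generics
#'
#' \code{metadata} (simulation diagnostics, filter counters) and
#' \code{colData} are re-exported from Bioconductor core packages for
#' convenience.
#' @name reexports
#' @importFrom S4Vectors metadata
#' @export metadata
#' @importFrom SummarizedExperiment colData
#' @export colData
NULL
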