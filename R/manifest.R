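#' Write a run manifest
#'
#' Records next to every written output what produced it: package
#' version, R version, configuration snapshot, master seed(s), input file
#' digests and a timestamp.
#'
#' @param path JSON file path.
#' @param config Named list snapshot of the run configuration.
#' @param seed Seed or seed vector used.
#' @param inputs Character vector of input file paths to digest.
#' @param outputs Character vector of output file paths produced.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seed = NA,
                           inputs = character(0), outputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    tool = "paox",
    version = as.character(utils::packageVersion("paox")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_digests = digests,
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
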