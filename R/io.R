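# Result output: tidy delimited tables with a commented metadata header
# (configuration hash, seed, units, downsampling factor), plus read-back.

metaHeader <- function(config, extra = character()) {
  c(sprintf("# caruSim %s", as.character(utils::packageVersion("caruSim"))),
    sprintf("# config-hash: %s", configHash(config)),
    sprintf("# seed: %d", as.integer(config@seed)),
    sprintf("# mode: %s", config@mode),
    sprintf("# phi: %g | eta: %g | ratio: %g", config@phi, config@eta,
            config@ratio),
    sprintf("# dt-ms: %g | period-ms: %g | beats: %d | discard: %d",
            config@dt, config@period, as.integer(config@beats),
            as.integer(config@discard)),
    extra)
}

writeTableWithHeader <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(df, digits = 17, scientific = NA, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write protocol results as tidy delimited tables
#'
#' Writes \code{beats.tsv} (one row per analyzed beat), \code{summary.tsv}
#' (one row per condition) and \code{det-reference.tsv} under \code{dir},
#' each with a commented metadata block carrying the configuration hash and
#' seed.  Units: sbar in mM, APD in ms, calcium in mM.
#'
#' @param result a \linkS4class{SweepResult}.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
writeResults <- function(result, dir) {
  stopifnot(is(result, "SweepResult"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hd <- metaHeader(result@config,
                   "# units: sbar mM | apd50/apd90 ms | peakCai/diasCaSR mM")
  writeTableWithHeader(result@beats, file.path(dir, "beats.tsv"), hd)
  writeTableWithHeader(result@summary, file.path(dir, "summary.tsv"), hd)
  writeTableWithHeader(result@detReference,
                       file.path(dir, "det-reference.tsv"), hd)
  saveConfig(result@config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read back a result table written by \code{\link{writeResults}}
#'
#' @param path table path.
#' @return data.frame; the commented metadata block is attached as the
#'   \code{"metadata"} attribute.
#' @export
readResultTable <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  attr(df, "metadata") <- meta
  df
}

#' Write a downsampled trace table
#'
#' @param trace data.frame trace from \code{\link{runCell}}.
#' @param path output path.
#' @param config the producing \linkS4class{SimulationConfig}.
#' @param downsample keep every downsample-th row (factor 1 keeps all);
#'   the factor is recorded in the metadata header.
#' @export
writeTrace <- function(trace, path, config, downsample = 1) {
  stopifnot(downsample >= 1, downsample == round(downsample))
  keep <- seq(1, nrow(trace), by = downsample)
  hd <- metaHeader(config, sprintf("# trace-downsample-factor: %d",
                                   as.integer(downsample)))
  writeTableWithHeader(trace[keep, , drop = FALSE], path, hd)
}
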