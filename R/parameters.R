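# All numeric constants live in one versioned table,
# inst/extdata/cell-parameters.tsv, with per-entry provenance.  The helpers
# below load that table and derive the per-module parameter lists.

#' Whole-cell model parameters
#'
#' Loads the packaged parameter table (or a user-supplied one in the same
#' format) and returns a named list of numeric constants.  Individual values
#' can be overridden through \code{...}; unknown names are rejected.
#'
#' @param file path of a tab-delimited parameter table with columns
#'   \code{name} and \code{value}; defaults to the table shipped with the
#'   package.
#' @param ... named numeric overrides, e.g. \code{phi = 2} or
#'   \code{eta = 0.5}.
#' @return named list of parameters.
#' @examples
#' p <- cellParameters(phi = 2)
#' p$phi
#' @export
cellParameters <- function(file = NULL, ...) {
  if (is.null(file))
    file <- system.file("extdata", "cell-parameters.tsv", package = "caruSim")
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  p <- as.list(stats::setNames(as.numeric(tab$value), tab$name))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- lapply(dots, as.numeric)
  }
  stopifnot(p$phi > 0, p$eta > 0, p$GCaL > 0, p$maxsr > p$minsr,
            p$minsr > 0, p$EC > 0)
  p
}

#' @rdname cellParameters
#' @param params a full parameter list from \code{cellParameters}.
#' @details \code{lccParameters} and \code{ryrParameters} extract the
#'   channel-scheme subsets (plus shared physical constants) used by
#'   \code{\link{lccRates}} and \code{\link{ryrRates}}.
#' @export
lccParameters <- function(params = cellParameters()) {
  params[c("Faraday", "Rgas", "Temp", "Cao", "GCaL", "VofsCaL", "x7",
           "fSlowScale", "phi", "eta")]
}

#' @rdname cellParameters
#' @export
ryrParameters <- function(params = cellParameters()) {
  params[c("k1prime", "k2prime", "k3", "k4", "maxsr", "minsr", "EC",
           "gammaRyR", "kcasrLiteral", "ryrTimeScale", "Vrel", "phi")]
}

# flat named numeric vector handed to the C++ engine
paramVector <- function(params) {
  unlist(params[vapply(params, is.numeric, logical(1))])
}
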