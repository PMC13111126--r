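# Fixture generator: reference deterministic traces, analytically solvable
# toy Markov schemes, and synthetic release-integral samples for the
# statistics layer.  Everything is produced programmatically from a seed;
# equal seeds give identical fixtures.

#' Generate the package's test fixtures
#'
#' Produces (a) a one-beat deterministic reference trace bundle,
#' (b) small toy Markov schemes (2-4 states) with their analytic
#' equilibria attached, and (c) synthetic release-integral sample sets
#' (unimodal, bimodal, and a 1/sqrt(N) pure-sampling-noise dispersion
#' family) for the statistics layer.
#'
#' @param seed integer seed.
#' @param dir optional directory; when given, fixtures are also written as
#'   plain-text tables (deterministic bytes for a fixed seed).
#' @param detBeat logical; include the one-beat deterministic trace (runs
#'   the cell model for one pacing cycle).
#' @return named list of fixtures.
#' @export
generateFixtures <- function(seed = 1, dir = NULL, detBeat = TRUE) {
  set.seed(as.integer(seed))

  twoState <- list(
    rates = rateSpec(c("A", "B"), c("B", "A"), c(0.4, 0.1),
                     stateNames = c("A", "B")),
    equilibrium = c(A = 0.1 / 0.5, B = 0.4 / 0.5))  # k21/(k12+k21) etc.

  threeState <- list(
    rates = rateSpec(c("A", "B", "B", "C"), c("B", "A", "C", "B"),
                     c(0.8, 0.2, 0.5, 0.3), stateNames = c("A", "B", "C")))
  threeState$equilibrium <- steadyStateOccupancy(threeState$rates)

  fourState <- list(
    rates = rateSpec(c("R", "O", "O", "I", "R", "RI", "RI", "I"),
                     c("O", "R", "I", "O", "RI", "R", "I", "RI"),
                     c(0.3, 0.06, 0.02, 0.005, 0.02, 0.005, 0.3, 0.06),
                     stateNames = c("R", "O", "I", "RI")))
  fourState$equilibrium <- steadyStateOccupancy(fourState$rates)

  unimodal <- stats::rnorm(400, mean = 10, sd = 1)
  z <- stats::runif(400) < 0.4
  bimodal <- ifelse(z, stats::rnorm(400, 14, 0.5), stats::rnorm(400, 8, 0.5))
  nGrid <- 2^(4:9)
  dispersionFamily <- lapply(stats::setNames(nGrid, paste0("N", nGrid)),
                             function(n) stats::rnorm(200, 10, 8 / sqrt(n)))

  out <- list(seed = as.integer(seed),
              toySchemes = list(twoState = twoState,
                                threeState = threeState,
                                fourState = fourState),
              sbarSamples = list(unimodal = unimodal, bimodal = bimodal,
                                 dispersionFamily = dispersionFamily))

  if (detBeat) {
    ref <- runCell(steadyCellState(), cellParameters(), nBeats = 1,
                   mode = "deterministic", traceEvery = 50)
    out$detBeat <- list(trace = ref$trace, beats = ref$beats)
  }

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fmt <- function(x) sprintf("%.17g", x)
    for (nm in names(out$toySchemes)) {
      sc <- out$toySchemes[[nm]]
      df <- data.frame(from = sc$rates@from, to = sc$rates@to,
                       rate = fmt(sc$rates@rate))
      writeLines(c(sprintf("# seed: %d", out$seed),
                   sprintf("# equilibrium: %s",
                           paste(names(sc$equilibrium),
                                 fmt(sc$equilibrium), sep = "=",
                                 collapse = " "))),
                 file.path(dir, paste0("toy-", nm, ".tsv")))
      suppressWarnings(utils::write.table(
        df, file.path(dir, paste0("toy-", nm, ".tsv")), sep = "\t",
        quote = FALSE, row.names = FALSE, append = TRUE))
    }
    for (nm in names(out$sbarSamples)) {
      x <- out$sbarSamples[[nm]]
      if (is.list(x))
        x <- data.frame(n = rep(as.integer(sub("^N", "", names(x))),
                                lengths(x)),
                        sbar = fmt(unlist(x, use.names = FALSE)))
      else x <- data.frame(sbar = fmt(x))
      utils::write.table(x, file.path(dir, paste0("sbar-", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (detBeat)
      utils::write.table(
        format(out$detBeat$trace, digits = 10, trim = TRUE),
        file.path(dir, "det-beat-trace.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
  }
  out
}
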