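# Whole-cell model: coupling of membrane potential, background ionic
# currents, Na+/K+ bookkeeping, the LCC and RyR channel populations and the
# calcium cycling into a single time-stepping cell model with pacing.
# The stepping loop lives in src/cell.cpp; this file provides the S4
# surface, state conversion, and R-level single evaluations.

stateVectorNames <- function() {
  c("V", "m", "h", "j", "xr1", "xr2", "xs", "r", "s", "Nai", "Ki",
    "CaiFree", "CaSRFree", "CassFree",
    paste0("lcc.", lccStateNames()), paste0("ryr.", ryrStateNames()))
}

#' Flatten a CellState to the engine's numeric layout (and back)
#'
#' @param state a \linkS4class{CellState}.
#' @return named numeric vector in the fixed engine order.
#' @export
flattenState <- function(state) {
  stopifnot(is(state, "CellState"))
  stats::setNames(
    c(state@V, state@gates, state@Nai, state@Ki, state@CaiFree,
      state@CaSRFree, state@CassFree, occupancy(state@lcc),
      occupancy(state@ryr)),
    stateVectorNames())
}

#' @rdname flattenState
#' @param x named numeric vector in the engine order.
#' @param t simulation clock to attach (ms).
#' @export
inflateState <- function(x, t = 0) {
  stopifnot(identical(names(x), stateVectorNames()))
  gn <- c("m", "h", "j", "xr1", "xr2", "xs", "r", "s")
  new("CellState",
      V = unname(x[["V"]]),
      gates = stats::setNames(unname(x[gn]), gn),
      Nai = x[["Nai"]], Ki = x[["Ki"]],
      CaiFree = x[["CaiFree"]], CaSRFree = x[["CaSRFree"]],
      CassFree = x[["CassFree"]],
      lcc = channelPopulation(lccStateNames(),
                              unname(x[paste0("lcc.", lccStateNames())]),
                              mode = "deterministic"),
      ryr = channelPopulation(ryrStateNames(),
                              unname(x[paste0("ryr.", ryrStateNames())]),
                              mode = "deterministic"),
      t = t)
}

#' Resting initial state of the cell model
#'
#' The reference model's published resting values (1 Hz steady pacing
#' starting point): V = -86.2 mV, Cai = 7e-5 mM, CaSR = 1.3 mM,
#' Nai = 7.67 mM, Ki = 138.3 mM, gates at their resting values; all LCC
#' channels in the deep closed state, all RyR in the resting state.
#'
#' @return a \linkS4class{CellState}.
#' @export
initialCellState <- function() {
  gn <- c("m", "h", "j", "xr1", "xr2", "xs", "r", "s")
  new("CellState",
      V = -86.2,
      gates = stats::setNames(c(0, 0.75, 0.75, 0, 1, 0, 0, 1), gn),
      Nai = 7.67, Ki = 138.3,
      CaiFree = 0.00007, CaSRFree = 1.3, CassFree = 0.00007,
      lcc = channelPopulation(lccStateNames(), c(1, 0, 0, 0, 0, 0, 0),
                              mode = "deterministic"),
      ryr = channelPopulation(ryrStateNames(), c(1, 0, 0, 0),
                              mode = "deterministic"),
      t = 0)
}

#' Paced steady state shipped with the package
#'
#' A cell state obtained by pacing the deterministic control model at 1 Hz
#' until per-beat drift is negligible, stored as a plain-text snapshot.
#' Scaled protocols start here so that short transient-discard blocks
#' suffice.
#'
#' @return a \linkS4class{CellState}.
#' @export
steadyCellState <- function() {
  f <- system.file("extdata", "steady-state-control-1hz.tsv",
                   package = "caruSim")
  readCellState(f)
}

#' Read or write a cell-state snapshot
#'
#' Columnar text format (name, value), suitable for restarting runs.
#'
#' @param state a \linkS4class{CellState}.
#' @param path file path.
#' @export
writeCellState <- function(state, path) {
  x <- flattenState(state)
  utils::write.table(data.frame(name = names(x), value = sprintf("%.17g", x)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCellState
#' @export
readCellState <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  inflateState(stats::setNames(as.numeric(tab$value), tab$name))
}

#' Pacing stimulus
#'
#' Rectangular depolarizing pulse applied at each pacing onset: equals
#' \code{amplitude} for \code{start <= t mod period < start + duration} and
#' zero elsewhere.
#'
#' @param t time in ms (vectorized).
#' @param period pacing period in ms.
#' @param amplitude pulse height in pA/pF (depolarizing positive).
#' @param duration pulse width in ms.
#' @param start pulse onset within the cycle in ms.
#' @return stimulus current in pA/pF.
#' @export
stimulusCurrent <- function(t, period = 1000, amplitude = 52,
                            duration = 1, start = 10) {
  tb <- t %% period
  ifelse(tb >= start & tb < start + duration, amplitude, 0)
}

#' All membrane currents and fluxes at a state
#'
#' Single evaluation of the engine's current computation: the eleven
#' background currents plus ICaL, and the calcium fluxes Irel, Iup, Ileak,
#' Ixfer.  \code{backgroundCurrents} returns the subset not carried by the
#' channel populations.
#'
#' @param state a \linkS4class{CellState}.
#' @param params full parameter list from \code{\link{cellParameters}}.
#' @return named list of current densities (pA/pF) and fluxes (mM/ms).
#' @export
cellCurrents <- function(state, params = cellParameters()) {
  out <- .cellCurrents(paramVector(params), flattenState(state))
  bad <- names(out)[!vapply(out, is.finite, logical(1))]
  if (length(bad))
    stop("non-finite current: ", paste(bad, collapse = ", "))
  out
}

#' @rdname cellCurrents
#' @export
backgroundCurrents <- function(state, params = cellParameters()) {
  cellCurrents(state, params)[c("INa", "IK1", "Ito", "IKr", "IKs",
                                "INaK", "IpK", "IbNa")]
}

#' Run the paced cell model
#'
#' Advances the whole-cell model over \code{nBeats} pacing cycles at fixed
#' step \code{dt}.  In stochastic mode the LCC and RyR populations are
#' integer channel counts advanced by binomial tau-leaping; in
#' deterministic mode they are occupancy fractions advanced by the
#' mean-field occupancy ODE.  All other variables are deterministic in both
#' modes.
#'
#' @param state starting \linkS4class{CellState} (see
#'   \code{\link{steadyCellState}}).
#' @param params full parameter list from \code{\link{cellParameters}}
#'   (set \code{phi}/\code{eta} there for the intervention scenarios).
#' @param nBeats number of pacing cycles to simulate.
#' @param mode "deterministic" or "stochastic".
#' @param nlcc number of L-type channels (stochastic mode).
#' @param ratio RyR:LCC ratio, NRyR = ratio * nlcc.
#' @param dt time step in ms.
#' @param period pacing period in ms.
#' @param stimStart,stimAmplitude,stimDuration stimulus onset (ms within
#'   each cycle), height (pA/pF) and width (ms).
#' @param seed integer seed for the stochastic channel sampling; with equal
#'   seeds and configuration, trajectories are bit-reproducible.  NULL
#'   leaves the R random stream untouched.
#' @param traceEvery record the downsampled trace every this many steps
#'   (0 = record no trace).
#' @return list with \code{beats} (one row per beat: release integral
#'   \code{sbar} in mM, APD50/APD90 in ms, peak and minimum free cytosolic
#'   calcium, peak V, diastolic SR load, peak release flux),
#'   \code{finalState} (a \linkS4class{CellState}) and, if requested,
#'   \code{trace}.
#' @export
runCell <- function(state = steadyCellState(), params = cellParameters(),
                    nBeats = 1, mode = c("deterministic", "stochastic"),
                    nlcc = 128, ratio = 5, dt = 0.001, period = 1000,
                    stimStart = 10, stimAmplitude = 52, stimDuration = 1,
                    seed = NULL, traceEvery = 0) {
  mode <- match.arg(mode)
  stopifnot(is(state, "CellState"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  nryr <- as.integer(round(ratio * nlcc))
  res <- .cellRun(paramVector(params), flattenState(state), dt, period,
                  as.integer(nBeats), stimStart, stimAmplitude,
                  stimDuration, identical(mode, "stochastic"),
                  as.integer(nlcc), nryr, as.integer(traceEvery))
  res$finalState <- inflateState(
    stats::setNames(as.numeric(res$finalState), stateVectorNames()),
    t = nBeats * period)
  res$beats <- as.data.frame(res$beats)
  res
}
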