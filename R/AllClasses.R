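#' @import methods
#' @importFrom stats rbinom rmultinom runif rexp quantile median IQR sd approx
#' @importFrom utils read.delim write.table modifyList
#' @importFrom graphics hist
#' @importFrom Rcpp evalCpp
#' @useDynLib caruSim, .registration = TRUE
NULL

#' ChannelPopulation: a population of identical ion channels over a Markov
#' state set
#'
#' In stochastic mode \code{counts} holds non-negative integer occupancies
#' that sum exactly to \code{total}; in deterministic mode it holds real
#' occupancy fractions that sum to one.  The class is the substrate for both
#' the L-type calcium channel (7 states) and the ryanodine receptor
#' (4 states) populations, but is generic: any named state set is accepted.
#'
#' @slot stateNames ordered character vector of state labels.
#' @slot counts numeric vector, parallel to \code{stateNames}: integer counts
#'   (stochastic) or fractions (deterministic).
#' @slot total integer, number of channels (stochastic mode); 1 is stored in
#'   deterministic mode where the notion of channel number does not apply.
#' @slot mode either \code{"stochastic"} or \code{"deterministic"}.
#' @export
setClass("ChannelPopulation",
  representation(
    stateNames = "character",
    counts     = "numeric",
    total      = "numeric",
    mode       = "character"
  )
)

setValidity("ChannelPopulation", function(object) {
  msgs <- character()
  n <- length(object@stateNames)
  if (n < 2L) msgs <- c(msgs, "at least two states are required")
  if (anyDuplicated(object@stateNames))
    msgs <- c(msgs, "state names must be unique")
  if (length(object@counts) != n)
    msgs <- c(msgs, "counts must be parallel to stateNames")
  if (!object@mode %in% c("stochastic", "deterministic"))
    msgs <- c(msgs, "mode must be 'stochastic' or 'deterministic'")
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msgs <- c(msgs, "occupancies must be finite and non-negative")
  if (identical(object@mode, "stochastic")) {
    if (any(object@counts != round(object@counts)))
      msgs <- c(msgs, "stochastic occupancies must be integers")
    if (abs(sum(object@counts) - object@total) > 0)
      msgs <- c(msgs, "counts must sum exactly to the channel total")
    if (object@total < 1)
      msgs <- c(msgs, "total number of channels must be at least 1")
  } else {
    if (abs(sum(object@counts) - 1) > 1e-10)
      msgs <- c(msgs, "fractions must sum to 1 within 1e-10")
    if (any(object@counts > 1 + 1e-10))
      msgs <- c(msgs, "fractions must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' RateSpec: the directed transition set of one channel scheme
#'
#' Holds the edges of a Markov scheme with rate values (per ms) evaluated at
#' one operating point (membrane potential, calcium).  Self-transitions are
#' disallowed and all rates must be finite and non-negative.
#'
#' @slot stateNames the scheme's ordered state set.
#' @slot from,to character vectors naming the source and target state of each
#'   directed transition.
#' @slot rate numeric vector of rates in 1/ms.
#' @export
setClass("RateSpec",
  representation(
    stateNames = "character",
    from       = "character",
    to         = "character",
    rate       = "numeric"
  )
)

setValidity("RateSpec", function(object) {
  msgs <- character()
  ne <- length(object@from)
  if (length(object@to) != ne || length(object@rate) != ne)
    msgs <- c(msgs, "from, to and rate must have equal length")
  if (!all(object@from %in% object@stateNames) ||
      !all(object@to %in% object@stateNames))
    msgs <- c(msgs, "all sources and targets must belong to the state set")
  if (any(object@from == object@to))
    msgs <- c(msgs, "self-transitions are not allowed")
  if (any(!is.finite(object@rate)) || any(object@rate < 0))
    msgs <- c(msgs, "rates must be finite and non-negative")
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: a validated simulation configuration
#'
#' @slot mode "stochastic" or "deterministic".
#' @slot nlcc integer vector of L-type channel counts (one entry per sweep
#'   point; a single value for a plain run).
#' @slot ratio RyR:LCC count ratio r, so that NRyR = r * NLCC.
#' @slot phi phosphorylation multiplier (LCC opening, RyR k1, SERCA
#'   affinity).
#' @slot eta LCC inactivation-rate multiplier (eta < 1 upregulates the
#'   channel, eta > 1 downregulates it).
#' @slot dt time step in ms.
#' @slot period pacing period in ms.
#' @slot beats,discard total number of paced beats and the leading number of
#'   beats discarded as transient.
#' @slot seed integer random seed.
#' @slot stimAmplitude,stimDuration rectangular stimulus height (pA/pF,
#'   depolarizing positive) and width (ms).
#' @slot outputDir output directory ("" to keep results in memory only).
#' @slot parameterFile path of the cell parameter table ("" for the packaged
#'   defaults).
#' @export
setClass("SimulationConfig",
  representation(
    mode          = "character",
    nlcc          = "numeric",
    ratio         = "numeric",
    phi           = "numeric",
    eta           = "numeric",
    dt            = "numeric",
    period        = "numeric",
    beats         = "numeric",
    discard       = "numeric",
    seed          = "numeric",
    stimAmplitude = "numeric",
    stimDuration  = "numeric",
    outputDir     = "character",
    parameterFile = "character"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- configViolations(object)
  if (length(msgs)) msgs else TRUE
})

#' CellState: the full state of the whole-cell model
#'
#' Membrane potential, Hodgkin-Huxley gate variables of the background
#' currents, intracellular sodium and potassium, free calcium in the three
#' compartments, the two channel populations, and the simulation clock.
#'
#' @slot V membrane potential (mV).
#' @slot gates named numeric vector (m, h, j, xr1, xr2, xs, r, s), each in
#'   [0, 1].
#' @slot Nai,Ki intracellular Na+ and K+ (mM).
#' @slot CaiFree,CaSRFree,CassFree free calcium in cytosol, SR and
#'   subsarcolemmal space (mM).
#' @slot lcc,ryr the LCC and RyR \linkS4class{ChannelPopulation}s.
#' @slot t simulation clock (ms).
#' @export
setClass("CellState",
  representation(
    V        = "numeric",
    gates    = "numeric",
    Nai      = "numeric",
    Ki       = "numeric",
    CaiFree  = "numeric",
    CaSRFree = "numeric",
    CassFree = "numeric",
    lcc      = "ChannelPopulation",
    ryr      = "ChannelPopulation",
    t        = "numeric"
  )
)

setValidity("CellState", function(object) {
  msgs <- character()
  if (!is.finite(object@V) || object@V < -150 || object@V > 100)
    msgs <- c(msgs, "V must be finite and within a physical range")
  gn <- c("m", "h", "j", "xr1", "xr2", "xs", "r", "s")
  if (!identical(names(object@gates), gn))
    msgs <- c(msgs, paste("gates must be named", paste(gn, collapse = ", ")))
  else if (any(object@gates < -1e-9) || any(object@gates > 1 + 1e-9))
    msgs <- c(msgs, "gate variables must lie in [0, 1]")
  conc <- c(object@Nai, object@Ki, object@CaiFree, object@CaSRFree,
            object@CassFree)
  if (any(!is.finite(conc)) || any(conc < 0))
    msgs <- c(msgs, "concentrations must be finite and non-negative")
  if (length(msgs)) msgs else TRUE
})

#' SweepResult: per-beat summaries and descriptive statistics of a protocol
#' run
#'
#' @slot beats data.frame with one row per analyzed beat (columns: scenario,
#'   mode, nlcc, nryr, beat, sbar, apd50, apd90, peakCai, diasCaSR).
#' @slot summary data.frame with one row per condition (descriptive
#'   statistics of the per-beat release integral).
#' @slot detReference data.frame with the deterministic reference value per
#'   scenario.
#' @slot config the \linkS4class{SimulationConfig} that produced the result.
#' @export
setClass("SweepResult",
  representation(
    beats        = "data.frame",
    summary      = "data.frame",
    detReference = "data.frame",
    config       = "SimulationConfig"
  )
)

setMethod("show", "ChannelPopulation", function(object) {
  cat(sprintf("ChannelPopulation (%s, %d states", object@mode,
              length(object@stateNames)))
  if (identical(object@mode, "stochastic"))
    cat(sprintf(", N = %d", as.integer(object@total)))
  cat(")\n")
  print(stats::setNames(object@counts, object@stateNames))
})

setMethod("show", "RateSpec", function(object) {
  cat(sprintf("RateSpec over {%s}\n", paste(object@stateNames, collapse = ", ")))
  print(data.frame(from = object@from, to = object@to, rate = object@rate))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  mode: %s | NLCC: %s | NRyR = %g x NLCC\n", object@mode,
              paste(object@nlcc, collapse = ","), object@ratio))
  cat(sprintf("  phi = %g, eta = %g | dt = %g ms, period = %g ms\n",
              object@phi, object@eta, object@dt, object@period))
  cat(sprintf("  beats = %d (discard %d) | seed = %d\n",
              as.integer(object@beats), as.integer(object@discard),
              as.integer(object@seed)))
})

setMethod("show", "CellState", function(object) {
  cat(sprintf("CellState at t = %.3f ms: V = %.2f mV\n", object@t, object@V))
  cat(sprintf("  [Ca]i = %.5g mM, [Ca]SR = %.4g mM, [Ca]ss = %.5g mM\n",
              object@CaiFree, object@CaSRFree, object@CassFree))
  cat(sprintf("  Nai = %.3f mM, Ki = %.2f mM\n", object@Nai, object@Ki))
  cat(sprintf("  LCC open fraction %.4g | RyR open fraction %.4g\n",
              occupancy(object@lcc)["O"], occupancy(object@ryr)["O"]))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %d analyzed beats over %d condition(s)\n",
              nrow(object@beats), nrow(object@summary)))
  print(object@summary)
})
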