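# Seven-state L-type calcium channel Markov scheme.
#
# The scheme is built from the reference ventricular model's L-type gate
# rate functions (activation gate d, slow and fast voltage inactivation
# gates f and f2, calcium-dependent inactivation gate fCass), arranged as
#
#   C  <--d+/d-->  C'  <--phi*x7*d+ / x7*d--->  O  <--fca-/fca+-->  ICa
#   (deep closed)  (activated closed)         (open)
#                   |                           |
#              f-/f+ (IC)                  f2-/f2+ (If2)
#                                               |
#                                     cf*f-/cf*f+ (If, deep)
#
# i.e. a two-step voltage activation chain, a serial voltage-inactivation
# ladder O <-> If2 <-> If (fast then slow gate), parallel calcium-dependent
# inactivation off the open state, and closed-state inactivation off C'.
# The forward/backward rates of each branch are the Hodgkin-Huxley opening
# and closing rates of the corresponding gate, x_inf/tau_x and
# (1 - x_inf)/tau_x; cf (fSlowScale) is a fitted time-scale constant of the
# deep step that compensates the ladder's reduced source pool so the
# whole-cell kinetics match the reference model (it cancels from the step's
# equilibrium).  The channel regulation multiplier eta scales the two
# voltage inactivation rates f- and f2-; the phosphorylation multiplier phi
# scales the final opening transition C' -> O = phi * x7 * d+.

#' LCC scheme state names
#' @return character vector of the seven state labels.
#' @export
lccStateNames <- function() c("C", "Cp", "O", "If", "If2", "ICa", "IC")

# Hodgkin-Huxley quantities of the reference model's L-type gates.
# Exported because the inactivation-rate definitions f- = eta*(1-f_inf)/tau_f
# and f2- = eta*(1-f2_inf)/tau_f2 are written in terms of them.

#' Reference-model L-type gate curves
#'
#' Steady-state values and time constants of the activation gate d, the two
#' voltage inactivation gates f and f2, and the calcium-dependent
#' inactivation gate fCass, as functions of membrane potential (mV) and
#' subspace calcium (mM).
#'
#' @param V membrane potential in mV.
#' @param Cass free subspace calcium in mM.
#' @return named list with elements dInf, tauD, fInf, tauF, f2Inf, tauF2,
#'   fcassInf, tauFcass.
#' @export
lccGateCurves <- function(V, Cass) {
  dInf <- 1 / (1 + exp((-8 - V) / 7.5))
  aD <- 1.4 / (1 + exp((-35 - V) / 13)) + 0.25
  bD <- 1.4 / (1 + exp((V + 5) / 5))
  gD <- 1 / (1 + exp((50 - V) / 20))
  tauD <- aD * bD + gD
  fInf <- 1 / (1 + exp((V + 20) / 7))
  tauF <- 1102.5 * exp(-(V + 27)^2 / 225) + 200 / (1 + exp((13 - V) / 10)) +
    180 / (1 + exp((V + 30) / 10)) + 20
  f2Inf <- 0.67 / (1 + exp((V + 35) / 7)) + 0.33
  tauF2 <- 562 * exp(-(V + 27)^2 / 240) + 31 / (1 + exp((25 - V) / 10)) +
    80 / (1 + exp((V + 30) / 10))
  csq <- (Cass / 0.05)^2
  fcassInf <- 0.6 / (1 + csq) + 0.4
  tauFcass <- 80 / (1 + csq) + 2
  list(dInf = dInf, tauD = tauD, fInf = fInf, tauF = tauF,
       f2Inf = f2Inf, tauF2 = tauF2, fcassInf = fcassInf,
       tauFcass = tauFcass)
}

#' Transition rates of the 7-state LCC scheme at one operating point
#'
#' Evaluates the twelve directed transition rates at (V, Cass).  The voltage
#' inactivation rates f- and f2- are scaled by \code{eta}; the final opening
#' transition C' -> O equals \code{phi * x7 * d+}.  With
#' \code{eta = phi = 1} the control scheme is recovered.
#'
#' @param V membrane potential in mV (physical range -100..80).
#' @param Cass free subspace calcium in mM (0..10).
#' @param params list from \code{\link{lccParameters}} (fields phi, eta,
#'   x7 are used here).
#' @return a \linkS4class{RateSpec} over \code{\link{lccStateNames}}.
#' @export
lccRates <- function(V, Cass, params = lccParameters()) {
  if (!is.finite(V) || V < -150 || V > 100)
    stop("V outside physical range")
  if (!is.finite(Cass) || Cass < 0)
    stop("Cass must be non-negative")
  g <- lccGateCurves(V, Cass)
  dPlus <- g$dInf / g$tauD
  dMinus <- (1 - g$dInf) / g$tauD
  fMinus <- params$eta * (1 - g$fInf) / g$tauF
  fPlus <- g$fInf / g$tauF
  f2Minus <- params$eta * (1 - g$f2Inf) / g$tauF2
  f2Plus <- g$f2Inf / g$tauF2
  fcaMinus <- (1 - g$fcassInf) / g$tauFcass
  fcaPlus <- g$fcassInf / g$tauFcass
  from <- c("C", "Cp", "Cp", "O", "O", "If2", "If2", "If", "O", "ICa",
            "Cp", "IC")
  to   <- c("Cp", "C", "O", "Cp", "If2", "O", "If", "If2", "ICa", "O",
            "IC", "Cp")
  rate <- c(dPlus, dMinus,
            params$phi * params$x7 * dPlus, params$x7 * dMinus,
            f2Minus, f2Plus,
            params$fSlowScale * fMinus, params$fSlowScale * fPlus,
            fcaMinus, fcaPlus,
            fMinus, fPlus)
  if (any(!is.finite(rate)) || any(rate < 0)) {
    bad <- which(!is.finite(rate) | rate < 0)[1]
    stop(sprintf("non-finite LCC rate on edge %s->%s at V=%g, Cass=%g",
                 from[bad], to[bad], V, Cass))
  }
  rateSpec(from, to, rate, stateNames = lccStateNames())
}

#' Whole-cell L-type calcium current
#'
#' Goldman-Hodgkin-Katz-form current through the open L-type channels,
#' \deqn{I_{CaL} = O \, G_{CaL} \, 4 \Delta V F^2/(RT)\,
#'   \frac{0.25\,[Ca]_{ss} e^{2\Delta V F/RT} - [Ca]_o}
#'        {e^{2\Delta V F/RT} - 1},\qquad \Delta V = V - 15\,\mathrm{mV},}
#' where \code{O} is the open \emph{fraction} of the population, so the
#' deterministic whole-cell current does not depend on the number of
#' channels.  The removable singularity at \eqn{\Delta V = 0} is evaluated
#' by its series limit.
#'
#' @param openFraction open-state occupancy fraction in [0, 1].
#' @param V membrane potential in mV.
#' @param Cass free subspace calcium in mM.
#' @param params list from \code{\link{lccParameters}}.
#' @return current density in pA/pF (negative = inward).
#' @export
icalCurrent <- function(openFraction, V, Cass, params = lccParameters()) {
  stopifnot(openFraction >= 0, openFraction <= 1 + 1e-12)
  dV <- V - params$VofsCaL
  FRT <- params$Faraday / (params$Rgas * params$Temp)
  x <- 2 * dV * FRT
  scale <- openFraction * params$GCaL * 4 * params$Faraday * FRT
  if (abs(x) < 1e-5) {
    # series of x*(0.25*Cass*e^x - Cao)/(e^x - 1) around x = 0
    num0 <- 0.25 * Cass - params$Cao
    val <- num0 + x * (0.25 * Cass - num0 / 2)
    return(scale * (params$Rgas * params$Temp / (2 * params$Faraday)) * val)
  }
  scale * dV * (0.25 * Cass * exp(x) - params$Cao) / expm1(x)
}
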