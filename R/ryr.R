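# Four-state ryanodine receptor scheme: R (resting closed), O (open),
# I (inactivated), RI (resting-inactivated).  Opening R->O and RI->I is
# driven by subspace calcium squared (CICR) and facilitated by SR load
# through the modulation factor kcasr; inactivation R->RI and O->I is
# linear in subspace calcium (calmodulin-like regulation).

#' RyR scheme state names
#' @return character vector of the four state labels.
#' @export
ryrStateNames <- function() c("R", "O", "I", "RI")

#' SR-load modulation factor of RyR gating
#'
#' \deqn{k_{casr} = maxsr - \frac{maxsr - minsr}{1 + (EC/[Ca]_{SR})^2}}
#' which decreases monotonically from \code{maxsr} (= 2.5, depleted SR) to
#' \code{minsr} (= 1.0, overloaded SR), with value
#' \code{(maxsr + minsr)/2} at \code{Ca_SR = EC}.  The opening rate
#' \code{k1 = phi * k1' / kcasr} therefore \emph{increases} with SR load
#' (luminal facilitation) while the inactivation rate
#' \code{k2 = k2' * kcasr * gamma} decreases.
#'
#' @param CaSR free SR calcium in mM (> 0).
#' @param params list from \code{\link{ryrParameters}}.
#' @return dimensionless factor strictly between \code{minsr} and
#'   \code{maxsr}.
#' @examples
#' kcasr(1.5)   # half-point: (2.5 + 1.0)/2 = 1.75
#' @export
kcasr <- function(CaSR, params = ryrParameters()) {
  if (any(!is.finite(CaSR)) || any(CaSR <= 0))
    stop("CaSR must be positive")
  params$maxsr - (params$maxsr - params$minsr) / (1 + (params$EC / CaSR)^2)
}

#' Transition rates of the 4-state RyR scheme at one operating point
#'
#' Edges R->O and RI->I carry \code{k1 * Cass^2}; edges R->RI and O->I
#' carry \code{k2 * Cass}; the reverse edges O->R and I->RI carry the
#' constant \code{k3}, and RI->R and I->O carry \code{k4}.  Here
#' \code{k1 = phi * k1' / kcasr(CaSR)} and
#' \code{k2 = k2' * kcasr(CaSR) * gamma}; with \code{phi = gamma = 1} the
#' control rates are recovered.  The R <-> O and RI <-> I pairs additionally
#' carry the fitted time-scale factor \code{ryrTimeScale}, which cancels
#' from every equilibrium ratio and restores the reference model's
#' quasi-equilibrium open gating (see the methods vignette).
#'
#' @param Cass free subspace calcium in mM (>= 0).
#' @param CaSR free SR calcium in mM (> 0).
#' @param params list from \code{\link{ryrParameters}}.
#' @return a \linkS4class{RateSpec} over \code{\link{ryrStateNames}}.
#' @export
ryrRates <- function(Cass, CaSR, params = ryrParameters()) {
  if (!is.finite(Cass) || Cass < 0) stop("Cass must be non-negative")
  kc <- kcasr(CaSR, params)
  k1 <- if (params$kcasrLiteral > 0) params$phi * params$k1prime * kc
        else params$phi * params$k1prime / kc
  k2 <- params$k2prime * kc * params$gammaRyR
  open <- params$ryrTimeScale * k1 * Cass^2
  close <- params$ryrTimeScale * params$k3
  inact <- k2 * Cass
  from <- c("R", "O", "O", "I", "R", "RI", "RI", "I")
  to   <- c("O", "R", "I", "O", "RI", "R", "I", "RI")
  rate <- c(open, close, inact, params$k4, inact, params$k4,
            open, close)
  if (any(!is.finite(rate)))
    stop(sprintf("non-finite RyR rate at Cass=%g, CaSR=%g", Cass, CaSR))
  rateSpec(from, to, rate, stateNames = ryrStateNames())
}

#' SR calcium release flux
#'
#' \deqn{I_{rel} = O \cdot V_{rel} \cdot ([Ca]_{SR} - [Ca]_{ss})}
#' with \code{O} the open \emph{fraction} of the RyR population (the same
#' normalization convention as \code{\link{icalCurrent}}), so the
#' deterministic flux does not depend on the number of receptors.
#'
#' @param openFraction open-state occupancy fraction in [0, 1].
#' @param CaSR,Cass free SR and subspace calcium in mM.
#' @param Vrel maximal release rate in 1/ms.
#' @return flux in mM/ms (positive: SR to subspace).
#' @export
irelFlux <- function(openFraction, CaSR, Cass,
                     Vrel = ryrParameters()$Vrel) {
  stopifnot(openFraction >= 0, openFraction <= 1 + 1e-12)
  openFraction * Vrel * (CaSR - Cass)
}
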