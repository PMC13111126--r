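# Three-compartment calcium cycling (cytosol, SR, subsarcolemmal space)
# with instantaneous buffering, transfer/leak/uptake fluxes and the
# sarcolemmal calcium currents adopted from the reference model.

#' Free calcium from total under instantaneous buffering
#'
#' Buffering is treated as an algebraic equilibrium
#' \code{Ca_buff = Ca_free * Buf / (Ca_free + K_buf)}; given the total
#' (free + bound) concentration this solves the resulting quadratic for the
#' unique non-negative free concentration.
#'
#' @param total total calcium (mM, >= 0; vectorized).
#' @param Buf buffer concentration (mM).
#' @param Kbuf buffer affinity (mM).
#' @return free calcium in mM; round-trips with
#'   \code{\link{totalFromFree}} to 1e-10.
#' @export
bufferedFree <- function(total, Buf, Kbuf) {
  if (any(!is.finite(total)) || any(total < 0))
    stop("total calcium must be non-negative")
  b <- Buf + Kbuf - total
  (-b + sqrt(b * b + 4 * Kbuf * total)) / 2
}

#' @rdname bufferedFree
#' @param free free calcium (mM).
#' @export
totalFromFree <- function(free, Buf, Kbuf) {
  free + free * Buf / (free + Kbuf)
}

#' SERCA uptake flux
#'
#' \deqn{I_{up} = \frac{V_{maxup}}{1 + (K_{up}/\phi)^2 / [Ca]_i^2}}
#' The phosphorylation multiplier \code{phi} lowers the effective
#' half-saturation \code{Kup/phi}, so uptake is monotone increasing in both
#' the cytosolic calcium and \code{phi}.
#'
#' @param CaiFree free cytosolic calcium in mM (>= 0; the limit at 0 is a
#'   zero flux).
#' @param phi phosphorylation multiplier (> 0).
#' @param params full parameter list from \code{\link{cellParameters}}.
#' @return uptake flux in mM/ms.
#' @export
iup <- function(CaiFree, phi = 1, params = cellParameters()) {
  if (any(CaiFree < 0)) stop("CaiFree must be non-negative")
  keff <- params$Kup / phi
  ifelse(CaiFree == 0, 0,
         params$Vmaxup / (1 + (keff / CaiFree)^2))
}

#' SR leak and subspace transfer fluxes
#'
#' Linear in their concentration gradients: \code{Ileak = Vleak *
#' (CaSR - Cai)} and \code{Ixfer = Vxfer * (Cass - Cai)}.
#'
#' @param CaSRFree,CaiFree,CassFree free calcium concentrations in mM.
#' @param Vleak,Vxfer rate constants in 1/ms.
#' @return flux in mM/ms.
#' @export
ileak <- function(CaSRFree, CaiFree, Vleak = cellParameters()$Vleak) {
  Vleak * (CaSRFree - CaiFree)
}

#' @rdname ileak
#' @export
ixfer <- function(CassFree, CaiFree, Vxfer = cellParameters()$Vxfer) {
  Vxfer * (CassFree - CaiFree)
}

#' Sarcolemmal calcium currents
#'
#' \code{incx} is the sodium-calcium exchanger current, \code{ipca} the
#' saturating sarcolemmal calcium pump \code{GpCa*Ca/(KpCa + Ca)}, and
#' \code{ibca} the background calcium current \code{GbCa*(V - ECa)} with
#' Nernst potential \code{ECa = RT/(2F) log(Cao/Cai)}.
#'
#' @param V membrane potential in mV.
#' @param Nai intracellular sodium in mM.
#' @param CaiFree free cytosolic calcium in mM.
#' @param params full parameter list from \code{\link{cellParameters}}.
#' @return current density in pA/pF.
#' @export
incx <- function(V, Nai, CaiFree, params = cellParameters()) {
  FRT <- params$Faraday / (params$Rgas * params$Temp)
  g <- params$gammaNCX
  num <- exp(g * V * FRT) * Nai^3 * params$Cao -
    exp((g - 1) * V * FRT) * params$Nao^3 * CaiFree * params$alphaNCX
  den <- (params$KmNai^3 + params$Nao^3) * (params$KmCa + params$Cao) *
    (1 + params$ksat * exp((g - 1) * V * FRT))
  out <- params$kNaCa * num / den
  if (any(!is.finite(out))) stop("non-finite INaCa")
  out
}

#' @rdname incx
#' @export
ipca <- function(CaiFree, params = cellParameters()) {
  params$GpCa * CaiFree / (params$KpCa + CaiFree)
}

#' @rdname incx
#' @export
ibca <- function(V, CaiFree, params = cellParameters()) {
  ECa <- params$Rgas * params$Temp / (2 * params$Faraday) *
    log(params$Cao / CaiFree)
  out <- params$GbCa * (V - ECa)
  if (any(!is.finite(out))) stop("non-finite IbCa")
  out
}

#' Time derivatives of the three total calcium pools
#'
#' Implements the compartment balance
#' \deqn{d[Ca]_i/dt = -\frac{(I_{bCa} + I_{pCa} - 2 I_{NaCa})\,C_m}{2 V_c F}
#'   + \frac{V_{sr}}{V_c}(I_{leak} - I_{up}) + I_{xfer}}
#' \deqn{d[Ca]_{SR}/dt = I_{up} - I_{leak} - I_{rel}}
#' \deqn{d[Ca]_{ss}/dt = -\frac{I_{CaL}\,C_m}{2 V_{ss} F}
#'   + \frac{V_{sr}}{V_{ss}} I_{rel} - \frac{V_c}{V_{ss}} I_{xfer}}
#' applied to the \emph{total} (free + buffered) concentrations; free
#' concentrations are recovered with \code{\link{bufferedFree}} after each
#' step.  With the sarcolemmal terms zeroed, the volume-weighted total
#' \code{Vc*Cai + Vsr*CaSR + Vss*Cass} is conserved exactly.
#'
#' @param state named list or vector with \code{CaiFree}, \code{CaSRFree},
#'   \code{CassFree} (mM).
#' @param ICaL,INaCa,IpCa,IbCa sarcolemmal currents in pA/pF.
#' @param Irel SR release flux in mM/ms.
#' @param phi phosphorylation multiplier entering the uptake.
#' @param params full parameter list from \code{\link{cellParameters}}.
#' @return named numeric vector \code{c(dCai, dCaSR, dCass)}: derivatives
#'   of the total concentrations in mM/ms.
#' @export
calciumDerivatives <- function(state, ICaL, Irel, INaCa, IpCa, IbCa,
                               phi = 1, params = cellParameters()) {
  Cai <- state[["CaiFree"]]; CaSR <- state[["CaSRFree"]]
  Cass <- state[["CassFree"]]
  Iupv <- iup(Cai, phi, params)
  Ilk <- ileak(CaSR, Cai, params$Vleak)
  Ixf <- ixfer(Cass, Cai, params$Vxfer)
  cf <- params$Cm / (2 * params$Faraday)
  dCai <- -(IbCa + IpCa - 2 * INaCa) * cf / params$Vc +
    params$Vsr / params$Vc * (Ilk - Iupv) + Ixf
  dCaSR <- Iupv - Ilk - Irel
  dCass <- -ICaL * cf / params$Vss + params$Vsr / params$Vss * Irel -
    params$Vc / params$Vss * Ixf
  out <- c(dCai = dCai, dCaSR = dCaSR, dCass = dCass)
  if (any(!is.finite(out))) stop("non-finite calcium derivative")
  out
}
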