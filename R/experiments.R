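# Protocols and statistics: the pacing protocol, the per-beat SR-release
# statistic, APD measures, dispersion/histogram/bimodality analysis of the
# release distribution, and transition-point detection on channel-count
# sweeps.

#' Per-beat SR release integral
#'
#' The release statistic of one pacing cycle: the Riemann sum
#' \deqn{\bar S = (T/N) \sum_i I_{rel}(t_i) = \Delta t \sum_i I_{rel}(t_i)}
#' of the SR release flux over exactly one period.
#'
#' @param irel numeric vector: the release flux (mM/ms) sampled at every
#'   step of one pacing period.
#' @param dt step length in ms.
#' @return the release integral in mM.
#' @export
beatReleaseIntegral <- function(irel, dt) {
  if (length(irel) == 0) stop("empty release trace")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
  dt * sum(irel)
}

#' Action potential duration at a repolarization fraction
#'
#' Measures the duration from the action-potential upstroke to the
#' downstroke crossing of \code{Vpeak - f*(Vpeak - Vdias)}, where
#' \code{Vdias} is the potential at the stimulus onset, with linear
#' interpolation between samples.  A beat without a repolarization crossing
#' (e.g. an early-afterdepolarization morphology running past the cycle
#' end) yields \code{NA} rather than an error.
#'
#' @param v membrane-potential trace of one beat (mV), evenly sampled.
#' @param dt sample spacing in ms.
#' @param fraction repolarization fraction, typically 0.5 or 0.9.
#' @param stimTime stimulus onset within the trace, in ms.
#' @return duration in ms, or \code{NA} when the crossing is missing.
#' @export
apd <- function(v, dt, fraction = 0.9, stimTime = 0) {
  stopifnot(length(v) > 2, is.finite(dt), dt > 0,
            fraction > 0, fraction < 1)
  iStim <- max(1L, min(length(v), floor(stimTime / dt) + 1L))
  vDias <- v[iStim]
  iPeak <- iStim - 1L + which.max(v[iStim:length(v)])
  vPeak <- v[iPeak]
  if (vPeak - vDias < 5) return(NA_real_)
  thr <- vPeak - fraction * (vPeak - vDias)
  tUp <- NA_real_
  if (iPeak > iStim) {
    up <- which(v[iStim:(iPeak - 1L)] <= thr & v[(iStim + 1L):iPeak] > thr)
    if (length(up)) {
      i <- iStim + up[1L] - 1L
      tUp <- (i - 1L) * dt + (thr - v[i]) / (v[i + 1L] - v[i]) * dt
    }
  }
  if (!is.finite(tUp)) tUp <- (iStim - 1L) * dt
  tDown <- NA_real_
  if (iPeak < length(v)) {
    dn <- which(v[iPeak:(length(v) - 1L)] >= thr &
                  v[(iPeak + 1L):length(v)] < thr)
    if (length(dn)) {
      i <- iPeak + dn[1L] - 1L
      tDown <- (i - 1L) * dt + (thr - v[i]) / (v[i + 1L] - v[i]) * dt
    }
  }
  if (!is.finite(tDown)) return(NA_real_)
  tDown - tUp
}

#' Number of analyzed beats of a protocol
#'
#' Simple protocol arithmetic: total beats minus the transient-discard
#' block.  The standard full-scale protocol (1100 beats, 100 discarded)
#' retains 1000 analyzed beats.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return integer count of analyzed beats.
#' @export
analyzedBeats <- function(config) {
  n <- as.integer(config@beats - config@discard)
  if (n <= 0)
    stop("discarding every beat leaves an empty analysis set")
  n
}

#' Run the pacing protocol over a channel-count grid
#'
#' For every NLCC in \code{config@nlcc} (with NRyR = ratio * NLCC) the
#' stochastic model is paced for \code{beats} cycles, the leading
#' \code{discard} cycles are dropped, and per-beat summaries plus
#' descriptive statistics of the release integral are collected.  A
#' deterministic reference run under the same parameters is always
#' included.  A run that aborts on numerical instability is recorded with
#' its error message and the sweep continues.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param startState starting \linkS4class{CellState}; defaults to the
#'   packaged paced steady state.
#' @param scenario label stored with the results (e.g. "control",
#'   "phi=2"); purely descriptive, the physics is set by \code{config@phi}
#'   and \code{config@eta}.
#' @return a \linkS4class{SweepResult}.
#' @export
runProtocol <- function(config, startState = steadyCellState(),
                        scenario = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  nAna <- analyzedBeats(config)
  if (is.null(scenario))
    scenario <- sprintf("phi=%g,eta=%g", config@phi, config@eta)
  pfile <- if (nzchar(config@parameterFile)) config@parameterFile else NULL
  params <- cellParameters(file = pfile, phi = config@phi, eta = config@eta)
  keep <- (config@discard + 1):config@beats

  runOne <- function(mode, nlcc, seed) {
    res <- runCell(startState, params, nBeats = config@beats, mode = mode,
                   nlcc = nlcc, ratio = config@ratio, dt = config@dt,
                   period = config@period, stimAmplitude = config@stimAmplitude,
                   stimDuration = config@stimDuration, seed = seed)
    res$beats[keep, , drop = FALSE]
  }

  # deterministic reference
  det <- runOne("deterministic", config@nlcc[1], NULL)
  detRef <- data.frame(scenario = scenario,
                       sbar = mean(det$sbar), sbarSD = stats::sd(det$sbar),
                       apd50 = mean(det$apd50, na.rm = TRUE),
                       apd90 = mean(det$apd90, na.rm = TRUE),
                       peakCai = mean(det$peakCai))

  beats <- list()
  summ <- list()
  doStoch <- identical(config@mode, "stochastic")
  for (i in seq_along(config@nlcc)) {
    nl <- config@nlcc[i]
    nr <- as.integer(round(config@ratio * nl))
    b <- if (doStoch) {
      tryCatch(runOne("stochastic", nl, config@seed + 7919L * i),
               error = function(e) e)
    } else det
    if (inherits(b, "error")) {
      summ[[i]] <- data.frame(scenario = scenario, mode = config@mode,
                              nlcc = nl, nryr = nr, n = 0L,
                              mean = NA_real_, median = NA_real_,
                              q25 = NA_real_, q75 = NA_real_, iqr = NA_real_,
                              relativeIQR = NA_real_, detSbar = detRef$sbar,
                              error = conditionMessage(b))
      next
    }
    s <- b$sbar
    beats[[i]] <- data.frame(scenario = scenario, mode = config@mode,
                             nlcc = nl, nryr = nr,
                             beat = seq_len(nrow(b)), sbar = s,
                             apd50 = b$apd50, apd90 = b$apd90,
                             peakCai = b$peakCai, diasCaSR = b$diasCaSR)
    q <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE)
    summ[[i]] <- data.frame(scenario = scenario, mode = config@mode,
                            nlcc = nl, nryr = nr, n = length(s),
                            mean = mean(s), median = q[2], q25 = q[1],
                            q75 = q[3], iqr = q[3] - q[1],
                            relativeIQR = if (q[2] > 0) (q[3] - q[1]) / q[2]
                                          else Inf,
                            detSbar = detRef$sbar, error = "")
  }
  new("SweepResult",
      beats = do.call(rbind, beats),
      summary = do.call(rbind, summ),
      detReference = detRef,
      config = config)
}

#' Dispersion, histogram and modality of a release-integral sample
#'
#' Computes the relative dispersion IQR/median, a Freedman-Diaconis
#' histogram, and a reproducible two-component modality assessment: the
#' sample is split by a two-component location fit (k-means with
#' deterministic quartile initialization) and called bimodal when the
#' component means are separated by more than \code{minSeparation} times
#' the pooled within-component spread AND the minor component holds more
#' than 10% of the sample.  The default separation threshold of 3.5 sits
#' above the value such a split produces on a single Gaussian by
#' construction (about 2.65), so unimodal noise is not flagged.
#'
#' @param x numeric sample of per-beat release integrals (>= 30 values).
#' @param minSeparation separation threshold in pooled-spread units.
#' @param minWeight minimal minor-component weight.
#' @return list with \code{relativeIQR}, \code{histogram} (breaks,
#'   counts), \code{nModes} (1 or 2) and \code{modeLocations}.
#' @export
dispersionAndModes <- function(x, minSeparation = 3.5, minWeight = 0.1) {
  x <- as.numeric(x)
  if (length(x) < 30) stop("at least 30 samples are required")
  if (any(!is.finite(x))) stop("samples must be finite")
  if (max(x) == min(x)) {
    return(list(relativeIQR = 0,
                histogram = list(breaks = c(x[1] - 0.5, x[1] + 0.5),
                                 counts = length(x)),
                nModes = 1L, modeLocations = x[1]))
  }
  md <- stats::median(x)
  relIQR <- if (md != 0) stats::IQR(x) / md else Inf
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  centers <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  res <- list(relativeIQR = relIQR,
              histogram = list(breaks = h$breaks, counts = h$counts))
  if (centers[1] == centers[2]) {
    res$nModes <- 1L
    res$modeLocations <- md
    return(res)
  }
  km <- stats::kmeans(x, centers = matrix(centers, ncol = 1),
                      iter.max = 100)
  ord <- order(km$centers)
  m <- as.numeric(km$centers)[ord]
  nk <- km$size[ord]
  v <- vapply(ord, function(g) {
    xs <- x[km$cluster == g]
    if (length(xs) > 1) stats::var(xs) else 0
  }, numeric(1))
  pooled <- sqrt(sum(nk * v) / sum(nk))
  minorW <- min(nk) / sum(nk)
  bimodal <- pooled > 0 && (m[2] - m[1]) > minSeparation * pooled &&
    minorW > minWeight
  res$nModes <- if (bimodal) 2L else 1L
  res$modeLocations <- if (bimodal) m else md
  res
}

#' Locate the stochastic-to-deterministic transition on a channel-count
#' grid
#'
#' Scans the relative dispersion of the release integral over an NLCC grid
#' (powers of two) and reports the grid value at which the largest
#' fold-reduction between successive points occurs.  A curve whose largest
#' fold-reduction stays below \code{minFold} (e.g. the 1/sqrt(N) decay of
#' pure sampling noise, fold sqrt(2) per octave) is reported as having no
#' transition.
#'
#' @param x a \linkS4class{SweepResult}, or a data.frame with columns
#'   \code{nlcc} and \code{dispersion}.
#' @param minFold smallest fold-reduction accepted as a transition.
#' @return list with \code{transition} (the NLCC value before the largest
#'   collapse, or \code{NA} when absent) and \code{curve} (data.frame
#'   nlcc, dispersion, foldReduction).
#' @export
detectTransition <- function(x, minFold = 3) {
  if (is(x, "SweepResult")) {
    s <- x@summary[x@summary$error == "", ]
    x <- data.frame(nlcc = s$nlcc, dispersion = s$relativeIQR)
  }
  stopifnot(all(c("nlcc", "dispersion") %in% names(x)))
  x <- x[order(x$nlcc), ]
  if (nrow(x) < 4) stop("at least 4 grid points are required")
  n <- nrow(x)
  fold <- c(x$dispersion[-n] / x$dispersion[-1], NA)
  curve <- data.frame(nlcc = x$nlcc, dispersion = x$dispersion,
                      foldReduction = fold)
  best <- which.max(fold[-n])
  transition <- if (length(best) && is.finite(fold[best]) &&
                    fold[best] >= minFold) x$nlcc[best] else NA_real_
  list(transition = transition, curve = curve)
}
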