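# Markov-chain population propagation: binomial/multinomial tau-leaping, an
# exact event-by-event simulator used as a validation oracle, and the
# mean-field occupancy ODE used in deterministic mode.

#' Per-transition success probability over one step
#'
#' For a transition with rate \code{k} (1/ms) held constant over a step of
#' length \code{dt} (ms), the probability that a given channel takes the
#' transition is \code{1 - exp(-k * dt)}.
#'
#' @param k transition rate in 1/ms (vectorized, each >= 0).
#' @param dt step length in ms (> 0).
#' @return probability in [0, 1], monotone increasing in both arguments.
#' @examples
#' transitionProbability(0.060, 0.001)
#' @export
transitionProbability <- function(k, dt) {
  if (any(!is.finite(k)) || any(k < 0))
    stop("transition rate 'k' must be finite and non-negative")
  if (!is.finite(dt) || dt <= 0)
    stop("step length 'dt' must be positive")
  -expm1(-k * dt)
}

# Internal kernel shared by tauLeapStep and the tests: operates on a plain
# integer count vector and an edge list (0-based indices are avoided; edges
# are given as integer source/target columns).  For each source state the
# number of leavers is Binomial(n, 1 - exp(-ktot*dt)) and is split over the
# outgoing transitions in proportion to their rates (multinomial), which
# reproduces the per-transition binomial marginals to O(k*dt) while making
# negative populations structurally impossible.
tauLeapCounts <- function(counts, src, dst, rate, dt) {
  delta <- integer(length(counts))
  for (i in sort(unique(src))) {
    n <- counts[i]
    if (n == 0) next
    sel <- which(src == i)
    ki <- rate[sel]
    ktot <- sum(ki)
    if (ktot == 0) next
    nLeave <- stats::rbinom(1L, n, -expm1(-ktot * dt))
    if (nLeave == 0) next
    moves <- if (length(sel) == 1L) nLeave else
      as.integer(stats::rmultinom(1L, nLeave, ki / ktot))
    delta[i] <- delta[i] - nLeave
    for (m in seq_along(sel))
      delta[dst[sel[m]]] <- delta[dst[sel[m]]] + moves[m]
  }
  counts + delta
}

#' One binomial tau-leaping step of a stochastic channel population
#'
#' Advances integer state occupancies by one step of length \code{dt} with
#' the rates in \code{rates} frozen at the current operating point.  For
#' every source state the total number of leaving channels is drawn from a
#' binomial with success probability \code{1 - exp(-ktot*dt)} (ktot = sum of
#' outgoing rates) and partitioned multinomially over the outgoing
#' transitions, so each per-transition count is marginally binomial to
#' O(k*dt), no state can go negative, and the population total is conserved
#' exactly.
#'
#' @param pop a stochastic-mode \linkS4class{ChannelPopulation}.
#' @param rates a \linkS4class{RateSpec} over the same state set.
#' @param dt step length in ms.
#' @return the advanced \linkS4class{ChannelPopulation}.
#' @export
tauLeapStep <- function(pop, rates, dt) {
  stopifnot(is(pop, "ChannelPopulation"), is(rates, "RateSpec"))
  if (!identical(pop@mode, "stochastic"))
    stop("tauLeapStep requires a stochastic-mode population")
  if (!identical(pop@stateNames, rates@stateNames))
    stop("population and rates must share one state set")
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
  src <- match(rates@from, pop@stateNames)
  dst <- match(rates@to, pop@stateNames)
  newCounts <- tauLeapCounts(pop@counts, src, dst, rates@rate, dt)
  if (any(newCounts < 0) || sum(newCounts) != pop@total)
    stop("internal error: tau-leap produced an invalid population")
  initialize(pop, counts = as.numeric(newCounts))
}

#' Exact stochastic simulation of a small channel population
#'
#' Event-by-event (Gillespie) simulation with rates frozen between events.
#' Intended as a statistically exact oracle for validating the tau-leaping
#' scheme on small systems; it is far too slow for production runs.
#'
#' @param pop a stochastic-mode \linkS4class{ChannelPopulation}.
#' @param rates a \linkS4class{RateSpec}, or a function
#'   \code{function(pop, t)} returning one (rates are then re-evaluated
#'   after every event, i.e. treated as piecewise constant).
#' @param tEnd end time in ms (> 0).
#' @return list with \code{times} (event times, starting at 0),
#'   \code{counts} (matrix of occupancies after each event, one row per
#'   recorded time) and \code{final} (the final population).
#' @export
ssaExact <- function(pop, rates, tEnd) {
  stopifnot(is(pop, "ChannelPopulation"))
  if (!identical(pop@mode, "stochastic"))
    stop("ssaExact requires a stochastic-mode population")
  if (!is.finite(tEnd) || tEnd <= 0) stop("'tEnd' must be positive")
  rateFn <- if (is.function(rates)) rates else function(pop, t) rates
  t <- 0
  counts <- pop@counts
  times <- t
  hist <- list(counts)
  repeat {
    rs <- rateFn(initialize(pop, counts = counts), t)
    src <- match(rs@from, pop@stateNames)
    dst <- match(rs@to, pop@stateNames)
    prop <- rs@rate * counts[src]          # propensity of each transition
    a0 <- sum(prop)
    if (a0 <= 0) break
    t <- t + stats::rexp(1L, a0)
    if (t >= tEnd) break
    e <- sample.int(length(prop), 1L, prob = prop / a0)
    counts[src[e]] <- counts[src[e]] - 1
    counts[dst[e]] <- counts[dst[e]] + 1
    times <- c(times, t)
    hist[[length(hist) + 1L]] <- counts
  }
  mat <- do.call(rbind, hist)
  colnames(mat) <- pop@stateNames
  list(times = times, counts = mat,
       final = initialize(pop, counts = as.numeric(counts)))
}

#' One explicit-Euler step of the mean-field occupancy equation
#'
#' Advances occupancy fractions by the master equation
#' dx_i/dt = sum_j (k_ji x_j - k_ij x_i): the deterministic limit of the
#' channel population.
#'
#' @param fractions named numeric vector of occupancy fractions (or a
#'   deterministic-mode \linkS4class{ChannelPopulation}).
#' @param rates a \linkS4class{RateSpec}.
#' @param dt step length in ms.
#' @return object of the same kind as \code{fractions}, advanced by one
#'   step.  The fraction sum is preserved to 1e-10 per step; a step that
#'   drives any fraction outside [-1e-9, 1+1e-9] aborts with an instability
#'   error advising a smaller \code{dt}.
#' @export
deterministicStep <- function(fractions, rates, dt) {
  stopifnot(is(rates, "RateSpec"))
  if (!is.finite(dt) || dt <= 0) stop("'dt' must be positive")
  asPop <- is(fractions, "ChannelPopulation")
  x <- if (asPop) {
    if (!identical(fractions@mode, "deterministic"))
      stop("deterministicStep requires deterministic-mode occupancies")
    stats::setNames(fractions@counts, fractions@stateNames)
  } else fractions
  if (!identical(names(x), rates@stateNames))
    stop("fractions must be named by the scheme's state set, in order")
  Q <- rateMatrix(rates)
  xNew <- as.numeric(x + dt * crossprod(Q, x))
  if (abs(sum(xNew) - sum(x)) > 1e-10)
    stop("internal error: occupancy sum not preserved")
  if (any(xNew < -1e-9) || any(xNew > 1 + 1e-9))
    stop("occupancy ODE unstable at this dt; use a smaller step")
  if (asPop) initialize(fractions, counts = xNew)
  else stats::setNames(xNew, names(x))
}

#' Steady-state occupancy of a Markov scheme
#'
#' Solves the linear balance equations Q^T x = 0, sum(x) = 1 directly;
#' used as an independent closed-form reference for the iterated engines.
#'
#' @param rates a \linkS4class{RateSpec}.
#' @return named numeric vector of equilibrium fractions.
#' @export
steadyStateOccupancy <- function(rates) {
  Q <- rateMatrix(rates)
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  x <- qr.solve(A, b)
  stats::setNames(as.numeric(x), rates@stateNames)
}
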