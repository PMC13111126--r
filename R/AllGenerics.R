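#' @rdname ChannelPopulation-class
#' @param stateNames ordered character vector of state labels.
#' @param counts integer counts (stochastic) or fractions (deterministic).
#' @param mode "stochastic" or "deterministic".
#' @return a validated \linkS4class{ChannelPopulation}.
#' @examples
#' channelPopulation(c("C", "O"), c(10, 0))
#' channelPopulation(c("C", "O"), c(0.8, 0.2), mode = "deterministic")
#' @export
channelPopulation <- function(stateNames, counts, mode = "stochastic") {
  counts <- as.numeric(counts)
  total <- if (identical(mode, "stochastic")) sum(counts) else 1
  new("ChannelPopulation", stateNames = as.character(stateNames),
      counts = counts, total = total, mode = mode)
}

#' @rdname RateSpec-class
#' @param from,to source/target state names of each directed transition.
#' @param rate transition rates in 1/ms.
#' @param stateNames the scheme state set; defaults to the states appearing
#'   in \code{from}/\code{to}.
#' @return a validated \linkS4class{RateSpec}.
#' @examples
#' rateSpec(from = "C", to = "O", rate = 0.5, stateNames = c("C", "O"))
#' @export
rateSpec <- function(from, to, rate, stateNames = NULL) {
  if (is.null(stateNames)) stateNames <- unique(c(from, to))
  new("RateSpec", stateNames = as.character(stateNames),
      from = as.character(from), to = as.character(to),
      rate = as.numeric(rate))
}

#' Occupancy fractions of a channel population
#'
#' @param pop a \linkS4class{ChannelPopulation}.
#' @return named numeric vector of occupancy fractions summing to one.
#' @export
occupancy <- function(pop) {
  stopifnot(is(pop, "ChannelPopulation"))
  x <- pop@counts
  if (identical(pop@mode, "stochastic")) x <- x / pop@total
  stats::setNames(x, pop@stateNames)
}

#' State names of a channel population or rate specification
#' @param x a \linkS4class{ChannelPopulation} or \linkS4class{RateSpec}.
#' @export
stateNames <- function(x) x@stateNames

#' Channel counts of a stochastic population
#' @param pop a \linkS4class{ChannelPopulation}.
#' @export
channelCounts <- function(pop) {
  stopifnot(is(pop, "ChannelPopulation"))
  stats::setNames(pop@counts, pop@stateNames)
}

#' Total number of channels
#' @param pop a \linkS4class{ChannelPopulation}.
#' @export
channelTotal <- function(pop) pop@total

#' Transition-rate generator matrix of a RateSpec
#'
#' Entry [i, j] (i != j) is the rate of the i -> j transition; the diagonal
#' carries minus the total exit rate, so columnsums of the transpose vanish
#' and \code{Q} can be used directly in the occupancy master equation
#' dx/dt = Q^T x.
#'
#' @param rates a \linkS4class{RateSpec}.
#' @return square numeric matrix with dimnames from the state set.
#' @export
rateMatrix <- function(rates) {
  stopifnot(is(rates, "RateSpec"))
  s <- rates@stateNames
  Q <- matrix(0, length(s), length(s), dimnames = list(s, s))
  for (e in seq_along(rates@from))
    Q[rates@from[e], rates@to[e]] <- Q[rates@from[e], rates@to[e]] +
      rates@rate[e]
  diag(Q) <- -rowSums(Q)
  Q
}
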