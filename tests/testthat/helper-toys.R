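# Small Markov schemes and states shared across the test files.

twoStateRates <- function(k12 = 0.4, k21 = 0.1) {
  rateSpec(c("A", "B"), c("B", "A"), c(k12, k21), stateNames = c("A", "B"))
}

# cyclic 3-state toy used for the tau-leap vs exact-simulation comparison
threeStateRates <- function() {
  rateSpec(from = c("A", "B", "B", "C", "C", "A"),
           to   = c("B", "A", "C", "B", "A", "C"),
           rate = c(0.8, 0.2, 0.5, 0.3, 0.1, 0.05),
           stateNames = c("A", "B", "C"))
}

# deterministic occupancy propagation of a frozen scheme (independent of
# the engine under test: direct matrix-exponential-free Euler at fine dt)
relaxOccupancy <- function(x0, rates, tEnd, dt = 1e-3) {
  x <- x0
  Q <- rateMatrix(rates)
  for (i in seq_len(round(tEnd / dt))) x <- x + dt * as.numeric(crossprod(Q, x))
  x
}

# a mid-plateau cell state (used where a depolarized operating point is
# needed); derived from the packaged steady state by a partial beat and
# cached across tests
.plateauCache <- new.env()
plateauState <- function() {
  if (is.null(.plateauCache$s))
    .plateauCache$s <- runCell(steadyCellState(), cellParameters(),
                               nBeats = 1, mode = "deterministic",
                               period = 120)$finalState
  .plateauCache$s
}
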