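# Markov-chain population engine: tau-leaping, the exact event-by-event
# oracle, and the mean-field occupancy ODE.

test_that("transition probability follows 1 - exp(-k dt) and rejects bad input", {
  expect_equal(transitionProbability(0, 0.001), 0)
  expect_equal(transitionProbability(1e9, 0.001), 1, tolerance = 1e-12)
  # closed form at the RyR closing rate k3 = 0.060 / ms
  expect_equal(transitionProbability(0.060, 0.001), 5.99982000359e-05,
               tolerance = 1e-9)
  # monotone in both arguments
  ks <- c(0.01, 0.1, 1, 10)
  expect_true(all(diff(transitionProbability(ks, 0.5)) > 0))
  expect_true(all(diff(sapply(c(0.1, 0.5, 2), function(dt)
    transitionProbability(1, dt))) > 0))
  expect_error(transitionProbability(-1, 0.001), "non-negative")
  expect_error(transitionProbability(1, 0), "positive")
})

test_that("tau-leap step conserves channels exactly and keeps counts non-negative", {
  set.seed(42)
  rates <- threeStateRates()
  pop <- channelPopulation(c("A", "B", "C"), c(50, 30, 20))
  for (i in 1:500) {
    pop <- tauLeapStep(pop, rates, 0.05)   # coarse dt stresses the scheme
    expect_identical(sum(channelCounts(pop)), 100)
    expect_true(all(channelCounts(pop) >= 0))
  }
})

test_that("tau-leap leaves the population unchanged under zero rates", {
  rates <- rateSpec(c("A", "B"), c("B", "A"), c(0, 0),
                    stateNames = c("A", "B"))
  pop <- channelPopulation(c("A", "B"), c(7, 3))
  set.seed(1)
  expect_identical(channelCounts(tauLeapStep(pop, rates, 0.001)),
                   channelCounts(pop))
})

test_that("per-transition tau-leap counts match binomial moments", {
  set.seed(7)
  n <- 10000L; k <- 1; dt <- 0.001
  p <- 1 - exp(-k * dt)
  movers <- replicate(10000, {
    caruSim:::tauLeapCounts(c(n, 0L), 1L, 2L, k, dt)[2]
  })
  m <- n * p                       # approximately 9.995
  v <- n * p * (1 - p)
  expect_lt(abs(mean(movers) - m), 3 * sqrt(v / length(movers)))
  # sample variance of a binomial, allow 3 standard errors of the variance
  seVar <- v * sqrt(2 / (length(movers) - 1))
  expect_lt(abs(var(movers) - v), 4 * seVar)
})

test_that("multinomial partition reproduces per-edge binomial marginals", {
  set.seed(11)
  # two competing edges; marginal movers on each must match Binomial(n, p_i)
  kA <- 2; kB <- 0.5; dt <- 0.01; n <- 2000L
  draws <- t(replicate(4000, {
    caruSim:::tauLeapCounts(c(n, 0L, 0L), c(1L, 1L), c(2L, 3L),
                            c(kA, kB), dt)[2:3]
  }))
  ktot <- kA + kB
  pTot <- 1 - exp(-ktot * dt)
  for (i in 1:2) {
    pi <- pTot * c(kA, kB)[i] / ktot    # marginal to O(k dt)
    m <- n * pi; v <- n * pi * (1 - pi)
    expect_lt(abs(mean(draws[, i]) - m), 4 * sqrt(v / nrow(draws)) + n * pi * ktot * dt * 0.01)
  }
})

test_that("exact simulation reproduces analytic exponential decay", {
  set.seed(3)
  k <- 0.5; tEnd <- 1
  rates <- rateSpec("A", "B", k, stateNames = c("A", "B"))
  n <- 100L
  left <- replicate(500, {
    pop <- channelPopulation(c("A", "B"), c(n, 0))
    channelCounts(ssaExact(pop, rates, tEnd)$final)[["A"]]
  })
  m <- n * exp(-k * tEnd)
  v <- n * exp(-k * tEnd) * (1 - exp(-k * tEnd))
  expect_lt(abs(mean(left) - m), 3 * sqrt(v / length(left)))
})

test_that("exact simulation with zero rates has no events", {
  rates <- rateSpec(c("A", "B"), c("B", "A"), c(0, 0),
                    stateNames = c("A", "B"))
  pop <- channelPopulation(c("A", "B"), c(5, 5))
  out <- ssaExact(pop, rates, 10)
  expect_identical(length(out$times), 1L)
  expect_identical(channelCounts(out$final), channelCounts(pop))
  expect_error(ssaExact(pop, rates, -1), "positive")
})

test_that("tau-leap and exact simulation agree in distribution on a 3-state toy", {
  set.seed(19)
  rates <- threeStateRates()
  n <- 30L; tEnd <- 0.5; dt <- 0.001
  src <- match(rates@from, rates@stateNames)
  dst <- match(rates@to, rates@stateNames)
  nrep <- 300
  tauA <- replicate(nrep, {
    counts <- c(n, 0L, 0L)
    for (i in seq_len(tEnd / dt))
      counts <- caruSim:::tauLeapCounts(counts, src, dst, rates@rate, dt)
    counts[1]
  })
  ssaA <- replicate(nrep, {
    pop <- channelPopulation(c("A", "B", "C"), c(n, 0, 0))
    channelCounts(ssaExact(pop, rates, tEnd)$final)[["A"]]
  })
  # two-sample comparison at the 1% level
  expect_gt(suppressWarnings(ks.test(tauA, ssaA))$p.value, 0.01)
})

test_that("deterministic stepping reaches the analytic two-state equilibrium", {
  rates <- twoStateRates(0.4, 0.1)
  x <- c(A = 1, B = 0)
  for (i in 1:20000) x <- deterministicStep(x, rates, 0.01)
  expect_equal(unname(x[["B"]]), 0.4 / 0.5, tolerance = 1e-6)
  expect_equal(sum(x), 1, tolerance = 1e-10)
  # identity under zero rates
  z <- rateSpec(c("A", "B"), c("B", "A"), c(0, 0), stateNames = c("A", "B"))
  expect_identical(deterministicStep(c(A = 0.3, B = 0.7), z, 0.1),
                   c(A = 0.3, B = 0.7))
})

test_that("deterministic step aborts with advice when dt is too large", {
  rates <- twoStateRates(1000, 0)
  expect_error(deterministicStep(c(A = 1, B = 0), rates, 0.01),
               "smaller")
})

test_that("deterministic relaxation error scales like O(dt)", {
  rates <- twoStateRates(0.4, 0.1)
  exact <- function(t) 0.8 * (1 - exp(-0.5 * t))  # occupancy of B from A
  errAt <- function(dt) {
    x <- c(A = 1, B = 0)
    for (i in seq_len(round(2 / dt))) x <- deterministicStep(x, rates, dt)
    abs(x[["B"]] - exact(2))
  }
  e1 <- errAt(0.02); e2 <- errAt(0.002)
  expect_lt(e2, e1 / 5)   # tenfold dt reduction: at least ~5x error drop
})

test_that("stochastic trajectories are bit-reproducible for a fixed seed", {
  rates <- threeStateRates()
  run <- function(seed) {
    set.seed(seed)
    pop <- channelPopulation(c("A", "B", "C"), c(40, 5, 5))
    out <- matrix(0, 50, 3)
    for (i in 1:50) {
      pop <- tauLeapStep(pop, rates, 0.01)
      out[i, ] <- channelCounts(pop)
    }
    out
  }
  expect_identical(run(99L), run(99L))
  expect_false(identical(run(99L), run(100L)))
})

test_that("population and rate classes enforce their invariants", {
  expect_error(channelPopulation(c("A", "B"), c(-1, 2)), "non-negative")
  expect_error(channelPopulation(c("A", "B"), c(0.5, 0.2)), "integers")
  expect_error(channelPopulation(c("A", "B"), c(0.5, 0.2),
                                 mode = "deterministic"), "sum to 1")
  expect_error(rateSpec("A", "A", 1, stateNames = "A"), "elf-transitions")
  expect_error(rateSpec("A", "B", -2, stateNames = c("A", "B")),
               "non-negative")
  expect_error(rateSpec("A", "Z", 1, stateNames = c("A", "B")), "belong")
})
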