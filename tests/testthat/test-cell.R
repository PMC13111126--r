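# Whole-cell model: resting stability, current cross-checks between the
# R formulas and the compiled engine, pacing morphology, reproducibility,
# and the stochastic-to-deterministic consistency of one step.

test_that("background currents vanish when all conductances are zeroed", {
  p <- cellParameters(GNa = 0, GK1 = 0, Gto = 0, GKr = 0, GKs = 0,
                      PNaK = 0, GpK = 0, GbNa = 0)
  bc <- backgroundCurrents(initialCellState(), p)
  expect_true(all(abs(unlist(bc)) == 0))
})

test_that("inward rectifier is outward above the potassium reversal", {
  st <- initialCellState()
  p <- cellParameters()
  EK <- p$Rgas * p$Temp / p$Faraday * log(p$Ko / st@Ki)
  stUp <- st; stUp@V <- EK + 20
  expect_gt(backgroundCurrents(stUp, p)$IK1, 0)
  stDn <- st; stDn@V <- EK - 10
  expect_lt(backgroundCurrents(stDn, p)$IK1, 0)
})

test_that("net membrane current is near zero at the resting state", {
  cur <- cellCurrents(initialCellState(), cellParameters())
  expect_lt(abs(cur$Iion), 0.05)   # |dV/dt| < 0.05 mV/ms without stimulus
})

test_that("the resting state is stable over 1e4 unstimulated steps", {
  # let the published resting values settle briefly, then require that a
  # further 1e4 unstimulated steps barely move the membrane potential
  settled <- runCell(initialCellState(), cellParameters(), nBeats = 1,
                     mode = "deterministic", period = 500,
                     stimAmplitude = 0)$finalState
  res <- runCell(settled, cellParameters(), nBeats = 1,
                 mode = "deterministic", period = 10, stimAmplitude = 0)
  expect_lt(abs(res$finalState@V - settled@V), 0.1)
})

test_that("engine currents match the R module formulas at arbitrary states", {
  p <- cellParameters(phi = 1.7, eta = 0.6)
  for (st in list(initialCellState(), plateauState())) {
    cur <- cellCurrents(st, p)
    o <- occupancy(st@lcc)[["O"]]
    expect_equal(cur$ICaL, icalCurrent(o, st@V, st@CassFree,
                                       lccParameters(p)), tolerance = 1e-12)
    expect_equal(cur$Irel,
                 irelFlux(occupancy(st@ryr)[["O"]], st@CaSRFree,
                          st@CassFree, p$Vrel), tolerance = 1e-12)
    expect_equal(cur$Iup, iup(st@CaiFree, p$phi, p), tolerance = 1e-12)
    expect_equal(cur$Ileak, ileak(st@CaSRFree, st@CaiFree, p$Vleak))
    expect_equal(cur$Ixfer, ixfer(st@CassFree, st@CaiFree, p$Vxfer))
    expect_equal(cur$INaCa, incx(st@V, st@Nai, st@CaiFree, p),
                 tolerance = 1e-12)
    expect_equal(cur$IpCa, ipca(st@CaiFree, p), tolerance = 1e-12)
    expect_equal(cur$IbCa, ibca(st@V, st@CaiFree, p), tolerance = 1e-12)
  }
})

test_that("one engine step advances the channel populations like the R engine", {
  st <- plateauState()
  p <- cellParameters()
  one <- runCell(st, p, nBeats = 1, mode = "deterministic", period = 0.001,
                 stimAmplitude = 0)
  lccR <- deterministicStep(occupancy(st@lcc),
                            lccRates(st@V, st@CassFree, lccParameters(p)),
                            0.001)
  ryrR <- deterministicStep(occupancy(st@ryr),
                            ryrRates(st@CassFree, st@CaSRFree,
                                     ryrParameters(p)), 0.001)
  expect_equal(unname(occupancy(one$finalState@lcc)), unname(lccR),
               tolerance = 1e-12)
  expect_equal(unname(occupancy(one$finalState@ryr)), unname(ryrR),
               tolerance = 1e-12)
})

test_that("a stimulated beat has normal action-potential morphology", {
  res <- runCell(steadyCellState(), cellParameters(), nBeats = 1,
                 mode = "deterministic", traceEvery = 100)
  tr <- res$trace
  expect_gt(max(tr$V), 0)                      # overshoot
  expect_lt(tail(tr$V, 2)[1], -70)             # repolarized within the cycle
  b <- res$beats
  expect_gt(b$apd90, b$apd50)
  expect_true(b$apd90 > 200 && b$apd90 < 450)
  expect_gt(b$peakCai, 5 * res$finalState@CaiFree)  # clear calcium transient
})

test_that("stimulus is a rectangular pulse with the configured timing", {
  expect_identical(stimulusCurrent(500), 0)             # mid-diastole
  expect_identical(stimulusCurrent(10.5), 52)           # inside the pulse
  expect_identical(stimulusCurrent(1010.5), 52)         # next cycle
  onsets <- seq(10.2, by = 1000, length.out = 1100)
  expect_identical(sum(stimulusCurrent(onsets) > 0), 1100L)  # 1100 pulses
})

test_that("stochastic runs are bit-reproducible for a fixed seed", {
  st <- steadyCellState()
  p <- cellParameters()
  a <- runCell(st, p, nBeats = 1, mode = "stochastic", nlcc = 64, ratio = 5,
               seed = 7, period = 250)
  b <- runCell(st, p, nBeats = 1, mode = "stochastic", nlcc = 64, ratio = 5,
               seed = 7, period = 250)
  c <- runCell(st, p, nBeats = 1, mode = "stochastic", nlcc = 64, ratio = 5,
               seed = 8, period = 250)
  expect_identical(flattenState(a$finalState), flattenState(b$finalState))
  expect_identical(a$beats$sbar, b$beats$sbar)
  expect_false(identical(flattenState(a$finalState),
                         flattenState(c$finalState)))
})

test_that("channel number is conserved through a full stochastic beat", {
  res <- runCell(steadyCellState(), cellParameters(), nBeats = 1,
                 mode = "stochastic", nlcc = 50, ratio = 5, seed = 3)
  # occupancies returned as counts/N must sum to one exactly
  expect_equal(sum(occupancy(res$finalState@lcc)), 1, tolerance = 1e-12)
  expect_equal(sum(occupancy(res$finalState@ryr)), 1, tolerance = 1e-12)
})

test_that("state snapshots round-trip through the text format", {
  st <- plateauState()
  f <- tempfile(fileext = ".tsv")
  writeCellState(st, f)
  st2 <- readCellState(f)
  expect_equal(flattenState(st2), flattenState(st), tolerance = 1e-15)
  unlink(f)
})

test_that("flatten/inflate are inverse maps", {
  st <- initialCellState()
  expect_equal(flattenState(inflateState(flattenState(st))),
               flattenState(st))
})
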