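# Seven-state L-type channel scheme: rate evaluation, eta/phi scaling,
# GHK current, and the channel's voltage-clamp behavior.

edgeRate <- function(rs, from, to) {
  rs@rate[rs@from == from & rs@to == to]
}

test_that("eta scales the voltage-inactivation rates exactly linearly", {
  ctrl <- lccRates(-10, 0.001, lccParameters(cellParameters()))
  half <- lccRates(-10, 0.001, lccParameters(cellParameters(eta = 0.5)))
  etaEdges <- list(c("O", "If2"), c("If2", "If"), c("Cp", "IC"))
  for (e in etaEdges)
    expect_equal(edgeRate(half, e[1], e[2]), 0.5 * edgeRate(ctrl, e[1], e[2]))
  # every other edge is untouched
  others <- !(paste(ctrl@from, ctrl@to) %in%
                sapply(etaEdges, paste, collapse = " "))
  expect_equal(half@rate[others], ctrl@rate[others])
})

test_that("phi scales only the final opening transition", {
  ctrl <- lccRates(5, 0.01, lccParameters(cellParameters()))
  dbl <- lccRates(5, 0.01, lccParameters(cellParameters(phi = 2)))
  expect_equal(edgeRate(dbl, "Cp", "O"), 2 * edgeRate(ctrl, "Cp", "O"))
  others <- !(dbl@from == "Cp" & dbl@to == "O")
  expect_equal(dbl@rate[others], ctrl@rate[others])
})

test_that("control scheme is recovered at eta = phi = 1", {
  a <- lccRates(-30, 0.0005, lccParameters(cellParameters()))
  b <- lccRates(-30, 0.0005, lccParameters(cellParameters(eta = 1, phi = 1)))
  expect_identical(a@rate, b@rate)
})

test_that("LCC rates are finite and non-negative over the physical range", {
  p <- lccParameters(cellParameters())
  for (V in seq(-100, 80, by = 20))
    for (Cass in c(0, 1e-4, 0.01, 1, 10)) {
      rs <- lccRates(V, Cass, p)
      expect_true(all(is.finite(rs@rate)) && all(rs@rate >= 0))
    }
})

test_that("L-type current is proportional to the open fraction and vanishes appropriately", {
  p <- lccParameters(cellParameters())
  expect_identical(icalCurrent(0, 0, 0.001, p), 0)
  expect_equal(icalCurrent(0.6, -20, 0.001, p),
               2 * icalCurrent(0.3, -20, 0.001, p))
  # zero of the GHK driving term: 0.25 Cass e^x = Cao
  V <- 30
  x <- 2 * (V - p$VofsCaL) * p$Faraday / (p$Rgas * p$Temp)
  CassZero <- p$Cao / (0.25 * exp(x))
  expect_equal(icalCurrent(1, V, CassZero, p), 0, tolerance = 1e-12)
})

test_that("removable singularity at deltaV = 0 is handled by the series limit", {
  p <- lccParameters(cellParameters())
  atOfs <- icalCurrent(0.5, p$VofsCaL, 0.01, p)
  near1 <- icalCurrent(0.5, p$VofsCaL + 1e-4, 0.01, p)
  near2 <- icalCurrent(0.5, p$VofsCaL - 1e-4, 0.01, p)
  # the symmetric average cancels the physical slope; what remains is the
  # series-vs-direct evaluation error
  expect_equal(atOfs, (near1 + near2) / 2, tolerance = 1e-9)
  expect_lt(abs(near1 - atOfs) / abs(atOfs), 1e-4)
  expect_true(is.finite(atOfs))
})

clampOpenTrace <- function(V, Cass, tEnd = 50, dt = 0.005,
                           params = lccParameters(cellParameters())) {
  rs <- lccRates(V, Cass, params)
  x <- stats::setNames(c(1, 0, 0, 0, 0, 0, 0), lccStateNames())
  out <- numeric(round(tEnd / dt))
  for (i in seq_along(out)) {
    x <- deterministicStep(x, rs, dt)
    out[i] <- x[["O"]]
  }
  out
}

test_that("voltage-clamp open fraction shows activation then inactivation", {
  tr <- clampOpenTrace(10, 0.0002)
  pk <- which.max(tr)
  expect_gt(max(tr), 0.2)
  expect_gt(pk, 5)                      # finite activation delay
  expect_lt(tr[length(tr)], 0.8 * max(tr))  # decays past the peak
})

test_that("raising subspace calcium accelerates inactivation (CDI)", {
  lo <- clampOpenTrace(10, 0.0002)
  hi <- clampOpenTrace(10, 1.0)
  expect_lt(tail(hi, 1) / max(hi), tail(lo, 1) / max(lo))
})

test_that("peak inward current is largest at intermediate clamp voltages", {
  p <- lccParameters(cellParameters())
  peakI <- sapply(c(-40, 0, 60), function(V) {
    tr <- clampOpenTrace(V, 0.0002, tEnd = 30, params = p)
    min(icalCurrent(max(tr), V, 0.0002, p))
  })
  expect_lt(peakI[2], peakI[1])   # stronger inward at 0 than at -40
  expect_lt(peakI[2], peakI[3])   # and than at +60
})

test_that("stochastic mean open fraction matches the deterministic limit", {
  set.seed(23)
  p <- lccParameters(cellParameters())
  rs <- lccRates(0, 0.0005, p)
  det <- steadyStateOccupancy(rs)[["O"]]
  n <- 10000L
  src <- match(rs@from, rs@stateNames)
  dst <- match(rs@to, rs@stateNames)
  # start at the deterministic equilibrium, average the open count
  counts <- as.integer(round(steadyStateOccupancy(rs) * n))
  counts[1] <- counts[1] + (n - sum(counts))
  openSum <- 0
  nSteps <- 1000L
  for (i in seq_len(nSteps)) {
    counts <- caruSim:::tauLeapCounts(counts, src, dst, rs@rate, 0.01)
    openSum <- openSum + counts[3]
  }
  meanOpen <- openSum / nSteps / n
  se <- sqrt(det * (1 - det) / n)   # single-snapshot SE (conservative floor)
  expect_lt(abs(meanOpen - det), max(3 * se, 0.02 * det))
})
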