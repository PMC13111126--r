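# Three-compartment calcium cycling: buffering, fluxes, sarcolemmal
# currents, and the structural conservation property.

test_that("buffering quadratic round-trips with the forward relation", {
  expect_identical(bufferedFree(0, 0.2, 0.001), 0)
  expect_equal(bufferedFree(5, 0, 0.3), 5)          # no buffer
  set.seed(4)
  for (i in 1:200) {
    free <- runif(1, 0, 10); Buf <- runif(1, 0, 20); Kbuf <- runif(1, 1e-4, 1)
    total <- totalFromFree(free, Buf, Kbuf)
    expect_equal(bufferedFree(total, Buf, Kbuf), free, tolerance = 1e-10)
  }
  expect_error(bufferedFree(-1, 0.2, 0.001), "non-negative")
})

test_that("SERCA uptake saturates and shifts affinity with phi", {
  p <- cellParameters()
  expect_equal(iup(1e6, 1, p), p$Vmaxup, tolerance = 1e-9)
  expect_equal(iup(p$Kup, 1, p), p$Vmaxup / 2)          # half-saturation
  expect_equal(iup(p$Kup / 2, 2, p), p$Vmaxup / 2)      # Kup/phi shifts
  expect_identical(iup(0, 1, p), 0)
  x <- seq(1e-5, 0.01, length.out = 50)
  expect_true(all(diff(iup(x, 1, p)) > 0))
  expect_true(all(iup(x, 2, p) > iup(x, 1, p)))         # monotone in phi
})

test_that("leak and transfer fluxes are linear in their gradients", {
  expect_identical(ileak(3, 3, 0.00036), 0)
  expect_identical(ixfer(0.001, 0.001, 0.0038), 0)
  expect_gt(ileak(3, 0.001, 0.00036), 0)
  expect_lt(ixfer(0.0001, 0.001, 0.0038), 0)
  expect_equal(ileak(3, 1, 2 * 0.00036), 2 * ileak(3, 1, 0.00036))
  expect_equal(ixfer(1, 0, 2 * 0.0038), 2 * ixfer(1, 0, 0.0038))
})

test_that("NCX reverses at its equilibrium condition", {
  p <- cellParameters()
  V <- -20; Nai <- 10
  FRT <- p$Faraday / (p$Rgas * p$Temp)
  # solve the numerator of the exchanger for the reversal Cai
  CaiRev <- exp(p$gammaNCX * V * FRT) * Nai^3 * p$Cao /
    (exp((p$gammaNCX - 1) * V * FRT) * p$Nao^3 * p$alphaNCX)
  expect_equal(incx(V, Nai, CaiRev, p), 0, tolerance = 1e-12)
  expect_gt(incx(V, Nai, CaiRev / 10, p), 0)
  expect_lt(incx(V, Nai, CaiRev * 10, p), 0)
})

test_that("sarcolemmal pump and background current behave canonically", {
  p <- cellParameters()
  expect_equal(ipca(p$KpCa, p), p$GpCa / 2)     # half-max at KpCa
  ECa <- p$Rgas * p$Temp / (2 * p$Faraday) * log(p$Cao / 0.0001)
  expect_equal(ibca(ECa, 0.0001, p), 0, tolerance = 1e-12)
  expect_gt(ibca(ECa + 10, 0.0001, p), 0)
})

test_that("all-zero fluxes give zero calcium derivatives", {
  p <- cellParameters()
  st <- list(CaiFree = 0, CaSRFree = 0, CassFree = 0)
  d <- calciumDerivatives(st, ICaL = 0, Irel = 0, INaCa = 0, IpCa = 0,
                          IbCa = 0, phi = 1, params = p)
  expect_equal(unname(d), c(0, 0, 0))
})

test_that("pure uptake moves calcium antisymmetrically between cytosol and SR", {
  p <- cellParameters()
  st <- list(CaiFree = 0.001, CaSRFree = 0.001, CassFree = 0.001)
  pz <- cellParameters(Vleak = 0, Vxfer = 0)
  d <- calciumDerivatives(st, 0, 0, 0, 0, 0, phi = 1, params = pz)
  expect_gt(d[["dCaSR"]], 0)
  expect_equal(d[["dCai"]] * p$Vc, -d[["dCaSR"]] * p$Vsr, tolerance = 1e-12)
  expect_identical(d[["dCass"]], 0)
})

test_that("volume-weighted total calcium is conserved without sarcolemmal fluxes", {
  p <- cellParameters()
  # start from an excited configuration so every internal flux is active
  free <- c(CaiFree = 0.001, CaSRFree = 2.5, CassFree = 0.5)
  tot <- c(totalFromFree(free[1], p$Bufc, p$Kbufc),
           totalFromFree(free[2], p$Bufsr, p$Kbufsr),
           totalFromFree(free[3], p$Bufss, p$Kbufss))
  weight <- c(p$Vc, p$Vsr, p$Vss)
  total0 <- sum(weight * tot)
  dt <- 0.01
  ryrOpen <- 0.1
  for (i in 1:100000) {
    st <- list(CaiFree = free[[1]], CaSRFree = free[[2]], CassFree = free[[3]])
    Irel <- irelFlux(ryrOpen, free[[2]], free[[3]], p$Vrel)
    d <- calciumDerivatives(st, ICaL = 0, Irel = Irel, INaCa = 0, IpCa = 0,
                            IbCa = 0, phi = 1, params = p)
    tot <- tot + dt * unname(d)
    free <- c(bufferedFree(tot[1], p$Bufc, p$Kbufc),
              bufferedFree(tot[2], p$Bufsr, p$Kbufsr),
              bufferedFree(tot[3], p$Bufss, p$Kbufss))
  }
  drift <- abs(sum(weight * tot) - total0) / total0
  expect_lt(drift, 1e-4)    # < 0.01% over 1e5 steps
})

test_that("fluxes are continuous in their arguments over physical ranges", {
  p <- cellParameters()
  # refining the grid should shrink the largest jump proportionally
  u1 <- iup(seq(1e-6, 0.05, length.out = 2000), 1, p)
  u2 <- iup(seq(1e-6, 0.05, length.out = 4000), 1, p)
  ratio <- max(abs(diff(u1))) / max(abs(diff(u2)))
  expect_gt(ratio, 1.5); expect_lt(ratio, 2.5)
  v <- seq(-90, 60, length.out = 400)
  nc <- incx(v, 8, 0.0002, p)
  expect_true(all(is.finite(nc)))
  expect_true(all(abs(diff(nc)) < 0.05))
})
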