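test_that("similarity reduction of air has four unit eigenvalues", {
  inst <- buildInstrument()
  b0 <- instrumentA(inst) %*% instrumentW(inst)
  C <- similarityReduce(b0, b0)
  ev <- muellerpol:::kernelEigenvalues(C)
  expect_equal(sort(Re(ev)), rep(1, 4), tolerance = 1e-10)
  expect_lt(max(abs(Im(ev))), 1e-10)
})

test_that("reduction spectra identify polarizer and retarder references", {
  inst <- buildInstrument()
  b0 <- instrumentA(inst) %*% instrumentW(inst)
  bref <- function(M) instrumentA(inst) %*% M %*% instrumentW(inst)
  ## quarter-wave plate at 45 deg: complex pair exp(+/- i pi/2), double 1
  Cq <- similarityReduce(b0, bref(makeLinearRetarder(90, 45)))
  fit <- fitReferenceParameters(Cq, list(kind = "retarder",
                                         retardance = 90, axis = 45))
  expect_equal(fit$retardance, 90, tolerance = 1e-8)
  expect_equal(fit$tau, 1, tolerance = 1e-8)
  ## retarder with true retardance 87 under nominal 90
  C87 <- similarityReduce(b0, bref(makeLinearRetarder(87, 10)))
  fit87 <- fitReferenceParameters(C87, list(kind = "retarder",
                                            retardance = 90, axis = 10))
  expect_equal(fit87$retardance, 87, tolerance = 1e-8)
  ## partial polarizer q, r recovered to high precision
  Cp <- similarityReduce(b0, bref(makeLinearDiattenuator(0.95, 0.02, 30)))
  fitp <- fitReferenceParameters(Cp, list(kind = "polarizer", axis = 30))
  expect_equal(fitp$q, 0.95, tolerance = 1e-9)
  expect_equal(fitp$r, 0.02, tolerance = 1e-9)
  ## pattern mismatch: a QWP fitted as a polarizer must error
  expect_error(fitReferenceParameters(Cq, list(kind = "polarizer", axis = 0)),
               "inconsistent")
  ## and a polarizer fitted as a retarder must error
  expect_error(fitReferenceParameters(Cp, list(kind = "retarder",
                                               retardance = 90, axis = 30)),
               "inconsistent")
})

test_that("fitted reference parameters are invariant to the axis angle", {
  inst <- buildInstrument()
  b0 <- instrumentA(inst) %*% instrumentW(inst)
  rets <- sapply(c(0, 20, 45, 77), function(ax) {
    C <- similarityReduce(b0, instrumentA(inst) %*%
                            makeLinearRetarder(83, ax) %*% instrumentW(inst))
    fitReferenceParameters(C, list(kind = "retarder", retardance = 90,
                                   axis = ax))$retardance
  })
  expect_equal(rets, rep(83, 4), tolerance = 1e-8)
})

test_that("noise-free ECM recovers ideal and perturbed instruments", {
  ## ideal round trip
  inst <- buildInstrument()
  cal <- calibrate(makeReferenceAcquisitions(inst))
  expect_lt(norm(instrumentW(cal) - instrumentW(inst), "F") /
              norm(instrumentW(inst), "F"), 1e-8)
  expect_lt(norm(instrumentA(cal) - instrumentA(inst), "F") /
              norm(instrumentA(inst), "F"), 1e-8)
  ## a 2 deg PSG polarizer offset must appear in the recovered column
  perturbed <- buildInstrument(idealSchedule(),
    psg_errors = list(pol_offset_deg = c(2, 0, 0, 0, 0, 0)))
  cal2 <- calibrate(makeReferenceAcquisitions(perturbed))
  expect_equal(instrumentW(cal2)[, 1],
               c(1, cos(4 * pi / 180), sin(4 * pi / 180), 0),
               tolerance = 1e-6)
  expect_gt(norm(instrumentW(cal2) - instrumentW(buildInstrument()), "F"),
            0.01)
})

test_that("a single polarizer reference leaves the kernel degenerate", {
  inst <- buildInstrument()
  A <- instrumentA(inst); W <- instrumentW(inst)
  b0 <- A %*% W
  refs <- referenceAcquisitionSet(b0, list(
    list(nominal = list(kind = "polarizer", q = 1, r = 0, axis = 0),
         b = A %*% makeLinearDiattenuator(1, 0, 0) %*% W)))
  expect_error(calibrate(refs), "ambiguous")
})

test_that("solveA round-trips, bounds noisy error, rejects rank-3 W", {
  inst <- buildInstrument()
  W <- instrumentW(inst); A0 <- instrumentA(inst)
  b0 <- A0 %*% W
  expect_lt(norm(solveA(b0, W) - A0, "F") / norm(A0, "F"), 1e-10)
  ## SNR 100 multiplicative noise: small relative error (Monte Carlo seeds)
  for (s in 1:5) {
    set.seed(s)
    bn <- b0 * (1 + rnorm(48, sd = 0.01))
    expect_lt(norm(solveA(bn, W) - A0, "F") / norm(A0, "F"), 0.02)
  }
  W3 <- W; W3[4, ] <- 0
  expect_error(solveA(b0, W3), "rank")
  ## air rank deficiency is caught at the reduction step
  expect_error(similarityReduce(matrix(1, 8, 6), b0), "rank")
})

test_that("calibration requires an air measurement", {
  expect_error(calibrate(list(refs = list())), "air")
  expect_error(referenceAcquisitionSet(matrix(-1, 8, 6), list()),
               "at least one")
})

test_that("noisy references still give ~percent-level parameter errors on a
           clear-slide sample", {
  inst <- buildInstrument(idealSchedule(),
                          psg_errors = list(pol_offset_deg = 1),
                          psa_errors = list(qwp_ret_offset_deg = 2))
  for (s in 1:4) {
    cal <- calibrate(makeReferenceAcquisitions(
      inst, noise = list(rel_sd = 0.01), seed = s))
    mi <- reconstructMueller(forwardAcquire(diag(4), inst), cal@instrument)
    sc <- mmpdDecomposePixel(matrix(mi@field[1, 1, , ], 4, 4))$scalars
    ## dimensionless parameters of the identity sample stay at the % scale
    expect_lt(max(abs(sc[c("D", "Delta", "DeltaL", "DeltaC")])), 0.05)
    expect_lt(abs(sc[["delta_deg"]]), 3)
  }
})

test_that("kernel residual grows with reference noise", {
  inst <- buildInstrument()
  r0 <- calibrationResidual(calibrate(makeReferenceAcquisitions(inst)))
  r1 <- calibrationResidual(calibrate(makeReferenceAcquisitions(
    inst, noise = list(rel_sd = 1e-3), seed = 2)))
  r2 <- calibrationResidual(calibrate(makeReferenceAcquisitions(
    inst, noise = list(rel_sd = 1e-2), seed = 2)))
  expect_lt(r0, r1)
  expect_lt(r1, r2)
})

test_that("pixel-by-pixel calibration recovers a spatially varying W field", {
  ## 2 x 2 image: one pixel's PSG polarizer offset differs
  insts <- list(buildInstrument(),
                buildInstrument(idealSchedule(),
                                psg_errors = list(pol_offset_deg = 2)))
  mkStack <- function(M) {
    arr <- array(0, c(2, 2, 48))
    for (i in 1:2) for (j in 1:2) {
      inst <- insts[[if (i == 1 && j == 1) 2 else 1]]
      arr[i, j, ] <- as.vector(instrumentA(inst) %*% M %*% instrumentW(inst))
    }
    arr
  }
  refs <- list(
    list(nominal = list(kind = "polarizer", q = 1, r = 0, axis = 0),
         stack = mkStack(makeLinearDiattenuator(1, 0, 0))),
    list(nominal = list(kind = "polarizer", q = 1, r = 0, axis = 45),
         stack = mkStack(makeLinearDiattenuator(1, 0, 45))),
    list(nominal = list(kind = "polarizer", q = 1, r = 0, axis = 90),
         stack = mkStack(makeLinearDiattenuator(1, 0, 90))),
    list(nominal = list(kind = "retarder", retardance = 90, axis = 0),
         stack = mkStack(makeLinearRetarder(90, 0))),
    list(nominal = list(kind = "retarder", retardance = 90, axis = 45),
         stack = mkStack(makeLinearRetarder(90, 45))))
  pc <- calibratePixelwise(mkStack(diag(4)), refs)
  expect_equal(pc$W[1, 1, , ], instrumentW(insts[[2]]), tolerance = 1e-6)
  expect_equal(pc$W[2, 2, , ], instrumentW(insts[[1]]), tolerance = 1e-6)
  expect_true(all(is.finite(pc$residual)))
})
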