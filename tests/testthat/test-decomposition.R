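test_that("identity decomposes to all-zero scalars", {
  sc <- mmpdDecomposePixel(diag(4))$scalars
  expect_equal(unname(sc[c("D", "R_deg", "delta_deg", "psi_deg",
                           "Delta", "DeltaL", "DeltaC")]),
               rep(0, 7), tolerance = 1e-9)
})

test_that("random constructor products re-factor exactly (seeded oracle)", {
  set.seed(101)
  for (i in 1:60) {
    rp <- randomMuellerProduct()
    px <- mmpdDecomposePixel(rp$M)
    remul <- px$m11 * px$MDelta %*% px$MR %*% px$MD
    expect_lt(norm(remul - rp$M, "F") / norm(rp$M, "F"), 1e-10)
    expect_equal(unname(px$scalars["delta_deg"]), rp$pars$delta,
                 tolerance = 1e-8)
    expect_equal(unname(px$scalars["psi_deg"]), rp$pars$psi,
                 tolerance = 1e-8)
    expect_equal(unname(px$scalars["DeltaC"]), 1 - rp$pars$abc[3],
                 tolerance = 1e-8)
    expect_equal(unname(px$scalars["DeltaL"]),
                 1 - (rp$pars$abc[1] + rp$pars$abc[2]) / 2,
                 tolerance = 1e-8)
    expect_equal(unname(px$scalars["D"]), rp$pars$D, tolerance = 1e-8)
  }
})

test_that("compiled image path agrees with the R reference implementation", {
  set.seed(202)
  n <- 12
  field <- array(0, c(n, 1, 4, 4))
  ref <- matrix(0, n, 11)
  for (i in seq_len(n)) {
    M <- randomMuellerProduct()$M
    field[i, 1, , ] <- M / M[1, 1]
    px <- mmpdDecomposePixel(M)
    ref[i, ] <- c(px$scalars, mmtTransform(M))
  }
  mi <- new("MuellerImage", field = field, normalized = TRUE,
            valid = matrix(TRUE, n, 1), meta = list())
  maps <- polarimetricMaps(mi)
  nm <- c("D", "R_deg", "delta_deg", "psi_deg", "Delta", "DeltaL", "DeltaC",
          "axis_deg", "b", "t", "A_mmt")
  for (k in seq_along(nm)) {
    got <- paramMap(maps, nm[k])[, 1]
    if (nm[k] == "axis_deg") {
      ## axis is defined modulo 180
      d <- abs(got - ref[, k]) %% 180
      expect_lt(max(pmin(d, 180 - d)), 1e-7)
    } else {
      expect_equal(got, ref[, k], tolerance = 1e-7)
    }
  }
})

test_that("ideal polarizer (D = 1) takes the pseudo-inverse branch", {
  px <- mmpdDecomposePixel(makeLinearDiattenuator(1, 0, 20))
  expect_equal(unname(px$scalars["D"]), 1, tolerance = 1e-12)
  expect_true(all(is.finite(px$scalars[c("D", "Delta")])))
})

test_that("retarder fast-axis map is recovered and rotates with the sample", {
  M <- makeLinearRetarder(30, 25)
  px <- mmpdDecomposePixel(M)
  expect_equal(unname(px$scalars["axis_deg"]), 25, tolerance = 1e-9)
  ## rotating the sample rotates the fast axis, leaves delta and MMT alone
  R20 <- muellerRotation(20) %*% M %*% muellerRotation(-20)
  px2 <- mmpdDecomposePixel(R20)
  expect_equal(unname(px2$scalars["axis_deg"]), 45, tolerance = 1e-9)
  expect_equal(unname(px2$scalars["delta_deg"]), 30, tolerance = 1e-9)
  mm <- mmtTransform(M); mm2 <- mmtTransform(R20)
  expect_equal(mm2, mm, tolerance = 1e-12)
})

test_that("MMT parameters match closed forms", {
  expect_equal(mmtTransform(diag(4)), c(b = 1, t = 0, A_mmt = 0))
  a <- 0.8; c0 <- 0.6
  mm <- mmtTransform(makeDiagonalDepolarizer(a, a, c0))
  expect_equal(unname(mm["b"]), a, tolerance = 1e-12)
  expect_equal(unname(mm["t"]), 0, tolerance = 1e-12)
  ## ideal polarizer: b = t, maximal anisotropy
  expect_equal(unname(mmtTransform(makeLinearDiattenuator(1, 0, 0))["A_mmt"]),
               1, tolerance = 1e-12)
  ## zero central block: anisotropy defined as 0
  expect_equal(unname(mmtTransform(makeDiagonalDepolarizer(0, 0, 1))["A_mmt"]),
               0)
})

test_that("reconstruction round-trips noise-free samples", {
  inst <- buildInstrument()
  ## identity sample
  mi <- reconstructMueller(forwardAcquire(diag(4), inst), inst)
  expect_matrix_equal(mi@field[1, 1, , ], diag(4), 1e-10)
  ## known retarder-depolarizer product
  M <- makeDiagonalDepolarizer(0.95, 0.9, 0.85) %*% makeLinearRetarder(40, 15)
  mi2 <- reconstructMueller(forwardAcquire(M, inst), inst)
  expect_matrix_equal(mi2@field[1, 1, , ], M, 1e-9)
  ## perturbed instrument, matched reconstruction
  instp <- buildInstrument(idealSchedule(),
                           psg_errors = list(pol_offset_deg = 2),
                           psa_errors = list(qwp_offset_deg = -1))
  mi3 <- reconstructMueller(forwardAcquire(M, instp), instp)
  expect_matrix_equal(mi3@field[1, 1, , ], M, 1e-9)
})

test_that("all-zero pixels are flagged invalid, not errors", {
  inst <- buildInstrument()
  st <- forwardAcquire(array(diag(4), c(1, 1, 4, 4)), inst)
  fr <- array(0, c(2, 1, 48)); fr[1, 1, ] <- st@frames[1, 1, ]
  stack <- new("IntensityStack", frames = fr, bitDepth = "float",
               meta = list())
  mi <- reconstructMueller(stack, inst)
  expect_true(mi@valid[1, 1])
  expect_false(mi@valid[2, 1])
  expect_true(all(is.na(mi@field[2, 1, , ])))
})

test_that("frame permutation is exposed by the physicality-violation rate", {
  ph <- makeRingPhantom(ringPhantomSpec(n = 24L, pitch_um = 40,
                                        innerRadius_um = 150,
                                        width_um = 250,
                                        delta_baseline_deg = 20,
                                        delta_bump_deg = 40,
                                        d_level = 0.08))
  inst <- buildInstrument()
  st <- forwardAcquire(ph@mueller, inst)
  ## the Cloude mode with a small slack tolerates the phantom's mildly
  ## circular-biased depolarizer but pounces on scrambled matrices
  good <- physicalityViolationRate(reconstructMueller(st, inst),
                                   tol = 0.02, cloude = TRUE)
  set.seed(9)
  perm <- sample(48)
  stp <- new("IntensityStack", frames = st@frames[, , perm],
             bitDepth = "float", meta = st@meta)
  bad <- physicalityViolationRate(reconstructMueller(stp, inst),
                                  tol = 0.02, cloude = TRUE)
  expect_equal(good, 0)
  expect_gt(bad, 0.2)
})

test_that("counterpart parameters stay put while delta and DeltaC sweep", {
  inst <- buildInstrument()
  for (dl in c(2, 8, 14)) for (dc in c(0.01, 0.03, 0.05)) {
    M <- makeDiagonalDepolarizer(1, 1, 1 - dc) %*% makeLinearRetarder(dl, 40)
    sc <- pipelineScalars(M, inst)
    expect_equal(unname(sc["delta_deg"]), dl, tolerance = 1e-6)
    expect_equal(unname(sc["DeltaC"]), dc, tolerance = 1e-8)
    expect_lt(abs(sc[["psi_deg"]]), 0.35)
    expect_lt(abs(sc[["DeltaL"]]), 0.01)
  }
})

test_that("arccos clipping events are counted, not fatal", {
  M <- diag(4) + matrix(rnorm(16, sd = 1e-13), 4, 4)
  M[1, 1] <- 1
  px <- mmpdDecomposePixel(M)
  expect_true(is.finite(px$scalars[["R_deg"]]))
  expect_gte(px$clips, 0)
})
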