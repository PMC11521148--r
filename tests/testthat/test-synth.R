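test_that("zero bump amplitude gives a flat retardance field", {
  ph <- makeRingPhantom(ringPhantomSpec(n = 64L, pitch_um = 15,
                                        innerRadius_um = 120,
                                        width_um = 300,
                                        delta_bump_deg = 0))
  inside <- ph@truth$inside
  expect_true(all(ph@truth$delta_deg[inside] == 2))
  expect_true(all(ph@truth$delta_deg[!inside] == 0))
})

test_that("phantom truth matches direct decomposition of its Mueller field", {
  ph <- makeRingPhantom(ringPhantomSpec(n = 48L, pitch_um = 20,
                                        innerRadius_um = 120,
                                        width_um = 300))
  maps <- polarimetricMaps(ph@mueller)
  inside <- ph@truth$inside
  expect_lt(max(abs(paramMap(maps, "delta_deg")[inside] -
                      ph@truth$delta_deg[inside])), 1e-7)
  expect_lt(max(abs(paramMap(maps, "DeltaC")[inside] -
                      ph@truth$DeltaC[inside])), 1e-9)
  expect_lt(max(abs(paramMap(maps, "D")[inside] -
                      ph@truth$D[inside])), 1e-9)
  ## circumferential fast axis: recovered axis equals the truth mod 180
  d <- abs(paramMap(maps, "axis_deg")[inside] -
             ph@truth$axis_deg[inside]) %% 180
  expect_lt(max(pmin(d, 180 - d)), 1e-6)
  ## outside the ring: clean identity
  ## acos is infinitely steep at its endpoint: identity pixels carry
  ## ~1e-6 deg of floating-point dust in the retardance
  expect_true(all(abs(paramMap(maps, "delta_deg")[!inside]) < 1e-4))
})

test_that("every phantom pixel is a physical Mueller matrix", {
  ph <- makeRingPhantom(ringPhantomSpec(n = 24L, pitch_um = 40,
                                        innerRadius_um = 150,
                                        width_um = 250,
                                        defect_count = 2L))
  expect_equal(physicalityViolationRate(ph@mueller), 0)
})

test_that("unphysical phantom specifications are rejected", {
  expect_error(makeRingPhantom(ringPhantomSpec(dc_baseline = 0.9,
                                               dc_bump = 0.2)),
               "unphysical")
  expect_error(makeRingPhantom(ringPhantomSpec(delta_bump_center = 1.5)),
               "\\(0, 1\\)")
})

test_that("cohort defaults follow the trajectories and are deterministic", {
  spec <- timeCourseSpec(phantom_n = 32L)
  spec$delta_sd <- lapply(spec$delta_sd, function(x) x * 0)
  spec$dc_sd <- lapply(spec$dc_sd, function(x) x * 0)
  co <- makeCohort(spec)
  tr <- co$truth
  for (g in c("control", "treated")) {
    got <- tapply(tr$true_delta_deg[tr$group == g], tr$day[tr$group == g],
                  unique)
    expect_equal(as.numeric(got), spec$delta_mean[[g]], tolerance = 1e-12)
  }
  ## group sizes follow the design
  expect_equal(as.vector(table(tr$day[tr$group == "control"])),
               c(8, 8, 12, 9, 13))
  expect_equal(as.vector(table(tr$day[tr$group == "treated"])),
               c(8, 8, 9, 10, 9))
  ## determinism under the seed
  co2 <- makeCohort(timeCourseSpec(phantom_n = 32L))
  co3 <- makeCohort(timeCourseSpec(phantom_n = 32L))
  expect_identical(co2$truth, co3$truth)
})

test_that("cohort phantom ring means hit the sampled targets", {
  co <- makeCohort(timeCourseSpec(phantom_n = 64L, seed = 9L))
  s <- co$samples[[5]]
  ph <- makeRingPhantom(s$spec)
  inside <- ph@truth$inside
  expect_lt(abs(mean(ph@truth$delta_deg[inside]) - s$meta$true_delta_deg) /
              s$meta$true_delta_deg, 0.01)
  expect_lt(abs(mean(ph@truth$DeltaC[inside]) - s$meta$true_DeltaC) /
              s$meta$true_DeltaC, 0.01)
})

test_that("reference acquisitions are deterministic under a seed", {
  inst <- buildInstrument()
  r1 <- makeReferenceAcquisitions(inst, noise = list(rel_sd = 0.01), seed = 3)
  r2 <- makeReferenceAcquisitions(inst, noise = list(rel_sd = 0.01), seed = 3)
  r3 <- makeReferenceAcquisitions(inst, noise = list(rel_sd = 0.01), seed = 4)
  expect_identical(r1$b0, r2$b0)
  expect_identical(r1$refs[[4]]$b, r2$refs[[4]]$b)
  expect_false(identical(r1$b0, r3$b0))
})

test_that("Watson sampler concentrates around the mean axis", {
  set.seed(61)
  V <- muellerpol:::rWatson(500, c(0, 0, 1), 100)
  expect_equal(dim(V), c(500L, 3L))
  expect_lt(max(abs(sqrt(rowSums(V^2)) - 1)), 1e-12)
  expect_gt(mean(abs(V[, 3])), 0.95)
  ## truth-level SV ordering across concentrations
  sv <- sapply(c(5, 20, 1e6), function(k)
    sphericalVariance(muellerpol:::rWatson(300, c(1, 0, 0), k)))
  expect_true(all(diff(sv) < 0))
  expect_lt(sv[3], 1e-3)
})

test_that("fiber volumes carry machine-readable ground truth", {
  vol <- makeFiberVolume(n_fibers = 10, dims = c(32, 32, 16), seed = 8)
  expect_s4_class(vol, "FiberVolume")
  expect_equal(dim(vol@meta$true_axes), c(10L, 3L))
  expect_true(all(vol@voxels >= 0))
  ## determinism
  vol2 <- makeFiberVolume(n_fibers = 10, dims = c(32, 32, 16), seed = 8)
  expect_identical(vol@voxels, vol2@voxels)
})
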