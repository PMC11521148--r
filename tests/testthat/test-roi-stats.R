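test_that("scaled-MAD mask keeps constant maps and recovers planted outliers", {
  expect_true(all(madMask(matrix(5, 20, 20))))
  set.seed(31)
  m <- matrix(rnorm(10000), 100, 100)
  idx <- sample(10000, 50)
  m[idx] <- 10
  mask <- madMask(m)
  expect_true(all(!mask[idx]))          # every planted outlier excluded
  expect_lt(sum(!mask) - 50, 60)        # few extra tail exclusions
  ## non-finite pixels are excluded too
  m2 <- matrix(rnorm(100), 10, 10); m2[1, 1] <- NA
  expect_false(madMask(m2)[1, 1])
  expect_error(madMask(matrix(NA_real_, 3, 3)), "finite")
})

test_that("null exclusion fraction sits at the 3-sigma tail mass", {
  set.seed(32)
  m <- matrix(rnorm(2e5), 400, 500)
  frac <- mean(!madMask(m))
  expect_gt(frac, 0.0027 - 0.0015)
  expect_lt(frac, 0.0027 + 0.0015)
})

test_that("masking is idempotent when no new outliers appear", {
  set.seed(33)
  m <- matrix(rnorm(10000), 100, 100)
  m[sample(10000, 30)] <- 8
  mask1 <- madMask(m)
  m2 <- m; m2[!mask1] <- NA
  mask2 <- madMask(m2)
  ## everything retained in pass 1 that pass 2 would drop must be genuinely
  ## extreme under the re-estimated spread; allow a handful of border flips
  expect_lt(sum(mask1 & !mask2), 0.005 * sum(mask1))
})

test_that("ROI summary reports masked means, maxima and pixel counts", {
  maps <- new("PolarimetricMaps",
              maps = list(delta_deg = matrix(5, 10, 10),
                          Delta = matrix(0.01, 10, 10)),
              factors = list(), clipCount = 0L, meta = list())
  row <- roiSummary(maps, day = 7L, group = "control")
  expect_equal(row$mean_delta_deg, 5)
  expect_equal(row$max_delta_deg, 5)
  expect_identical(row$n_pixels, 100L)
  expect_error(roiSummary(maps, mask = matrix(FALSE, 10, 10)), "empty")
})

test_that("phantom masked mean matches the analytic area-weighted mean", {
  spec <- ringPhantomSpec(n = 128L, pitch_um = 10, innerRadius_um = 150,
                          width_um = 400)
  ph <- makeRingPhantom(spec)
  truthMean <- ringProfileMean(spec$delta_baseline_deg, spec$delta_bump_deg,
                               spec$delta_bump_center, spec$delta_bump_width,
                               spec$innerRadius_um, spec$width_um)
  pixelMean <- mean(ph@truth$delta_deg[ph@truth$inside])
  expect_lt(abs(pixelMean - truthMean) / truthMean, 0.01)
})

test_that("defect regions are excluded and the clean mean is restored", {
  spec <- ringPhantomSpec(n = 96L, pitch_um = 10, innerRadius_um = 120,
                          width_um = 330, defect_count = 4L, seed = 5L)
  ph <- makeRingPhantom(spec)
  maps <- polarimetricMaps(ph@mueller)
  dmap <- paramMap(maps, "Delta")
  dmap[!ph@truth$inside] <- NA
  mask <- madMask(dmap)
  expect_gt(mean(!mask[ph@truth$defect]), 0.95)
  clean <- makeRingPhantom(ringPhantomSpec(n = 96L, pitch_um = 10,
                                           innerRadius_um = 120,
                                           width_um = 330, seed = 5L))
  cleanMean <- mean(clean@truth$delta_deg[clean@truth$inside])
  maskedMean <- mean(paramMap(maps, "delta_deg")[mask & ph@truth$inside])
  ## masking also trims some legitimate bump pixels; 2% slack covers that
  expect_lt(abs(maskedMean - cleanMean) / cleanMean, 0.02)
})

test_that("radial profiles find flatness, bumps and heterogeneity ordering", {
  spec <- ringPhantomSpec(n = 128L, pitch_um = 10, innerRadius_um = 150,
                          width_um = 400)
  ctr <- c(64.5, 64.5)
  flat <- matrix(3, 128, 128)
  pf <- radialProfile(flat, ctr, 150, 400, 10, n_bins = 10)
  expect_equal(pf$sd, 0)
  expect_true(all(pf$profile$value == 3))
  ph <- makeRingPhantom(spec)
  pb <- radialProfile(ph@truth$delta_deg, ph@geometry$center, 150, 400, 10,
                      n_bins = 20, mask = ph@truth$inside)
  ## bump centred at 30% of the width: argmax within one bin of 120 um
  expect_lt(abs(pb$peak_um - 0.3 * 400), 400 / 20 + 1e-9)
  expect_gt(pb$sd, 0)
  expect_error(radialProfile(flat, ctr, 2000, 400, 10), "beyond")
})

test_that("ring centre least-squares fit recovers the phantom geometry", {
  ph <- makeRingPhantom(ringPhantomSpec(n = 96L, pitch_um = 10,
                                        innerRadius_um = 120,
                                        width_um = 330))
  fit <- fitRingCenter(ph@truth$inside)
  expect_lt(max(abs(fit$center - ph@geometry$center)), 1)
})

test_that("Spearman battery flags monotone trends and perfect pairs", {
  set.seed(41)
  n <- 30
  tb <- data.frame(day = rep(c(2, 4, 7, 14, 21), each = 6),
                   group = rep(c("control", "treated"), 15))
  tb$mean_delta_deg <- tb$day + 0.01 * seq_len(n)   # monotone in day
  tb$mean_R_deg <- tb$mean_delta_deg          # psi == 0: R tracks delta
  tb$mean_DeltaC <- rnorm(n)
  sb <- spearmanBattery(tb)
  expect_equal(sb$rho["mean_delta_deg", "mean_R_deg"], 1)
  d <- sb$design
  expect_gt(d$rho_day[d$parameter == "mean_delta_deg"], 0.97)
  ## constant column reported missing
  tb$mean_D <- 1
  sb2 <- spearmanBattery(tb)
  expect_true(is.na(sb2$design$rho_day[sb2$design$parameter == "mean_D"]))
  expect_error(spearmanBattery(tb[1:2, ]), "3 rows")
})

test_that("rank statistics are invariant under monotone map transforms", {
  set.seed(42)
  tb <- data.frame(day = rep(c(2, 7, 21), each = 8),
                   group = "control",
                   mean_delta_deg = rnorm(24, rep(c(3, 6, 9), each = 8)))
  sb1 <- spearmanBattery(tb, params = "mean_delta_deg")
  t1 <- groupTests(tb, "mean_delta_deg", shapiro = FALSE)
  tb2 <- tb; tb2$mean_delta_deg <- exp(tb$mean_delta_deg)
  sb2 <- spearmanBattery(tb2, params = "mean_delta_deg")
  t2 <- groupTests(tb2, "mean_delta_deg", shapiro = FALSE)
  expect_equal(sb1$design$rho_day, sb2$design$rho_day)
  expect_equal(t1$kruskal$p, t2$kruskal$p)
  expect_equal(t1$pairwise_days$p, t2$pairwise_days$p)
})

test_that("group tests behave on degenerate and shifted groups", {
  ## perfectly interleaved tie-free samples: the exact two-sided rank-sum
  ## statistic sits at its null centre, p = 1
  tb <- data.frame(day = rep(c(2, 7), each = 4), group = "control",
                   y = c(1, 4, 5, 8, 2, 3, 6, 7))
  gt <- groupTests(tb, "y", shapiro = FALSE)
  expect_equal(gt$pairwise_days$p, 1)
  ## clearly shifted groups are detected
  set.seed(43)
  tb2 <- data.frame(day = rep(c(2, 7), each = 10), group = "control",
                    y = c(rnorm(10), rnorm(10, 5)))
  gt2 <- groupTests(tb2, "y", shapiro = FALSE)
  expect_lt(gt2$pairwise_days$p, 0.001)
  expect_lt(gt2$kruskal$p, 0.001)
  ## Holm adjustment available behind the flag
  tb3 <- data.frame(day = rep(c(2, 7, 21), each = 6), group = "control",
                    y = rnorm(18))
  gt3 <- groupTests(tb3, "y", adjust = "holm", shapiro = FALSE)
  expect_true(all(gt3$pairwise_days$p_adj >= gt3$pairwise_days$p))
  ## between-group tests and the Shapiro-Wilk report
  tb4 <- data.frame(day = rep(c(2, 7), each = 12),
                    group = rep(c("control", "treated"), 12))
  set.seed(44)
  tb4$y <- rnorm(24) + ifelse(tb4$group == "treated" & tb4$day == 7, 4, 0)
  gt4 <- groupTests(tb4, "y")
  expect_lt(gt4$between_groups$p[gt4$between_groups$day == 7], 0.01)
  expect_gt(gt4$between_groups$p[gt4$between_groups$day == 2], 0.05)
  expect_true(all(c("group", "day", "W", "p") %in% names(gt4$shapiro)))
})
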