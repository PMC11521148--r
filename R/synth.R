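## Synthetic-data generators: ring-tissue Mueller phantoms with known ground
## truth, time-course/treatment cohorts, calibration reference acquisitions,
## and 3D fiber volumes. These stand in for all microscope data; every
## generator returns machine-readable ground truth alongside the data.

#' Default ring phantom specification
#'
#' Desk-scale geometry: a 256 x 256 image at 10 um pitch holding a full
#' annulus of the nominal 750-um trough width (the real mold's 5-mm ring
#' only ever shows a partial arc in one field of view; the phantom shrinks
#' the inner radius so the whole ring is visible). The linear retardance and
#' circular depolarization follow `baseline + bump` radial profiles with the
#' bump centred at 30% of the ring width from the inner edge, emulating the
#' observed peak near the inner ring. The fast axis is circumferential (the
#' mold guides cells along the ring); this package's axis zero reference is
#' the image +x direction.
#'
#' @param ... overrides for any field of the returned list.
#' @return a named list (see field names in the function body).
#' @export
ringPhantomSpec <- function(...) {
  spec <- list(
    n = 256L,                  # image side, pixels
    pitch_um = 10,
    center = NULL,             # default: image centre
    innerRadius_um = 400,
    width_um = 750,
    axis_pattern = "circumferential",   # or "constant"
    axis_deg = 0,              # used when axis_pattern = "constant"
    delta_baseline_deg = 2,
    delta_bump_deg = 9,        # bump amplitude
    delta_bump_center = 0.3,   # fraction of width from the inner edge
    delta_bump_width = 0.15,   # gaussian sigma, fraction of width
    dc_baseline = 0.010,
    dc_bump = 0.030,
    dc_bump_center = 0.3,
    dc_bump_width = 0.20,
    dl_level = 0.005,
    psi_deg = 0,
    d_level = 0.05,
    defect_count = 0L,
    defect_magnitude = 0.4,
    defect_radius_px = 3,
    seed = 1L)
  over <- list(...)
  spec[names(over)] <- over
  spec
}

validateRingSpec <- function(spec) {
  with(spec, {
    if (delta_baseline_deg < 0 || delta_baseline_deg + delta_bump_deg > 180)
      stop("unphysical linear retardance profile")
    if (dc_baseline < 0 || dc_baseline + dc_bump >= 1)
      stop("unphysical circular depolarization profile")
    if (dl_level < 0 || dl_level >= 1) stop("unphysical DeltaL")
    if (d_level < 0 || d_level > 1) stop("unphysical diattenuation")
    if (delta_bump_center <= 0 || delta_bump_center >= 1 ||
        dc_bump_center <= 0 || dc_bump_center >= 1)
      stop("bump centre fraction must lie in (0, 1)")
  })
  invisible(spec)
}

## Pixelwise product of two N x 4 x 4 matrix fields.
pixelwiseMatMul <- function(A, B) {
  d <- dim(A)
  C <- array(0, d)
  for (i in 1:4) for (j in 1:4) {
    acc <- 0
    for (k in 1:4) acc <- acc + A[, i, k] * B[, k, j]
    C[, i, j] <- acc
  }
  C
}

## Vectorized linear retarder field: delta, axis in degrees (vectors).
retarderField <- function(delta_deg, axis_deg) {
  n <- length(delta_deg)
  dl <- deg2rad(delta_deg); a <- 2 * deg2rad(axis_deg)
  C <- cos(a); S <- sin(a); cd <- cos(dl); sd <- sin(dl)
  M <- array(0, c(n, 4, 4))
  M[, 1, 1] <- 1
  M[, 2, 2] <- C^2 + S^2 * cd;      M[, 2, 3] <- C * S * (1 - cd)
  M[, 2, 4] <- -S * sd
  M[, 3, 2] <- C * S * (1 - cd);    M[, 3, 3] <- S^2 + C^2 * cd
  M[, 3, 4] <- C * sd
  M[, 4, 2] <- S * sd;              M[, 4, 3] <- -C * sd
  M[, 4, 4] <- cd
  M
}

## Vectorized normalized linear diattenuator field along axis_deg.
diattenuatorField <- function(D, axis_deg) {
  n <- length(D)
  a <- 2 * deg2rad(axis_deg)
  dx <- D * cos(a); dy <- D * sin(a)
  sq <- sqrt(pmax(1 - D^2, 0))
  Dn <- pmax(D, 1e-300)
  hx <- dx / Dn; hy <- dy / Dn
  M <- array(0, c(n, 4, 4))
  M[, 1, 1] <- 1
  M[, 1, 2] <- dx; M[, 2, 1] <- dx
  M[, 1, 3] <- dy; M[, 3, 1] <- dy
  M[, 2, 2] <- sq + (1 - sq) * hx^2
  M[, 2, 3] <- (1 - sq) * hx * hy
  M[, 3, 2] <- M[, 2, 3]
  M[, 3, 3] <- sq + (1 - sq) * hy^2
  M[, 4, 4] <- sq
  z <- D < 1e-12
  if (any(z)) for (i in 2:3) M[z, i, i] <- 1
  M
}

#' Generate a ring-tissue Mueller phantom
#'
#' Per pixel inside the annulus the Mueller matrix is composed as
#' `MDelta(1, 1 - DeltaL, 1 - DeltaC) %*% MR(delta(r), axis(x, y)) %*%
#' MD(D)`; outside-ring pixels are clean identity. Optional defect spots
#' carry high depolarization so the scaled-MAD mask can find them. Returns
#' ground-truth parameter fields alongside the composed matrix field.
#'
#' @param spec a specification from [ringPhantomSpec()].
#' @return a [RingPhantom-class].
#' @export
makeRingPhantom <- function(spec = ringPhantomSpec()) {
  validateRingSpec(spec)
  n <- spec$n
  ctr <- spec$center %||% c((n + 1) / 2, (n + 1) / 2)
  px <- spec$pitch_um
  xx <- (row(matrix(0, n, n)) - ctr[1]) * px
  yy <- (col(matrix(0, n, n)) - ctr[2]) * px
  r <- sqrt(xx^2 + yy^2)
  f <- (r - spec$innerRadius_um) / spec$width_um   # 0..1 across the ring
  inside <- f >= 0 & f <= 1

  bump <- function(center, width) exp(-((f - center) / width)^2 / 2)
  delta <- ifelse(inside,
                  spec$delta_baseline_deg +
                    spec$delta_bump_deg * bump(spec$delta_bump_center,
                                               spec$delta_bump_width), 0)
  dc <- ifelse(inside,
               spec$dc_baseline + spec$dc_bump * bump(spec$dc_bump_center,
                                                      spec$dc_bump_width), 0)
  dl <- ifelse(inside, spec$dl_level, 0)
  dd <- ifelse(inside, spec$d_level, 0)
  psi <- ifelse(inside, spec$psi_deg, 0)
  axis <- if (spec$axis_pattern == "circumferential")
    (rad2deg(atan2(yy, xx)) + 90) %% 180 else
    matrix(spec$axis_deg, n, n)

  defect <- matrix(FALSE, n, n)
  if (spec$defect_count > 0) {
    set.seed(spec$seed)
    idx <- which(inside)
    pick <- sample(idx, spec$defect_count)
    for (p in pick) {
      pr <- (p - 1) %% n + 1; pc <- (p - 1) %/% n + 1
      dist <- sqrt((row(defect) - pr)^2 + (col(defect) - pc)^2)
      defect <- defect | (dist <= spec$defect_radius_px)
    }
    defect <- defect & inside
    dc[defect] <- spec$defect_magnitude
    dl[defect] <- spec$defect_magnitude
  }

  N <- n * n
  MR <- retarderField(as.vector(delta), as.vector(axis))
  if (spec$psi_deg != 0) {
    psiF <- retarderField(rep(0, N), rep(0, N))   # placeholder identity
    p <- deg2rad(as.vector(psi))
    psiF[, 2, 2] <- cos(p); psiF[, 2, 3] <- -sin(p)
    psiF[, 3, 2] <- sin(p); psiF[, 3, 3] <- cos(p)
    psiF[, 4, 4] <- 1
    MR <- pixelwiseMatMul(psiF, MR)
  }
  MD <- diattenuatorField(as.vector(dd), as.vector(axis))
  M <- pixelwiseMatMul(MR, MD)
  ## left-multiply by the diagonal depolarizer: scales rows 2-4
  M[, 3, ] <- M[, 3, ] * (1 - as.vector(dl))
  M[, 2, ] <- M[, 2, ] * (1 - as.vector(dl))
  M[, 4, ] <- M[, 4, ] * (1 - as.vector(dc))

  field <- array(M, c(n, n, 4, 4))
  mi <- new("MuellerImage", field = field, normalized = TRUE,
            valid = matrix(TRUE, n, n), meta = list(phantom = TRUE))
  truth <- list(delta_deg = delta, DeltaC = dc, DeltaL = dl,
                psi_deg = psi, D = dd,
                axis_deg = ifelse(inside, axis, NA_real_),
                inside = inside, defect = defect)
  new("RingPhantom", truth = truth, mueller = mi, spec = spec,
      geometry = list(center = ctr, innerRadius_um = spec$innerRadius_um,
                      width_um = spec$width_um, pitch_um = px))
}

#' Area-weighted analytic ring mean of a baseline + bump profile
#'
#' The mean over the annulus of `baseline + amp * exp(-((f - c)/w)^2 / 2)`
#' with `f` the fractional radial position, weighted by the annular area
#' element. Used as the closed-form ground truth for masked ROI means of
#' defect-free phantoms.
#'
#' @param baseline,amp,center,width profile parameters.
#' @param innerRadius_um,width_um ring geometry.
#' @return the analytic mean.
#' @export
ringProfileMean <- function(baseline, amp, center, width,
                            innerRadius_um, width_um) {
  g <- function(f) exp(-((f - center) / width)^2 / 2)
  num <- stats::integrate(function(f)
    g(f) * (innerRadius_um + f * width_um), 0, 1)$value
  den <- stats::integrate(function(f)
    innerRadius_um + f * width_um, 0, 1)$value
  baseline + amp * num / den
}

#' Default time-course cohort specification
#'
#' Mean trajectories of linear retardance (degrees) and circular
#' depolarization, and the between-sample standard deviations and group
#' sizes, for a control arm and a growth-factor-treated arm over culture
#' days 2 to 21. The treated retardance plateaus after day 7 while the
#' control rises through day 21.
#'
#' @param ... overrides for any field.
#' @return a named list.
#' @export
timeCourseSpec <- function(...) {
  spec <- list(
    days = c(2L, 4L, 7L, 14L, 21L),
    delta_mean = list(control = c(4.37, 2.31, 3.32, 7.66, 11.02),
                      treated = c(3.73, 4.00, 12.55, 13.23, 11.96)),
    delta_sd = list(control = c(0.77, 0.89, 1.03, 1.32, 2.99),
                    treated = c(1.06, 0.65, 2.21, 2.15, 2.69)),
    dc_mean = list(control = c(12.83, 22.93, 14.24, 28.47, 35.44) / 1000,
                   treated = c(13.25, 14.70, 50.65, 44.39, 43.93) / 1000),
    dc_sd = list(control = c(3.04, 28.28, 3.23, 12.55, 12.42) / 1000,
                 treated = c(1.934, 3.25, 24.33, 17.42, 15.70) / 1000),
    n = list(control = c(8L, 8L, 12L, 9L, 13L),
             treated = c(8L, 8L, 9L, 10L, 9L)),
    phantom_n = 96L,            # per-sample phantom image side, pixels
    seed = 1L)
  over <- list(...)
  spec[names(over)] <- over
  if (any(unlist(spec$delta_mean) < 0) || any(unlist(spec$dc_mean) < 0))
    stop("trajectories must be non-negative")
  spec
}

rtruncnorm0 <- function(n, mean, sd, upper = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x > 0 && x < upper) { out[i] <- x; break }
    }
  }
  out
}

#' Generate a synthetic time-course cohort
#'
#' Samples per-(day, arm) mean parameters from truncated normal
#' between-sample variation around the trajectory means and builds one ring
#' phantom specification per sample, with the radial profile scaled so its
#' area-weighted mean equals the sampled value (70% baseline, 30% bump by
#' default). Deterministic under the spec seed.
#'
#' @param spec a [timeCourseSpec()].
#' @return list with `samples` (list of `list(spec, meta)`) and `truth`
#'   (data.frame: sample_id, batch_id, day, group, true_delta_deg,
#'   true_DeltaC).
#' @export
makeCohort <- function(spec = timeCourseSpec()) {
  set.seed(spec$seed)
  samples <- list()
  truth <- NULL
  sid <- 0L
  for (g in c("control", "treated")) {
    for (k in seq_along(spec$days)) {
      nk <- spec$n[[g]][k]
      dvals <- rtruncnorm0(nk, spec$delta_mean[[g]][k],
                           spec$delta_sd[[g]][k], upper = 180)
      cvals <- rtruncnorm0(nk, spec$dc_mean[[g]][k],
                           spec$dc_sd[[g]][k], upper = 0.9)
      for (s in seq_len(nk)) {
        sid <- sid + 1L
        ## split target mean into baseline + bump with the analytic mean
        ## of the bump profile, so the area-weighted mean equals the target
        ## pitch scales with the image side so the full 120..450 um annulus
        ## always fits the 960-um field regardless of phantom_n
        ps <- ringPhantomSpec(n = spec$phantom_n,
                              pitch_um = 960 / spec$phantom_n,
                              innerRadius_um = 120, width_um = 330,
                              seed = spec$seed + sid)
        bumpMean <- ringProfileMean(0, 1, ps$delta_bump_center,
                                    ps$delta_bump_width,
                                    ps$innerRadius_um, ps$width_um)
        ps$delta_baseline_deg <- 0.7 * dvals[s]
        ps$delta_bump_deg <- 0.3 * dvals[s] / bumpMean
        bumpMeanC <- ringProfileMean(0, 1, ps$dc_bump_center,
                                     ps$dc_bump_width,
                                     ps$innerRadius_um, ps$width_um)
        ps$dc_baseline <- 0.7 * cvals[s]
        ps$dc_bump <- 0.3 * cvals[s] / bumpMeanC
        meta <- data.frame(sample_id = sprintf("S%03d", sid),
                           batch_id = sprintf("B%d", (sid - 1L) %/% 20L + 1L),
                           day = spec$days[k], group = g,
                           true_delta_deg = dvals[s], true_DeltaC = cvals[s],
                           stringsAsFactors = FALSE)
        samples[[sid]] <- list(spec = ps, meta = meta)
        truth <- rbind(truth, meta)
      }
    }
  }
  list(samples = samples, truth = truth)
}

#' Reference acquisitions for eigenvalue calibration
#'
#' Forward-acquires the canonical reference set (air; linear polarizer at 0,
#' 45 and 90 deg; quarter-wave plate at 0 and 45 deg) through a given,
#' possibly imperfect, instrument. Optional multiplicative and additive
#' Gaussian frame noise; byte-identical under a fixed seed.
#'
#' @param instrument an [InstrumentModel-class].
#' @param noise `NULL` or `list(rel_sd =, add_sd =)`.
#' @param gain intensity scale.
#' @param seed integer seed (used only when noise is on).
#' @return a `ReferenceAcquisitionSet`.
#' @export
makeReferenceAcquisitions <- function(instrument, noise = NULL, gain = 1,
                                      seed = 1) {
  refs <- list(
    list(kind = "polarizer", q = 1, r = 0, axis = 0),
    list(kind = "polarizer", q = 1, r = 0, axis = 45),
    list(kind = "polarizer", q = 1, r = 0, axis = 90),
    list(kind = "retarder", retardance = 90, axis = 0),
    list(kind = "retarder", retardance = 90, axis = 45))
  A <- instrument@A; W <- instrument@W
  noisify <- function(B, k) {
    B[B < 0 & B > -1e-9 * max(abs(B))] <- 0   # floating-point dust
    if (is.null(noise)) return(B)
    set.seed(as.integer(seed) + k)
    if (!is.null(noise$rel_sd) && noise$rel_sd > 0)
      B <- B * (1 + stats::rnorm(length(B), sd = noise$rel_sd))
    if (!is.null(noise$add_sd) && noise$add_sd > 0)
      B <- B + stats::rnorm(length(B), sd = noise$add_sd)
    B[B < 0] <- 0
    B
  }
  b0 <- noisify(gain * A %*% W, 0L)
  bl <- lapply(seq_along(refs), function(i) {
    M <- elementaryMueller(refs[[i]])
    list(nominal = refs[[i]], b = noisify(gain * A %*% M %*% W, i))
  })
  referenceAcquisitionSet(b0, bl, meta = list(coarse_aligned = TRUE))
}

## ---- fiber volumes ----

## Sample n axes from a bipolar Watson distribution around mean_axis.
rWatson <- function(n, mean_axis, kappa) {
  stopifnot(kappa > 0)
  mu <- mean_axis / sqrt(sum(mean_axis^2))
  t <- numeric(0)
  while (length(t) < n) {
    m <- max(64, 4 * (n - length(t)))
    cand <- stats::runif(m, -1, 1)
    keep <- stats::runif(m) < exp(kappa * (cand^2 - 1))
    t <- c(t, cand[keep])
  }
  t <- t[seq_len(n)]
  phi <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(pmax(1 - t^2, 0))
  V <- cbind(st * cos(phi), st * sin(phi), t)
  ## rotate e3 onto mu
  e3 <- c(0, 0, 1)
  if (sum((mu - e3)^2) < 1e-12) return(V)
  if (sum((mu + e3)^2) < 1e-12) return(-V)
  a <- c(e3[2] * mu[3] - e3[3] * mu[2], e3[3] * mu[1] - e3[1] * mu[3],
         e3[1] * mu[2] - e3[2] * mu[1])
  s <- sqrt(sum(a^2)); c0 <- sum(e3 * mu)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + K + K %*% K * (1 - c0) / s^2
  V %*% t(R)
}

## Separable Gaussian blur in the Fourier domain (periodic boundaries).
fftBlur3 <- function(vol, sigma_vox) {
  if (all(sigma_vox <= 0)) return(vol)
  d <- dim(vol)
  gk <- lapply(1:3, function(a) {
    f <- fftFreqIndex(d[a]) / d[a]
    exp(-2 * pi^2 * sigma_vox[a]^2 * f^2)
  })
  G <- outer(outer(gk[[1]], gk[[2]]), gk[[3]])
  dim(G) <- d
  Re(fft(fft(vol) * G, inverse = TRUE)) / prod(d)
}

#' Render a synthetic fiber volume with Watson-distributed axes
#'
#' Straight cylinders with axes drawn from a bipolar Watson distribution of
#' concentration `kappa` around a mean direction, rasterized into the
#' volume, Gaussian-blurred (point-spread emulation) and Poisson-noised.
#' The true axes are returned in the volume metadata.
#'
#' @param n_fibers number of cylinders.
#' @param mean_axis length-3 mean direction (need not be unit).
#' @param kappa Watson concentration (> 0; larger = more aligned).
#' @param fiber_radius_um cylinder radius in micrometres.
#' @param dims volume size in voxels, length 3.
#' @param voxelSize micrometres per voxel, length 3 or scalar.
#' @param psf_sd_um isotropic Gaussian blur standard deviation.
#' @param intensity cylinder interior intensity (photon scale).
#' @param background background photon level.
#' @param seed integer seed.
#' @return a [FiberVolume-class]; `meta$true_axes` is the n x 3 axis matrix.
#' @export
makeFiberVolume <- function(n_fibers = 40, mean_axis = c(1, 0, 0),
                            kappa = 20, fiber_radius_um = 1.5,
                            dims = c(64, 64, 32), voxelSize = 1,
                            psf_sd_um = 0.6, intensity = 60,
                            background = 2, seed = 1) {
  if (length(voxelSize) == 1) voxelSize <- rep(voxelSize, 3)
  set.seed(as.integer(seed))
  axes <- rWatson(n_fibers, mean_axis, kappa)
  ext <- dims * voxelSize
  X <- array(rep((seq_len(dims[1]) - 0.5) * voxelSize[1],
                 times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep((seq_len(dims[2]) - 0.5) * voxelSize[2],
                     each = dims[1]), times = dims[3]), dims)
  Z <- array(rep((seq_len(dims[3]) - 0.5) * voxelSize[3],
                 each = dims[1] * dims[2]), dims)
  vol <- array(0, dims)
  for (i in seq_len(n_fibers)) {
    ctr <- stats::runif(3) * ext
    v <- axes[i, ]
    px <- X - ctr[1]; py <- Y - ctr[2]; pz <- Z - ctr[3]
    proj <- px * v[1] + py * v[2] + pz * v[3]
    dist2 <- px^2 + py^2 + pz^2 - proj^2
    vol <- vol + intensity * (dist2 <= fiber_radius_um^2)
  }
  vol <- fftBlur3(vol, psf_sd_um / voxelSize) + background
  vol[vol < 0] <- 0
  vol[] <- stats::rpois(length(vol), lambda = vol)
  fiberVolume(vol, voxelSize,
              meta = list(true_axes = axes, kappa = kappa,
                          mean_axis = mean_axis / sqrt(sum(mean_axis^2)),
                          seed = seed))
}
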