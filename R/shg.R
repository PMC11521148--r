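## 3D fiber orientation from SHG-like volumes: windowed subvolume Fourier
## spectra, spectral second-moment tensor (fiber axis = eigenvector of the
## smallest eigenvalue: the spectral energy of a fiber lies in the plane
## normal to the fiber), and axial dispersion statistics including the
## spherical variance.

#' Constructor for a fiber volume
#'
#' @param voxels X x Y x Z array of non-negative intensities.
#' @param voxelSize micrometres per voxel along x, y, z (length 3 or scalar).
#' @param meta metadata list.
#' @return a [FiberVolume-class].
#' @export
fiberVolume <- function(voxels, voxelSize = c(1, 1, 1), meta = list()) {
  if (length(voxelSize) == 1) voxelSize <- rep(voxelSize, 3)
  new("FiberVolume", voxels = voxels, voxelSize = as.numeric(voxelSize),
      meta = meta)
}

hannWindow <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

fftFreqIndex <- function(n) {
  ## signed integer frequency index of an unshifted DFT axis
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

## Fiber axis of one windowed subvolume. Returns list(v, weight, valid).
subvolumeAxis <- function(sub, voxelSize, window_list, shell_cut,
                         energy_threshold) {
  d <- dim(sub)
  w <- sub * window_list
  F <- fft(w)
  P <- Mod(F)^2
  dc <- P[1, 1, 1]
  kx <- fftFreqIndex(d[1]); ky <- fftFreqIndex(d[2]); kz <- fftFreqIndex(d[3])
  shell <- sqrt(outer(outer(kx^2, ky^2, "+"), kz^2, "+"))
  pass <- shell > shell_cut
  energy <- sum(P[pass])
  if (dc <= 0 || energy / dc < energy_threshold)
    return(list(v = c(NA, NA, NA), weight = energy, valid = FALSE))
  ## physical frequency coordinates (cycles/um) honour anisotropic voxels
  fx <- kx / (d[1] * voxelSize[1])
  fy <- ky / (d[2] * voxelSize[2])
  fz <- kz / (d[3] * voxelSize[3])
  p <- P[pass]
  gx <- array(rep(fx, times = d[2] * d[3]), d)[pass]
  gy <- array(rep(rep(fy, each = d[1]), times = d[3]), d)[pass]
  gz <- array(rep(fz, each = d[1] * d[2]), d)[pass]
  T <- matrix(c(sum(p * gx * gx), sum(p * gx * gy), sum(p * gx * gz),
                sum(p * gx * gy), sum(p * gy * gy), sum(p * gy * gz),
                sum(p * gx * gz), sum(p * gy * gz), sum(p * gz * gz)), 3, 3)
  ed <- eigen(T, symmetric = TRUE)
  v <- ed$vectors[, 3]              # smallest eigenvalue
  v <- v / sqrt(sum(v^2))
  list(v = v, weight = energy, valid = TRUE)
}

## Canonical sign for reporting a single axis: first nonzero of (x, y, z)
## component made positive.
canonicalAxis <- function(v) {
  s <- if (abs(v[1]) > 1e-9) sign(v[1]) else if (abs(v[2]) > 1e-9) sign(v[2])
       else sign(v[3])
  v * ifelse(s == 0, 1, s)
}

axisAngles <- function(v) {
  theta <- (rad2deg(atan2(v[2], v[1]))) %% 180
  phi <- rad2deg(asin(max(-1, min(1, v[3]))))
  c(theta_deg = theta, phi_deg = phi)
}

#' Estimate local fiber orientations over a volume
#'
#' Tiles the volume with cubic subvolumes (default 32 voxels, 50% overlap),
#' applies a Hann window, removes the DC term and the lowest two frequency
#' shells (suppressing illumination gradients), and takes the fiber axis of
#' each subvolume as the eigenvector of the smallest eigenvalue of the
#' spectral second-moment tensor. Subvolumes whose passband spectral energy
#' relative to the DC power falls below `energy_threshold` are flagged
#' invalid (flat or noise-only content).
#'
#' @param vol a [FiberVolume-class].
#' @param subvolume_size cubic subvolume side in voxels.
#' @param step grid step in voxels (default half the subvolume).
#' @param energy_threshold passband-to-DC power ratio below which a
#'   subvolume is invalid.
#' @param shell_cut frequency shells (integer radius) removed around DC.
#' @return an [OrientationField-class].
#' @export
estimateOrientations <- function(vol, subvolume_size = 32,
                                 step = subvolume_size / 2,
                                 energy_threshold = 0.5, shell_cut = 2) {
  stopifnot(is(vol, "FiberVolume"))
  d <- dim(vol@voxels)
  s <- rep(subvolume_size, 3)
  if (any(s > d)) stop("subvolume does not fit in the volume")
  win <- outer(outer(hannWindow(s[1]), hannWindow(s[2])), hannWindow(s[3]))
  dim(win) <- s
  starts <- lapply(1:3, function(a) {
    st <- seq(1, d[a] - s[a] + 1, by = max(1, round(step)))
    unique(st)
  })
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    x0 <- grid$x[g]; y0 <- grid$y[g]; z0 <- grid$z[g]
    sub <- vol@voxels[x0:(x0 + s[1] - 1), y0:(y0 + s[2] - 1),
                      z0:(z0 + s[3] - 1)]
    r <- subvolumeAxis(sub, vol@voxelSize, win, shell_cut, energy_threshold)
    v <- if (r$valid) canonicalAxis(r$v) else c(NA_real_, NA_real_, NA_real_)
    ang <- if (r$valid) axisAngles(v) else c(theta_deg = NA_real_,
                                             phi_deg = NA_real_)
    data.frame(ix = x0 + (s[1] - 1) / 2, iy = y0 + (s[2] - 1) / 2,
               iz = z0 + (s[3] - 1) / 2, vx = v[1], vy = v[2], vz = v[3],
               theta_deg = ang[["theta_deg"]], phi_deg = ang[["phi_deg"]],
               weight = r$weight, valid = r$valid)
  })
  new("OrientationField", axes = do.call(rbind, rows),
      meta = list(subvolume_size = subvolume_size, step = step,
                  energy_threshold = energy_threshold,
                  shell_cut = shell_cut, voxelSize = vol@voxelSize))
}

## Fold axial vectors into the hemisphere around the dominant eigenvector of
## their scatter matrix (sign chosen for a non-negative dot product).
## Rotation-invariant and respects the antipodal identification v ~ -v.
foldAxes <- function(V) {
  V <- as.matrix(V)
  if (any(sqrt(rowSums(V^2)) < 1e-12)) stop("zero vector in axis set")
  V <- V / sqrt(rowSums(V^2))
  Sc <- crossprod(V)
  mu <- eigen(Sc, symmetric = TRUE)$vectors[, 1]
  s <- sign(V %*% mu)
  s[s == 0] <- 1
  V * as.vector(s)
}

#' Spherical variance of a set of orientation axes
#'
#' `SV = 1 - || sum_i v_i || / n`, between 0 (perfectly aligned) and 1
#' (dispersed). Axes are antipodally identified: unless
#' `already_folded = TRUE`, each vector is first flipped into the hemisphere
#' around the dominant eigenvector of the axis scatter matrix.
#'
#' @param axes n x 3 matrix of unit vectors (rows), or a length-3 vector.
#' @param already_folded skip the hemisphere folding.
#' @return SV in `[0, 1]`.
#' @export
sphericalVariance <- function(axes, already_folded = FALSE) {
  if (is.null(dim(axes))) axes <- matrix(axes, ncol = 3)
  V <- as.matrix(axes)
  stopifnot(ncol(V) == 3, nrow(V) >= 1)
  if (!already_folded) V <- foldAxes(V) else {
    if (any(sqrt(rowSums(V^2)) < 1e-12)) stop("zero vector in axis set")
    V <- V / sqrt(rowSums(V^2))
  }
  1 - sqrt(sum(colSums(V)^2)) / nrow(V)
}

#' Dispersion summary of an orientation field
#'
#' Mean and standard deviation of the in-plane and out-of-plane angles
#' (computed on hemisphere-folded axes) and the spherical variance, raw and
#' normalized by `sv_max`. The default `sv_max = 0.4` is a configuration
#' constant (the literature's theoretical maximum under its folding
#' convention); with this package's folding the empirical maximum for
#' uniform random axes is close to, but not asserted to be, that value.
#'
#' @param field an [OrientationField-class] (or n x 3 axis matrix).
#' @param sv_max normalization constant for SV.
#' @return list: `n`, `mean_theta_deg`, `sd_theta_deg`, `mean_phi_deg`,
#'   `sd_phi_deg`, `sv`, `sv_normalized`, `mean_axis` (unit 3-vector).
#' @export
dispersionSummary <- function(field, sv_max = 0.4) {
  V <- if (is(field, "OrientationField")) {
    ax <- field@axes
    as.matrix(ax[ax$valid, c("vx", "vy", "vz")])
  } else as.matrix(field)
  if (nrow(V) < 1) stop("no valid axes")
  Vf <- foldAxes(V)
  m <- colSums(Vf)
  mean_axis <- m / sqrt(sum(m^2))
  ang <- t(apply(Vf, 1, axisAngles))
  ## in-plane angles are axial (period 180): average on the doubled angle
  th2 <- 2 * deg2rad(ang[, 1])
  mean_theta <- (rad2deg(atan2(mean(sin(th2)), mean(cos(th2)))) / 2) %% 180
  dev <- ((ang[, 1] - mean_theta + 90) %% 180) - 90
  sv <- sphericalVariance(Vf, already_folded = TRUE)
  list(n = nrow(Vf),
       mean_theta_deg = mean_theta,
       sd_theta_deg = stats::sd(dev),
       mean_phi_deg = mean(ang[, 2]),
       sd_phi_deg = stats::sd(ang[, 2]),
       sv = sv, sv_normalized = sv / sv_max,
       mean_axis = mean_axis)
}

#' Angular distance between two axes (antipodally identified)
#'
#' @param u,v unit 3-vectors.
#' @return angle in degrees, in `[0, 90]`.
#' @export
axisAngleBetween <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  rad2deg(acos(min(1, abs(sum(u * v)))))
}
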