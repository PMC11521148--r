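## Lu-Chipman polar decomposition (M = MDelta %*% MR %*% MD) and the
## rotation-invariant Mueller-matrix-transformation parameters.

#' @useDynLib muellerpol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

clip1 <- function(x, counter_env = NULL) {
  if (!is.null(counter_env) && (x > 1 || x < -1))
    counter_env$clips <- counter_env$clips + 1L
  min(1, max(-1, x))
}

#' Lu-Chipman polar decomposition of a single Mueller matrix
#'
#' Factorizes `M` (after m11 normalization) as a depolarizer times a
#' retarder times a diattenuator, `MDelta %*% MR %*% MD`, and derives the
#' scalar parameters: diattenuation `D`, total/linear/circular retardance
#' `R_deg`, `delta_deg`, `psi_deg`, total/linear/circular depolarization
#' `Delta`, `DeltaL`, `DeltaC`, and the retarder fast-axis orientation
#' `axis_deg`. The depolarizer block is built from the matrix square root of
#' `m' m'^T` with the sign of `det(m')`; arccos/sqrt arguments are clipped
#' into range and the clip events counted. By default `DeltaL`/`DeltaC` read
#' the diagonal of the depolarizer block; `depol_from = "eigen"` uses its
#' eigenvalues, attributed to the linear/circular channels by the dominant
#' component of each eigenvector.
#'
#' @param M 4 x 4 Mueller matrix with `m11 > 0`.
#' @param depol_from `"diagonal"` (default) or `"eigen"`.
#' @return a list with `MDelta`, `MR`, `MD` (normalized factors), `m11`,
#'   `scalars` (named numeric vector), and `clips` (clip-event count).
#' @export
mmpdDecomposePixel <- function(M, depol_from = c("diagonal", "eigen")) {
  depol_from <- match.arg(depol_from)
  stopifnot(is.matrix(M), all(dim(M) == 4))
  m11 <- M[1, 1]
  if (!is.finite(m11) || m11 <= 0) stop("m11 must be positive")
  Mn <- M / m11
  cnt <- new.env(); cnt$clips <- 0L

  ## diattenuator factor from the first row
  dv <- Mn[1, 2:4]
  D <- sqrt(sum(dv^2))
  if (D > 1) { D <- 1; cnt$clips <- cnt$clips + 1L }
  if (D < 1e-12) {
    MD <- diag(4)
    Mp <- Mn
  } else {
    dh <- dv / sqrt(sum(dv^2))
    sq <- sqrt(max(1 - D^2, 0))
    mD3 <- sq * diag(3) + (1 - sq) * tcrossprod(dh)
    MD <- rbind(c(1, dv), cbind(dv, mD3))
    MDi <- tryCatch(solve(MD), error = function(e) pinv(MD))
    if (1 - D < 1e-12) MDi <- pinv(MD)   # singular (ideal polarizer) branch
    Mp <- Mn %*% MDi
  }

  ## depolarizer factor from the matrix square-root construction
  mp <- Mp[2:4, 2:4]
  S <- mp %*% t(mp)
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 0] <- { cnt$clips <- cnt$clips + sum(lam < 0); 0 }
  s <- sqrt(lam)                       # descending
  k1 <- sum(s); k2 <- s[1] * s[2] + s[2] * s[3] + s[3] * s[1]
  k3 <- prod(s)
  dt <- det(mp)
  sgn <- if (dt >= 0) 1 else -1
  if (abs(dt) < 1e-14 && dt < 0) sgn <- 1   # tie resolved positive
  den <- S + k2 * diag(3)
  deni <- tryCatch(solve(den), error = function(e) pinv(den))
  mDel <- sgn * deni %*% (k1 * S + k3 * diag(3))
  PDel <- Mp[2:4, 1]
  MDelta <- rbind(c(1, 0, 0, 0), cbind(PDel, mDel))

  ## retarder factor
  mDeli <- tryCatch(solve(mDel), error = function(e) pinv(mDel))
  mR <- mDeli %*% mp
  MR <- rbind(c(1, 0, 0, 0), cbind(0, mR))

  R <- rad2deg(acos(clip1((1 + sum(diag(mR))) / 2 - 1, cnt)))
  delta <- rad2deg(acos(clip1(
    sqrt((mR[1, 1] + mR[2, 2])^2 + (mR[2, 1] - mR[1, 2])^2) - 1, cnt)))
  psi <- rad2deg(atan2(mR[2, 1] - mR[1, 2], mR[1, 1] + mR[2, 2]))
  if (depol_from == "diagonal") {
    Delta <- 1 - abs(sum(diag(mDel))) / 3
    DeltaL <- 1 - (abs(mDel[1, 1]) + abs(mDel[2, 2])) / 2
    DeltaC <- 1 - abs(mDel[3, 3])
  } else {
    ed <- eigen((mDel + t(mDel)) / 2, symmetric = TRUE)
    circ <- which.max(abs(ed$vectors[3, ]))
    lin <- setdiff(1:3, circ)
    Delta <- 1 - mean(abs(ed$values))
    DeltaL <- 1 - mean(abs(ed$values[lin]))
    DeltaC <- 1 - abs(ed$values[circ])
  }
  r1 <- mR[2, 3] - mR[3, 2]
  r2 <- mR[3, 1] - mR[1, 3]
  axis <- if (sqrt(r1^2 + r2^2) > 1e-9) 0.5 * rad2deg(atan2(r2, r1))
          else NA_real_

  list(MDelta = MDelta, MR = MR, MD = MD, m11 = m11,
       scalars = c(D = D, R_deg = R, delta_deg = delta, psi_deg = psi,
                   Delta = Delta, DeltaL = DeltaL, DeltaC = DeltaC,
                   axis_deg = axis),
       clips = cnt$clips)
}

#' Mueller-matrix-transformation parameters of a single matrix
#'
#' Rotation-invariant parameters from the central block of the m11-
#' normalized matrix: `b = (m22 + m33) / 2`,
#' `t = sqrt((m22 - m33)^2 + (m23 + m32)^2) / 2`, and the degree of
#' anisotropy `A_mmt = 2 b t / (b^2 + t^2)` (0 when `b = t = 0`).
#'
#' @param M 4 x 4 Mueller matrix (normalized internally by m11).
#' @return named numeric vector `c(b, t, A_mmt)`.
#' @export
mmtTransform <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == 4), M[1, 1] > 0)
  Mn <- M / M[1, 1]
  b <- (Mn[2, 2] + Mn[3, 3]) / 2
  t <- sqrt((Mn[2, 2] - Mn[3, 3])^2 + (Mn[2, 3] + Mn[3, 2])^2) / 2
  A <- if (b == 0 && t == 0) 0 else 2 * b * t / (b^2 + t^2)
  c(b = b, t = t, A_mmt = A)
}

#' Pixel-wise polarimetric parameter maps of a Mueller image
#'
#' Runs the Lu-Chipman decomposition and the Mueller-matrix transformation
#' at every valid pixel (compiled path) and returns all scalar maps:
#' `D`, `R_deg`, `delta_deg`, `psi_deg`, `Delta`, `DeltaL`, `DeltaC`,
#' `axis_deg`, `b`, `t`, `A_mmt`.
#'
#' @param mi a [MuellerImage-class] (or an H x W x 4 x 4 array).
#' @return a [PolarimetricMaps-class].
#' @export
polarimetricMaps <- function(mi) {
  meta <- list()
  if (is(mi, "MuellerImage")) {
    field <- mi@field; valid <- mi@valid; meta <- mi@meta
  } else {
    field <- mi
    valid <- matrix(TRUE, dim(field)[1], dim(field)[2])
  }
  d <- dim(field)
  flat <- matrix(field, d[1] * d[2], 16)
  flat[!as.vector(valid), ] <- NA_real_
  res <- .mmpd_maps_cpp(flat)
  nm <- c("D", "R_deg", "delta_deg", "psi_deg", "Delta", "DeltaL", "DeltaC",
          "axis_deg", "b", "t", "A_mmt")
  maps <- lapply(seq_along(nm), function(k) matrix(res$maps[, k], d[1], d[2]))
  names(maps) <- nm
  new("PolarimetricMaps", maps = maps, factors = list(),
      clipCount = as.integer(res$clips), meta = meta)
}

#' Reconstruct a Mueller image from an intensity stack
#'
#' Per pixel, `M = pinv(A) %*% B %*% pinv(W)` with `B` the pixel's 8 x 6
#' intensity matrix in schedule order. All-zero or non-finite pixels are
#' flagged invalid rather than raising an error.
#'
#' @param stack an [IntensityStack-class] (48 frames, PSG-major order).
#' @param instrument the [InstrumentModel-class] (ideal or calibrated).
#' @param normalize divide each pixel by its m11 (default `TRUE`).
#' @return a [MuellerImage-class].
#' @export
reconstructMueller <- function(stack, instrument, normalize = TRUE) {
  if (is(instrument, "CalibrationResult")) instrument <- instrument@instrument
  fr <- stack@frames
  d <- dim(fr)
  if (d[3] != 48) stop("frame-count mismatch: expected 48 frames")
  P <- kronecker(t(pinv(instrument@W)), pinv(instrument@A))   # 16 x 48
  Bflat <- matrix(fr, d[1] * d[2], 48)
  Mflat <- Bflat %*% t(P)
  valid <- matrix(rowSums(abs(Bflat)) > 0 & rowSums(!is.finite(Bflat)) == 0,
                  d[1], d[2])
  m11 <- Mflat[, 1]
  valid <- valid & matrix(is.finite(m11) & m11 > 0, d[1], d[2])
  if (normalize) {
    Mflat <- Mflat / m11
    Mflat[!as.vector(valid), ] <- NA_real_
  }
  field <- array(Mflat, c(d[1], d[2], 4, 4))
  new("MuellerImage", field = field, normalized = normalize, valid = valid,
      meta = list(schedule_digest = stack@meta$schedule_digest,
                  gain = stack@meta$gain))
}

#' Rate of physicality violations across an image
#'
#' Fraction of valid pixels whose Mueller matrix fails [isPhysical()]. A
#' useful corruption detector: frame permutations or schedule mismatches
#' push this rate up sharply.
#'
#' @param mi a [MuellerImage-class].
#' @param tol physicality tolerance passed to [isPhysical()].
#' @param cloude use the stricter coherency-eigenvalue test (with `tol`
#'   as the allowed relative negativity); effective for corruption
#'   detection since scrambled matrices are rarely near-PSD.
#' @return fraction in `[0, 1]`.
#' @export
physicalityViolationRate <- function(mi, tol = 1e-6, cloude = FALSE) {
  d <- dim(mi@field)
  idx <- which(mi@valid)
  if (!length(idx)) return(NA_real_)
  flat <- matrix(mi@field, d[1] * d[2], 16)
  bad <- vapply(idx, function(k) {
    !isPhysical(matrix(flat[k, ], 4, 4), tol = tol, cloude = cloude)
  }, logical(1))
  mean(bad)
}
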