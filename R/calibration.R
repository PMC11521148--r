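## Eigenvalue calibration method (ECM), generalized to the overdetermined
## 8-analyzer x 6-generator geometry. With B0 = A W (air) and Bi = A Mi W for
## reference sample Mi, the 6 x 6 reduction Ci = pinv(B0) Bi = pinv(W) Mi W
## shares its nonzero eigenvalues with Mi (basis invariance). Reference
## transmittances/retardances are fitted from those eigenvalues; W is the
## null vector of the stacked linear operator W -> Mi W - W Ci, with the
## reference axis angles refined numerically; A follows as B0 pinv(W).

#' Moore-Penrose pseudo-inverse
#'
#' @param M numeric matrix.
#' @param tol relative singular-value cutoff.
#' @return the pseudo-inverse of `M`.
#' @export
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Similarity reduction of a reference measurement
#'
#' Computes `C = pinv(b0) %*% b_i`. Its four non-negligible eigenvalues equal
#' the eigenvalues of the reference sample's Mueller matrix; the remaining
#' two are numerically zero and are discarded downstream.
#'
#' @param b0 8 x 6 air intensity matrix (must have numerical rank 4).
#' @param b_i 8 x 6 intensity matrix of the reference sample.
#' @return a 6 x 6 matrix.
#' @export
similarityReduce <- function(b0, b_i) {
  stopifnot(all(dim(b0) == c(8, 6)), all(dim(b_i) == c(8, 6)))
  if (numericalRank(b0) < 4)
    stop("air measurement has rank < 4: calibration impossible")
  pinv(b0) %*% b_i
}

numericalRank <- function(M, tol = 1e-8) {
  d <- svd(M, nu = 0, nv = 0)$d
  sum(d > tol * max(d))
}

## The four structurally nonzero eigenvalues of a 6 x 6 reduction, sorted by
## decreasing modulus.
kernelEigenvalues <- function(C) {
  ev <- eigen(C, only.values = TRUE)$values
  ev[order(Mod(ev), decreasing = TRUE)][1:4]
}

#' Fit reference-sample parameters from the reduction spectrum
#'
#' Transmittances and retardance are basis-invariant functions of the
#' eigenvalues of the reference Mueller matrix, so they can be fitted
#' without knowing the reference axis angle. A polarizer contributes real
#' eigenvalues `{q, sqrt(q r), sqrt(q r), r}`; a retarder of transmittance
#' `tau` contributes `{tau, tau, tau e^{+i delta}, tau e^{-i delta}}`. The
#' axis angle stays at its nominal value here and is refined in [solveW()].
#'
#' @param C_i 6 x 6 reduction from [similarityReduce()].
#' @param nominal list with `kind` (`"air"`, `"polarizer"`/`"diattenuator"`,
#'   `"retarder"`) and nominal `axis` / `retardance` / `q` / `r`.
#' @param tol eigenvalue-pattern tolerance.
#' @return the nominal list with fitted `q`, `r` or `retardance`, `tau`.
#' @export
fitReferenceParameters <- function(C_i, nominal, tol = 1e-6) {
  ev <- kernelEigenvalues(C_i)
  scale <- max(Mod(ev))
  kind <- nominal$kind
  if (kind == "air") {
    if (max(Mod(ev - mean(ev))) > 1e-3 * scale)
      warning("air reduction eigenvalues are not all equal")
    return(nominal)
  }
  if (kind %in% c("polarizer", "diattenuator")) {
    ## Only a large-modulus complex pair (a retarder-like spectrum) is
    ## inconsistent; the degenerate sqrt(q r) pair of a noisy near-ideal
    ## polarizer drifts complex with small modulus and is harmless.
    bigComplex <- abs(Im(ev)) > 0.2 * scale & Mod(ev) > 0.5 * scale
    if (any(bigComplex))
      stop("complex eigenvalues: spectrum inconsistent with a polarizer")
    ## q is the well-separated top eigenvalue (stable under noise); r comes
    ## from the trace identity tr(C) = q + r + 2 sqrt(q r) = (sqrt q +
    ## sqrt r)^2, which is noise-stable unlike the smallest eigenvalue of a
    ## rank-deficient reference.
    q <- max(Re(ev))
    s <- Re(sum(eigen(C_i, only.values = TRUE)$values))
    r <- max(sqrt(max(s, 0)) - sqrt(max(q, 0)), 0)^2
    nominal$q <- q
    nominal$r <- min(r, q)
    nominal$kind <- "polarizer"
    return(nominal)
  }
  if (kind == "retarder") {
    im <- abs(Im(ev))
    cand <- which(im > max(tol, 1e-3) * scale)
    if (!length(cand)) {
      if ((nominal$retardance %||% 0) < 1) {
        nominal$retardance <- 0; nominal$tau <- mean(Re(ev))
        return(nominal)
      }
      stop("no complex eigenvalue pair: spectrum inconsistent with a retarder")
    }
    top <- cand[which.max(Mod(ev)[cand])]
    nominal$retardance <- rad2deg(abs(Arg(ev[top])))
    nominal$tau <- Mod(ev[top])
    return(nominal)
  }
  stop("unknown reference kind: ", kind)
}

## Mueller matrix of a fitted reference at axis angle theta.
referenceMueller <- function(fit, axis_deg) {
  switch(fit$kind,
    air = diag(4),
    polarizer = {
      ## noisy fits may put q marginally above 1; factor the gain out
      g <- max(fit$q, 1)
      g * makeLinearDiattenuator(fit$q / g, min(fit$r, fit$q) / g, axis_deg)
    },
    retarder = (fit$tau %||% 1) * makeLinearRetarder(fit$retardance, axis_deg),
    stop("unknown reference kind: ", fit$kind))
}

## K(theta) = sum_i H_i' H_i with H_i = I6 (x) Mi - t(Ci) (x) I4, the normal
## matrix of the linear system vec(Mi W - W Ci) = 0 over vec(W) (24-dim).
ecmKernelMatrix <- function(C_list, fits, angles) {
  K <- matrix(0, 24, 24)
  for (i in seq_along(C_list)) {
    Mi <- referenceMueller(fits[[i]], angles[i])
    Hi <- kronecker(diag(6), Mi) - kronecker(t(C_list[[i]]), diag(4))
    K <- K + crossprod(Hi)
  }
  K
}

#' Solve for the generator matrix W (ECM kernel step)
#'
#' Finds the 4 x 6 matrix `W` minimizing `sum_i || Mi(theta_i) W - W Ci ||^2`
#' over `W` and the free reference axis angles, via the null space of the
#' stacked linear operator. The first non-air reference keeps its nominal
#' axis angle (that choice pins the laboratory frame); remaining angles are
#' refined numerically from their nominal starting values. The scale is
#' fixed by `W[1, 1] = 1`.
#'
#' @param C_list list of 6 x 6 reductions (one per reference, air included).
#' @param fits fitted reference parameters from [fitReferenceParameters()],
#'   each with a nominal `axis`.
#' @param optimize_angles refine free axis angles (default `TRUE`).
#' @param degeneracy_tol relative size below which the second-smallest kernel
#'   eigenvalue flags an ambiguous (degenerate) calibration.
#' @return list with `W` (4 x 6), `angles` (fitted axis angles, degrees),
#'   `residual` (smallest-to-next kernel eigenvalue ratio).
#' @export
solveW <- function(C_list, fits, optimize_angles = TRUE,
                   degeneracy_tol = 1e-7) {
  stopifnot(length(C_list) == length(fits))
  nominal <- vapply(fits, function(f) f$axis %||% 0, numeric(1))
  isAir <- vapply(fits, function(f) f$kind == "air", logical(1))
  free <- which(!isAir)
  if (length(free)) free <- free[-1]   # first non-air angle pins the frame
  obj <- function(off) {
    ang <- nominal
    ang[free] <- nominal[free] + off
    ev <- eigen(ecmKernelMatrix(C_list, fits, ang), symmetric = TRUE,
                only.values = TRUE)$values
    rev(ev)[1] / max(rev(ev)[2], .Machine$double.eps)
  }
  off <- numeric(length(free))
  ## only refine when the nominal angles do not already solve the system
  ## (simplex wobble would otherwise degrade an exact solution)
  if (optimize_angles && length(free) > 0 && obj(off) > 1e-13) {
    o <- stats::optim(off, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
    off <- o$par
  }
  angles <- nominal
  angles[free] <- nominal[free] + off
  K <- ecmKernelMatrix(C_list, fits, angles)
  ed <- eigen(K, symmetric = TRUE)
  ev <- rev(ed$values)
  scale <- mean(abs(ed$values))
  if (ev[2] < degeneracy_tol * scale)
    stop("ambiguous calibration: ECM kernel null space has dimension > 1 ",
         "(reference set does not constrain the instrument)")
  Wv <- matrix(ed$vectors[, 24], 4, 6)
  if (abs(Wv[1, 1]) < 1e-12)
    stop("degenerate solution: W[1,1] = 0, cannot fix the scale")
  Wv <- Wv / Wv[1, 1]
  list(W = Wv, angles = angles, residual = ev[1] / ev[2])
}

#' Solve for the analyzer matrix A from the air measurement
#'
#' `A = b0 %*% pinv(W)`; a forward consistency check `||A W - b0|| / ||b0||`
#' guards against an inconsistent air measurement.
#'
#' @param b0 8 x 6 air intensity matrix.
#' @param W 4 x 6 generator matrix (rank 4).
#' @param tol relative residual above which the air measurement is rejected.
#' @return an 8 x 4 matrix.
#' @export
solveA <- function(b0, W, tol = 0.05) {
  if (numericalRank(W) < 4) stop("W has rank < 4")
  A <- b0 %*% pinv(W)
  rel <- norm(A %*% W - b0, "F") / norm(b0, "F")
  if (rel > tol)
    stop(sprintf("inconsistent air measurement: relative residual %.3g", rel))
  A
}

#' Construct a reference acquisition set
#'
#' @param b0 8 x 6 air intensity matrix.
#' @param refs list of `list(nominal = <reference spec>, b = <8 x 6 matrix>)`.
#' @param meta optional metadata (e.g. `coarse_aligned = TRUE` to record the
#'   null-intensity bench pre-alignment).
#' @return a validated list of class `"ReferenceAcquisitionSet"`.
#' @export
referenceAcquisitionSet <- function(b0, refs, meta = list()) {
  stopifnot(all(dim(b0) == c(8, 6)))
  if (length(refs) < 1) stop("at least one non-air reference is required")
  clamp <- function(B) {
    dust <- -1e-9 * max(abs(B))        # floating-point dust is not a signal
    if (any(B < dust)) stop("intensities must be non-negative")
    B[B < 0] <- 0
    B
  }
  b0 <- clamp(b0)
  for (i in seq_along(refs)) {
    stopifnot(all(dim(refs[[i]]$b) == c(8, 6)))
    refs[[i]]$b <- clamp(refs[[i]]$b)
  }
  structure(list(b0 = b0, refs = refs, meta = meta),
            class = "ReferenceAcquisitionSet")
}

#' Eigenvalue calibration of the polarimeter
#'
#' Chains [similarityReduce()], [fitReferenceParameters()], [solveW()] and
#' [solveA()] on a reference acquisition set (air plus, canonically, a linear
#' polarizer at 0/45/90 deg and a quarter-wave plate at 0/45 deg). All
#' references enter one kernel system simultaneously. Deterministic.
#'
#' @param refs a `ReferenceAcquisitionSet` from [referenceAcquisitionSet()]
#'   or [makeReferenceAcquisitions()].
#' @param optimize_angles refine the free reference axis angles.
#' @param air_tol forward-consistency tolerance passed to [solveA()].
#' @return a [CalibrationResult-class].
#' @export
calibrate <- function(refs, optimize_angles = TRUE, air_tol = 0.05) {
  if (!inherits(refs, "ReferenceAcquisitionSet"))
    stop("missing or malformed reference set (air measurement required)")
  C_list <- c(list(similarityReduce(refs$b0, refs$b0)),
              lapply(refs$refs, function(r) similarityReduce(refs$b0, r$b)))
  fits <- c(list(list(kind = "air", axis = 0)),
            lapply(refs$refs, function(r) {
              fitReferenceParameters(similarityReduce(refs$b0, r$b),
                                     r$nominal)
            }))
  sw <- solveW(C_list, fits, optimize_angles = optimize_angles)
  A <- solveA(refs$b0, sw$W, tol = air_tol)
  inst <- new("InstrumentModel", W = sw$W, A = A,
              schedule = list(), meta = list(calibrated = TRUE))
  for (i in seq_along(fits)) fits[[i]]$axis <- sw$angles[i]
  new("CalibrationResult", instrument = inst, refFits = fits[-1],
      residual = sw$residual,
      meta = list(coarse_aligned = isTRUE(refs$meta$coarse_aligned)))
}

#' Pixel-by-pixel eigenvalue calibration
#'
#' Applies [calibrate()] independently at every pixel of per-pixel reference
#' acquisitions, with optional box-filter smoothing of the recovered W and A
#' fields (off by default).
#'
#' @param b0_stack H x W x 48 air acquisition (frames in schedule order).
#' @param ref_stacks list of `list(nominal =, stack = <H x W x 48 array>)`.
#' @param smooth odd box-filter width in pixels, or `NULL` for none.
#' @param optimize_angles refine reference axis angles at every pixel.
#' @return list with `W` (H x W x 4 x 6), `A` (H x W x 8 x 4), `residual`
#'   (H x W).
#' @export
calibratePixelwise <- function(b0_stack, ref_stacks, smooth = NULL,
                               optimize_angles = FALSE) {
  d <- dim(b0_stack)
  stopifnot(length(d) == 3, d[3] == 48)
  Wf <- array(NA_real_, c(d[1], d[2], 4, 6))
  Af <- array(NA_real_, c(d[1], d[2], 8, 4))
  res <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    b0 <- matrix(b0_stack[i, j, ], 8, 6)
    refs <- referenceAcquisitionSet(b0, lapply(ref_stacks, function(r)
      list(nominal = r$nominal, b = matrix(r$stack[i, j, ], 8, 6))))
    cal <- calibrate(refs, optimize_angles = optimize_angles)
    Wf[i, j, , ] <- instrumentW(cal)
    Af[i, j, , ] <- instrumentA(cal)
    res[i, j] <- calibrationResidual(cal)
  }
  if (!is.null(smooth)) {
    Wf <- boxSmoothField(Wf, smooth)
    Af <- boxSmoothField(Af, smooth)
  }
  list(W = Wf, A = Af, residual = res)
}

## Box smoothing of an H x W x a x b field along the two image axes.
boxSmoothField <- function(f, width) {
  stopifnot(width %% 2 == 1)
  h <- (width - 1) / 2
  d <- dim(f)
  out <- f
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ii <- max(1, i - h):min(d[1], i + h)
    jj <- max(1, j - h):min(d[2], j + h)
    out[i, j, , ] <- apply(f[ii, jj, , , drop = FALSE], c(3, 4), mean)
  }
  out
}
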