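## Elementary Mueller matrices and physical-validity checks.
##
## Conventions used package-wide (stated here once):
##   * Angles in all public interfaces are degrees, measured counter-clockwise
##     from horizontal looking into the beam; radians are internal only.
##   * Stokes vectors are column 4-vectors (s0, s1, s2, s3) with right-circular
##     light S = (1, 0, 0, 1).
##   * Retarder matrices follow the Lu-Chipman sign convention: a quarter-wave
##     plate with fast axis at 0 deg maps (1,0,1,0) -> (1,0,0,-1).
##   * Mueller matrix elements are referred to 1-based, m11 top-left.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Mueller rotation matrix
#'
#' Rotation of the polarization reference frame by `angle_deg` (counter-
#' clockwise looking into the beam). Used to rotate elementary elements to an
#' arbitrary axis: `M(theta) = R(theta) %*% M(0) %*% R(-theta)`.
#'
#' @param angle_deg rotation angle in degrees.
#' @return a 4x4 rotation Mueller matrix.
#' @export
muellerRotation <- function(angle_deg) {
  a <- 2 * deg2rad(angle_deg)
  c2 <- cos(a); s2 <- sin(a)
  matrix(c(1,  0,   0,  0,
           0, c2, -s2,  0,
           0, s2,  c2,  0,
           0,  0,   0,  1), 4, 4, byrow = TRUE)
}

#' Linear retarder Mueller matrix
#'
#' Standard rotated linear retarder: unit transmittance (m11 = 1),
#' determinant 1. `makeLinearRetarder(0, theta)` is the identity for any
#' `theta`.
#'
#' @param retardance_deg linear retardance in degrees.
#' @param axis_deg fast-axis orientation in degrees.
#' @return a 4x4 Mueller matrix.
#' @export
makeLinearRetarder <- function(retardance_deg, axis_deg = 0) {
  d <- deg2rad(retardance_deg)
  a <- 2 * deg2rad(axis_deg)
  C <- cos(a); S <- sin(a)
  cd <- cos(d); sd <- sin(d)
  matrix(c(1, 0, 0, 0,
           0, C^2 + S^2 * cd, C * S * (1 - cd), -S * sd,
           0, C * S * (1 - cd), S^2 + C^2 * cd,  C * sd,
           0, S * sd, -C * sd, cd), 4, 4, byrow = TRUE)
}

#' Circular retarder (rotator) Mueller matrix
#'
#' A pure circular retarder with circular retardance `psi_deg`; equivalently
#' an optical rotator by `psi_deg / 2` of geometric angle.
#'
#' @param psi_deg circular retardance in degrees.
#' @return a 4x4 Mueller matrix.
#' @export
makeCircularRetarder <- function(psi_deg) {
  p <- deg2rad(psi_deg)
  matrix(c(1, 0, 0, 0,
           0,  cos(p), -sin(p), 0,
           0,  sin(p),  cos(p), 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' Linear diattenuator (partial polarizer) Mueller matrix
#'
#' Two-transmittance linear diattenuator: intensity transmittance `q` along
#' the axis and `r` orthogonal to it. An ideal polarizer has `q = 1, r = 0`;
#' the diattenuation is `D = (q - r) / (q + r)`.
#'
#' @param q_transmittance transmittance along the axis, in `[0, 1]`.
#' @param r_transmittance transmittance across the axis, `r <= q`.
#' @param axis_deg transmission-axis orientation in degrees.
#' @return a 4x4 Mueller matrix.
#' @export
makeLinearDiattenuator <- function(q_transmittance, r_transmittance = 0,
                                   axis_deg = 0) {
  q <- q_transmittance; r <- r_transmittance
  if (!is.finite(q) || !is.finite(r) || r > q || r < 0 || q > 1)
    stop("require 0 <= r <= q <= 1")
  g <- sqrt(q * r)
  m0 <- 0.5 * matrix(c(q + r, q - r, 0, 0,
                       q - r, q + r, 0, 0,
                       0, 0, 2 * g, 0,
                       0, 0, 0, 2 * g), 4, 4, byrow = TRUE)
  R <- muellerRotation(axis_deg)
  R %*% m0 %*% muellerRotation(-axis_deg)
}

#' Diagonal depolarizer Mueller matrix
#'
#' `diag(1, a, b, c)`: `a` and `b` are the retained polarizance of the two
#' linear channels (H/V and +/-45), `c` of the circular channel. Circular
#' depolarization after decomposition is `1 - c`.
#'
#' @param a,b,c channel factors, each in `[0, 1]`.
#' @return a 4x4 Mueller matrix.
#' @export
makeDiagonalDepolarizer <- function(a, b, c) {
  v <- c(a, b, c)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("depolarizer diagonal entries must lie in [0, 1]")
  diag(c(1, a, b, c))
}

#' Elementary sample constructor from a parameter list
#'
#' Dispatches on `kind` in `retarder`, `diattenuator` (or `polarizer`),
#' `depolarizer`, `rotator`, `air`. This parameterizes the calibration
#' reference set (air, polarizers, quarter-wave plate).
#'
#' @param spec a list with fields `kind` and, as applicable, `retardance`,
#'   `axis`, `q`, `r`, `diag` (length-3), `psi`.
#' @return a 4x4 Mueller matrix.
#' @export
elementaryMueller <- function(spec) {
  switch(spec$kind,
    air = diag(4),
    retarder = makeLinearRetarder(spec$retardance, spec$axis %||% 0),
    polarizer = ,
    diattenuator = makeLinearDiattenuator(spec$q %||% 1, spec$r %||% 0,
                                          spec$axis %||% 0),
    depolarizer = makeDiagonalDepolarizer(spec$diag[1], spec$diag[2],
                                          spec$diag[3]),
    rotator = makeCircularRetarder(spec$psi),
    stop("unknown elementary kind: ", spec$kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic grid of 26 fully polarized Stokes directions: the unit
## directions through face centres, edge midpoints and corners of a cube.
stokesTestGrid <- function() {
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, , drop = FALSE]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cbind(1, dirs)   # rows are Stokes vectors (s0 = 1, fully polarized)
}

#' Physical-validity check for a Mueller matrix
#'
#' Checks that every fully polarized probe state on a fixed 26-direction
#' Stokes grid is mapped to a physical Stokes vector (non-negative intensity,
#' degree of polarization at most 1, within `tol`), and that `m11 > 0`.
#' With `cloude = TRUE` the stricter coherency-matrix eigenvalue test is used
#' instead: all four eigenvalues of the Hermitian coherency matrix must be
#' `>= -tol`.
#'
#' @param M 4x4 Mueller matrix.
#' @param tol numeric tolerance.
#' @param cloude use the Cloude eigenvalue test instead of the Stokes grid.
#' @return logical scalar.
#' @export
isPhysical <- function(M, tol = 1e-9, cloude = FALSE) {
  if (!is.matrix(M) || any(dim(M) != 4) || any(!is.finite(M))) return(FALSE)
  if (M[1, 1] <= 0) return(FALSE)
  if (cloude) {
    ev <- eigen(coherencyMatrix(M), symmetric = TRUE, only.values = TRUE)$values
    return(all(ev >= -tol * max(abs(ev), 1)))
  }
  S_out <- stokesTestGrid() %*% t(M)   # rows = output Stokes vectors
  s0 <- S_out[, 1]
  if (any(s0 < -tol)) return(FALSE)
  dop2 <- rowSums(S_out[, 2:4]^2)
  all(dop2 <= (s0 + tol)^2 * (1 + tol))
}

## Hermitian coherency matrix of a Mueller matrix (Cloude). Used only by the
## optional strict physicality mode.
coherencyMatrix <- function(M) {
  P <- list(diag(2),
            matrix(c(1, 0, 0, -1), 2, 2),
            matrix(c(0, 1, 1, 0), 2, 2),
            matrix(c(0, 1i, -1i, 0), 2, 2))
  H <- matrix(0 + 0i, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    A <- kronecker(P[[i]], Conj(P[[j]]))
    H <- H + M[i, j] * A
  }
  H / 4
}

#' Degree of polarization of a Stokes vector
#'
#' @param s length-4 Stokes vector.
#' @return `sqrt(s1^2 + s2^2 + s3^2) / s0`.
#' @export
degreeOfPolarization <- function(s) {
  stopifnot(length(s) == 4, s[1] > 0)
  sqrt(sum(s[2:4]^2)) / s[1]
}
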