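## Digital twin of the PSG/PSA polarimeter: the 6 x 8 measurement schedule,
## forward intensity synthesis B = A M W, noise and quantization.

#' The standard 48-frame measurement schedule
#'
#' Six generator states (polarizer at 0, 45, 90, -45 deg; quarter-wave plate
#' added at 45 / -45 deg for right/left circular) and eight analyzer
#' configurations: analyzers for 0, 45, 90, -45 deg, right and left circular,
#' plus two redundant configurations repeating the 0 and 45 deg analyzers
#' with the quarter-wave plate inserted at the alternate orientation. The
#' instrument literature does not pin down the two redundant analyzer states;
#' they are configurable here (edit the returned list before
#' [buildInstrument()]).
#'
#' @return a list with elements `psg` (6 settings) and `psa` (8 settings);
#'   each setting is `list(pol_deg=, qwp_in=, qwp_deg=)`.
#' @export
idealSchedule <- function() {
  psg <- list(
    list(pol_deg =   0, qwp_in = FALSE, qwp_deg = 0),
    list(pol_deg =  45, qwp_in = FALSE, qwp_deg = 0),
    list(pol_deg =  90, qwp_in = FALSE, qwp_deg = 0),
    list(pol_deg = -45, qwp_in = FALSE, qwp_deg = 0),
    list(pol_deg =   0, qwp_in = TRUE,  qwp_deg =  45),  # right circular
    list(pol_deg =   0, qwp_in = TRUE,  qwp_deg = -45))  # left circular
  psa <- list(
    list(pol_deg =   0, qwp_in = FALSE, qwp_deg = 0),
    list(pol_deg =  45, qwp_in = FALSE, qwp_deg = 0),
    list(pol_deg =  90, qwp_in = FALSE, qwp_deg = 0),
    list(pol_deg = -45, qwp_in = FALSE, qwp_deg = 0),
    list(pol_deg =   0, qwp_in = TRUE,  qwp_deg = -45),  # right circular
    list(pol_deg =   0, qwp_in = TRUE,  qwp_deg =  45),  # left circular
    list(pol_deg =   0, qwp_in = TRUE,  qwp_deg =   0),  # redundant 0 deg
    list(pol_deg =  45, qwp_in = TRUE,  qwp_deg =  45))  # redundant 45 deg
  list(psg = psg, psa = psa)
}

## Stokes vector produced by one PSG setting (unpolarized unit-intensity
## source -> polarizer -> optional QWP), normalized to s0 = 1.
psgStokes <- function(setting, pert = NULL) {
  pol <- makeLinearDiattenuator(1, pert$pol_r %||% 0,
                                setting$pol_deg + (pert$pol_offset_deg %||% 0))
  s <- pol %*% c(1, 0, 0, 0)
  if (setting$qwp_in) {
    qwp <- makeLinearRetarder(90 + (pert$qwp_ret_offset_deg %||% 0),
                              setting$qwp_deg + (pert$qwp_offset_deg %||% 0))
    s <- qwp %*% s
  }
  as.numeric(s / s[1])
}

## Analyzer projection row for one PSA setting (optional QWP then polarizer
## then detector): first row of P %*% QWP.
psaRow <- function(setting, pert = NULL) {
  M <- makeLinearDiattenuator(1, pert$pol_r %||% 0,
                              setting$pol_deg + (pert$pol_offset_deg %||% 0))
  if (setting$qwp_in) {
    qwp <- makeLinearRetarder(90 + (pert$qwp_ret_offset_deg %||% 0),
                              setting$qwp_deg + (pert$qwp_offset_deg %||% 0))
    M <- M %*% qwp
  }
  as.numeric(M[1, ])
}

#' Build an instrument model from a schedule and optical imperfections
#'
#' Perturbations model systematic imperfections of the generator/analyzer
#' optics: polarizer axis offsets, quarter-wave-plate axis and retardance
#' offsets, and finite polarizer extinction. Offsets beyond 10 deg (axis) or
#' 20 deg (retardance) are rejected as outside the intended small-
#' imperfection regime.
#'
#' @param schedule a schedule from [idealSchedule()].
#' @param psg_errors,psa_errors `NULL` (ideal) or a list with any of
#'   `pol_offset_deg`, `qwp_offset_deg`, `qwp_ret_offset_deg`, `pol_r`
#'   (extinction transmittance); each either a scalar applied to all
#'   states or a vector, one entry per state.
#' @return an [InstrumentModel-class].
#' @export
buildInstrument <- function(schedule = idealSchedule(), psg_errors = NULL,
                            psa_errors = NULL) {
  checkPert <- function(p, n) {
    for (f in c("pol_offset_deg", "qwp_offset_deg"))
      if (any(abs(p[[f]] %||% 0) > 10))
        stop(f, " exceeds the 10 deg imperfection bound")
    if (any(abs(p$qwp_ret_offset_deg %||% 0) > 20))
      stop("qwp_ret_offset_deg exceeds the 20 deg imperfection bound")
    if (any((p$pol_r %||% 0) < 0 | (p$pol_r %||% 0) > 0.2))
      stop("pol_r must lie in [0, 0.2]")
    lapply(seq_len(n), function(i) {
      lapply(p, function(v) if (length(v) > 1) v[[i]] else v)
    })
  }
  pg <- checkPert(psg_errors %||% list(), length(schedule$psg))
  pa <- checkPert(psa_errors %||% list(), length(schedule$psa))
  W <- vapply(seq_along(schedule$psg),
              function(j) psgStokes(schedule$psg[[j]], pg[[j]]),
              numeric(4))
  A <- t(vapply(seq_along(schedule$psa),
                function(i) psaRow(schedule$psa[[i]], pa[[i]]),
                numeric(4)))
  obj <- new("InstrumentModel", W = W, A = A, schedule = schedule,
             meta = list(perturbed = !is.null(psg_errors) ||
                           !is.null(psa_errors),
                         psg_errors = psg_errors, psa_errors = psa_errors))
  validObject(obj)
  obj
}

#' Forward-acquire a 48-frame intensity stack
#'
#' Synthesizes, per pixel, `B[i, j] = A[i, ] %*% M %*% W[, j]`, scaled by
#' `gain` so the brightest ideal frame sits near full well, then applies
#' optional Poisson shot noise and Gaussian read noise, clips at zero and
#' quantizes at the requested bit depth. Deterministic under a fixed seed.
#'
#' @param M_field H x W x 4 x 4 array, a [MuellerImage-class], or a single
#'   4 x 4 matrix (treated as a 1 x 1 image).
#' @param instrument an [InstrumentModel-class].
#' @param gain full-well scaling: the ideal air frame maximum maps to `gain`.
#' @param noise `NULL` for the noise-free path, or
#'   `list(shot = TRUE/FALSE, read_sd = counts)`.
#' @param bitDepth `"float"` (no quantization), `"8"` or `"16"`.
#' @param seed integer seed for the noise draws (required when noise is on).
#' @return an [IntensityStack-class].
#' @export
forwardAcquire <- function(M_field, instrument, gain = 1, noise = NULL,
                           bitDepth = "float", seed = NULL) {
  if (is(M_field, "MuellerImage")) M_field <- M_field@field
  if (is.matrix(M_field) && all(dim(M_field) == 4))
    M_field <- array(M_field, c(1, 1, 4, 4))
  d <- dim(M_field)
  stopifnot(length(d) == 4, d[3] == 4, d[4] == 4)
  H <- d[1]; Wd <- d[2]
  A <- instrument@A; W <- instrument@W
  ## vec(B) = (t(W) %x% A) vec(M): one 16 x 48 operator for all pixels
  G <- kronecker(t(W), A)                       # 48 x 16
  Mflat <- matrix(M_field, H * Wd, 16)          # column-major: (i,j) pairs
  B <- Mflat %*% t(G)                           # (H*W) x 48
  if (min(B) < -1e-8 * max(abs(B)))
    stop("negative ideal intensities: sign-convention or physicality bug")
  B[B < 0] <- 0
  B <- B * gain
  if (!is.null(noise)) {
    if (is.null(seed)) stop("a seed is required for the noisy path")
    set.seed(as.integer(seed))
    if (isTRUE(noise$shot)) B[] <- stats::rpois(length(B), lambda = B)
    if (!is.null(noise$read_sd) && noise$read_sd > 0)
      B <- B + stats::rnorm(length(B), sd = noise$read_sd)
    B[B < 0] <- 0
  }
  if (bitDepth != "float") {
    top <- 2^as.integer(bitDepth) - 1
    B <- round(B)
    B[B > top] <- top
  }
  fr <- array(B, c(H, Wd, 48))
  new("IntensityStack", frames = fr, bitDepth = bitDepth,
      meta = list(gain = gain, noise = noise, seed = seed,
                  frame_order = "psg_major_psa_minor",
                  schedule_digest = scheduleDigest(instrument@schedule)))
}

#' Average several independently noisy acquisitions (rolling averaging)
#'
#' Emulates frame averaging on the bench: acquires `k` stacks with seeds
#' `seed, seed + 1, ...` and averages them.
#'
#' @inheritParams forwardAcquire
#' @param k number of stacks averaged.
#' @return an [IntensityStack-class] with `bitDepth = "float"`.
#' @export
forwardAcquireAveraged <- function(M_field, instrument, k = 4, gain = 1,
                                   noise = NULL, bitDepth = "float",
                                   seed = 1) {
  acc <- NULL
  for (i in seq_len(k)) {
    st <- forwardAcquire(M_field, instrument, gain = gain, noise = noise,
                         bitDepth = bitDepth, seed = seed + i - 1L)
    acc <- if (is.null(acc)) st@frames else acc + st@frames
  }
  new("IntensityStack", frames = acc / k, bitDepth = "float",
      meta = list(gain = gain, noise = noise, seed = seed, averaged = k))
}

## Stable digest of a schedule (for manifests and frame-order checks).
scheduleDigest <- function(schedule) {
  s <- paste(utils::capture.output(utils::str(schedule)), collapse = "\n")
  f <- tempfile(); on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

## Per-pixel 8 x 6 intensity matrix of a stack pixel.
pixelB <- function(stack, i, j) {
  matrix(stack@frames[i, j, ], 8, 6)
}
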