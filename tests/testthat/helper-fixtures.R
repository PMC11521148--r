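## Shared fixture builders for the test suite. Everything is generated in
## code under fixed seeds; no data files.

## A random physical Mueller matrix composed from the elementary
## constructors: depolarizer %*% (circular+linear retarder) %*% diattenuator.
## Returns the matrix plus the construction parameters.
randomMuellerProduct <- function(rng = NULL, max_D = 0.3) {
  if (!is.null(rng)) set.seed(rng)
  pars <- list(
    delta = stats::runif(1, 1, 160),
    theta = stats::runif(1, -90, 90),
    psi = stats::runif(1, -30, 30),
    abc = stats::runif(3, 0.7, 1),
    D = stats::runif(1, 0, max_D),
    axD = stats::runif(1, -90, 90))
  q <- 0.9
  r <- q * (1 - pars$D) / (1 + pars$D)
  M <- makeDiagonalDepolarizer(pars$abc[1], pars$abc[2], pars$abc[3]) %*%
    (makeCircularRetarder(pars$psi) %*%
       makeLinearRetarder(pars$delta, pars$theta)) %*%
    makeLinearDiattenuator(q, r, pars$axD)
  list(M = M, pars = pars)
}

## A small random instrument perturbation within the documented bounds.
randomPerturbation <- function() {
  list(pol_offset_deg = stats::runif(1, -3, 3),
       qwp_offset_deg = stats::runif(1, -3, 3),
       qwp_ret_offset_deg = stats::runif(1, -5, 5),
       pol_r = stats::runif(1, 0, 0.02))
}

## Homogeneous single-pixel phantom through the full noise-free pipeline:
## forward acquisition -> pseudo-inverse reconstruction -> decomposition.
pipelineScalars <- function(M, instrument = buildInstrument()) {
  st <- forwardAcquire(M, instrument)
  mi <- reconstructMueller(st, instrument)
  mmpdDecomposePixel(matrix(mi@field[1, 1, , ], 4, 4))$scalars
}

expect_matrix_equal <- function(object, expected, tol = 1e-12) {
  expect_lt(max(abs(object - expected)), tol)
}
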