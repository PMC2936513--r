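# Linear stability of the homogeneous solution, assessed per spatial
# frequency in Fourier space.

# Fourier transform of the unit-area Gaussian kernel at angular frequency q
# (rad/mm): exp(-sigma^2 q^2 / 2).
.kernelFourier <- function(q, sigma) exp(-(sigma^2) * q^2 / 2)

# transfer-function derivatives at the homogeneous fixed point
.fixedPointSlopes <- function(params, fp) {
  list(fe = .transferSlope(fp@ueBar, params@betaE, params@thetaE),
       fi = .transferSlope(fp@uiBar, params@betaI, params@thetaI))
}

#' Growth rates of spatial-frequency modes around the homogeneous state
#'
#' Eigenvalues of the 2x2 Jacobian of the linearized field equations at
#' angular frequency `q`:
#' \deqn{J(q) = \begin{pmatrix} (-1 + g_{EE} f'_E W_{EE}(q))/\tau_E &
#'  -g_{IE} f'_I/\tau_E \\ g_{EI} f'_E W_{EI}(q)/\tau_I & -1/\tau_I
#'  \end{pmatrix}}
#' where `W` are the Gaussian kernel transforms and the derivatives are taken
#' at the fixed point. The mode is stable iff both eigenvalues have negative
#' real part; as `q` grows the kernels' transforms vanish and the eigenvalues
#' approach `-1/tauE`, `-1/tauI`.
#'
#' @param params a [FieldParams-class].
#' @param q angular spatial frequency, rad/mm (vectorized).
#' @param fp optionally a precomputed [FixedPoint-class].
#' @return complex matrix `[length(q) x 2]` of eigenvalues (1/ms).
#' @export
dispersion <- function(params, q, fp = homogeneousFixedPoint(params)) {
  sl <- .fixedPointSlopes(params, fp)
  out <- matrix(complex(real = NA_real_), length(q), 2)
  for (i in seq_along(q)) {
    Wee <- .kernelFourier(q[i], params@sigmaEE)
    Wei <- .kernelFourier(q[i], params@sigmaEI)
    J <- matrix(c((-1 + params@gEE * sl$fe * Wee) / params@tauE,
                  params@gEI * sl$fe * Wei / params@tauI,
                  -params@gIE * sl$fi / params@tauE,
                  -1 / params@tauI), 2, 2)
    out[i, ] <- eigen(J, only.values = TRUE)$values
  }
  out
}

# margins of the two stability conditions at frequency q:
#   A (trace):       (1 - gEE fe' Wee)/tauE + 1/tauI > 0
#   B (determinant): (1 - gEE fe' Wee) + gIE gEI fi' fe' Wei > 0
.stabilityMargins <- function(params, q, sl) {
  Wee <- .kernelFourier(q, params@sigmaEE)
  Wei <- .kernelFourier(q, params@sigmaEI)
  a <- params@gEE * sl$fe * Wee
  m1 <- (1 - a) / params@tauE + 1 / params@tauI
  m2 <- (1 - a) + params@gIE * params@gEI * sl$fi * sl$fe * Wei
  cbind(m1, m2)
}

#' Check linear stability of the homogeneous solution
#'
#' Evaluates the trace and determinant conditions of the frequency-indexed
#' linearization over a dense grid of spatial frequencies
#' `[0, freqMax]` (default `4 / min(sigma)` rad/mm - Gaussian transforms are
#' inert beyond that), refines around the worst frequency by golden-section
#' search, and reports the margins there. The homogeneous state is
#' asymptotically stable iff both margins are positive at every frequency.
#'
#' If the resting homogeneous branch itself has been destroyed by runaway
#' recurrent excitation (see [homogeneousFixedPoint()]), there is no stable
#' resting state to linearize about and the verdict is unstable with
#' `NA` margins and an explanatory `note`.
#'
#' @param params a [FieldParams-class].
#' @param freqMax largest probed frequency, rad/mm.
#' @param nFreq number of grid points.
#' @return A [StabilityVerdict-class].
#' @examples
#' isStable(checkStability(fieldParams()))            # reference set: stable
#' isStable(checkStability(fieldParams(gEE = 1250)))  # inflated gain: unstable
#' @export
checkStability <- function(params, freqMax = 4 / min(params@sigmaEE, params@sigmaEI),
                           nFreq = 512L) {
  fp <- withCallingHandlers(
    tryCatch(homogeneousFixedPoint(params), noRestState = function(e) e),
    error = function(e) e)
  if (inherits(fp, "noRestState"))
    return(new("StabilityVerdict", stable = FALSE, worstFrequency = NA_real_,
               margin1 = NA_real_, margin2 = NA_real_, freqGrid = numeric(0),
               note = conditionMessage(fp)))
  if (inherits(fp, "error")) stop(fp)
  sl <- .fixedPointSlopes(params, fp)
  qs <- seq(0, freqMax, length.out = nFreq)
  mg <- .stabilityMargins(params, qs, sl)
  worstOf <- pmin(mg[, 1], mg[, 2])
  iw <- which.min(worstOf)
  # golden-section refinement of the minimal margin around the worst grid point
  lo <- qs[max(1L, iw - 1L)]; hi <- qs[min(nFreq, iw + 1L)]
  f <- function(q) min(.stabilityMargins(params, q, sl))
  opt <- optimize(f, c(lo, hi))
  qWorst <- if (opt$objective < worstOf[iw]) opt$minimum else qs[iw]
  mWorst <- .stabilityMargins(params, qWorst, sl)
  stable <- all(worstOf > 0) && min(mWorst) > 0
  new("StabilityVerdict", stable = stable, worstFrequency = unname(qWorst),
      margin1 = unname(mWorst[1, 1]), margin2 = unname(mWorst[1, 2]),
      freqGrid = qs, note = "")
}

#' Eigenvalues of the full discretized linear operator
#'
#' Direct eigendecomposition of the `2 nPositions` dimensional Jacobian of
#' the spatially discretized system at the homogeneous fixed point - the
#' brute-force counterpart to the Fourier-space criteria, used for
#' cross-validation. (Because the discrete convolution is zero-padded rather
#' than circular, edge modes make this operator slightly more stable than the
#' infinite-domain criteria; agreement is expected away from marginality.)
#'
#' @param params a [FieldParams-class].
#' @param grid a [SpaceTimeGrid-class].
#' @return complex vector of eigenvalues (1/ms).
#' @export
discretizedSpectrum <- function(params, grid = spaceTimeGrid()) {
  fp <- homogeneousFixedPoint(params)
  sl <- .fixedPointSlopes(params, fp)
  cp <- .couplings(params, grid)
  n <- grid@nPositions
  A11 <- (-diag(n) + cp$Mee * sl$fe) / params@tauE
  A12 <- diag(-params@gIE * sl$fi / params@tauE, n)
  A21 <- (cp$Mei * sl$fe) / params@tauI
  A22 <- diag(-1 / params@tauI, n)
  J <- rbind(cbind(A11, A12), cbind(A21, A22))
  eigen(J, only.values = TRUE)$values
}
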