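# Two-layer neural field core: transfer function, coupling kernels, Euler
# integration (C++ inner loop) and the homogeneous fixed point.

#' Logistic transfer (axonal response) function
#'
#' Relates depolarization to firing rate: `1 / (1 + exp(-beta * (u - theta)))`,
#' strictly increasing with limits 0 and 1 and value 1/2 at the threshold.
#'
#' @param u membrane potential, mV (vectorized).
#' @param beta slope, 1/mV.
#' @param theta threshold, mV.
#' @return firing rate in `[0, 1]`.
#' @examples
#' transferRate(-40, 0.15, -40)   # 0.5 at threshold
#' @export
transferRate <- function(u, beta, theta) {
  stopifnot(beta > 0)
  1 / (1 + exp(-beta * (u - theta)))
}

# derivative of the logistic transfer at u
.transferSlope <- function(u, beta, theta) {
  f <- transferRate(u, beta, theta)
  beta * f * (1 - f)
}

#' Gaussian coupling kernel
#'
#' Synaptic weight per mm at a given cortical distance: a unit-area Gaussian
#' scaled by the coupling gain. Even in distance (translation invariant,
#' isotropic).
#'
#' @param distance cortical distance, mm (vectorized).
#' @param sigma kernel width, mm.
#' @param gain coupling gain.
#' @return synaptic weight density, 1/mm times gain.
#' @examples
#' couplingKernel(0, 1.27, 1)   # peak 1/(1.27 sqrt(2 pi))
#' @export
couplingKernel <- function(distance, sigma, gain = 1) {
  stopifnot(sigma > 0)
  gain * dnorm(distance, sd = sigma)
}

#' Dense coupling matrix for a grid
#'
#' Toeplitz matrix `M[i, j] = gain * w(x_i - x_j) * pixelPitch` built from the
#' discretely normalized kernel of [discreteGaussian()], so that row sums in
#' the grid interior equal `gain` exactly and the convolution `M %*% f` is the
#' zero-padded discrete integral of the field equations.
#'
#' @param grid a [SpaceTimeGrid-class].
#' @param sigma kernel width, mm.
#' @param gain coupling gain.
#' @return `nPositions x nPositions` matrix.
#' @export
couplingMatrix <- function(grid, sigma, gain) {
  k <- discreteGaussian(sigma, grid@pixelPitch)
  K <- attr(k, "halfWidth")
  n <- grid@nPositions
  M <- matrix(0, n, n)
  D <- outer(seq_len(n), seq_len(n), "-")
  idx <- abs(D) <= K
  M[idx] <- k[D[idx] + K + 1]
  gain * M * grid@pixelPitch
}

#' One explicit-Euler step of the two-layer field
#'
#' Reference R implementation of the discretized update used by the C++
#' integrator; exposed for testing and for composing custom integration
#' schemes. The excitatory layer receives recurrent excitation through the
#' `Mee` coupling matrix, strictly local inhibition `-gIE * f_i(uI)` and the
#' afferent input; the inhibitory layer receives `Mei`-coupled excitation
#' only.
#'
#' @param uEv,uIv state vectors, mV.
#' @param inputRow afferent drive at this instant, mV (length `nPositions`).
#' @param params a [FieldParams-class].
#' @param dt time step, ms; must satisfy `dt <= min(tauE, tauI) / 5`.
#' @param Mee,Mei coupling matrices (precomputed via [couplingMatrix()]; built
#'   on the fly from `grid` if omitted).
#' @param grid a [SpaceTimeGrid-class] (only needed when matrices are omitted).
#' @return list with updated `uE`, `uI`.
#' @export
fieldStep <- function(uEv, uIv, inputRow, params, dt, Mee = NULL, Mei = NULL,
                      grid = NULL) {
  if (dt > min(params@tauE, params@tauI) / 5)
    stop("dt must be <= min(tauE, tauI)/5 for the explicit-Euler accuracy guard")
  if (is.null(Mee)) Mee <- couplingMatrix(grid, params@sigmaEE, params@gEE)
  if (is.null(Mei)) Mei <- couplingMatrix(grid, params@sigmaEI, params@gEI)
  fe <- transferRate(uEv, params@betaE, params@thetaE)
  fi <- transferRate(uIv, params@betaI, params@thetaI)
  uEn <- uEv + dt / params@tauE *
    (-uEv + params@hE + drop(Mee %*% fe) - params@gIE * fi + inputRow)
  uIn <- uIv + dt / params@tauI * (-uIv + params@hI + drop(Mei %*% fe))
  if (any(!is.finite(uEn)) || any(!is.finite(uIn)))
    stop("field step produced non-finite state (instability); reduce dt or gains")
  list(uE = uEn, uI = uIn)
}

#' Homogeneous fixed point (resting branch) of the field equations
#'
#' Solves `ue = hE + gEE f_e(ue) - gIE f_i(ui)`, `ui = hI + gEI f_e(ue)`
#' (unit-area kernels integrate to one in the homogeneous state). The system
#' reduces to a scalar root problem in `ue`. With strong recurrent
#' excitation the equations are bistable (a quiescent and a saturated active
#' state coexist); the physically meaningful baseline is the *resting*
#' branch, obtained here by continuation: the root is tracked from the
#' decoupled system (all gains zero, where it equals `(hE, hI)` exactly)
#' while the gains are ramped up to their requested values. If the branch is
#' destroyed on the way (a saddle-node fold, e.g. under strongly inflated
#' `gEE`), the model has no resting state and an error of class
#' `"noRestState"` is signaled.
#'
#' @param params a [FieldParams-class].
#' @param tol residual tolerance, mV.
#' @param nRamp continuation steps for the gain ramp.
#' @return A [FixedPoint-class] on the resting branch.
#' @examples
#' homogeneousFixedPoint(fieldParams(gEE = 0, gIE = 0, gEI = 0))  # (hE, hI)
#' @export
homogeneousFixedPoint <- function(params, tol = 1e-10, nRamp = 40L) {
  gOf <- function(ue, s) {
    fe <- transferRate(ue, params@betaE, params@thetaE)
    ui <- params@hI + s * params@gEI * fe
    -ue + params@hE + s * params@gEE * fe -
      s * params@gIE * transferRate(ui, params@betaI, params@thetaI)
  }
  ue <- params@hE  # exact root of the decoupled system (s = 0)
  maxStep <- 25    # a fold makes the root jump by more than this, mV
  for (s in seq(0, 1, length.out = nRamp + 1L)[-1]) {
    g <- function(u) gOf(u, s)
    if (abs(g(ue)) < tol) next
    # bracket around the previous root, expanding up to maxStep
    half <- 0.5
    found <- FALSE
    while (half <= maxStep) {
      lo <- ue - half; hi <- ue + half
      if (g(lo) * g(hi) < 0) {
        ue <- uniroot(g, c(lo, hi), tol = tol / 10)$root
        found <- TRUE
        break
      }
      half <- half * 2
    }
    if (!found)
      stop(structure(class = c("noRestState", "error", "condition"),
                     list(message = sprintf(
                       paste("resting homogeneous solution lost at gain ramp s = %.2f",
                             "(saddle-node fold: runaway recurrent excitation)"), s),
                       call = sys.call(-1))))
  }
  # polish at s = 1
  g1 <- function(u) gOf(u, 1)
  if (abs(g1(ue)) > tol) {
    pol <- tryCatch(uniroot(g1, c(ue - 1, ue + 1), tol = tol / 10,
                            extendInt = "yes")$root, error = function(e) ue)
    if (abs(g1(pol)) < abs(g1(ue))) ue <- pol
  }
  uiBar <- params@hI + params@gEI * transferRate(ue, params@betaE, params@thetaE)
  new("FixedPoint", ueBar = ue, uiBar = uiBar, residual = abs(g1(ue)))
}

# shared plumbing: precompute coupling matrices for a parameter set
.couplings <- function(params, grid) {
  list(Mee = couplingMatrix(grid, params@sigmaEE, params@gEE),
       Mei = couplingMatrix(grid, params@sigmaEI, params@gEI))
}

.parsVec <- function(params)
  list(tauE = params@tauE, tauI = params@tauI, hE = params@hE, hI = params@hI,
       gIE = params@gIE, betaE = params@betaE, betaI = params@betaI,
       thetaE = params@thetaE, thetaI = params@thetaI)

#' Simulate the two-layer field for one stimulus
#'
#' Starting from `uE = uI = 0` everywhere, the system is relaxed for
#' `relaxMs` of model time without input (the terminal drift is checked
#' against `driftTol`), then integrated through the stimulus window (with any
#' moving-stimulus lead-in) by explicit Euler with `sub` substeps per frame.
#' With `init = "fixedpoint"` the relaxation is replaced by starting at the
#' algebraic homogeneous fixed point plus a short 100 ms settle - identical
#' state up to the drift tolerance, used inside identification loops for
#' speed.
#'
#' @param params a [FieldParams-class].
#' @param input an [InputField-class] (or a protocol via [simulateCondition()]).
#' @param grid a [SpaceTimeGrid-class].
#' @param sub Euler substeps per frame (default 10, i.e. dt = 0.96 ms).
#' @param relaxMs relaxation period, ms of model time.
#' @param init `"zero"` (relax from zero) or `"fixedpoint"`.
#' @param driftTol maximum terminal relaxation drift, mV/ms.
#' @param condition label stored in the trajectory.
#' @param fp optional precomputed [FixedPoint-class] (used with
#'   `init = "fixedpoint"`; avoids re-solving inside parameter-scan loops).
#' @return A [FieldTrajectory-class] with frames at the imaging times.
#' @export
simulateField <- function(params, input, grid, sub = 10L, relaxMs = 2000,
                          init = c("zero", "fixedpoint"), driftTol = 1e-5,
                          condition = "", fp = NULL) {
  init <- match.arg(init)
  dt <- grid@frameDt / sub
  if (dt > min(params@tauE, params@tauI) / 5)
    stop("dt = frameDt/sub must be <= min(tauE, tauI)/5; increase sub")
  cp <- .couplings(params, grid)
  pv <- .parsVec(params)
  n <- grid@nPositions
  if (init == "fixedpoint") {
    if (is.null(fp)) fp <- homogeneousFixedPoint(params)
    u0e <- rep(fp@ueBar, n); u0i <- rep(fp@uiBar, n)
    # edges of the buffered grid rest slightly off the homogeneous state
    # (zero-padded kernels); 400 ms settles them below the drift tolerance
    relaxMs <- 400
  } else {
    u0e <- numeric(n); u0i <- numeric(n)
  }
  rel <- do.call(.nf_relax, c(list(cp$Mee, cp$Mei, u0e, u0i,
                                   as.integer(round(relaxMs / dt)), dt), pv))
  if (rel$drift > driftTol)
    stop(sprintf("relaxation did not settle within %g ms: terminal drift %.3g mV/ms (tolerance %.3g)",
                 relaxMs, rel$drift, driftTol))
  win <- do.call(.nf_window, c(list(cp$Mee, cp$Mei, rel$ue, rel$ui,
                                    input@values, input@leadFrames,
                                    grid@nFrames, as.integer(sub), dt), pv))
  new("FieldTrajectory", uE = win$uE, uI = win$uI, grid = grid, params = params,
      relaxed = TRUE, condition = condition)
}

#' Simulate one named stimulus condition
#'
#' Builds the afferent drive for `protocol` and integrates the field.
#'
#' @param params a [FieldParams-class].
#' @param protocol a [StimulusProtocol-class].
#' @param grid a [SpaceTimeGrid-class].
#' @param condition label (defaults to the protocol kind).
#' @param ... passed to [simulateField()].
#' @return A [FieldTrajectory-class].
#' @examples
#' \donttest{
#' traj <- simulateCondition(fieldParams(), stimulusProtocol("flashed_square"),
#'                           spaceTimeGrid())
#' }
#' @export
simulateCondition <- function(params, protocol, grid, condition = protocol@kind, ...) {
  input <- stimulusDrive(protocol, grid, params)
  simulateField(params, input, grid, condition = condition, ...)
}

#' Simulate a set of conditions
#'
#' @param params a [FieldParams-class].
#' @param protocols named list of [StimulusProtocol-class] objects
#'   (default [defaultProtocols()]).
#' @param grid a [SpaceTimeGrid-class].
#' @param ... passed to [simulateField()].
#' @return named list of [FieldTrajectory-class] objects.
#' @export
simulateConditions <- function(params, protocols = defaultProtocols(),
                               grid = spaceTimeGrid(), ...) {
  out <- lapply(names(protocols), function(nm)
    simulateCondition(params, protocols[[nm]], grid, condition = nm, ...))
  names(out) <- names(protocols)
  out
}
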