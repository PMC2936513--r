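# Synthetic VSD recording generator: known ground truth pushed through the
# acquisition and normalization chain (2-D frame stacks, trial noise,
# physiological artifacts, blank division, 1-D reduction).

#' Configuration of the synthetic recording generator
#'
#' The generator emulates trial-resolved camera frames: the model's
#' aggregated 1-D signal modulated along the medial-lateral (x) axis by a
#' Gaussian cross-section, riding on a DC fluorescence level, with
#' multiplicative heartbeat and respiration artifacts (phase-locked across
#' trials up to a per-trial jitter) and white pixel noise; blank trials carry
#' artifacts and noise only.
#'
#' @param params ground-truth [FieldParams-class].
#' @param a,b,c ground-truth mixture (dF/F per mV; defaults give
#'   `kappa = 0.54` and a peak dye amplitude of roughly 1e-2 dF/F).
#' @param nTrials,nBlank stimulus / blank trial counts (default 24 each).
#' @param noiseSd white-noise sd per pixel and frame (raw fluorescence units,
#'   relative to `dcLevel = 1`).
#' @param heartbeatAmp,heartbeatHz,respirationAmp,respirationHz artifact
#'   amplitudes (fractional) and frequencies.
#' @param phaseJitter per-trial artifact phase jitter, radians. The base
#'   phases are shared between stimulus and blank trials, emulating
#'   heartbeat/respiration-triggered acquisition (which is what makes blank
#'   division effective); the jitter models imperfect locking.
#' @param xCenter,xSd lateral Gaussian profile center and sd, in x-pixel
#'   units (1-based over the 24-pixel axis; defaults place mean +- 1 sd at
#'   pixels 4-20).
#' @param nX,nPre x-resolution and number of pre-stimulus frames
#'   (default 24 pixels; 21 frames, approximately 200 ms).
#' @param dcLevel baseline fluorescence level.
#' @param seed integer seed (mandatory).
#' @return object of class `SynthConfig` (a list).
#' @export
synthConfig <- function(params = fieldParams(), a = 3.45e-5, b = 4.05e-5,
                        c = 0, nTrials = 24L, nBlank = 24L, noiseSd = 0.012,
                        heartbeatAmp = 0.01, heartbeatHz = 2.5,
                        respirationAmp = 0.02, respirationHz = 0.4,
                        phaseJitter = 0.05,
                        xCenter = 12, xSd = 8, nX = 24L, nPre = 21L,
                        dcLevel = 1, seed) {
  stopifnot(!missing(seed), nTrials >= 1L, nBlank >= 1L, noiseSd >= 0,
            a >= 0, b >= 0)
  structure(list(params = params, a = a, b = b, c = c,
                 nTrials = as.integer(nTrials), nBlank = as.integer(nBlank),
                 noiseSd = noiseSd, heartbeatAmp = heartbeatAmp,
                 heartbeatHz = heartbeatHz, respirationAmp = respirationAmp,
                 respirationHz = respirationHz, phaseJitter = phaseJitter,
                 xCenter = xCenter, xSd = xSd,
                 nX = as.integer(nX), nPre = as.integer(nPre),
                 dcLevel = dcLevel, seed = as.integer(seed)),
            class = "SynthConfig")
}

#' @export
print.SynthConfig <- function(x, ...) {
  cat(sprintf(paste0("SynthConfig: %d trials + %d blanks, noise sd %.3g, ",
                     "kappa_true = %.3f, seed %d\n"),
              x$nTrials, x$nBlank, x$noiseSd,
              if (x$a + x$b > 0) x$b / (x$a + x$b) else NA, x$seed))
  invisible(x)
}

# multiplicative artifact time course for one trial: session base phases
# (shared by stimulus and blank trials) plus per-trial jitter
.artifact <- function(cfg, tMs, basePhases) {
  ph <- basePhases + rnorm(2, 0, cfg$phaseJitter)
  (1 + cfg$heartbeatAmp * sin(2 * pi * cfg$heartbeatHz * tMs / 1000 + ph[1])) *
    (1 + cfg$respirationAmp * sin(2 * pi * cfg$respirationHz * tMs / 1000 + ph[2]))
}

#' Generate a synthetic VSD recording for one stimulus condition
#'
#' Simulates the ground-truth field (unless a trajectory is supplied),
#' aggregates it with the ground-truth mixture, and emits per-trial camera
#' frame stacks `[nX x nMapped x (nPre + nFrames)]` plus blank stacks and a
#' ground-truth bundle.
#'
#' @param cfg a [synthConfig()].
#' @param protocol a [StimulusProtocol-class].
#' @param grid a [SpaceTimeGrid-class].
#' @param traj optional precomputed [FieldTrajectory-class] for the
#'   ground-truth parameters (skips the simulation).
#' @return list with `trials` (list of arrays), `blanks` (list of arrays),
#'   and `groundTruth` (noiseless 1-D pattern, mixture, kappa, params,
#'   trajectory).
#' @export
generateRecording <- function(cfg, protocol, grid = spaceTimeGrid(), traj = NULL) {
  set.seed(cfg$seed)
  if (is.null(traj))
    traj <- simulateCondition(cfg$params, protocol, grid)
  # noiseless 1-D dye deviation from the resting state (the homogeneous fixed
  # point: for moving stimuli frame 1 already carries the traveling bump, so
  # the frame-1 profile is not a valid reference)
  fp <- homogeneousFixedPoint(cfg$params)
  ue <- uE(traj, mapped = TRUE); ui <- uI(traj, mapped = TRUE)
  dye1d <- cfg$a * (ue - fp@ueBar) + cfg$b * (ui - fp@uiBar) + cfg$c
  nY <- nrow(dye1d); nFr <- ncol(dye1d)
  prof <- exp(-((seq_len(cfg$nX) - cfg$xCenter)^2) / (2 * cfg$xSd^2))
  nTot <- cfg$nPre + nFr
  tMs <- (seq_len(nTot) - 1) * grid@frameDt   # acquisition clock
  dyeFull <- cbind(matrix(0, nY, cfg$nPre), dye1d)
  basePhases <- runif(2, 0, 2 * pi)
  makeStack <- function(withSignal) {
    art <- .artifact(cfg, tMs, basePhases)
    stack <- array(0, dim = c(cfg$nX, nY, nTot))
    for (f in seq_len(nTot)) {
      sig <- if (withSignal) outer(prof, dyeFull[, f]) else matrix(0, cfg$nX, nY)
      stack[, , f] <- cfg$dcLevel * (1 + sig) * art[f] +
        if (cfg$noiseSd > 0) matrix(rnorm(cfg$nX * nY, sd = cfg$noiseSd),
                                    cfg$nX, nY) else 0
    }
    stack
  }
  trials <- lapply(seq_len(cfg$nTrials), function(i) makeStack(TRUE))
  blanks <- lapply(seq_len(cfg$nBlank), function(i) makeStack(FALSE))
  list(trials = trials, blanks = blanks,
       groundTruth = list(dye1d = dye1d, a = cfg$a, b = cfg$b, c = cfg$c,
                          kappa = if (cfg$a + cfg$b > 0) cfg$b / (cfg$a + cfg$b)
                                  else NA_real_,
                          params = cfg$params, traj = traj))
}

#' Preprocess trial stacks into a 1-D dye pattern
#'
#' The normalization chain applied to the recordings: per-pixel DC
#' normalization against the pre-stimulus mean, division by the blank-trial
#' average, trial averaging, averaging of the central x-pixels (4-20,
#' 1-based, inclusive) and subtraction of the early-window mean
#' (first `baselineMs` of the analysis window over all positions). Pre-stimulus
#' frames are dropped from the output.
#'
#' @param trials,blanks lists of `[nX x nY x (nPre + nFrames)]` arrays.
#' @param grid a [SpaceTimeGrid-class] describing the analysis window.
#' @param nPre number of pre-stimulus frames in the stacks.
#' @param xPixels 1-based x-pixel range averaged into the 1-D signal.
#' @param baselineRef `"prestim"` or `"early"` (see above).
#' @param baselineMs early-window baseline length, ms (for `"early"`).
#' @param condition,nTrials metadata for the returned pattern.
#' @return A [DyePattern-class] `[nY x nFrames]`.
#' @export
preprocessRecording <- function(trials, blanks, grid = spaceTimeGrid(),
                                nPre = 21L, xPixels = 4:20,
                                baselineRef = c("prestim", "early"),
                                baselineMs = 20,
                                condition = "", nTrials = length(trials)) {
  stopifnot(length(trials) >= 1L, length(blanks) >= 1L)
  baselineRef <- match.arg(baselineRef)
  if (nPre < 1L) baselineRef <- "early"
  dcNorm <- function(stack) {
    dc <- apply(stack[, , seq_len(nPre), drop = FALSE], c(1, 2), mean)
    if (any(dc == 0)) stop("zero DC level in pre-stimulus period")
    sweep(stack, c(1, 2), dc, "/")
  }
  blankAvg <- Reduce(`+`, lapply(blanks, dcNorm)) / length(blanks)
  if (any(blankAvg == 0)) stop("blank average contains zeros; cannot divide")
  normTrials <- lapply(trials, function(tr) dcNorm(tr) / blankAvg)
  avg <- Reduce(`+`, normTrials) / length(normTrials)
  oneD <- apply(avg[xPixels, , , drop = FALSE], c(2, 3), mean)  # nY x nTot
  win <- oneD[, (nPre + 1):dim(oneD)[2], drop = FALSE]
  ref <- if (baselineRef == "prestim") {
    mean(oneD[, seq_len(nPre)])
  } else {
    nb <- max(1L, sum((seq_len(ncol(win)) - 1) * grid@frameDt < baselineMs))
    mean(win[, seq_len(nb)])
  }
  win <- win - ref
  dyePattern(win, grid, condition = condition, nTrials = nTrials)
}

#' Deterministic miniature fixtures for testing
#'
#' Small, programmatically generated objects: a 15-position toy grid, a
#' gentle toy parameter set (with its brute-force homogeneous fixed point), a
#' synthetic traveling front of known speed, and a tiny dye pattern. All
#' content is a pure function of `seed`.
#'
#' @param seed integer seed.
#' @return named list of fixtures.
#' @export
makeFixtureSuite <- function(seed = 1L) {
  set.seed(as.integer(seed))
  toyGrid <- spaceTimeGrid(nPositions = 15L, nMapped = 5L, pixelPitch = 0.14,
                           frameDt = 9.6, nFrames = 12L)
  toyParams <- fieldParams(gEE = 20, gIE = 10, gEI = 20, sigmaEE = 0.4,
                           sigmaEI = 0.4)
  fp <- homogeneousFixedPoint(toyParams)
  frontGrid <- spaceTimeGrid(nPositions = 50L, nMapped = 50L, nFrames = 20L)
  # step front advancing 2 px per frame: cortical speed 2 * 0.14 mm / 9.6 ms
  front <- matrix(0, 50, 20)
  for (f in seq_len(20)) front[seq_len(min(50, 2 * f)), f] <- 1
  frontSpeed <- 2 * frontGrid@pixelPitch / frontGrid@frameDt  # mm/ms = m/s
  noise <- matrix(rnorm(5 * 12, sd = 0.1), 5, 12)
  list(toyGrid = toyGrid, toyParams = toyParams, toyFixedPoint = fp,
       frontGrid = frontGrid, front = front, frontSpeed = frontSpeed,
       noisePattern = noise, seed = as.integer(seed))
}
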