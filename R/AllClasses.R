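#' @import methods
#' @importFrom stats lm coef cor pchisq rnorm runif setNames sd var quantile
#'   wilcox.test optimize uniroot dnorm pnorm confint
#' @importFrom utils head tail modifyList packageVersion
#' @useDynLib neurofield, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# SpaceTimeGrid
# ---------------------------------------------------------------------------

#' Space-time discretization of the simulated cortical patch
#'
#' The model is simulated on `nPositions` equally spaced positions along the
#' posterior-anterior cortical axis; the central `nMapped` positions are mapped
#' onto the pixels of the imaged region, the rest serve as a boundary buffer.
#' Frames are sampled every `frameDt` milliseconds.
#'
#' @slot nPositions integer, number of simulated positions (default 150).
#' @slot nMapped integer, number of mapped (imaged) positions (default 50).
#' @slot pixelPitch numeric, spacing in mm per pixel (default 0.14).
#' @slot frameDt numeric, frame duration in ms (default 9.6).
#' @slot nFrames integer, number of sampled frames in the analysis window.
#' @slot t0Offset numeric, experiment-clock time (ms) of frame 1.
#' @exportClass SpaceTimeGrid
setClass("SpaceTimeGrid",
  representation(nPositions = "integer", nMapped = "integer",
                 pixelPitch = "numeric", frameDt = "numeric",
                 nFrames = "integer", t0Offset = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nMapped > object@nPositions)
      msg <- c(msg, "nMapped must not exceed nPositions")
    if ((object@nPositions - object@nMapped) %% 2L != 0L)
      msg <- c(msg, "mapped block must be centered (equal padding on both sides)")
    if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be > 0")
    if (object@frameDt <= 0) msg <- c(msg, "frameDt must be > 0")
    if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Construct a SpaceTimeGrid
#'
#' Defaults follow the imaging setup modeled by the package: 150 simulated
#' positions of which the central 50 are mapped to the camera pixels, a pixel
#' pitch of 0.14 mm (7 mm imaged extent over 50 pixels) and 9.6 ms frames over
#' a 250 ms analysis window (26 frames).
#'
#' @param nPositions number of simulated positions.
#' @param nMapped number of mapped positions.
#' @param pixelPitch mm per pixel.
#' @param frameDt ms per frame.
#' @param nFrames frames in the analysis window.
#' @param t0Offset experiment-clock time of frame 1 (ms).
#' @return A [SpaceTimeGrid-class] object.
#' @examples
#' grid <- spaceTimeGrid()
#' positionsMm(grid)[1:3]
#' @export
spaceTimeGrid <- function(nPositions = 150L, nMapped = 50L, pixelPitch = 0.14,
                          frameDt = 9.6, nFrames = 26L, t0Offset = 0) {
  new("SpaceTimeGrid", nPositions = as.integer(nPositions),
      nMapped = as.integer(nMapped), pixelPitch = pixelPitch,
      frameDt = frameDt, nFrames = as.integer(nFrames), t0Offset = t0Offset)
}

#' Cortical coordinates of the simulated positions
#'
#' Positions are pixel centers; the mapped block spans `[0, nMapped * pixelPitch)`
#' mm so buffer positions carry negative coordinates below it.
#'
#' @param grid a [SpaceTimeGrid-class].
#' @return numeric vector of length `nPositions`, in mm.
#' @export
positionsMm <- function(grid) {
  pad <- (grid@nPositions - grid@nMapped) / 2
  (seq_len(grid@nPositions) - 0.5 - pad) * grid@pixelPitch
}

#' Indices of the mapped positions within the simulated grid
#' @param grid a [SpaceTimeGrid-class].
#' @return integer vector of length `nMapped`.
#' @export
mappedIndices <- function(grid) {
  pad <- (grid@nPositions - grid@nMapped) / 2L
  seq.int(pad + 1L, pad + grid@nMapped)
}

#' Frame times of the analysis window
#' @param grid a [SpaceTimeGrid-class].
#' @return numeric vector of length `nFrames`, ms on the experiment clock.
#' @export
frameTimes <- function(grid) (seq_len(grid@nFrames) - 1) * grid@frameDt + grid@t0Offset

setMethod("show", "SpaceTimeGrid", function(object) {
  cat(sprintf("SpaceTimeGrid: %d positions (%d mapped), %.3g mm/px, %d frames x %.3g ms\n",
              object@nPositions, object@nMapped, object@pixelPitch,
              object@nFrames, object@frameDt))
})

# ---------------------------------------------------------------------------
# FieldParams
# ---------------------------------------------------------------------------

#' Parameters of the two-layer neural field
#'
#' The 15 parameters of the model: membrane time constants and resting
#' potentials of both layers, three coupling gains (recurrent excitation
#' `gEE`, local inhibition of the excitatory layer `gIE`, excitation of the
#' inhibitory layer `gEI`), Gaussian kernel widths, logistic transfer-function
#' slopes and thresholds, and the feed-forward gain and smoothing width.
#' Coupling kernels are normalized to unit area before gain multiplication, so
#' the gains are resolution independent.
#'
#' @slot tauE,tauI time constants, ms.
#' @slot hE,hI resting potentials, mV.
#' @slot gEE,gIE,gEI coupling gains (dimensionless; signs live in the equations).
#' @slot sigmaEE,sigmaEI kernel widths, mm.
#' @slot betaE,betaI transfer slopes, 1/mV.
#' @slot thetaE,thetaI transfer thresholds, mV.
#' @slot gFF feed-forward gain.
#' @slot sigmaFF feed-forward smoothing width, mm.
#' @exportClass FieldParams
setClass("FieldParams",
  representation(tauE = "numeric", tauI = "numeric", hE = "numeric", hI = "numeric",
                 gEE = "numeric", gIE = "numeric", gEI = "numeric",
                 sigmaEE = "numeric", sigmaEI = "numeric",
                 betaE = "numeric", betaI = "numeric",
                 thetaE = "numeric", thetaI = "numeric",
                 gFF = "numeric", sigmaFF = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@tauE <= 0 || object@tauI <= 0) msg <- c(msg, "time constants must be > 0")
    if (object@sigmaEE <= 0 || object@sigmaEI <= 0 || object@sigmaFF <= 0)
      msg <- c(msg, "kernel widths must be > 0")
    if (object@betaE <= 0 || object@betaI <= 0) msg <- c(msg, "transfer slopes must be > 0")
    if (object@gEE < 0 || object@gIE < 0 || object@gEI < 0 || object@gFF < 0)
      msg <- c(msg, "gains must be >= 0 (signs are carried by the equations)")
    if (length(msg)) msg else TRUE
  })

#' Construct a FieldParams object
#'
#' The defaults are the selected parameter values of the model's reference
#' configuration: `tauE = 19.2`, `tauI = 28.8` ms, `hE = hI = -60` mV,
#' `gEE = 125`, `gIE = 50`, `gEI = 125`, `sigmaEE = sigmaEI = 1.27` mm,
#' `betaE = 0.15`, `betaI = 0.1` 1/mV, `thetaE = thetaI = -40` mV, `gFF = 70`,
#' `sigmaFF = 0.51` mm.
#'
#' @param tauE,tauI time constants (ms).
#' @param hE,hI resting potentials (mV).
#' @param gEE,gIE,gEI coupling gains.
#' @param sigmaEE,sigmaEI kernel widths (mm).
#' @param betaE,betaI transfer slopes (1/mV).
#' @param thetaE,thetaI transfer thresholds (mV).
#' @param gFF feed-forward gain.
#' @param sigmaFF feed-forward smoothing width (mm).
#' @return A [FieldParams-class] object.
#' @examples
#' p <- fieldParams()           # reference configuration
#' q <- fieldParams(gEE = 200)  # one override
#' @export
fieldParams <- function(tauE = 19.2, tauI = 28.8, hE = -60, hI = -60,
                        gEE = 125, gIE = 50, gEI = 125,
                        sigmaEE = 1.27, sigmaEI = 1.27,
                        betaE = 0.15, betaI = 0.1,
                        thetaE = -40, thetaI = -40,
                        gFF = 70, sigmaFF = 0.51) {
  new("FieldParams", tauE = tauE, tauI = tauI, hE = hE, hI = hI,
      gEE = gEE, gIE = gIE, gEI = gEI, sigmaEE = sigmaEE, sigmaEI = sigmaEI,
      betaE = betaE, betaI = betaI, thetaE = thetaE, thetaI = thetaI,
      gFF = gFF, sigmaFF = sigmaFF)
}

#' Coerce FieldParams to a named list
#' @param params a [FieldParams-class].
#' @return named list of the 15 parameters.
#' @export
paramsAsList <- function(params) {
  nm <- slotNames("FieldParams")
  setNames(lapply(nm, function(s) slot(params, s)), nm)
}

#' Build FieldParams from a named list, filling unstated values with defaults
#' @param x named list with any subset of the parameter names.
#' @return A [FieldParams-class].
#' @export
paramsFromList <- function(x) do.call(fieldParams, x[names(x) %in% slotNames("FieldParams")])

setMethod("show", "FieldParams", function(object) {
  cat("FieldParams (two-layer neural field)\n")
  cat(sprintf("  tauE=%.4g tauI=%.4g ms | hE=%.4g hI=%.4g mV (h - theta: %.4g, %.4g)\n",
              object@tauE, object@tauI, object@hE, object@hI,
              object@hE - object@thetaE, object@hI - object@thetaI))
  cat(sprintf("  gEE=%.4g gIE=%.4g gEI=%.4g | sigmaEE=%.4g sigmaEI=%.4g mm\n",
              object@gEE, object@gIE, object@gEI, object@sigmaEE, object@sigmaEI))
  cat(sprintf("  betaE=%.4g betaI=%.4g 1/mV | thetaE=%.4g thetaI=%.4g mV | gFF=%.4g sigmaFF=%.4g mm\n",
              object@betaE, object@betaI, object@thetaE, object@thetaI,
              object@gFF, object@sigmaFF))
})

# ---------------------------------------------------------------------------
# StimulusProtocol
# ---------------------------------------------------------------------------

#' Stimulus protocol in cortical coordinates
#'
#' Describes one of the four stimulus kinds: a flashed square, a flashed bar,
#' the line-motion sequence (square then bar) or a square translating at a
#' fixed visual speed. Extents and the anchor are cortical distances (mm);
#' onsets/offsets are on the experiment clock (ms); the retino-cortical
#' magnification converts deg/s to mm/s for moving stimuli.
#'
#' For `moving_square` the motion is treated as ongoing at the window start:
#' the square's leading edge passes `anchorPosition + squareExtent/2` (the
#' center of the flashed square's footprint) at t = 0, having entered from
#' below the simulated grid, so the analysis window captures steady
#' translation rather than a motion-onset transient.
#'
#' @slot kind one of `"flashed_square"`, `"flashed_bar"`, `"line_motion"`,
#'   `"moving_square"`.
#' @slot squareExtent,barExtent cortical extents, mm.
#' @slot squareOnset,squareOffset,barOnset,barOffset times, ms.
#' @slot speedDegS visual speed for moving stimuli, deg/s.
#' @slot magnification cortical magnification, mm per visual degree.
#' @slot anchorPosition cortical position (mm) of the square's lower edge;
#'   the bar shares this edge and extends anteriorly.
#' @exportClass StimulusProtocol
setClass("StimulusProtocol",
  representation(kind = "character", squareExtent = "numeric", barExtent = "numeric",
                 squareOnset = "numeric", squareOffset = "numeric",
                 barOnset = "numeric", barOffset = "numeric",
                 speedDegS = "numeric", magnification = "numeric",
                 anchorPosition = "numeric"),
  validity = function(object) {
    msg <- character()
    kinds <- c("flashed_square", "flashed_bar", "line_motion", "moving_square")
    if (!(object@kind %in% kinds))
      msg <- c(msg, paste("kind must be one of:", paste(kinds, collapse = ", ")))
    if (object@squareOffset < object@squareOnset) msg <- c(msg, "squareOffset < squareOnset")
    if (object@barOffset < object@barOnset) msg <- c(msg, "barOffset < barOnset")
    if (object@kind == "moving_square" && object@speedDegS <= 0)
      msg <- c(msg, "speedDegS must be > 0 for moving_square")
    if (object@magnification <= 0) msg <- c(msg, "magnification must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a StimulusProtocol
#'
#' Defaults reproduce the line-motion timing (square 20-70 ms, 10 ms gap, bar
#' 80-210 ms) with a 1.5 mm square anchored at 2.25 mm and a 2.5 mm bar
#' sharing the square's lower cortical edge, at a magnification of 1.1 mm/deg.
#' See the methods vignette for how these reconstructed extents were fixed.
#'
#' @param kind stimulus kind.
#' @param squareExtent,barExtent cortical extents (mm).
#' @param squareOnset,squareOffset,barOnset,barOffset times (ms).
#' @param speedDegS visual speed (deg/s), moving stimuli only.
#' @param magnification mm per visual degree.
#' @param anchorPosition cortical position of the square's lower edge (mm).
#' @return A [StimulusProtocol-class].
#' @examples
#' stimulusProtocol("line_motion")
#' stimulusProtocol("moving_square", speedDegS = 16)
#' @export
stimulusProtocol <- function(kind = c("flashed_square", "flashed_bar",
                                      "line_motion", "moving_square"),
                             squareExtent = 1.5, barExtent = 2.5,
                             squareOnset = 20, squareOffset = 70,
                             barOnset = 80, barOffset = 210,
                             speedDegS = NA_real_, magnification = 1.1,
                             anchorPosition = 2.25) {
  kind <- match.arg(kind)
  if (kind == "moving_square" && is.na(speedDegS))
    stop("speedDegS is required for moving_square")
  new("StimulusProtocol", kind = kind, squareExtent = squareExtent,
      barExtent = barExtent, squareOnset = squareOnset, squareOffset = squareOffset,
      barOnset = barOnset, barOffset = barOffset,
      speedDegS = if (is.na(speedDegS)) 0 else speedDegS,
      magnification = magnification, anchorPosition = anchorPosition)
}

#' The seven stimulus conditions of the study design
#'
#' Flashed square, flashed bar, line-motion, and squares moving at 4, 8, 16
#' and 32 deg/s. Names are `square`, `bar`, `lm`, `mov4` ... `mov32`.
#'
#' @param ... overrides passed to every [stimulusProtocol()] call
#'   (e.g. `magnification`).
#' @return named list of seven [StimulusProtocol-class] objects.
#' @export
defaultProtocols <- function(...) {
  out <- list(
    square = stimulusProtocol("flashed_square", ...),
    bar    = stimulusProtocol("flashed_bar", ...),
    lm     = stimulusProtocol("line_motion", ...))
  for (v in c(4, 8, 16, 32))
    out[[paste0("mov", v)]] <- stimulusProtocol("moving_square", speedDegS = v, ...)
  out
}

#' Names of the four conditions used for parameter identification
#'
#' The flashed square, flashed bar, line-motion stimulus and the square moving
#' at 32 deg/s; the remaining moving speeds are held out for generalization.
#' @return character vector of condition names.
#' @export
trainingConditions <- function() c("square", "bar", "lm", "mov32")

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf("StimulusProtocol <%s>", object@kind))
  if (object@kind == "moving_square")
    cat(sprintf(" %g deg/s x %g mm/deg", object@speedDegS, object@magnification))
  cat(sprintf(" | square %g mm @ [%g,%g] ms", object@squareExtent,
              object@squareOnset, object@squareOffset))
  if (object@kind %in% c("flashed_bar", "line_motion"))
    cat(sprintf(" | bar %g mm @ [%g,%g] ms", object@barExtent,
                object@barOnset, object@barOffset))
  cat(sprintf(" | anchor %g mm\n", object@anchorPosition))
})

# ---------------------------------------------------------------------------
# InputField, FieldTrajectory, FixedPoint
# ---------------------------------------------------------------------------

#' Afferent input field
#'
#' Smoothed, gain-scaled and delayed stimulus drive. `values` has one column
#' per integration frame including `leadFrames` columns of pre-window motion
#' lead-in (zero for flashed stimuli); column `leadFrames + f` drives the
#' interval starting at window frame `f`.
#'
#' @slot values matrix `[nPositions x (leadFrames + nFrames - 1)]`, mV.
#' @slot grid the [SpaceTimeGrid-class].
#' @slot delayFrames integer, applied retino-cortical delay in frames.
#' @slot leadFrames integer, number of pre-window columns.
#' @exportClass InputField
setClass("InputField",
  representation(values = "matrix", grid = "SpaceTimeGrid",
                 delayFrames = "integer", leadFrames = "integer"),
  validity = function(object) {
    if (any(!is.finite(object@values))) return("input values must be finite")
    if (any(object@values < 0)) return("input values must be >= 0")
    TRUE
  })

setMethod("show", "InputField", function(object) {
  cat(sprintf("InputField: %d x %d (lead %d frames, delay %d frames), peak %.3g mV\n",
              nrow(object@values), ncol(object@values), object@leadFrames,
              object@delayFrames, max(object@values)))
})

#' Simulated field trajectory
#'
#' Paired excitatory/inhibitory membrane-potential matrices sampled at the
#' imaging frame times, over all simulated positions.
#'
#' @slot uE,uI matrices `[nPositions x nFrames]`, mV.
#' @slot grid the [SpaceTimeGrid-class].
#' @slot params the generating [FieldParams-class].
#' @slot relaxed logical, whether frame 1 is the relaxed resting state.
#' @slot condition character label (may be `""`).
#' @exportClass FieldTrajectory
setClass("FieldTrajectory",
  representation(uE = "matrix", uI = "matrix", grid = "SpaceTimeGrid",
                 params = "FieldParams", relaxed = "logical", condition = "character"),
  validity = function(object) {
    if (!all(is.finite(object@uE)) || !all(is.finite(object@uI)))
      return("trajectory contains non-finite values")
    if (!identical(dim(object@uE), dim(object@uI)))
      return("uE and uI must have identical dimensions")
    TRUE
  })

#' @describeIn uE excitatory-layer accessor
#' @export
setGeneric("uE", function(x, mapped = FALSE) standardGeneric("uE"))
#' Access the excitatory / inhibitory layer of a trajectory
#' @param x a [FieldTrajectory-class].
#' @param mapped if `TRUE`, restrict rows to the mapped positions.
#' @return numeric matrix, mV.
#' @aliases uE uI
#' @export
setMethod("uE", "FieldTrajectory", function(x, mapped = FALSE) {
  if (mapped) x@uE[mappedIndices(x@grid), , drop = FALSE] else x@uE
})
#' @rdname uE
#' @export
setGeneric("uI", function(x, mapped = FALSE) standardGeneric("uI"))
#' @rdname uE
#' @export
setMethod("uI", "FieldTrajectory", function(x, mapped = FALSE) {
  if (mapped) x@uI[mappedIndices(x@grid), , drop = FALSE] else x@uI
})

setMethod("show", "FieldTrajectory", function(object) {
  cat(sprintf("FieldTrajectory%s: %d positions x %d frames, uE in [%.3g, %.3g] mV, uI in [%.3g, %.3g] mV\n",
              if (nzchar(object@condition)) paste0(" <", object@condition, ">") else "",
              nrow(object@uE), ncol(object@uE), min(object@uE), max(object@uE),
              min(object@uI), max(object@uI)))
})

#' Homogeneous fixed point of the field equations
#' @slot ueBar,uiBar fixed-point potentials, mV.
#' @slot residual maximum absolute equation residual, mV.
#' @exportClass FixedPoint
setClass("FixedPoint",
  representation(ueBar = "numeric", uiBar = "numeric", residual = "numeric"))

setMethod("show", "FixedPoint", function(object) {
  cat(sprintf("FixedPoint: ueBar = %.6f mV, uiBar = %.6f mV (residual %.2e mV)\n",
              object@ueBar, object@uiBar, object@residual))
})

# ---------------------------------------------------------------------------
# DyePattern, MixtureFit
# ---------------------------------------------------------------------------

#' Observed or synthetic dye signal
#'
#' A space-time matrix of fractional fluorescence changes over the mapped
#' positions, baseline-normalized so pre-stimulus frames sit near zero.
#'
#' @slot values matrix `[nMapped x nFrames]`, dF/F units.
#' @slot condition character condition label.
#' @slot grid the [SpaceTimeGrid-class].
#' @slot nTrials integer, trials averaged into the pattern.
#' @exportClass DyePattern
setClass("DyePattern",
  representation(values = "matrix", condition = "character",
                 grid = "SpaceTimeGrid", nTrials = "integer"),
  validity = function(object) {
    if (any(!is.finite(object@values))) return("dye values must be finite")
    TRUE
  })

#' Construct a DyePattern
#' @param values `[nMapped x nFrames]` matrix of dF/F values.
#' @param grid a [SpaceTimeGrid-class].
#' @param condition label.
#' @param nTrials trials averaged.
#' @return A [DyePattern-class].
#' @export
dyePattern <- function(values, grid, condition = "", nTrials = 1L) {
  new("DyePattern", values = values, grid = grid, condition = condition,
      nTrials = as.integer(nTrials))
}

#' Access the values of a DyePattern
#' @param x a [DyePattern-class].
#' @return numeric matrix.
#' @export
dyeValues <- function(x) x@values

setMethod("show", "DyePattern", function(object) {
  cat(sprintf("DyePattern%s: %d x %d, range [%.3g, %.3g] dF/F (n = %d trials)\n",
              if (nzchar(object@condition)) paste0(" <", object@condition, ">") else "",
              nrow(object@values), ncol(object@values), min(object@values),
              max(object@values), object@nTrials))
})

#' Fitted observation-model mixture
#'
#' Coefficients of the affine mixture `a * uE + b * uI + c` fitted to a dye
#' pattern under `a, b >= 0`, with the inhibitory share
#' `kappa = b / (a + b)` and fit diagnostics.
#'
#' @slot a,b non-negative mixing coefficients (dF/F per mV).
#' @slot c offset (dF/F).
#' @slot kappa inhibitory share in `[0, 1]` (NA when `a + b = 0`).
#' @slot rss residual sum of squares.
#' @slot rOverall Pearson correlation over the concatenated fit.
#' @slot rPerCondition named numeric, per-condition correlations.
#' @slot nonUnique logical, set when the two regressors are collinear.
#' @exportClass MixtureFit
setClass("MixtureFit",
  representation(a = "numeric", b = "numeric", c = "numeric", kappa = "numeric",
                 rss = "numeric", rOverall = "numeric",
                 rPerCondition = "numeric", nonUnique = "logical"),
  validity = function(object) {
    if (object@a < -1e-12 || object@b < -1e-12)
      return("mixture coefficients must be non-negative")
    TRUE
  })

#' Inhibitory share of a mixture fit
#' @param x a [MixtureFit-class].
#' @return numeric in `[0, 1]`.
#' @export
kappaOf <- function(x) x@kappa

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit: a = %.4g, b = %.4g, c = %.4g | kappa = %.3f | r = %.3f, RSS = %.4g%s\n",
              object@a, object@b, object@c, object@kappa, object@rOverall,
              object@rss, if (object@nonUnique) " [non-unique: collinear layers]" else ""))
  if (length(object@rPerCondition))
    cat("  per-condition r:",
        paste(sprintf("%s=%.3f", names(object@rPerCondition), object@rPerCondition),
              collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# StabilityVerdict, AmariParams, SpeedEstimate
# ---------------------------------------------------------------------------

#' Linear stability verdict for the homogeneous state
#'
#' Both margins must be positive at every probed spatial frequency for the
#' homogeneous solution to be asymptotically stable: `margin1` is the
#' trace condition `(1 - gEE fE' WEE(q))/tauE + 1/tauI` and `margin2` the
#' determinant condition `(1 - gEE fE' WEE(q)) + gIE gEI fI' fE' WEI(q)`,
#' reported at the worst probed frequency.
#'
#' @slot stable logical.
#' @slot worstFrequency rad/mm at which the smaller margin is attained.
#' @slot margin1,margin2 inequality slack at the worst frequency.
#' @slot freqGrid probed frequencies, rad/mm.
#' @slot note character; non-empty when stability fails structurally (no
#'   resting homogeneous state to linearize about).
#' @exportClass StabilityVerdict
setClass("StabilityVerdict",
  representation(stable = "logical", worstFrequency = "numeric",
                 margin1 = "numeric", margin2 = "numeric", freqGrid = "numeric",
                 note = "character"),
  prototype(note = ""))

#' Is the verdict stable?
#' @param x a [StabilityVerdict-class].
#' @return logical.
#' @export
isStable <- function(x) x@stable

setMethod("show", "StabilityVerdict", function(object) {
  cat(sprintf("StabilityVerdict: %s (worst q = %.4g rad/mm; margins %.4g, %.4g)\n",
              if (object@stable) "stable" else "UNSTABLE",
              object@worstFrequency, object@margin1, object@margin2))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

#' Parameters of the single-layer Amari control model
#'
#' @slot tau time constant, ms.
#' @slot h resting potential, mV.
#' @slot kernel `"gaussian"` or `"mexican_hat"`.
#' @slot gPlus,sigmaPlus excitatory kernel gain and width (mm).
#' @slot gMinus,sigmaMinus inhibitory-surround gain and width (mexican hat).
#' @slot beta,theta transfer slope (1/mV) and threshold (mV).
#' @exportClass AmariParams
setClass("AmariParams",
  representation(tau = "numeric", h = "numeric", kernel = "character",
                 gPlus = "numeric", sigmaPlus = "numeric",
                 gMinus = "numeric", sigmaMinus = "numeric",
                 beta = "numeric", theta = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@kernel %in% c("gaussian", "mexican_hat")))
      msg <- c(msg, "kernel must be 'gaussian' or 'mexican_hat'")
    if (object@sigmaPlus <= 0) msg <- c(msg, "sigmaPlus must be > 0")
    if (object@kernel == "mexican_hat" && object@sigmaMinus <= object@sigmaPlus)
      msg <- c(msg, "sigmaMinus must exceed sigmaPlus for a mexican hat")
    if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct AmariParams
#' @param tau time constant (ms).
#' @param h resting potential (mV).
#' @param kernel `"gaussian"` or `"mexican_hat"`.
#' @param gPlus,sigmaPlus excitatory kernel gain/width.
#' @param gMinus,sigmaMinus surround gain/width (mexican hat only).
#' @param beta,theta transfer slope and threshold.
#' @return An [AmariParams-class].
#' @export
amariParams <- function(tau = 19.2, h = -60, kernel = c("gaussian", "mexican_hat"),
                        gPlus = 125, sigmaPlus = 1.27,
                        gMinus = 50, sigmaMinus = 2.54,
                        beta = 0.15, theta = -40) {
  kernel <- match.arg(kernel)
  new("AmariParams", tau = tau, h = h, kernel = kernel, gPlus = gPlus,
      sigmaPlus = sigmaPlus, gMinus = if (kernel == "gaussian") 0 else gMinus,
      sigmaMinus = sigmaMinus, beta = beta, theta = theta)
}

setMethod("show", "AmariParams", function(object) {
  cat(sprintf("AmariParams <%s>: tau=%.4g h=%.4g g+=%.4g s+=%.4g", object@kernel,
              object@tau, object@h, object@gPlus, object@sigmaPlus))
  if (object@kernel == "mexican_hat")
    cat(sprintf(" g-=%.4g s-=%.4g", object@gMinus, object@sigmaMinus))
  cat(sprintf(" beta=%.4g theta=%.4g\n", object@beta, object@theta))
})

#' Wavefront propagation-speed estimate
#'
#' Earliest threshold-crossing times of a space-time pattern at a fraction of
#' its global maximum, with the least-squares position-versus-time fit.
#'
#' @slot thresholdFraction fraction of the global maximum (default 0.8).
#' @slot crossingTimes ms per mapped position (NA where never crossed).
#' @slot speed fitted speed, m/s.
#' @slot rSquared fit R^2.
#' @slot positionsUsed indices of positions with crossings.
#' @slot speedCI 95 percent confidence interval for the speed.
#' @exportClass SpeedEstimate
setClass("SpeedEstimate",
  representation(thresholdFraction = "numeric", crossingTimes = "numeric",
                 speed = "numeric", rSquared = "numeric",
                 positionsUsed = "integer", speedCI = "numeric"))

setMethod("show", "SpeedEstimate", function(object) {
  cat(sprintf("SpeedEstimate: %.4g m/s (R^2 = %.4f, %d positions, threshold %.0f%%)\n",
              object@speed, object@rSquared, length(object@positionsUsed),
              100 * object@thresholdFraction))
})
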