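# Stimulus construction: rasterize protocols onto the cortical grid, then
# smooth, scale and delay to obtain the afferent drive.

#' Discrete unit-area Gaussian kernel
#'
#' Gaussian samples at pixel offsets, normalized so that the discrete sum
#' times the pixel pitch equals one. Truncated at 6 sigma.
#'
#' @param sigma kernel width, mm.
#' @param pixelPitch mm per pixel.
#' @return numeric vector of odd length centered on zero offset
#'   (units 1/mm); attribute `halfWidth` gives the truncation in pixels.
#' @export
discreteGaussian <- function(sigma, pixelPitch) {
  K <- ceiling(6 * sigma / pixelPitch)
  offs <- (-K):K
  k <- exp(-(offs * pixelPitch)^2 / (2 * sigma^2))
  k <- k / (sum(k) * pixelPitch)
  structure(k, halfWidth = K)
}

# frame-interval midpoints for nCols intervals starting at window time t0
.intervalMidpoints <- function(nCols, frameDt, t0) (seq_len(nCols) - 1) * frameDt + t0 + frameDt / 2

.coveredRows <- function(xs, lo, hi) xs >= lo & xs < hi

#' Rasterize a stimulus protocol into a binary occupancy matrix
#'
#' The returned matrix has one column per integration frame interval;
#' an entry is 1 when the pixel center lies inside the stimulus footprint at
#' the interval's midpoint (half-open footprint, inclusive lower edge).
#' Flashed stimuli produce constant blocks in time; the moving square
#' translates at `speedDegS * magnification` mm/s with its motion ongoing at
#' the window start (the leading edge passes the flashed square's center,
#' `anchorPosition + squareExtent/2`, at t = 0). Moving-square lead-in
#' intervals, during which the square approaches from below the simulated
#' grid, are prepended and counted in the `leadFrames` attribute; the
#' footprint is clipped at the simulated-grid edges.
#'
#' @param protocol a [StimulusProtocol-class].
#' @param grid a [SpaceTimeGrid-class].
#' @return binary matrix `[nPositions x (leadFrames + nFrames - 1)]` with
#'   attribute `leadFrames` (0 for flashed stimuli).
#' @examples
#' occ <- buildStimulus(stimulusProtocol("line_motion"), spaceTimeGrid())
#' range(colSums(occ))
#' @export
buildStimulus <- function(protocol, grid) {
  xs <- positionsMm(grid)
  mappedTop <- grid@nMapped * grid@pixelPitch
  nCols <- grid@nFrames - 1L

  checkFit <- function(lo, hi, what) {
    if (lo < 0 || hi > mappedTop) {
      over <- max(hi - mappedTop, -lo)
      stop(sprintf("%s footprint [%g, %g] mm exceeds the mapped block [0, %g] by %.3g mm",
                   what, lo, hi, mappedTop, over))
    }
  }

  if (protocol@kind == "moving_square") {
    v <- protocol@speedDegS * protocol@magnification / 1000  # mm per ms
    width <- protocol@squareExtent
    startEdge <- protocol@anchorPosition + protocol@squareExtent / 2
    # lead-in long enough that the square starts fully below the simulated grid
    leadMs <- (startEdge - min(xs) + width) / v
    leadFrames <- as.integer(ceiling(leadMs / grid@frameDt))
    tm <- .intervalMidpoints(leadFrames + nCols, grid@frameDt,
                             -leadFrames * grid@frameDt)
    occ <- matrix(0, grid@nPositions, length(tm))
    for (f in seq_along(tm)) {
      lead <- startEdge + v * tm[f]
      occ[.coveredRows(xs, lead - width, lead), f] <- 1
    }
    attr(occ, "leadFrames") <- leadFrames
    return(occ)
  }

  occ <- matrix(0, grid@nPositions, nCols)
  tm <- .intervalMidpoints(nCols, grid@frameDt, 0)
  addFlash <- function(occ, lo, hi, on, off, what) {
    if (off <= on) return(occ)  # zero-duration stimulus: nothing lit
    checkFit(lo, hi, what)
    occ[.coveredRows(xs, lo, hi), tm >= on & tm < off] <- 1
    occ
  }
  sqLo <- protocol@anchorPosition
  sqHi <- sqLo + protocol@squareExtent
  barLo <- protocol@anchorPosition
  barHi <- barLo + protocol@barExtent
  if (protocol@kind %in% c("flashed_square", "line_motion"))
    occ <- addFlash(occ, sqLo, sqHi, protocol@squareOnset, protocol@squareOffset, "square")
  if (protocol@kind %in% c("flashed_bar", "line_motion"))
    occ <- addFlash(occ, barLo, barHi, protocol@barOnset, protocol@barOffset, "bar")
  occ <- pmin(occ, 1)
  attr(occ, "leadFrames") <- 0L
  occ
}

#' Smooth, scale and delay a stimulus occupancy into the afferent drive
#'
#' Each column is convolved with a unit-area Gaussian of width `sigmaFF`
#' (zero-padded linear convolution), multiplied by the feed-forward gain, and
#' the whole matrix is shifted right by `delayFrames` columns (zero-filled at
#' the start) to model the fixed retino-cortical delay. For a stimulus much
#' wider than `sigmaFF` the interior plateau equals `gainFF` exactly.
#'
#' @param occupancy matrix from [buildStimulus()] (or compatible), with an
#'   optional `leadFrames` attribute.
#' @param grid a [SpaceTimeGrid-class].
#' @param sigmaFF feed-forward smoothing width, mm.
#' @param gainFF feed-forward gain (sets the drive scale in mV).
#' @param delayFrames retino-cortical delay in frames (default 2 = 19.2 ms).
#' @return An [InputField-class].
#' @export
smoothAndDelay <- function(occupancy, grid, sigmaFF, gainFF, delayFrames = 2L) {
  stopifnot(sigmaFF > 0, gainFF > 0, delayFrames >= 0)
  if (sigmaFF < grid@pixelPitch / 2)
    warning("sigmaFF is smaller than half the pixel pitch; the smoothing kernel is under-resolved")
  k <- discreteGaussian(sigmaFF, grid@pixelPitch)
  K <- attr(k, "halfWidth")
  np <- nrow(occupancy)
  sm <- apply(occupancy, 2, function(col) {
    full <- stats::convolve(col, rev(k), type = "open")
    full[(K + 1):(K + np)] * grid@pixelPitch
  })
  sm <- matrix(sm, nrow = np)
  out <- matrix(0, np, ncol(sm))
  if (delayFrames < ncol(sm))
    out[, (delayFrames + 1):ncol(sm)] <- sm[, 1:(ncol(sm) - delayFrames)]
  lead <- attr(occupancy, "leadFrames")
  out <- pmax(out, 0)  # clamp FFT round-off; the true convolution is non-negative
  new("InputField", values = gainFF * out, grid = grid,
      delayFrames = as.integer(delayFrames),
      leadFrames = as.integer(if (is.null(lead)) 0L else lead))
}

#' Build the afferent drive for a protocol in one call
#'
#' Convenience wrapper: [buildStimulus()] followed by [smoothAndDelay()] with
#' the feed-forward parameters taken from `params`.
#'
#' @param protocol a [StimulusProtocol-class].
#' @param grid a [SpaceTimeGrid-class].
#' @param params a [FieldParams-class] (uses `gFF`, `sigmaFF`).
#' @param delayFrames retino-cortical delay in frames.
#' @return An [InputField-class].
#' @export
stimulusDrive <- function(protocol, grid, params = fieldParams(), delayFrames = 2L) {
  smoothAndDelay(buildStimulus(protocol, grid), grid,
                 sigmaFF = params@sigmaFF, gainFF = params@gFF,
                 delayFrames = delayFrames)
}
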