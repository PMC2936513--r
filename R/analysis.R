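# Quantitative response analyses: superposition nonlinearity with interval
# statistics, layer correlation, wavefront propagation speed, onset slopes.

#' Analysis intervals on the imaging frame clock
#'
#' 1-based frame indices: pre-stimulus frames 1-4, "facilitatory" frames
#' 5-12, "suppressive" frames 13-20. Intervals must be disjoint and ordered.
#'
#' @param pre,facilitatory,suppressive integer frame vectors.
#' @return list of the three intervals.
#' @export
intervalSpec <- function(pre = 1:4, facilitatory = 5:12, suppressive = 13:20) {
  iv <- list(pre = pre, facilitatory = facilitatory, suppressive = suppressive)
  all_ <- unlist(iv)
  if (anyDuplicated(all_) || is.unsorted(all_))
    stop("intervals must be disjoint and ordered")
  iv
}

#' Superposition test: line-motion versus square + bar
#'
#' Compares the response to the combined (line-motion) stimulus against the
#' superposition of the individually evoked square and bar responses:
#' `difference = LM - (square + bar)`. Per interval, all pixel values of the
#' two patterns are pooled and compared by a two-sided Mann-Whitney U test
#' (normal approximation with tie correction; exact enumeration for small
#' samples). Positive difference mass indicates facilitation, negative mass
#' suppression.
#'
#' @param respSquare,respBar,respLM space-time matrices on identical grids
#'   and clocks (e.g. baseline-subtracted aggregated signals or dye patterns).
#' @param intervals an [intervalSpec()] list.
#' @return list with `difference` (matrix) and `intervals`: per interval the
#'   U statistic, two-tailed p, group sizes and the net difference mass.
#' @export
superpositionCompare <- function(respSquare, respBar, respLM,
                                 intervals = intervalSpec()) {
  if (!identical(dim(respSquare), dim(respBar)) ||
      !identical(dim(respSquare), dim(respLM)))
    stop("response matrices must share dimensions (aligned shapes and clocks)")
  super <- respSquare + respBar
  diffMat <- respLM - super
  res <- lapply(intervals, function(fr) {
    if (max(fr) > ncol(respLM)) stop("interval exceeds the number of frames")
    x <- as.vector(respLM[, fr]); y <- as.vector(super[, fr])
    wt <- wilcox.test(x, y, alternative = "two.sided",
                      exact = (length(x) <= 50 && length(y) <= 50 &&
                                 !anyDuplicated(c(x, y))),
                      correct = TRUE)
    list(U = unname(wt$statistic), p = wt$p.value,
         n1 = length(x), n2 = length(y), netMass = sum(diffMat[, fr]))
  })
  list(difference = diffMat, intervals = res)
}

#' Exact two-sided Mann-Whitney U by enumeration
#'
#' Brute-force null distribution of U over all assignments of the pooled
#' values into the two groups; intended for validation at small sample sizes.
#'
#' @param x,y numeric samples (combined size kept small).
#' @return list with `U` and exact two-tailed `p`.
#' @export
mannWhitneyExact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (choose(n1 + n2, n1) > 2e5) stop("sample too large for enumeration")
  uStat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U <- uStat(x, y)
  pool <- c(x, y)
  combs <- utils::combn(n1 + n2, n1)
  Us <- apply(combs, 2, function(ix) uStat(pool[ix], pool[-ix]))
  # two-tailed: doubled smaller tail, capped at 1
  pLo <- mean(Us <= U); pHi <- mean(Us >= U)
  list(U = U, p = min(1, 2 * min(pLo, pHi)))
}

#' Correlation between the excitatory and inhibitory activity patterns
#'
#' Pearson correlation over the flattened mapped space-time blocks of the two
#' layers.
#'
#' @param traj a [FieldTrajectory-class] (relaxed).
#' @return scalar r; `NA` with a warning if either layer has zero variance.
#' @export
layerCorrelation <- function(traj) {
  x <- as.vector(uE(traj, mapped = TRUE))
  y <- as.vector(uI(traj, mapped = TRUE))
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in a layer; correlation undefined")
    return(NA_real_)
  }
  cor(x, y)
}

#' Wavefront propagation speed from threshold crossings
#'
#' For each mapped position, the earliest time at which the pattern reaches
#' `thresholdFraction` of its global maximum is found with linear sub-frame
#' interpolation (positions already above threshold at the first frame have
#' no upward crossing and are excluded). The speed is the least-squares slope
#' of position versus crossing time over all crossing positions, converted to
#' m/s via the pixel pitch and frame duration.
#'
#' @param pattern space-time matrix `[nMapped x nFrames]` with a positive
#'   global maximum (e.g. a baseline-subtracted aggregated signal).
#' @param grid a [SpaceTimeGrid-class].
#' @param thresholdFraction fraction of the global maximum (default 0.8).
#' @return A [SpeedEstimate-class]; fewer than 3 crossing positions yield
#'   `speed = NA` with a warning.
#' @export
propagationSpeed <- function(pattern, grid, thresholdFraction = 0.8) {
  if (max(pattern) <= 0) stop("pattern must have a positive global maximum")
  thr <- thresholdFraction * max(pattern)
  nP <- nrow(pattern)
  cross <- rep(NA_real_, nP)
  for (i in seq_len(nP)) {
    v <- pattern[i, ]
    j <- which(v >= thr)[1]
    if (is.na(j) || j == 1L) next
    t1 <- (j - 2) * grid@frameDt
    cross[i] <- t1 + (thr - v[j - 1]) / (v[j] - v[j - 1]) * grid@frameDt
  }
  used <- which(!is.na(cross))
  if (length(used) < 3L) {
    warning("fewer than 3 threshold-crossing positions; no speed estimate")
    return(new("SpeedEstimate", thresholdFraction = thresholdFraction,
               crossingTimes = cross, speed = NA_real_, rSquared = NA_real_,
               positionsUsed = integer(0), speedCI = c(NA_real_, NA_real_)))
  }
  pos <- (used - 0.5) * grid@pixelPitch    # mm
  tms <- cross[used]                       # ms
  fit <- lm(pos ~ tms)
  sm <- summary(fit)
  ci <- suppressWarnings(stats::confint(fit, "tms", level = 0.95))
  new("SpeedEstimate", thresholdFraction = thresholdFraction,
      crossingTimes = cross, speed = unname(coef(fit)[2]),  # mm/ms == m/s
      rSquared = sm$r.squared, positionsUsed = as.integer(used),
      speedCI = as.numeric(ci))
}

#' Onset slope of a pixel time course
#'
#' Least-squares slope of one pixel's time course over a time window, in
#' signal units per ms. Standard windows are 20-70 ms for square-driven
#' conditions and 80-130 ms for the flashed bar.
#'
#' @param pattern space-time matrix `[positions x nFrames]`.
#' @param windowMs numeric length-2, window on the frame clock (ms).
#' @param pixel row index.
#' @param grid a [SpaceTimeGrid-class].
#' @return slope, signal units / ms.
#' @export
onsetSlope <- function(pattern, windowMs, pixel, grid) {
  tt <- frameTimes(grid)
  sel <- tt >= windowMs[1] & tt <= windowMs[2]
  if (sum(sel) < 2L) stop("onset window must contain at least 2 frames")
  y <- pattern[pixel, sel]
  unname(coef(lm(y ~ tt[sel]))[2])
}
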