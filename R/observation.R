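# Observation model: affine excitation/inhibition mixture mapping the field
# state to the dye signal, fitted by constrained least squares.

#' Aggregate a trajectory into the modeled dye signal
#'
#' `a * uE + b * uI + c` restricted to the mapped positions and sampled
#' frames. With `baseline = TRUE` the mean of the first `baselineMs` of the
#' window is subtracted (mirroring the dye preprocessing), which is the form
#' used in model-only response analyses.
#'
#' @param traj a [FieldTrajectory-class].
#' @param a,b non-negative mixing coefficients (dF/F per mV).
#' @param c offset (dF/F).
#' @param baseline subtract the early-window mean?
#' @param baselineMs length of the baseline window, ms (default 20).
#' @return matrix `[nMapped x nFrames]`.
#' @export
aggregateSignal <- function(traj, a, b, c = 0, baseline = FALSE, baselineMs = 20) {
  stopifnot(a >= 0, b >= 0)
  ag <- a * uE(traj, mapped = TRUE) + b * uI(traj, mapped = TRUE) + c
  if (baseline) {
    nb <- max(1L, sum(frameTimes(traj@grid) - traj@grid@t0Offset < baselineMs))
    ag <- ag - mean(ag[, seq_len(nb)])
  }
  ag
}

#' Default model-only mixture
#'
#' For analyses that need an aggregated signal without a dye fit the package
#' uses the reference inhibitory share `kappa = 0.54`: `a = 1 - kappa`,
#' `b = kappa`, `c = 0`.
#'
#' @param kappa inhibitory share.
#' @return list with `a`, `b`, `c`.
#' @export
defaultMixture <- function(kappa = 0.54) list(a = 1 - kappa, b = kappa, c = 0)

# Solve min ||a x + b y + c - d||^2 s.t. a, b >= 0 by active sets: the
# unconstrained normal equations, then each boundary face, keeping the
# feasible candidate with the smallest RSS (ties toward the interior).
.nnls2 <- function(x, y, d) {
  n <- length(d)
  xm <- mean(x); ym <- mean(y); dm <- mean(d)
  xc <- x - xm; yc <- y - ym; dc <- d - dm
  sxx <- sum(xc * xc); syy <- sum(yc * yc); sxy <- sum(xc * yc)
  sxd <- sum(xc * dc); syd <- sum(yc * dc)
  det <- sxx * syy - sxy * sxy
  cand <- list()
  if (det > 1e-12 * max(sxx * syy, 1e-300)) {
    a <- (syy * sxd - sxy * syd) / det
    b <- (sxx * syd - sxy * sxd) / det
    cand <- c(cand, list(c(a, b)))
  }
  if (sxx > 0) cand <- c(cand, list(c(sxd / sxx, 0)))
  if (syy > 0) cand <- c(cand, list(c(0, syd / syy)))
  cand <- c(cand, list(c(0, 0)))
  best <- NULL; bestRss <- Inf
  for (ab in cand) {
    if (any(!is.finite(ab)) || ab[1] < 0 || ab[2] < 0) next
    rss <- sum((dc - ab[1] * xc - ab[2] * yc)^2)
    thr <- if (is.finite(bestRss)) bestRss - 1e-15 * max(1, bestRss) else Inf
    if (rss < thr) { best <- ab; bestRss <- rss }
  }
  cOff <- dm - best[1] * xm - best[2] * ym
  list(a = best[1], b = best[2], c = cOff, rss = bestRss)
}

#' Fit the observation-model mixture by constrained least squares
#'
#' Minimizes the squared error of `a uE + b uI + c` against the concatenated
#' dye signal over all supplied conditions, subject to `a, b >= 0` (the
#' offset is unconstrained), by exact active-set enumeration of the two
#' constraints after offset centering. Returns the inhibitory share
#' `kappa = b/(a + b)` together with overall and per-condition Pearson
#' correlations.
#'
#' @param trajs a [FieldTrajectory-class], or a named list of them.
#' @param dyes a [DyePattern-class] (or plain matrix), or a list matching
#'   `trajs`; concatenation follows the list order.
#' @return A [MixtureFit-class].
#' @examples
#' \donttest{
#' traj <- simulateCondition(fieldParams(), stimulusProtocol("flashed_square"),
#'                           spaceTimeGrid())
#' dye <- aggregateSignal(traj, 0.5, 0.5, 0.1)
#' fitMixture(traj, dye)   # recovers (0.5, 0.5, 0.1)
#' }
#' @export
fitMixture <- function(trajs, dyes) {
  if (is(trajs, "FieldTrajectory")) trajs <- list(trajs)
  if (!is.list(dyes) || is(dyes, "DyePattern")) dyes <- list(dyes)
  stopifnot(length(trajs) == length(dyes))
  dyeMat <- function(d) if (is(d, "DyePattern")) d@values else d
  xs <- lapply(trajs, uE, mapped = TRUE)
  ys <- lapply(trajs, uI, mapped = TRUE)
  ds <- lapply(dyes, dyeMat)
  for (i in seq_along(xs))
    if (!identical(dim(xs[[i]]), dim(ds[[i]])))
      stop("trajectory and dye pattern shapes differ for condition ", i)
  x <- unlist(lapply(xs, as.vector)); y <- unlist(lapply(ys, as.vector))
  d <- unlist(lapply(ds, as.vector))
  nonUnique <- FALSE
  if (sd(x) > 0 && sd(y) > 0 && abs(cor(x, y)) > 1 - 1e-10) nonUnique <- TRUE
  sol <- .nnls2(x, y, d)
  fitted <- sol$a * x + sol$b * y + sol$c
  rAll <- if (sd(fitted) > 0 && sd(d) > 0) cor(d, fitted) else NA_real_
  rPer <- numeric(0)
  if (length(trajs) > 1L || !is.null(names(trajs))) {
    rPer <- vapply(seq_along(xs), function(i) {
      fi <- sol$a * as.vector(xs[[i]]) + sol$b * as.vector(ys[[i]]) + sol$c
      di <- as.vector(ds[[i]])
      if (sd(fi) > 0 && sd(di) > 0) cor(di, fi) else NA_real_
    }, numeric(1))
    names(rPer) <- if (!is.null(names(trajs))) names(trajs) else
      paste0("condition", seq_along(trajs))
  }
  kap <- if (sol$a + sol$b > 0) sol$b / (sol$a + sol$b) else NA_real_
  new("MixtureFit", a = sol$a, b = sol$b, c = sol$c, kappa = kap,
      rss = sol$rss, rOverall = rAll, rPerCondition = rPer,
      nonUnique = nonUnique)
}

#' Compare the full mixture to its single-layer restrictions
#'
#' Fits the full model and the two restrictions (`b = 0`: excitation only;
#' `a = 0`: inhibition only) and forms the goodness-of-fit statistic
#' `n * (RSS_restricted - RSS_full) / RSS_full`, referred to a chi-square
#' distribution with one degree of freedom (a Wald-type test). The residuals
#' of space-time fits are correlated and heteroscedastic, which inflates the
#' statistic; the p-values are therefore indicative rather than exact.
#'
#' @param trajs,dyes as in [fitMixture()].
#' @return list with `rssFull`, `rssEOnly`, `rssIOnly`, the two statistics
#'   (`waldEOnly` for dropping the inhibitory regressor, `waldIOnly` for
#'   dropping the excitatory one), `df`, p-values, and `n`.
#' @export
restrictedFitTest <- function(trajs, dyes) {
  if (is(trajs, "FieldTrajectory")) trajs <- list(trajs)
  if (!is.list(dyes) || is(dyes, "DyePattern")) dyes <- list(dyes)
  dyeMat <- function(d) if (is(d, "DyePattern")) d@values else d
  x <- unlist(lapply(trajs, function(t) as.vector(uE(t, mapped = TRUE))))
  y <- unlist(lapply(trajs, function(t) as.vector(uI(t, mapped = TRUE))))
  d <- unlist(lapply(dyes, function(dd) as.vector(dyeMat(dd))))
  n <- length(d)
  full <- .nnls2(x, y, d)
  eOnly <- .nnls2(x, rep(0, n), d)   # b forced to 0
  iOnly <- .nnls2(rep(0, n), y, d)   # a forced to 0
  stat <- function(rssR) {
    if (full$rss <= 0) return(NA_real_)
    n * (rssR - full$rss) / full$rss
  }
  wE <- stat(eOnly$rss); wI <- stat(iOnly$rss)
  list(rssFull = full$rss, rssEOnly = eOnly$rss, rssIOnly = iOnly$rss,
       waldEOnly = wE, waldIOnly = wI, df = 1L,
       pEOnly = if (is.na(wE)) NA_real_ else pchisq(wE, df = 1, lower.tail = FALSE),
       pIOnly = if (is.na(wI)) NA_real_ else pchisq(wI, df = 1, lower.tail = FALSE),
       n = n,
       note = "residual space-time correlation inflates the statistic")
}

#' Correlation achieved at fixed mixing ratios
#'
#' For each `kappa` on the grid the regressor `(1 - kappa) uE + kappa uI` is
#' fitted to the dye signal with free scale and offset, and the Pearson
#' correlation of the fit is recorded. `kappa = 0` and `kappa = 1` reproduce
#' the single-layer restricted fits.
#'
#' @param trajs,dyes as in [fitMixture()].
#' @param kappaGrid numeric vector in `[0, 1]`.
#' @return data.frame with columns `kappa`, `r`; attribute `best` holds the
#'   argmax row.
#' @export
kappaSweep <- function(trajs, dyes, kappaGrid = seq(0, 1, by = 0.02)) {
  stopifnot(all(kappaGrid >= 0 & kappaGrid <= 1))
  if (is(trajs, "FieldTrajectory")) trajs <- list(trajs)
  if (!is.list(dyes) || is(dyes, "DyePattern")) dyes <- list(dyes)
  dyeMat <- function(d) if (is(d, "DyePattern")) d@values else d
  x <- unlist(lapply(trajs, function(t) as.vector(uE(t, mapped = TRUE))))
  y <- unlist(lapply(trajs, function(t) as.vector(uI(t, mapped = TRUE))))
  d <- unlist(lapply(dyes, function(dd) as.vector(dyeMat(dd))))
  r <- vapply(kappaGrid, function(k) {
    z <- (1 - k) * x + k * y
    if (sd(z) == 0 || sd(d) == 0) return(NA_real_)
    cor(d, z)  # free positive scale and offset leave Pearson r unchanged
  }, numeric(1))
  out <- data.frame(kappa = kappaGrid, r = r)
  attr(out, "best") <- out[which.max(out$r), , drop = FALSE]
  out
}
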