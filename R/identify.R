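# Parameter identification: exhaustive grid search with four selection
# criteria, the correlation/kappa objective, CMA-ES refinement, and AIC.

#' Grid specification for the parameter search
#'
#' Per-parameter candidate lists for the 10 searched parameters (three values
#' each in the full design), with the remaining parameters fixed; the
#' excitatory and inhibitory resting potentials are tied (`hI = hE`).
#'
#' @param tauE,tauI,h,gEE,gIE,gEI,sigmaEE,sigmaEI,betaE,betaI numeric vectors
#'   of candidate values; `h` feeds both resting potentials.
#' @param fixed a [FieldParams-class] providing the non-searched values.
#' @return object of class `GridSpec` (list with `values`, `fixed`, `size`).
#' @export
gridSpec <- function(tauE, tauI, h, gEE, gIE, gEI, sigmaEE, sigmaEI,
                     betaE, betaI, fixed = fieldParams()) {
  values <- list(tauE = tauE, tauI = tauI, h = h, gEE = gEE, gIE = gIE,
                 gEI = gEI, sigmaEE = sigmaEE, sigmaEI = sigmaEI,
                 betaE = betaE, betaI = betaI)
  structure(list(values = values, fixed = fixed,
                 size = prod(lengths(values))), class = "GridSpec")
}

#' The full published search grid (3 points per searched parameter, 3^10 configurations)
#' @param fixed a [FieldParams-class] with the fixed parameter values.
#' @return a `GridSpec`.
#' @export
defaultGridSpec <- function(fixed = fieldParams()) {
  gridSpec(tauE = c(9.6, 19.2, 28.8), tauI = c(9.6, 19.2, 28.8),
           h = c(-100, -80, -60),
           gEE = c(50, 125, 200), gIE = c(50, 125, 200), gEI = c(50, 125, 200),
           sigmaEE = c(0.64, 1.27, 1.91), sigmaEI = c(0.64, 1.27, 1.91),
           betaE = c(0.05, 0.1, 0.15), betaI = c(0.05, 0.1, 0.15),
           fixed = fixed)
}

#' @export
print.GridSpec <- function(x, ...) {
  cat(sprintf("GridSpec: %d configurations over %d searched parameters (hI = hE tied)\n",
              x$size, length(x$values)))
  invisible(x)
}

# materialize configuration i (1-based, row-major over the value lists)
.gridConfig <- function(grid, i) {
  lens <- lengths(grid$values)
  idx <- integer(length(lens))
  rem <- i - 1L
  for (k in rev(seq_along(lens))) {  # last parameter varies fastest
    idx[k] <- rem %% lens[k] + 1L
    rem <- rem %/% lens[k]
  }
  v <- mapply(function(vals, j) vals[j], grid$values, idx)
  p <- paramsAsList(grid$fixed)
  p$tauE <- v[["tauE"]]; p$tauI <- v[["tauI"]]
  p$hE <- v[["h"]]; p$hI <- v[["h"]]
  p$gEE <- v[["gEE"]]; p$gIE <- v[["gIE"]]; p$gEI <- v[["gEI"]]
  p$sigmaEE <- v[["sigmaEE"]]; p$sigmaEI <- v[["sigmaEI"]]
  p$betaE <- v[["betaE"]]; p$betaI <- v[["betaI"]]
  paramsFromList(p)
}

# onset-slope windows per condition kind (ms): early window for square-driven
# conditions, the bar window for the flashed bar
.onsetWindow <- function(kind) {
  if (kind == "flashed_bar") c(80, 130) else c(20, 70)
}

#' Exhaustive grid search with the four selection criteria
#'
#' For every configuration the field is simulated for the training
#' conditions, the mixture is fitted, and four criteria are evaluated:
#' (1) linear stability of the homogeneous state, (2) decay of the response
#' back to rest after stimulus offset (within `decayTol` of the fixed point
#' at the end of an extended run), (3) overall dye/model correlation above
#' `rMin`, and (4) onset-window slope of the model within
#' `slopeBand` times the dye slope at the stimulus-center pixel (windows
#' 20-70 ms for square-driven conditions, 80-130 ms for the bar). A
#' configuration survives iff all four hold. Iteration order is
#' deterministic; a finite `budget` truncates the scan and flags the report
#' incomplete.
#'
#' @param grid a `GridSpec`.
#' @param protocols named list of [StimulusProtocol-class] (training set).
#' @param dyes named list of [DyePattern-class] matching `protocols`.
#' @param stGrid a [SpaceTimeGrid-class].
#' @param rMin criterion-(3) correlation threshold.
#' @param slopeBand criterion-(4) model/dye slope-ratio band.
#' @param decayTol criterion-(2) tolerance as a fraction of the peak deviation.
#' @param extendMs extra zero-input time simulated for the decay check.
#' @param budget maximum number of configurations to evaluate.
#' @param verbose print progress every 50 configurations.
#' @return a `SelectionReport`: data.frame with one row per configuration
#'   (criteria flags, overall r, kappa, survivor flag); attributes
#'   `complete`, `survivors`.
#' @export
runGridSearch <- function(grid, protocols, dyes, stGrid = spaceTimeGrid(),
                          rMin = 0.8, slopeBand = c(0.5, 2), decayTol = 0.01,
                          extendMs = 250, budget = Inf, verbose = FALSE) {
  stopifnot(identical(names(protocols), names(dyes)))
  nEval <- min(grid$size, budget)
  if (grid$size == 0 || nEval == 0) {
    rep0 <- data.frame(config = integer(0), stable = logical(0),
                       decays = logical(0), rPass = logical(0),
                       slopePass = logical(0), r = numeric(0),
                       kappa = numeric(0), survives = logical(0))
    attr(rep0, "complete") <- TRUE
    attr(rep0, "survivors") <- integer(0)
    class(rep0) <- c("SelectionReport", "data.frame")
    return(rep0)
  }
  extGrid <- spaceTimeGrid(stGrid@nPositions, stGrid@nMapped, stGrid@pixelPitch,
                           stGrid@frameDt,
                           stGrid@nFrames + as.integer(ceiling(extendMs / stGrid@frameDt)),
                           stGrid@t0Offset)
  rows <- vector("list", nEval)
  for (i in seq_len(nEval)) {
    p <- .gridConfig(grid, i)
    row <- list(config = i, stable = FALSE, decays = FALSE, rPass = FALSE,
                slopePass = FALSE, r = NA_real_, kappa = NA_real_,
                survives = FALSE)
    verdict <- tryCatch(checkStability(p), error = function(e) NULL)
    row$stable <- !is.null(verdict) && isStable(verdict)
    if (row$stable) {
      sims <- tryCatch(
        lapply(protocols, function(pr) {
          # extended window: stimulus as specified, then zero input
          occ <- buildStimulus(pr, stGrid)
          lead <- attr(occ, "leadFrames")
          occExt <- cbind(occ, matrix(0, nrow(occ), extGrid@nFrames - stGrid@nFrames))
          attr(occExt, "leadFrames") <- lead
          inp <- smoothAndDelay(occExt, extGrid, p@sigmaFF, p@gFF)
          simulateField(p, inp, extGrid, init = "fixedpoint")
        }), error = function(e) NULL)
      if (!is.null(sims)) {
        fp <- homogeneousFixedPoint(p)
        winIdx <- seq_len(stGrid@nFrames)
        # criterion (2): terminal deviation small relative to the peak
        row$decays <- all(vapply(sims, function(tr) {
          dev <- abs(uE(tr) - fp@ueBar)
          peak <- max(dev)
          peak == 0 || max(dev[, ncol(dev)]) < decayTol * peak
        }, logical(1)))
        trajsWin <- lapply(sims, function(tr)
          new("FieldTrajectory", uE = tr@uE[, winIdx], uI = tr@uI[, winIdx],
              grid = stGrid, params = p, relaxed = TRUE, condition = tr@condition))
        fit <- fitMixture(trajsWin, dyes)
        row$r <- fit@rOverall
        row$kappa <- fit@kappa
        row$rPass <- is.finite(fit@rOverall) && fit@rOverall > rMin
        # criterion (4): onset slopes at the stimulus-center pixel
        centerPx <- vapply(protocols, function(pr) {
          x0 <- pr@anchorPosition + pr@squareExtent / 2
          which.min(abs(positionsMm(stGrid)[mappedIndices(stGrid)] - x0))
        }, integer(1))
        ratios <- mapply(function(tr, dye, pr, px) {
          win <- .onsetWindow(pr@kind)
          ag <- aggregateSignal(tr, fit@a, fit@b, fit@c)
          sM <- onsetSlope(ag, win, px, stGrid)
          sD <- onsetSlope(dyeValues(dye), win, px, stGrid)
          if (sD == 0) return(NA_real_)
          sM / sD
        }, trajsWin, dyes, protocols, centerPx)
        row$slopePass <- all(is.finite(ratios) & ratios >= slopeBand[1] &
                               ratios <= slopeBand[2])
      }
    }
    row$survives <- row$stable && row$decays && row$rPass && row$slopePass
    rows[[i]] <- as.data.frame(row)
    if (verbose && i %% 50 == 0)
      message(sprintf("grid search: %d/%d configurations", i, nEval))
  }
  report <- do.call(rbind, rows)
  attr(report, "complete") <- nEval == grid$size
  attr(report, "survivors") <- report$config[report$survives]
  class(report) <- c("SelectionReport", "data.frame")
  report
}

#' Identification objective: correlation plus mixing-ratio penalty
#'
#' The scalar objective minimized during refinement: the negative mean of the
#' per-condition dye/model correlations plus
#' `tradeoff * (kappa - kappaTarget)^2`, where the mixture (and hence kappa)
#' is re-fitted for every parameter proposal. Simulation failures (divergence,
#' missing fixed point) yield `+Inf` so the optimizer treats them as
#' infeasible rather than crashing.
#'
#' @param params a [FieldParams-class].
#' @param protocols,dyes named lists as in [runGridSearch()].
#' @param stGrid a [SpaceTimeGrid-class].
#' @param tradeoff non-negative penalty weight.
#' @param kappaTarget target inhibitory share.
#' @param init integrator initialization (see [simulateField()]).
#' @param inputs optional named list of precomputed [InputField-class]
#'   drives matching `protocols` (they depend only on the fixed feed-forward
#'   parameters, so scan loops can reuse them).
#' @param mixture optional fixed mixture `list(a, b, c)`; when supplied the
#'   observation model is *not* refitted per proposal. Refitting makes `gEI`
#'   practically unidentifiable (the fitted `b` absorbs any rescaling of the
#'   inhibitory layer), so parameter-recovery experiments against synthetic
#'   dye with a known mixture should fix it.
#' @param metric `"correlation"` (negative mean per-condition r, the
#'   refinement objective) or `"rss"` (total squared error; sharper for
#'   recovery experiments since it is sensitive to absolute amplitude).
#' @return list with `value`, `rPerCondition`, `kappa`, `penalty`.
#' @export
identificationObjective <- function(params, protocols, dyes,
                                    stGrid = spaceTimeGrid(), tradeoff = 1,
                                    kappaTarget = 0.5, init = "fixedpoint",
                                    inputs = NULL, mixture = NULL,
                                    metric = c("correlation", "rss")) {
  stopifnot(tradeoff >= 0)
  metric <- match.arg(metric)
  sims <- tryCatch({
    fp <- if (identical(init, "fixedpoint")) homogeneousFixedPoint(params) else NULL
    lapply(names(protocols), function(nm) {
      inp <- if (is.null(inputs)) stimulusDrive(protocols[[nm]], stGrid, params)
             else inputs[[nm]]
      simulateField(params, inp, stGrid, condition = nm, init = init, fp = fp)
    })},
    error = function(e) NULL)
  if (is.null(sims))
    return(list(value = Inf, rPerCondition = NULL, kappa = NA_real_, penalty = NA_real_))
  names(sims) <- names(protocols)
  dyeMat <- function(d) if (is(d, "DyePattern")) d@values else d
  if (is.null(mixture)) {
    fit <- fitMixture(sims, dyes)
    coefs <- list(a = fit@a, b = fit@b, c = fit@c)
    kap <- fit@kappa
    rs <- fit@rPerCondition
    if (!length(rs)) rs <- setNames(fit@rOverall, "all")
  } else {
    coefs <- mixture
    kap <- if (coefs$a + coefs$b > 0) coefs$b / (coefs$a + coefs$b) else NA_real_
    rs <- vapply(names(sims), function(nm) {
      ag <- aggregateSignal(sims[[nm]], coefs$a, coefs$b, coefs$c)
      d <- dyeMat(dyes[[nm]])
      if (sd(ag) == 0 || sd(d) == 0) NA_real_ else cor(as.vector(d), as.vector(ag))
    }, numeric(1))
  }
  if (any(!is.finite(rs)))
    return(list(value = Inf, rPerCondition = rs, kappa = kap, penalty = NA_real_))
  pen <- if (is.finite(kap)) tradeoff * (kap - kappaTarget)^2 else 0
  value <- if (metric == "correlation") -mean(rs) + pen else {
    rss <- sum(vapply(names(sims), function(nm) {
      ag <- aggregateSignal(sims[[nm]], coefs$a, coefs$b, coefs$c)
      sum((dyeMat(dyes[[nm]]) - ag)^2)
    }, numeric(1)))
    rss + pen
  }
  list(value = value, rPerCondition = rs, kappa = kap, penalty = pen)
}

#' The parameter subset adjusted during refinement
#'
#' The two resting potentials, the three coupling gains and the two transfer
#' slopes - the seven parameters the evolutionary refinement is allowed to
#' change.
#' @return character vector of slot names.
#' @export
refinedSubset <- function() c("hE", "hI", "gEE", "gIE", "gEI", "betaE", "betaI")

#' Covariance matrix adaptation evolution strategy (minimization)
#'
#' A standard (mu/mu_w, lambda) CMA-ES with rank-one and rank-mu covariance
#' updates and cumulative step-size adaptation, using the published default
#' strategy parameters for the problem dimension. Coordinates are scaled by
#' `abs(start)` internally so a single global step size is meaningful across
#' parameters of different magnitude. If a whole generation evaluates to
#' non-finite values the step size is halved (logged in the trace) and the
#' generation resampled.
#'
#' @param fn objective function taking a numeric vector, returning a scalar
#'   (may be `Inf` for infeasible points).
#' @param start numeric start vector (non-zero entries).
#' @param seed integer random seed (mandatory: runs are reproducible).
#' @param sigma0 initial step size in scaled coordinates.
#' @param maxEvals evaluation budget.
#' @param stopTol stop when the best value improves less than this over the
#'   last 20 generations and sigma has shrunk below `1e-8`.
#' @param lower,upper optional box constraints (original coordinates);
#'   proposals outside are evaluated as `Inf`.
#' @return list with `par` (best-ever), `value`, `evals`, and `trace`
#'   (data.frame per generation: evals, sigma, best, bestEver).
#' @export
cmaES <- function(fn, start, seed, sigma0 = 0.1, maxEvals = 2000,
                  stopTol = 1e-12, lower = NULL, upper = NULL) {
  stopifnot(!missing(seed), all(start != 0))
  set.seed(as.integer(seed))
  n <- length(start)
  scale <- abs(start)
  wrap <- function(z) {  # scaled -> original
    x <- z * scale
    if (!is.null(lower) && any(x < lower)) return(Inf)
    if (!is.null(upper) && any(x > upper)) return(Inf)
    fn(x)
  }
  lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- start / scale
  sigma <- sigma0
  C <- diag(n); ps <- numeric(n); pc <- numeric(n)
  eig <- eigen(C, symmetric = TRUE)
  B <- eig$vectors; D <- sqrt(pmax(eig$values, 0))
  bestEver <- wrap(m); bestPar <- m
  evals <- 1L
  trace <- list()
  gen <- 0L
  while (evals < maxEvals) {
    gen <- gen + 1L
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)                     # N(0, C) samples
    X <- m + sigma * Y
    f <- apply(X, 2, wrap)
    evals <- evals + lambda
    if (all(!is.finite(f))) {              # all-infeasible generation
      sigma <- sigma / 2
      trace[[gen]] <- data.frame(evals = evals, sigma = sigma,
                                 best = NA_real_, bestEver = bestEver,
                                 restart = TRUE)
      next
    }
    ord <- order(f)
    sel <- ord[seq_len(mu)]
    yw <- drop(Y[, sel, drop = FALSE] %*% w)
    m <- m + sigma * yw
    # cumulative paths
    Cinvsqrt <- B %*% ((1 / pmax(D, 1e-300)) * t(B))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(Cinvsqrt %*% yw)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * gen)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
    # covariance update
    Ysel <- Y[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * Ysel %*% (w * t(Ysel))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    eig <- eigen((C + t(C)) / 2, symmetric = TRUE)
    B <- eig$vectors; D <- sqrt(pmax(eig$values, 1e-300))
    if (f[ord[1]] < bestEver) { bestEver <- f[ord[1]]; bestPar <- X[, ord[1]] }
    trace[[gen]] <- data.frame(evals = evals, sigma = sigma, best = f[ord[1]],
                               bestEver = bestEver, restart = FALSE)
    if (sigma < 1e-8) {
      recent <- tail(vapply(trace, function(t) t$bestEver, numeric(1)), 20)
      if (length(recent) == 20 && (recent[1] - recent[20]) < stopTol) break
    }
  }
  list(par = bestPar * scale, value = bestEver, evals = evals,
       trace = do.call(rbind, trace))
}

#' Refine field parameters with CMA-ES
#'
#' Optimizes the [identificationObjective()] over the refined parameter
#' subset, starting from `start` (all other parameters held fixed).
#'
#' @param start a [FieldParams-class] starting configuration.
#' @param protocols,dyes named lists of training conditions.
#' @param stGrid a [SpaceTimeGrid-class].
#' @param freeSubset names of the parameters to optimize
#'   (default [refinedSubset()]).
#' @param seed integer random seed (mandatory).
#' @param maxEvals evaluation budget.
#' @param sigma0 initial relative step size.
#' @param tradeoff,kappaTarget objective settings.
#' @param mixture,metric passed to [identificationObjective()].
#' @return list with `params` (best [FieldParams-class]), `value`, `trace`.
#' @export
refineCMAES <- function(start, protocols, dyes, stGrid = spaceTimeGrid(),
                        freeSubset = refinedSubset(), seed, maxEvals = 2000,
                        sigma0 = 0.1, tradeoff = 1, kappaTarget = 0.5,
                        mixture = NULL, metric = "correlation") {
  base <- paramsAsList(start)
  inputs <- lapply(protocols, stimulusDrive, grid = stGrid, params = start)
  fn <- function(x) {
    p <- base
    p[freeSubset] <- as.list(x)
    pObj <- tryCatch(paramsFromList(p), error = function(e) NULL)
    if (is.null(pObj)) return(Inf)
    identificationObjective(pObj, protocols, dyes, stGrid,
                            tradeoff = tradeoff, kappaTarget = kappaTarget,
                            inputs = inputs, mixture = mixture,
                            metric = metric)$value
  }
  res <- cmaES(fn, unlist(base[freeSubset]), seed = seed,
               sigma0 = sigma0, maxEvals = maxEvals)
  best <- base
  best[freeSubset] <- as.list(res$par)
  list(params = paramsFromList(best), value = res$value, evals = res$evals,
       trace = res$trace)
}

#' Akaike information criterion from a residual sum of squares
#'
#' `n * log(rss / n) + 2 k`. Comparable only across models fitted to the
#' identical data; absolute values carry no meaning.
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of data points.
#' @param k number of model parameters (`n > k`).
#' @return scalar AIC.
#' @examples
#' aic(5000 * exp(1), 5000, 13)   # 5000 + 26
#' @export
aic <- function(rss, n, k) {
  if (rss <= 0) stop("rss must be > 0 (degenerate fit)")
  if (n <= k) stop("n must exceed k")
  n * log(rss / n) + 2 * k
}
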