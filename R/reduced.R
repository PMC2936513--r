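# Control models: single-layer Amari field with Gaussian or Mexican-hat
# kernel, and the lateral-coupling-free feed-forward model.

# coupling matrix for an Amari kernel: g+ G(s+) or g+ G(s+) - g- G(s-)
.amariMatrix <- function(params, grid) {
  M <- couplingMatrix(grid, params@sigmaPlus, params@gPlus)
  if (params@kernel == "mexican_hat" && params@gMinus != 0)
    M <- M - couplingMatrix(grid, params@sigmaMinus, params@gMinus)
  M
}

#' Simulate the single-layer Amari field
#'
#' `tau du/dt = -u + h + (w * f(u))(x) + s(x, t)` with `w` either a single
#' excitatory Gaussian or a Mexican hat (difference of two unit-area
#' Gaussians, `g+ G(sigma+) - g- G(sigma-)`). Shares the integrator,
#' relaxation logic and sampling with the two-layer model; the result is
#' returned as a [FieldTrajectory-class] whose `uI` slot duplicates `uE` (one
#' layer), so downstream single-regressor fits can reuse the same plumbing.
#'
#' @param params an [AmariParams-class].
#' @param input an [InputField-class].
#' @param grid a [SpaceTimeGrid-class].
#' @param sub Euler substeps per frame.
#' @param relaxMs relaxation period, ms.
#' @param driftTol terminal drift tolerance, mV/ms.
#' @param condition label.
#' @return A [FieldTrajectory-class] (single layer; use `uE`).
#' @export
simulateAmari <- function(params, input, grid, sub = 10L, relaxMs = 2000,
                          driftTol = 1e-5, condition = "") {
  dt <- grid@frameDt / sub
  if (dt > params@tau / 5) stop("dt must be <= tau/5; increase sub")
  M <- .amariMatrix(params, grid)
  zero <- matrix(0, grid@nPositions, grid@nPositions)
  n <- grid@nPositions
  # reuse the two-layer integrator with the inhibitory layer decoupled
  pv <- list(tauE = params@tau, tauI = params@tau, hE = params@h, hI = params@h,
             gIE = 0, betaE = params@beta, betaI = params@beta,
             thetaE = params@theta, thetaI = params@theta)
  rel <- do.call(.nf_relax, c(list(M, zero, numeric(n), numeric(n),
                                   as.integer(round(relaxMs / dt)), dt), pv))
  if (rel$drift > driftTol)
    stop(sprintf("Amari relaxation did not settle: terminal drift %.3g mV/ms", rel$drift))
  win <- do.call(.nf_window, c(list(M, zero, rel$ue, rel$ui, input@values,
                                    input@leadFrames, grid@nFrames,
                                    as.integer(sub), dt), pv))
  twoLayer <- fieldParams(tauE = params@tau, tauI = params@tau,
                          hE = params@h, hI = params@h,
                          gEE = params@gPlus, gIE = 0, gEI = 0,
                          sigmaEE = params@sigmaPlus, sigmaEI = params@sigmaPlus,
                          betaE = params@beta, betaI = params@beta,
                          thetaE = params@theta, thetaI = params@theta)
  new("FieldTrajectory", uE = win$uE, uI = win$uE, grid = grid,
      params = twoLayer, relaxed = TRUE, condition = condition)
}

#' Simulate the feed-forward control model
#'
#' No lateral interactions: each position is an independent first-order
#' low-pass of the (already Gaussian-smoothed, delayed) afferent drive,
#' `tau du/dt = -u + s(x, t)`, starting from rest at zero. Spread of activity
#' can only come from the input smoothing itself.
#'
#' @param input an [InputField-class].
#' @param tau time constant, ms.
#' @param grid a [SpaceTimeGrid-class].
#' @param sub Euler substeps per frame.
#' @return A [FieldTrajectory-class] (single layer; baseline 0).
#' @export
simulateFeedforward <- function(input, tau, grid, sub = 10L) {
  stopifnot(tau > 0)
  dt <- grid@frameDt / sub
  n <- grid@nPositions
  u <- numeric(n)
  nLead <- input@leadFrames
  U <- matrix(0, n, grid@nFrames)
  nIntervals <- nLead + grid@nFrames - 1L
  for (k in seq_len(nIntervals)) {
    s <- input@values[, k]
    for (m in seq_len(sub)) u <- u + dt / tau * (-u + s)
    f <- k - nLead + 1L
    if (f >= 1L && f <= grid@nFrames) U[, f] <- u
  }
  pseudo <- fieldParams(tauE = tau, tauI = tau, gEE = 0, gIE = 0, gEI = 0)
  new("FieldTrajectory", uE = U, uI = U, grid = grid, params = pseudo,
      relaxed = TRUE, condition = "")
}

#' Head-to-head model comparison table
#'
#' Fits every model's output to the identical dye set with the matching
#' mixture protocol - the two-layer model with both layers (`a`, `b`, `c`),
#' single-layer models with one regressor plus offset - and reports RSS,
#' overall and per-condition correlations and AIC. Parameter counts `k`
#' include the mixture coefficients (two-layer: 10 searched dynamics
#' parameters + 3 mixture; single layer: the count supplied via `kDynamics`
#' + 2).
#'
#' @param models named list; each element is itself a named list of
#'   [FieldTrajectory-class] objects over the same conditions.
#' @param dyes named list of [DyePattern-class] matching those conditions.
#' @param kDynamics named integer vector: dynamics-parameter count per model
#'   (defaults: `twolayer = 10`, others `7`).
#' @param twoLayerModels names in `models` to fit with both layers
#'   (default `"twolayer"`).
#' @return data.frame with one row per model: `model`, `k`, `rss`,
#'   `rOverall`, per-condition correlations, `aic`.
#' @export
compareModels <- function(models, dyes, kDynamics = NULL,
                          twoLayerModels = "twolayer") {
  condNames <- names(dyes)
  rows <- lapply(names(models), function(nm) {
    trajs <- models[[nm]]
    if (!identical(names(trajs), condNames))
      stop(sprintf("model '%s' has conditions [%s]; dye set has [%s]", nm,
                   paste(names(trajs), collapse = ","), paste(condNames, collapse = ",")))
    twoLayer <- nm %in% twoLayerModels
    if (twoLayer) {
      fit <- fitMixture(trajs, dyes)
      kMix <- 3L
    } else {
      # single regressor: collapse uI onto uE so the active-set fit sees one layer
      single <- lapply(trajs, function(t)
        new("FieldTrajectory", uE = t@uE, uI = matrix(0, nrow(t@uI), ncol(t@uI)),
            grid = t@grid, params = t@params, relaxed = t@relaxed,
            condition = t@condition))
      fit <- fitMixture(single, dyes)
      kMix <- 2L
    }
    kDyn <- if (!is.null(kDynamics) && nm %in% names(kDynamics)) kDynamics[[nm]]
            else if (twoLayer) 10L else 7L
    n <- sum(vapply(dyes, function(d) length(dyeValues(d)), numeric(1)))
    k <- kDyn + kMix
    data.frame(model = nm, k = k, rss = fit@rss, rOverall = fit@rOverall,
               t(setNames(fit@rPerCondition, paste0("r_", names(fit@rPerCondition)))),
               aic = aic(fit@rss, n, k))
  })
  do.call(rbind, rows)
}
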