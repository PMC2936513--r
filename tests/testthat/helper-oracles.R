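# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized/C++ code paths: scalar double loops and
# exhaustive scans only.

# small toy setup shared by integrator tests: gentle gains, fast relaxation
toyGrid <- function(nFrames = 10L)
  spaceTimeGrid(nPositions = 15L, nMapped = 5L, pixelPitch = 0.14,
                frameDt = 9.6, nFrames = nFrames)

toyParams <- function()
  fieldParams(gEE = 20, gIE = 10, gEI = 20, sigmaEE = 0.4, sigmaEI = 0.4)

# dense double-loop Euler integrator: direct transcription of the discretized
# field equations, no matrix products, no convolution helpers
bruteForceIntegrate <- function(params, S, grid, sub = 10L, relaxMs = 400,
                                nLead = 0L) {
  np <- grid@nPositions
  dx <- grid@pixelPitch
  dt <- grid@frameDt / sub
  xs <- positionsMm(grid)
  kern <- function(sigma) {
    K <- ceiling(6 * sigma / dx)
    offs <- (-K):K
    k <- exp(-(offs * dx)^2 / (2 * sigma^2))
    list(k = k / (sum(k) * dx), K = K)
  }
  kee <- kern(params@sigmaEE); kei <- kern(params@sigmaEI)
  convAt <- function(f, i, kk) {
    acc <- 0
    for (j in seq_len(np)) {
      d <- i - j
      if (abs(d) <= kk$K) acc <- acc + kk$k[d + kk$K + 1] * f[j] * dx
    }
    acc
  }
  fe <- function(u) 1 / (1 + exp(-params@betaE * (u - params@thetaE)))
  fi <- function(u) 1 / (1 + exp(-params@betaI * (u - params@thetaI)))
  stepOnce <- function(ue, ui, s) {
    uen <- numeric(np); uin <- numeric(np)
    feu <- vapply(ue, fe, numeric(1))
    for (i in seq_len(np)) {
      exc <- params@gEE * convAt(feu, i, kee)
      inh <- params@gIE * fi(ui[i])
      uen[i] <- ue[i] + dt / params@tauE * (-ue[i] + params@hE + exc - inh + s[i])
      uin[i] <- ui[i] + dt / params@tauI *
        (-ui[i] + params@hI + params@gEI * convAt(feu, i, kei))
    }
    list(ue = uen, ui = uin)
  }
  ue <- numeric(np); ui <- numeric(np)
  for (k in seq_len(round(relaxMs / dt))) {
    st <- stepOnce(ue, ui, numeric(np)); ue <- st$ue; ui <- st$ui
  }
  UE <- matrix(0, np, grid@nFrames); UI <- matrix(0, np, grid@nFrames)
  if (nLead == 0L) { UE[, 1] <- ue; UI[, 1] <- ui }
  for (f in seq_len(nLead + grid@nFrames - 1L)) {
    s <- S[, f]
    for (m in seq_len(sub)) { st <- stepOnce(ue, ui, s); ue <- st$ue; ui <- st$ui }
    idx <- f - nLead + 1L
    if (idx >= 1L && idx <= grid@nFrames) { UE[, idx] <- ue; UI[, idx] <- ui }
  }
  list(uE = UE, uI = UI)
}

# exhaustive constrained least-squares oracle: fine grid over (a, b) >= 0
# with the offset solved in closed form, refined around the best cell
nnlsGridOracle <- function(x, y, d, aMax = 3, bMax = 3, n = 121L, levels = 4L) {
  rssOf <- function(a, b) {
    r <- d - a * x - b * y
    r <- r - mean(r)
    sum(r^2)
  }
  lo <- c(0, 0); hi <- c(aMax, bMax)
  best <- c(0, 0)
  for (lev in seq_len(levels)) {
    as <- seq(lo[1], hi[1], length.out = n)
    bs <- seq(lo[2], hi[2], length.out = n)
    rss <- outer(as, bs, Vectorize(rssOf))
    ix <- which(rss == min(rss), arr.ind = TRUE)[1, ]
    best <- c(as[ix[1]], bs[ix[2]])
    da <- diff(as[1:2]); db <- diff(bs[1:2])
    lo <- pmax(c(best[1] - 2 * da, best[2] - 2 * db), 0)
    hi <- c(best[1] + 2 * da, best[2] + 2 * db)
  }
  cOff <- mean(d - best[1] * x - best[2] * y)
  list(a = best[1], b = best[2], c = cOff, rss = rssOf(best[1], best[2]))
}

# 2-D grid-refinement root search for the homogeneous fixed point
fixedPointBisectOracle <- function(params, lo = -120, hi = 0, tol = 1e-9) {
  fe <- function(u) 1 / (1 + exp(-params@betaE * (u - params@thetaE)))
  fi <- function(u) 1 / (1 + exp(-params@betaI * (u - params@thetaI)))
  g <- function(ue) {
    ui <- params@hI + params@gEI * fe(ue)
    -ue + params@hE + params@gEE * fe(ue) - params@gIE * fi(ui)
  }
  for (it in seq_len(200)) {
    us <- seq(lo, hi, length.out = 201)
    gs <- vapply(us, g, numeric(1))
    flip <- which(gs[-1] * gs[-201] <= 0)[1]
    if (is.na(flip)) stop("oracle found no sign change")
    lo <- us[flip]; hi <- us[flip + 1]
    if (hi - lo < tol) break
  }
  ue <- (lo + hi) / 2
  c(ue = ue, ui = params@hI + params@gEI * fe(ue))
}

# exact Mann-Whitney U and two-sided p by full enumeration (independent of
# the package's mannWhitneyExact)
enumerateU <- function(x, y) {
  u <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U <- u(x, y)
  pool <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pool), n1)
  Us <- apply(idx, 2, function(i) u(pool[i], pool[-i]))
  list(U = U, p = min(1, 2 * min(mean(Us <= U), mean(Us >= U))))
}
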