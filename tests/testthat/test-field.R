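# Field core: transfer function, kernels, Euler step, simulation, fixed point.

test_that("logistic transfer has midpoint, saturation and a known value", {
  expect_equal(transferRate(-40, 0.15, -40), 0.5)
  expect_equal(transferRate(1e4, 0.15, -40), 1)
  expect_equal(transferRate(-1e4, 0.15, -40), 0)
  expect_equal(transferRate(-20, 0.15, -40), 1 / (1 + exp(-3)))
  u <- seq(-100, 20, by = 1)
  expect_true(all(diff(transferRate(u, 0.1, -40)) > 0))
})

test_that("coupling kernel is an even unit-area Gaussian scaled by gain", {
  d <- seq(-5, 5, by = 0.37)
  expect_equal(couplingKernel(d, 1.27, 2), couplingKernel(-d, 1.27, 2))
  expect_equal(couplingKernel(0, 1.27, 1), 1 / (1.27 * sqrt(2 * pi)))
  grid <- spaceTimeGrid()
  M <- couplingMatrix(grid, 1.27, 7)
  expect_equal(sum(M[75, ]), 7, tolerance = 1e-6)  # interior row sum = gain
})

test_that("decoupled field at rest is a fixed point; off-rest decays linearly", {
  p <- fieldParams(gEE = 0, gIE = 0, gEI = 0)
  grid <- toyGrid()
  n <- grid@nPositions
  st <- fieldStep(rep(p@hE, n), rep(p@hI, n), numeric(n), p, dt = 1, grid = grid)
  expect_equal(st$uE, rep(p@hE, n))
  expect_equal(st$uI, rep(p@hI, n))
  st2 <- fieldStep(rep(p@hE + 10, n), rep(p@hI, n), numeric(n), p, dt = 1,
                   grid = grid)
  expect_equal(st2$uE, rep(p@hE + 10 * (1 - 1 / p@tauE), n))
})

test_that("one Euler step matches a hand-rolled double-loop evaluation", {
  grid <- spaceTimeGrid(nPositions = 5L, nMapped = 5L, nFrames = 2L)
  p <- toyParams()
  set.seed(4)
  ue <- rnorm(5, -60, 5); ui <- rnorm(5, -58, 5); s <- runif(5, 0, 10)
  got <- fieldStep(ue, ui, s, p, dt = 1, grid = grid)
  # scalar double loop
  dx <- grid@pixelPitch
  kern <- function(sigma) {
    K <- ceiling(6 * sigma / dx); off <- (-K):K
    k <- exp(-(off * dx)^2 / (2 * sigma^2)); list(k = k / (sum(k) * dx), K = K)
  }
  kee <- kern(p@sigmaEE); kei <- kern(p@sigmaEI)
  fe <- 1 / (1 + exp(-p@betaE * (ue - p@thetaE)))
  fi <- 1 / (1 + exp(-p@betaI * (ui - p@thetaI)))
  for (i in 1:5) {
    ce <- 0; ci <- 0
    for (j in 1:5) {
      d <- i - j
      if (abs(d) <= kee$K) ce <- ce + kee$k[d + kee$K + 1] * fe[j] * dx
      if (abs(d) <= kei$K) ci <- ci + kei$k[d + kei$K + 1] * fe[j] * dx
    }
    expUe <- ue[i] + 1 / p@tauE * (-ue[i] + p@hE + p@gEE * ce - p@gIE * fi[i] + s[i])
    expUi <- ui[i] + 1 / p@tauI * (-ui[i] + p@hI + p@gEI * ci)
    expect_equal(got$uE[i], expUe, tolerance = 1e-13)
    expect_equal(got$uI[i], expUi, tolerance = 1e-13)
  }
})

test_that("simulated trajectory matches the brute-force dense integrator", {
  grid <- toyGrid()
  p <- toyParams()
  S <- matrix(0, grid@nPositions, grid@nFrames - 1)
  S[7:9, 2:5] <- 8
  inp <- new("InputField", values = S, grid = grid, delayFrames = 0L,
             leadFrames = 0L)
  got <- simulateField(p, inp, grid, relaxMs = 400)
  want <- bruteForceIntegrate(p, S, grid, relaxMs = 400)
  expect_lt(max(abs(uE(got) - want$uE)), 1e-10)
  expect_lt(max(abs(uI(got) - want$uI)), 1e-10)
})

test_that("zero input leaves every frame at the relaxed state", {
  grid <- toyGrid()
  p <- toyParams()
  S <- matrix(0, grid@nPositions, grid@nFrames - 1)
  inp <- new("InputField", values = S, grid = grid, delayFrames = 0L,
             leadFrames = 0L)
  tr <- simulateField(p, inp, grid, relaxMs = 1000)
  expect_lt(max(abs(uE(tr) - uE(tr)[, 1])), 1e-6)
})

test_that("a long zero-input run settles onto the algebraic fixed point", {
  # well-buffered grid: the interior matches the homogeneous solution
  grid <- spaceTimeGrid(nFrames = 2L)
  p <- fieldParams()
  S <- matrix(0, grid@nPositions, 1)
  inp <- new("InputField", values = S, grid = grid, delayFrames = 0L,
             leadFrames = 0L)
  tr <- simulateField(p, inp, grid, relaxMs = 2500)
  fp <- homogeneousFixedPoint(p)
  expect_lt(abs(uE(tr)[75, 1] - fp@ueBar), 1e-3)
  expect_lt(abs(uI(tr)[75, 1] - fp@uiBar), 1e-3)
})

test_that("fixed point: decoupled case exact, coupled case matches bisection oracle", {
  p0 <- fieldParams(gEE = 0, gIE = 0, gEI = 0, hE = -55, hI = -72)
  fp0 <- homogeneousFixedPoint(p0)
  expect_equal(fp0@ueBar, -55)
  expect_equal(fp0@uiBar, -72)
  p <- fieldParams()
  fp <- homogeneousFixedPoint(p)
  oracle <- fixedPointBisectOracle(p)
  expect_lt(abs(fp@ueBar - oracle[["ue"]]), 1e-8)
  expect_lt(abs(fp@uiBar - oracle[["ui"]]), 1e-8)
  expect_lt(fp@residual, 1e-9)
})

test_that("fixed-point and zero initializations agree after relaxation", {
  grid <- spaceTimeGrid()
  p <- fieldParams()
  inp <- stimulusDrive(stimulusProtocol("flashed_square"), grid, p)
  a <- simulateField(p, inp, grid, init = "zero", relaxMs = 2000)
  b <- simulateField(p, inp, grid, init = "fixedpoint")
  expect_lt(max(abs(uE(a) - uE(b))), 1e-3)
})

test_that("the integrator converges at first order in the time step", {
  # the post-stimulus collapse of the saturated state makes raw frame values
  # dt-stiff, so convergence is assessed by the error-halving signature and
  # by the stability of the derived quantities rather than a tiny frame-wise
  # tolerance
  grid <- spaceTimeGrid()
  p <- fieldParams()
  inp <- stimulusDrive(stimulusProtocol("flashed_square"), grid, p)
  a <- simulateField(p, inp, grid, sub = 10L, init = "fixedpoint")
  b <- simulateField(p, inp, grid, sub = 20L, init = "fixedpoint")
  c_ <- simulateField(p, inp, grid, sub = 40L, init = "fixedpoint")
  e1 <- max(abs(uE(a) - uE(b)))
  e2 <- max(abs(uE(b) - uE(c_)))
  expect_gt(e1 / e2, 1.5)   # ~2 for first-order Euler
  expect_lt(e1 / e2, 3)
  expect_lt(abs(layerCorrelation(a) - layerCorrelation(c_)), 0.02)
})

test_that("interior response is equivariant under input translation", {
  grid <- spaceTimeGrid()
  p <- fieldParams()
  base <- stimulusProtocol("flashed_square", anchorPosition = 2.25)
  shft <- stimulusProtocol("flashed_square", anchorPosition = 2.25 + 4 * 0.14)
  a <- uE(simulateCondition(p, base, grid, init = "fixedpoint"))
  b <- uE(simulateCondition(p, shft, grid, init = "fixedpoint"))
  # tolerance reflects residual boundary contamination: the response skirt
  # plus the kernel reach approaches the buffer edge at ~1e-2 mV level
  expect_lt(max(abs(b[40:120, ] - a[36:116, ])), 0.02)
})

test_that("stronger local inhibition never raises excitatory activity", {
  grid <- toyGrid()
  p1 <- toyParams()
  p2 <- fieldParams(gEE = 20, gIE = 14, gEI = 20, sigmaEE = 0.4, sigmaEI = 0.4)
  S <- matrix(0, grid@nPositions, grid@nFrames - 1); S[6:10, 2:6] <- 10
  inp <- new("InputField", values = S, grid = grid, delayFrames = 0L,
             leadFrames = 0L)
  a <- simulateField(p1, inp, grid, relaxMs = 600)
  b <- simulateField(p2, inp, grid, relaxMs = 600)
  expect_true(all(uE(b) <= uE(a) + 1e-9))
})

test_that("relaxation failure is reported with the drift magnitude", {
  grid <- toyGrid()
  p <- fieldParams()  # reference set needs ~1.3 s to relax from zero
  S <- matrix(0, grid@nPositions, grid@nFrames - 1)
  inp <- new("InputField", values = S, grid = grid, delayFrames = 0L,
             leadFrames = 0L)
  expect_error(simulateField(p, inp, grid, relaxMs = 100), "drift")
})
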