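# Synthetic VSD generator and preprocessing chain.

# shared gentle setup: toy-sized stacks keep the file fast
quickCfg <- function(seed, ...) {
  over <- list(...)
  do.call(synthConfig, modifyList(list(seed = seed, nTrials = 4L,
                                       nBlank = 4L), over))
}

test_that("a noiseless single-trial recording reduces to the forward model", {
  grid <- spaceTimeGrid()
  p <- fieldParams()
  traj <- simulateCondition(p, stimulusProtocol("flashed_square"), grid,
                            init = "fixedpoint")
  cfg <- synthConfig(seed = 3, noiseSd = 0, heartbeatAmp = 0,
                     respirationAmp = 0, nTrials = 1, nBlank = 1)
  rec <- generateRecording(cfg, stimulusProtocol("flashed_square"), grid,
                           traj = traj)
  dp <- preprocessRecording(rec$trials, rec$blanks, grid, nPre = cfg$nPre)
  # the lateral averaging attenuates by the mean Gaussian cross-section
  prof <- exp(-((1:24 - cfg$xCenter)^2) / (2 * cfg$xSd^2))
  atten <- mean(prof[4:20])
  expect_lt(max(abs(dyeValues(dp) - atten * rec$groundTruth$dye1d)), 1e-10)
})

test_that("generation is bit-identical under a fixed seed", {
  grid <- spaceTimeGrid()
  p <- fieldParams()
  traj <- simulateCondition(p, stimulusProtocol("flashed_square"), grid,
                            init = "fixedpoint")
  r1 <- generateRecording(quickCfg(17), stimulusProtocol("flashed_square"),
                          grid, traj = traj)
  r2 <- generateRecording(quickCfg(17), stimulusProtocol("flashed_square"),
                          grid, traj = traj)
  expect_identical(r1$trials, r2$trials)
  expect_identical(r1$blanks, r2$blanks)
  r3 <- generateRecording(quickCfg(18), stimulusProtocol("flashed_square"),
                          grid, traj = traj)
  expect_false(identical(r1$trials[[1]], r3$trials[[1]]))
})

test_that("stimulus trials identical to blanks preprocess to zero", {
  grid <- spaceTimeGrid(nFrames = 10L)
  nTot <- 21 + 10
  set.seed(1)
  stacks <- lapply(1:3, function(i) array(1 + 0.01 * sin(seq_len(nTot) / 3),
                                          c(24, 50, nTot))[, , , drop = FALSE])
  dim3 <- function(x) array(rep(x, each = 24 * 50), c(24, 50, nTot))
  st <- dim3(1 + 0.01 * sin(seq_len(nTot) / 3))
  dp <- preprocessRecording(list(st, st), list(st, st), grid, nPre = 21)
  expect_lt(max(abs(dyeValues(dp))), 1e-12)
})

test_that("a constant-in-time stack is nulled by DC normalization", {
  grid <- spaceTimeGrid(nFrames = 8L)
  st <- array(rep(runif(24 * 50, 0.5, 2), 21 + 8), c(24, 50, 21 + 8))
  dp <- preprocessRecording(list(st), list(st), grid, nPre = 21)
  expect_lt(max(abs(dyeValues(dp))), 1e-12)
})

test_that("zero DC or zero blank average raise errors", {
  grid <- spaceTimeGrid(nFrames = 4L)
  st <- array(1, c(24, 50, 25))
  bad <- st; bad[1, 1, 1:21] <- 0
  expect_error(preprocessRecording(list(bad), list(st), grid, nPre = 21),
               "zero DC")
})

test_that("trial-averaged noise scales as 1/sqrt(n)", {
  grid <- spaceTimeGrid()
  p <- fieldParams()
  traj <- simulateCondition(p, stimulusProtocol("flashed_square"), grid,
                            init = "fixedpoint")
  resSd <- vapply(c(1, 4, 24), function(nt) {
    cfg <- synthConfig(seed = 100 + nt, nTrials = nt, nBlank = 24,
                       heartbeatAmp = 0, respirationAmp = 0)
    rec <- generateRecording(cfg, stimulusProtocol("flashed_square"), grid,
                             traj = traj)
    dp <- preprocessRecording(rec$trials, rec$blanks, grid, nPre = cfg$nPre)
    prof <- exp(-((1:24 - cfg$xCenter)^2) / (2 * cfg$xSd^2))
    resid <- dyeValues(dp) - mean(prof[4:20]) * rec$groundTruth$dye1d
    sd(resid)
  }, numeric(1))
  # blank-average noise adds a common floor; ratios still track 1/sqrt(n)
  expect_equal(resSd[1] / resSd[2], 2, tolerance = 0.25)
  expect_equal(resSd[2] / resSd[3], sqrt(6), tolerance = 0.35)
})

test_that("phase-locked artifacts are largely removed by the blank division", {
  grid <- spaceTimeGrid()
  p <- fieldParams()
  traj <- simulateCondition(p, stimulusProtocol("flashed_square"), grid,
                            init = "fixedpoint")
  # artifact-only recording (no white noise, no signal scaling issue)
  cfg <- synthConfig(seed = 55, noiseSd = 0, a = 0, b = 0)
  rec <- generateRecording(cfg, stimulusProtocol("flashed_square"), grid,
                           traj = traj)
  dp <- preprocessRecording(rec$trials, rec$blanks, grid, nPre = cfg$nPre)
  residPower <- mean(dyeValues(dp)^2)
  # injected artifact power: one raw trial, x-averaged, DC-normalized,
  # without blank division
  one <- rec$trials[[1]]
  dc <- apply(one[, , 1:21, drop = FALSE], c(1, 2), mean)
  oneN <- sweep(one, c(1, 2), dc, "/")
  oneD <- apply(oneN[4:20, , , drop = FALSE], c(2, 3), mean)
  injected <- mean((oneD[, 22:dim(oneD)[2]] - 1)^2)
  expect_lt(residPower, 0.05 * injected)
})

test_that("the end-to-end pipeline recovers the generating kappa", {
  grid <- spaceTimeGrid()
  p <- fieldParams()
  prot <- defaultProtocols()[c("square", "lm")]
  trajs <- simulateConditions(p, prot, grid, init = "fixedpoint")
  dps <- lapply(names(prot), function(nm) {
    cfg <- synthConfig(seed = 600 + match(nm, names(prot)))
    rec <- generateRecording(cfg, prot[[nm]], grid, traj = trajs[[nm]])
    preprocessRecording(rec$trials, rec$blanks, grid, nPre = cfg$nPre,
                        condition = nm)
  })
  names(dps) <- names(prot)
  fit <- fitMixture(trajs, dps)
  expect_lt(abs(fit@kappa - 0.54), 0.05)
  expect_gt(fit@rOverall, 0.9)
})

test_that("fixture suite is deterministic and self-consistent", {
  f1 <- makeFixtureSuite(3)
  f2 <- makeFixtureSuite(3)
  expect_identical(f1$noisePattern, f2$noisePattern)
  expect_identical(f1$front, f2$front)
  # stored fixed point satisfies the field equations
  p <- f1$toyParams
  fe <- transferRate(f1$toyFixedPoint@ueBar, p@betaE, p@thetaE)
  fi <- transferRate(f1$toyFixedPoint@uiBar, p@betaI, p@thetaI)
  expect_equal(f1$toyFixedPoint@ueBar, p@hE + p@gEE * fe - p@gIE * fi,
               tolerance = 1e-8)
  expect_equal(f1$toyFixedPoint@uiBar, p@hI + p@gEI * fe, tolerance = 1e-8)
})
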