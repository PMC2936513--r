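# Identification: AIC, objective, CMA-ES, grid search.

test_that("AIC formula, degenerate inputs and nesting penalty", {
  expect_equal(aic(5000, 5000, 13), 26)              # unit mean square -> 2k
  expect_equal(aic(5000 * exp(1), 5000, 13), 5026)   # n ln(e) + 2k
  expect_error(aic(0, 100, 3), "rss")
  expect_error(aic(10, 3, 5), "n must exceed")
  expect_equal(aic(42, 1000, 6) - aic(42, 1000, 5), 2)
})

test_that("objective is -1 at perfect fit and responds to the penalty", {
  grid <- spaceTimeGrid()
  p <- fieldParams()
  prot <- defaultProtocols()[c("square", "bar")]
  trajs <- simulateConditions(p, prot, grid, init = "fixedpoint")
  dyes <- lapply(trajs, aggregateSignal, a = 0.46, b = 0.54, c = 0)
  ob0 <- identificationObjective(p, prot, dyes, grid, tradeoff = 0)
  expect_equal(ob0$value, -1, tolerance = 1e-9)
  expect_equal(unname(ob0$rPerCondition), c(1, 1), tolerance = 1e-9)
  obP <- identificationObjective(p, prot, dyes, grid, tradeoff = 2,
                                 kappaTarget = 0.5)
  expect_equal(obP$value, -1 + 2 * (obP$kappa - 0.5)^2, tolerance = 1e-9)
  # perturbing the parameters can only worsen (raise) the pure-correlation term
  pBad <- fieldParams(gEE = 160)
  obBad <- identificationObjective(pBad, prot, dyes, grid, tradeoff = 0)
  expect_gt(obBad$value, ob0$value)
})

test_that("simulation failure yields an infinite objective, not an error", {
  grid <- spaceTimeGrid()
  prot <- defaultProtocols()["square"]
  dyes <- list(square = matrix(0, grid@nMapped, grid@nFrames))
  ob <- identificationObjective(fieldParams(gEE = 1250), prot, dyes, grid)
  expect_identical(ob$value, Inf)
})

test_that("CMA-ES solves a 7-D sphere to 1e-6 within 2000 evaluations", {
  ctr <- c(2, -3, 1.5, 4, -1, 0.5, 2.5)
  res <- cmaES(function(x) sum((x - ctr)^2), start = ctr * 1.3, seed = 7,
               maxEvals = 2000)
  expect_lt(sqrt(res$value), 1e-6)
  expect_lte(res$evals, 2008)
  # best-so-far trace is monotone non-increasing
  expect_true(all(diff(res$trace$bestEver) <= 0))
})

test_that("CMA-ES runs are bit-identical under a fixed seed", {
  fn <- function(x) sum((x - c(1, 2, 3))^2) + 0.1 * sum(abs(x))
  r1 <- cmaES(fn, start = c(2, 1, 4), seed = 99, maxEvals = 300)
  r2 <- cmaES(fn, start = c(2, 1, 4), seed = 99, maxEvals = 300)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$trace, r2$trace)
})

test_that("grid search: the generating configuration survives all criteria", {
  grid <- spaceTimeGrid()
  p <- fieldParams()
  prot <- defaultProtocols()[c("square", "bar")]
  trajs <- simulateConditions(p, prot, grid, init = "fixedpoint")
  mix <- defaultMixture()
  dyes <- lapply(names(trajs), function(nm)
    dyePattern(aggregateSignal(trajs[[nm]], mix$a, mix$b), grid, nm))
  names(dyes) <- names(trajs)
  gs <- gridSpec(tauE = 19.2, tauI = 28.8, h = -60, gEE = 125, gIE = 50,
                 gEI = 125, sigmaEE = 1.27, sigmaEI = 1.27, betaE = 0.15,
                 betaI = 0.1)
  rep1 <- runGridSearch(gs, prot, dyes, grid)
  expect_equal(nrow(rep1), 1L)
  expect_true(rep1$stable && rep1$decays && rep1$rPass && rep1$slopePass)
  expect_true(rep1$survives)
  expect_gt(rep1$r, 0.999)
})

test_that("grid search: inflated recurrent gain fails the stability criterion", {
  grid <- spaceTimeGrid()
  prot <- defaultProtocols()["square"]
  dyes <- list(square = dyePattern(matrix(0, grid@nMapped, grid@nFrames),
                                   grid, "square"))
  gs <- gridSpec(tauE = 19.2, tauI = 28.8, h = -60, gEE = 1250, gIE = 50,
                 gEI = 125, sigmaEE = 1.27, sigmaEI = 1.27, betaE = 0.15,
                 betaI = 0.1)
  rep1 <- runGridSearch(gs, prot, dyes, grid)
  expect_false(rep1$stable)
  expect_false(rep1$survives)
})

test_that("empty grids and budget truncation are handled", {
  grid <- spaceTimeGrid()
  prot <- defaultProtocols()["square"]
  dyes <- list(square = dyePattern(matrix(0, grid@nMapped, grid@nFrames),
                                   grid, "square"))
  gs <- gridSpec(tauE = 19.2, tauI = 28.8, h = -60, gEE = 125, gIE = 50,
                 gEI = 125, sigmaEE = 1.27, sigmaEI = 1.27, betaE = 0.15,
                 betaI = 0.1)
  rep0 <- runGridSearch(gs, prot, dyes, grid, budget = 0)
  expect_equal(nrow(rep0), 0L)
  gs2 <- gs; gs2$values$betaE <- c(0.1, 0.15); gs2$size <- 2L
  repB <- runGridSearch(gs2, prot, dyes, grid, budget = 1)
  expect_equal(nrow(repB), 1L)
  expect_false(attr(repB, "complete"))
})

test_that("the generating grid point attains the best correlation on its grid", {
  grid <- spaceTimeGrid()
  p <- fieldParams()
  prot <- defaultProtocols()[c("square", "bar")]
  trajs <- simulateConditions(p, prot, grid, init = "fixedpoint")
  mix <- defaultMixture()
  dyes <- lapply(names(trajs), function(nm)
    dyePattern(aggregateSignal(trajs[[nm]], mix$a, mix$b), grid, nm))
  names(dyes) <- names(trajs)
  # 4 configurations: gEE x betaI around the generating values
  gs <- gridSpec(tauE = 19.2, tauI = 28.8, h = -60, gEE = c(125, 200),
                 gIE = 50, gEI = 125, sigmaEE = 1.27, sigmaEI = 1.27,
                 betaE = 0.15, betaI = c(0.1, 0.05))
  rep4 <- runGridSearch(gs, prot, dyes, grid)
  truth <- which(rep4$r > 0.9999)
  expect_equal(length(truth), 1L)
  expect_equal(rep4$r[truth], max(rep4$r, na.rm = TRUE))
})
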