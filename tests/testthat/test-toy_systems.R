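# Analytic landscapes, bead-chain construction and the Langevin sampler.

test_that("double well has the constructed barrier and minima", {
  dw <- makeDoubleWell(10, 2)
  U <- landscapeEnergy(dw, matrix(c(-1, 0, 1)))$energy
  expect_equal(U[2] - U[1], 10)
  expect_equal(U[1], 0)
  expect_equal(U[3], 0)
  g <- landscapeEnergy(dw, matrix(c(-1, 1)))$gradient
  expect_equal(as.numeric(g), c(0, 0))
  expect_error(makeDoubleWell(-1, 2), "positive")
  expect_error(makeDoubleWell(10, 0), "positive")
})

test_that("analytic FES is the shifted potential with min exactly 0", {
  dw <- makeDoubleWell(10, 2)
  fes <- analyticFES(dw, 401)
  expect_equal(min(fesValues(fes)), 0)
  axis <- fesAxes(fes)[[1]]
  expect_equal(fesValues(fes)[which.min(abs(axis))], 10, tolerance = 1e-3)
  expect_equal(fesValues(fes)[which.min(abs(axis - 1))], 0, tolerance = 1e-3)

  gm <- makeGaussianMixture(matrix(0.5), matrix(0.3), 4)
  fes1 <- analyticFES(gm, 201)
  expect_equal(fesAxes(fes1)[[1]][which.min(fesValues(fes1))], 0.5,
               tolerance = 1e-2)
  expect_error(analyticFES(dw, axes = list(seq(-10, 10, 0.1))), "outside")
})

test_that("grid refinement changes the FES only by interpolation error", {
  dw <- makeDoubleWell(8, 2)
  coarse <- analyticFES(dw, 101)
  fine <- analyticFES(dw, 201)
  interp <- approx(fesAxes(fine)[[1]], fesValues(fine),
                   xout = fesAxes(coarse)[[1]])$y
  # bounded by the h^2 curvature term of linear interpolation at 101 bins
  expect_lt(max(abs(interp - fesValues(coarse))), 5e-3)
})

test_that("bead chains carry the sequence charge table", {
  un <- buildBeadChain(sac6LoopSegment(FALSE))
  ph <- buildBeadChain(sac6LoopSegment(TRUE))
  expect_equal(un@charges[5], 0)
  expect_equal(ph@charges[5], -2)
  kIdx <- which(residues(sac6LoopSegment()) == "K")
  expect_equal(un@charges[kIdx], rep(1, 3))
  # identical apart from the phospho bead
  expect_equal(un@charges[-5], ph@charges[-5])
  expect_equal(un@masses, ph@masses)

  pg <- buildBeadChain(parsePeptide("GGGGG", 1))
  expect_equal(pg@charges, rep(0, 5))
  lin <- linearConformation(pg)
  expect_equal(dim(lin), c(5L, 3L))
  expect_equal(diff(lin[, 1]), rep(pg@bondLength, 4))
  expect_equal(lin[, 2], rep(0, 5))
})

test_that("identical seeds give bit-identical runs", {
  dw <- makeDoubleWell(5, 2)
  cfg <- simulationConfig(nSteps = 5000L, timestep = 0.01, saveStride = 50L,
                          seed = 99L)
  a <- langevinSample(dw, cfg)
  b <- langevinSample(dw, cfg)
  expect_identical(cvValues(a$cv), cvValues(b$cv))
  expect_identical(coords(a$trajectory), coords(b$trajectory))

  ch <- buildBeadChain(parsePeptide("GKGDG", 1))
  ccfg <- simulationConfig(nSteps = 2000L, saveStride = 100L, seed = 5L)
  r1 <- langevinSample(ch, ccfg)
  r2 <- langevinSample(ch, ccfg)
  expect_identical(coords(r1$trajectory), coords(r2$trajectory))
})

test_that("trajectory frame count and spacing follow the config", {
  dw <- makeDoubleWell(5, 2)
  cfg <- simulationConfig(nSteps = 1000L, timestep = 0.01, saveStride = 100L,
                          seed = 1L)
  r <- langevinSample(dw, cfg)
  expect_equal(nFrames(r$trajectory), 1000L %/% 100L + 1L)
  expect_equal(unique(round(diff(frameTimes(r$trajectory)), 10)), 1)
})

test_that("unstable integration aborts with a blow-up diagnostic", {
  ch <- buildBeadChain(parsePeptide("GGGGG", 1))
  cfg <- simulationConfig(nSteps = 5000L, timestep = 5, saveStride = 100L,
                          seed = 1L)  # far beyond the bond stability bound
  expect_error(langevinSample(ch, cfg), "blow-up")
})

test_that("harmonic sampling satisfies equipartition", {
  k <- 50
  hl <- makeHarmonic(k)
  cfg <- simulationConfig(nSteps = 200000L, timestep = 0.01,
                          saveStride = 10L, seed = 3L)
  r <- langevinSample(hl, cfg)
  v <- var(cvValues(r$cv)[, 1])
  expect_equal(v, boltzmannkB() * 298 / k, tolerance = 0.05)
})

test_that("zero temperature traps the particle in its starting basin", {
  dw <- makeDoubleWell(10, 2)
  cfg <- simulationConfig(temperature = 0, nSteps = 20000L, timestep = 0.01,
                          saveStride = 100L, seed = 1L)
  r <- langevinSample(dw, cfg, start = -1.2)
  expect_true(all(cvValues(r$cv)[, 1] < 0))
})

test_that("unbiased sampling reproduces the Boltzmann density", {
  dw <- makeDoubleWell(2.5, 2)   # low barrier so both wells are visited
  cfg <- simulationConfig(nSteps = 400000L, timestep = 0.01,
                          saveStride = 4L, seed = 17L)
  r <- langevinSample(dw, cfg)
  x <- cvValues(r$cv)[, 1]
  breaks <- seq(-2.2, 2.2, length.out = 45)
  emp <- hist(x, breaks = breaks, plot = FALSE)$density
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  U <- landscapeEnergy(dw, matrix(mid))$energy
  beta <- 1 / (boltzmannkB() * 298)
  ana <- exp(-beta * U)
  ana <- ana / sum(ana * diff(breaks))
  # total variation distance between sampled and analytic density
  expect_lt(0.5 * sum(abs(emp - ana) * diff(breaks)), 0.05)
})

test_that("ground-truth records: empty schedule gives uniform weights", {
  dw <- makeDoubleWell(5, 2)
  empty <- biasState("cv1")
  fix <- synthBiasRecords(dw, empty, times = 1:50, seed = 2)
  expect_equal(frameWeights(fix$weights), rep(1 / 50, 50))
})

test_that("ground-truth records: static bias weights follow exp(+beta V)", {
  dw <- makeDoubleWell(5, 2)
  sch <- biasState("cv1", wellTempered = FALSE, baseHeight = 3, sigma = 0.4)
  sch <- depositHill(sch, -1, 0)
  fix <- synthBiasRecords(dw, sch, times = seq(1, 20, length.out = 200),
                          seed = 3)
  s <- cvValues(fix$cv)[, 1]
  beta <- 1 / (boltzmannkB() * 298)
  direct <- exp(beta * biasEnergy(sch, matrix(s, ncol = 1)))
  direct <- direct / sum(direct)
  expect_equal(frameWeights(fix$weights), direct, tolerance = 1e-9)
})

test_that("three-state fixture occupancies hit their targets at n = 1e5", {
  fx <- threeStateFixture(n = 1e5, seed = 4)
  occ <- tabulate(fx$states, 3) / 1e5
  expect_true(all(abs(occ - fx$probs) < 0.01))
})
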