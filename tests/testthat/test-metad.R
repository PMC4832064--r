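# Metadynamics engine: bias evaluation, deposition rules, FES
# reconstruction, convergence diagnostics and HILLS I/O.

test_that("bias energy matches limits and a direct summation oracle", {
  st <- biasState(c("a", "b"), wellTempered = FALSE, sigma = c(0.2, 0.3))
  expect_equal(biasEnergy(st, c(0, 0)), 0)
  st1 <- depositHill(st, c(1, 2), 0)
  expect_equal(biasEnergy(st1, c(1, 2)), st1@baseHeight)
  set.seed(5)
  st2 <- st
  for (k in 1:100)
    st2 <- depositHill(st2, rnorm(2), k)
  pts <- matrix(rnorm(40), ncol = 2)
  direct <- apply(pts, 1, function(s) bruteBiasEnergy(st2, s))
  expect_equal(biasEnergy(st2, pts), direct, tolerance = 1e-10)
  expect_error(biasEnergy(st2, c(1, 2, 3)), "dimension mismatch")
})

test_that("bias energy is non-decreasing in time at fixed points", {
  set.seed(6)
  st <- biasState("cv1", wellTempered = FALSE)
  for (k in 1:30) st <- depositHill(st, rnorm(1), k)
  s <- matrix(seq(-2, 2, length.out = 11))
  prev <- rep(0, 11)
  for (t in seq(0, 30, by = 3)) {
    cur <- biasEnergy(st, s, t)
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("analytic bias gradient agrees with finite differences", {
  set.seed(8)
  st <- biasState(c("a", "b"), wellTempered = FALSE, sigma = c(0.3, 0.5))
  for (k in 1:20) st <- depositHill(st, rnorm(2), k)
  s <- c(0.3, -0.2)
  g <- biasGradient(st, s)
  h <- 1e-6
  for (d in 1:2) {
    e <- c(0, 0); e[d] <- h
    fd <- (biasEnergy(st, s + e) - biasEnergy(st, s - e)) / (2 * h)
    expect_equal(g[1, d], fd, tolerance = 1e-5)
  }
})

test_that("well-tempered deposition follows the height decay rule", {
  st <- biasState("cv1", wellTempered = TRUE, biasFactor = 10,
                  baseHeight = 1.0, sigma = 0.1)
  st <- depositHill(st, 0.5, 0)
  expect_equal(st@heights[1], 1.0)  # V = 0 at the first deposition
  st <- depositHill(st, 0.5, 1)
  expected <- exp(-1.0 / (boltzmannkB() * 9 * 298))
  expect_equal(st@heights[2], expected, tolerance = 1e-12)
  # heights at a revisited point never increase
  for (k in 2:10) st <- depositHill(st, 0.5, k)
  expect_true(all(diff(st@heights) <= 1e-14))

  std <- biasState("cv1", wellTempered = FALSE, baseHeight = 0.7)
  for (k in 0:5) std <- depositHill(std, 0.5, k)
  expect_equal(std@heights, rep(0.7, 6))
})

test_that("metadynamics runs are seed-deterministic and escape both basins", {
  dw <- makeDoubleWell(10, 2)
  bias <- biasState("cv1", wellTempered = FALSE, baseHeight = 0.3,
                    sigma = 0.1, depositionStride = 500L)
  cfg0 <- simulationConfig(nSteps = 0L, timestep = 0.01, saveStride = 1L,
                           seed = 1L)
  r0 <- runMetadynamics(dw, cfg0, bias)
  expect_equal(nHills(r0$bias), 0L)

  cfg <- simulationConfig(nSteps = 400000L, timestep = 0.01,
                          saveStride = 200L, seed = 13L)
  a <- runMetadynamics(dw, cfg, bias)
  b <- runMetadynamics(dw, cfg, bias)
  expect_identical(hills(a$bias), hills(b$bias))
  x <- cvValues(a$cv)[, 1]
  expect_gt(mean(x > 0.5), 0.05)
  expect_gt(mean(x < -0.5), 0.05)
})

test_that("FES reconstruction inverts the bias with min exactly 0", {
  st <- biasState("cv1", wellTempered = FALSE, baseHeight = 2.5, sigma = 0.2)
  st <- depositHill(st, 0, 0)
  fes <- reconstructFES(st, grid = list(seq(-3, 3, length.out = 301)))
  expect_equal(min(fesValues(fes)), 0)
  expect_equal(max(fesValues(fes)) - min(fesValues(fes)), 2.5,
               tolerance = 1e-4)
  # far field maps to the maximum, hill center to the minimum
  axis <- fesAxes(fes)[[1]]
  expect_equal(which.min(fesValues(fes)), which.min(abs(axis)))
  expect_error(reconstructFES(biasState("cv1")), "empty hill list")
})

test_that("the well-tempered scale factor reduces to standard as gamma grows", {
  set.seed(9)
  centers <- rnorm(20)
  mk <- function(wt, gamma) {
    st <- biasState("cv1", wellTempered = wt, biasFactor = gamma,
                    baseHeight = 1, sigma = 0.3)
    st@centers <- matrix(centers)
    st@widths <- matrix(rep(0.3, 20))
    st@heights <- rep(1, 20)
    st@times <- as.numeric(1:20)
    st
  }
  grid <- list(seq(-3, 3, length.out = 101))
  fStd <- fesValues(reconstructFES(mk(FALSE, NA), grid))
  fWT <- fesValues(reconstructFES(mk(TRUE, 1e9), grid))
  expect_equal(fWT, fStd, tolerance = 1e-6)
  fWT10 <- fesValues(reconstructFES(mk(TRUE, 10), grid))
  expect_equal(fWT10, fStd * (10 / 9), tolerance = 1e-9)
})

test_that("standard 1D metadynamics recovers the double-well barrier", {
  dw <- makeDoubleWell(10, 2)
  bias <- biasState("cv1", wellTempered = FALSE, baseHeight = 0.3,
                    sigma = 0.1, depositionStride = 500L)
  cfg <- simulationConfig(nSteps = 2e6, timestep = 0.01, saveStride = 1000L,
                          seed = 7L)
  run <- runMetadynamics(dw, cfg, bias)
  grid <- list(seq(-2, 2, length.out = 201))
  barrier <- barrierEstimate(run$bias, grid, at = 0, fraction = 0.2)
  expect_equal(barrier, 10, tolerance = 0.25)  # 1 kBT ~ 2.5 kJ/mol
})

test_that("block convergence flags diverse hills and settles for repeats", {
  rep10 <- biasState("cv1", wellTempered = FALSE, baseHeight = 1, sigma = 0.3)
  for (k in 1:10) rep10 <- depositHill(rep10, 0.2, k)
  grid <- list(seq(-2, 2, length.out = 101))
  devRep <- blockConvergence(rep10, grid, nBlocks = 5, mask = 50)
  expect_true(all(diff(devRep) <= 1e-9))  # identical increments per block

  spread <- biasState("cv1", wellTempered = FALSE, baseHeight = 2, sigma = 0.1)
  spread <- depositHill(spread, -1.5, 1)
  spread <- depositHill(spread, 0, 2)
  spread <- depositHill(spread, 1.5, 3)
  devSpread <- blockConvergence(spread, grid, nBlocks = 3, mask = 50)
  expect_true(all(devSpread > 1))
  expect_error(blockConvergence(spread, grid, nBlocks = 5), "fewer hills")
})

test_that("a converged run shows small late-block FES deviations", {
  dw <- makeDoubleWell(5, 2)
  bias <- biasState("cv1", wellTempered = TRUE, biasFactor = 10,
                    baseHeight = 0.5, sigma = 0.1, depositionStride = 250L)
  cfg <- simulationConfig(nSteps = 1e6, timestep = 0.01, saveStride = 1000L,
                          seed = 21L)
  run <- runMetadynamics(dw, cfg, bias)
  dev <- blockConvergence(run$bias, list(seq(-2, 2, length.out = 101)),
                          nBlocks = 5, mask = 10)
  expect_lt(dev[length(dev)], 2.5)  # within ~1 kBT late in the run
})

test_that("HILLS files round-trip and support hand-written input", {
  set.seed(10)
  st <- biasState(c("rg", "contact_number"), wellTempered = TRUE,
                  biasFactor = 10, baseHeight = 1, sigma = c(0.05, 0.5))
  for (k in 1:50) st <- depositHill(st, c(runif(1, 0.5, 2), runif(1, 0, 30)), k)
  tmp <- withr::local_tempfile()
  writeHills(st, tmp)
  back <- readHills(tmp)
  expect_equal(back@cvNames, st@cvNames)
  expect_true(back@wellTempered)
  expect_equal(back@biasFactor, 10)
  expect_equal(back@centers, st@centers, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back@heights, st@heights, tolerance = 1e-6)

  writeHills(biasState("cv1"), tmp)  # header only
  expect_error(readHills(tmp), "empty HILLS")

  hand <- withr::local_tempfile()
  writeLines(c("#! FIELDS time cv1 sigma_cv1 height biasf",
               "1.0 0.5 0.2 1.5 1",
               "2.0 -0.5 0.2 0.8 1"), hand)
  hs <- readHills(hand)
  manual <- 1.5 * exp(-(0.1 - 0.5)^2 / (2 * 0.2^2)) +
    0.8 * exp(-(0.1 + 0.5)^2 / (2 * 0.2^2))
  expect_equal(biasEnergy(hs, 0.1), manual, tolerance = 1e-9)
})

test_that("FES tables round-trip through the whitespace format", {
  st <- biasState(c("a", "b"), wellTempered = FALSE, sigma = c(0.3, 0.4))
  st <- depositHill(st, c(0, 1), 0)
  st <- depositHill(st, c(1, 0), 1)
  fes <- reconstructFES(st, grid = list(seq(-2, 2, length.out = 41),
                                        seq(-2, 2, length.out = 31)))
  tmp <- withr::local_tempfile()
  writeFESTable(fes, tmp)
  back <- readFESTable(tmp)
  expect_equal(fesAxes(back), fesAxes(fes), tolerance = 1e-6)
  expect_equal(fesValues(back), fesValues(fes), tolerance = 1e-5)
})
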