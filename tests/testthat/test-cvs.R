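# Collective variables: values, invariances and COLVAR I/O.

test_that("radius of gyration matches symmetry cases and the brute force", {
  two <- rbind(c(0, 0, 0), c(1.4, 0, 0))
  expect_equal(radiusOfGyration(two), 0.7)
  expect_equal(radiusOfGyration(matrix(c(3, 1, 2), 1)), 0)
  set.seed(1)
  frame <- matrix(rnorm(27 * 3), 27)
  m <- runif(27, 50, 200)
  expect_equal(radiusOfGyration(frame, masses = m, massWeighted = TRUE),
               bruteRg(frame, m), tolerance = 1e-12)
  expect_equal(radiusOfGyration(frame, massWeighted = FALSE),
               bruteRg(frame), tolerance = 1e-12)
  expect_error(radiusOfGyration(frame, integer(0)), "empty selection")
})

test_that("switching function hits its exact values and decays", {
  expect_equal(switchingValue(0, 0.65, 6, 12), 1)
  expect_equal(switchingValue(0.65, 0.65, 6, 12), 0.5)  # limit n/m
  expect_lt(switchingValue(6.5, 0.65, 6, 12), 1e-3)
  # continuity across the removable singularity
  eps <- 1e-9
  expect_equal(switchingValue(0.65 - eps, 0.65, 6, 12),
               switchingValue(0.65 + eps, 0.65, 6, 12), tolerance = 1e-8)
  # monotone non-increasing
  r <- seq(0, 3, length.out = 400)
  expect_true(all(diff(switchingValue(r, 0.65, 6, 12)) <= 1e-12))
})

test_that("contact number matches limits and the brute-force pair loop", {
  def <- cvDefinition("contact_number", 1:8,
                      switching = list(r0 = 0.65, n = 6L, m = 12L),
                      exclusion = 3L)
  far <- cbind(seq(0, 70, by = 10), 0, 0)
  expect_lt(contactNumber(far, def), 1e-3)
  collapsed <- matrix(0, 8, 3)
  nPairs <- sum(outer(1:8, 1:8, function(i, j) j - i >= 3))
  expect_equal(contactNumber(collapsed, def), nPairs)
  set.seed(2)
  frame <- matrix(rnorm(8 * 3, sd = 0.5), 8)
  expect_equal(contactNumber(frame, def),
               bruteContact(frame, 0.65, 6, 12, 3), tolerance = 1e-12)
})

test_that("stretching a terminal bead cannot increase the contact number", {
  def <- cvDefinition("contact_number", 1:6,
                      switching = list(r0 = 0.65, n = 6L, m = 12L),
                      exclusion = 2L)
  base <- cbind(seq(0, 1.5, length.out = 6), 0, 0)
  vals <- vapply(seq(0, 2, length.out = 20), function(shift) {
    f <- base
    f[6, 1] <- f[6, 1] + shift  # all pair distances to bead 6 grow
    contactNumber(f, def)
  }, 0.0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("Rg and contact number are invariant under rigid motions", {
  set.seed(3)
  frame <- matrix(rnorm(27 * 3), 27)
  def <- cvDefinition("contact_number", 1:27,
                      switching = list(r0 = 0.65, n = 6L, m = 12L),
                      exclusion = 3L)
  rg0 <- radiusOfGyration(frame)
  cn0 <- contactNumber(frame, def)
  for (rep in 1:10) {
    R <- randomRotation()
    shift <- rnorm(3, sd = 10)
    moved <- sweep(frame %*% t(R), 2, -shift)
    expect_equal(radiusOfGyration(moved), rg0, tolerance = 1e-10)
    expect_equal(contactNumber(moved, def), cn0, tolerance = 1e-10)
  }
})

test_that("CV series evaluation is frame-aligned and constant on constant input", {
  frame <- cbind(seq(0, 2.6, length.out = 14), 0, 0)
  arr <- array(rep(frame, 5), dim = c(14, 3, 5))
  traj <- new("Trajectory", times = 0:4 * 2, coords = arr,
              metadata = list())
  defs <- chainCVDefinitions(14)
  cv <- evaluateCVSeries(traj, defs)
  expect_equal(nFrames(cv), 5L)
  expect_equal(ncol(cvValues(cv)), 2L)
  expect_true(all(apply(cvValues(cv), 2, function(col)
    max(col) - min(col) == 0)))
  badDef <- chainCVDefinitions(20)
  expect_error(evaluateCVSeries(traj, badDef), "out of range")
})

test_that("COLVAR files round-trip to 6 decimals and tolerate comments", {
  set.seed(4)
  cv <- new("CVSeries", times = seq(0, 9, by = 1.5) * 2,
            values = matrix(runif(14, 0, 20), ncol = 2),
            cvNames = c("rg", "contact_number"))
  tmp <- withr::local_tempfile()
  writeColvar(cv, tmp)
  txt <- readLines(tmp)
  expect_match(txt[1], "^#! FIELDS time rg contact_number$")
  writeLines(c(txt[1], "# a stray comment", txt[-1]), tmp)
  back <- readColvar(tmp)
  expect_equal(back@cvNames, cv@cvNames)
  expect_equal(cvValues(back), cvValues(cv), tolerance = 1e-6)
  expect_equal(frameTimes(back), frameTimes(cv), tolerance = 1e-6)
})
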