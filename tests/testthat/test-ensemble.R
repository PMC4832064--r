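# Reweighting, weighted clustering, cluster thermodynamics, contact maps
# and interaction detection.

test_that("reweighting with no hills is exactly uniform", {
  cv <- new("CVSeries", times = 1:40, values = matrix(rnorm(40)),
            cvNames = "cv1")
  w <- reweightFrames(cv, biasState("cv1"),
                      analyticFES(makeDoubleWell(5, 2)))
  expect_identical(frameWeights(w), rep(1 / 40, 40))
  expect_equal(w@method, "uniform")
})

test_that("static-bias reweighting reproduces the closed form", {
  dw <- makeDoubleWell(5, 2)
  sch <- biasState("cv1", wellTempered = FALSE, baseHeight = 2, sigma = 0.3)
  sch <- depositHill(sch, -1, 0)
  sch <- depositHill(sch, -0.4, 0)
  fix <- synthBiasRecords(dw, sch, times = seq(1, 60, length.out = 400),
                          seed = 5)
  gt <- frameWeights(fix$weights)
  wTD <- reweightFrames(fix$cv, sch, analyticFES(dw, 2001))
  wStatic <- reweightFrames(fix$cv, sch, method = "static_bias")
  expect_lt(max(abs(frameWeights(wTD) - gt) / gt), 1e-6)
  expect_lt(max(abs(frameWeights(wStatic) - gt) / gt), 1e-6)
  expect_equal(sum(frameWeights(wTD)), 1)
})

test_that("time-dependent reweighting recovers the unbiased histogram", {
  dw <- makeDoubleWell(4, 2)
  sch <- biasState("cv1", wellTempered = FALSE, baseHeight = 0.8,
                   sigma = 0.25)
  set.seed(31)
  for (k in 1:12) sch <- depositHill(sch, runif(1, -1.3, 1.3), k * 5)
  times <- seq(0.5, 80, length.out = 4000)  # spans all bias epochs
  fix <- synthBiasRecords(dw, sch, times = times, seed = 6)
  w <- reweightFrames(fix$cv, sch, analyticFES(dw, 2001))
  expect_lt(max(abs(frameWeights(w) - frameWeights(fix$weights)) /
                  frameWeights(fix$weights)), 1e-6)
  # reweighted histogram vs the analytic unbiased density
  s <- cvValues(fix$cv)[, 1]
  breaks <- seq(-2.2, 2.2, length.out = 23)
  bin <- cut(s, breaks)
  emp <- tapply(frameWeights(w), bin, sum, default = 0)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  beta <- 1 / (boltzmannkB() * 298)
  ana <- exp(-beta * landscapeEnergy(dw, matrix(mid))$energy)
  ana <- ana / sum(ana)
  expect_lt(0.5 * sum(abs(emp - ana)), 0.05)
})

test_that("weights are invariant to a constant added to the bias", {
  dw <- makeDoubleWell(5, 2)
  sch <- biasState("cv1", wellTempered = FALSE, baseHeight = 1, sigma = 0.3)
  sch <- depositHill(sch, -1, 1)
  sch <- depositHill(sch, 0.5, 2)
  fix <- synthBiasRecords(dw, sch, times = seq(3, 30, length.out = 150),
                          seed = 7)
  fes <- analyticFES(dw, 1001)
  w0 <- reweightFrames(fix$cv, sch, fes)
  # a near-flat gigantic-width hill acts as a constant energy offset
  shifted <- sch
  shifted@centers <- rbind(shifted@centers, 0)
  shifted@widths <- rbind(shifted@widths, 1e6)
  shifted@heights <- c(shifted@heights, 7.3)
  shifted@times <- c(shifted@times, 2.5)
  wShift <- reweightFrames(fix$cv, shifted, fes)
  expect_equal(frameWeights(wShift), frameWeights(w0), tolerance = 1e-9)
})

test_that("degenerate clustering cases behave as constructed", {
  frames <- array(rep(matrix(rnorm(15), 5), 4), dim = c(5, 3, 4))
  traj <- new("Trajectory", times = 1:4, coords = frames, metadata = list())
  cl <- clusterConformations(traj, metric = "rmsd", cutoff = 0.1)
  expect_equal(length(populations(cl)), 1L)
  expect_equal(populations(cl), 100)

  pts <- rbind(c(0, 0), c(10, 0))
  cl2 <- clusterConformations(pts, c(0.5, 0.5), metric = "cv_space",
                              cutoff = 1)
  expect_equal(populations(cl2), c(50, 50))
  expect_equal(sort(representatives(cl2)), c(1L, 2L))
  expect_error(clusterConformations(pts, metric = "cv_space", cutoff = -1),
               "positive")
})

test_that("leader clustering equals the brute-force oracle with tie rule", {
  set.seed(12)
  for (rep in 1:5) {
    pts <- matrix(rnorm(60 * 2, sd = 1.2), 60)
    w <- runif(60); w <- w / sum(w)
    cl <- clusterConformations(pts, w, metric = "cv_space", cutoff = 0.8)
    D <- as.matrix(dist(pts))
    oracle <- bruteLeader(D, w, 0.8)
    # same extraction: compare populations per frame's cluster
    expect_equal(length(populations(cl)), length(oracle$weights))
    expect_equal(populations(cl)[assignments(cl)],
                 100 * oracle$weights[oracle$assignment], tolerance = 1e-9)
  }
})

test_that("RMSD clustering distances agree with a Kabsch oracle", {
  set.seed(13)
  base <- matrix(rnorm(21), 7)
  frames <- array(NA_real_, c(7, 3, 12))
  for (f in 1:12) {
    R <- randomRotation()
    frames[, , f] <- (base + matrix(rnorm(21, sd = 0.05 * f), 7)) %*% t(R) +
      matrix(rnorm(3, sd = 5), 7, 3, byrow = TRUE)
  }
  # oracle pairwise distances, then oracle leader clustering
  D <- matrix(0, 12, 12)
  for (i in 1:11) for (j in (i + 1):12) {
    D[i, j] <- D[j, i] <- bruteKabschRMSD(frames[, , i], frames[, , j])
  }
  traj <- new("Trajectory", times = 1:12, coords = frames, metadata = list())
  w <- rep(1 / 12, 12)
  cl <- clusterConformations(traj, w, metric = "rmsd", cutoff = 0.25)
  oracle <- bruteLeader(D, w, 0.25)
  expect_equal(populations(cl)[assignments(cl)],
               100 * oracle$weights[oracle$assignment], tolerance = 1e-6)
})

test_that("three-state fixture populations are recovered within 1%", {
  fx <- threeStateFixture(n = 2e4, seed = 14)
  cl <- clusterConformations(fx$points, fx$weights, metric = "cv_space",
                             cutoff = 2)
  top <- populations(cl)[1:3] / 100
  expect_true(all(abs(sort(top, TRUE) - sort(fx$probs, TRUE)) < 0.01))
})

test_that("populations always sum to 100 and free energies obey Boltzmann", {
  set.seed(15)
  for (rep in 1:5) {
    pts <- matrix(rnorm(200 * 2, sd = 2), 200)
    w <- runif(200)
    cl <- clusterConformations(pts, w / sum(w), metric = "cv_space",
                               cutoff = 0.7)
    expect_equal(sum(populations(cl)), 100, tolerance = 1e-6)
    expect_lte(length(populations(cl)), 200L)
    cl <- clusterFreeEnergies(cl, 298)
    p <- populations(cl)
    F <- freeEnergies(cl)
    expect_equal(F[1], 0)
    kT <- boltzmannkB() * 298
    for (i in seq_along(p)[-1])
      expect_equal(F[i] - F[1], -kT * log(p[i] / p[1]), tolerance = 1e-9)
    # larger population => smaller free energy
    expect_true(all(diff(F) >= -1e-12))
  }
})

test_that("the printed unphospho populations imply a gap under 5 kJ/mol", {
  gap <- populationFreeEnergyGap(c(68.6, 13.1), 298)
  expect_equal(gap, 4.1023, tolerance = 1e-4)
  expect_lt(gap, 5)
  expect_equal(populationFreeEnergyGap(c(20, 20)), 0)
  # inverse Boltzmann: population implied by a 10 kJ/mol gap below 93.64%
  kT <- boltzmannkB() * 298
  implied <- 93.64 * exp(-10 / kT)
  expect_equal(implied, 1.66, tolerance = 0.01)
  expect_equal(populationFreeEnergyGap(c(93.64, implied)), 10,
               tolerance = 1e-9)
})

test_that("contact maps match constructed fixtures and the brute force", {
  # two beads pinned in contact, two never in contact
  nF <- 30
  frames <- array(0, c(4, 3, nF))
  for (f in seq_len(nF)) {
    frames[1, , f] <- c(0, 0, 0)
    frames[3, , f] <- c(0.3, 0, 0)            # pair (1,3) always close
    frames[2, , f] <- c(5, 5, 0)
    frames[4, , f] <- c(-5, 8, f)             # pair (2,4) always far
  }
  traj <- new("Trajectory", times = seq_len(nF), coords = frames,
              metadata = list())
  map <- contactProbabilityMap(traj, cutoff = 0.45, exclusion = 2L)
  P <- contactProbabilities(map)
  expect_equal(P[1, 3], 1)
  expect_equal(P[2, 4], 0)
  expect_true(is.na(P[1, 2]))  # |i-j| < exclusion masked

  set.seed(16)
  frames <- array(rnorm(6 * 3 * 40, sd = 0.5), c(6, 3, 40))
  traj <- new("Trajectory", times = 1:40, coords = frames,
              metadata = list())
  w <- runif(40); w <- w / sum(w)
  map <- contactProbabilityMap(traj, w, cutoff = 0.5, exclusion = 2L)
  P <- contactProbabilities(map)
  for (i in 1:6) for (j in 1:6) {
    if (abs(i - j) < 2) next
    brute <- 0
    for (f in 1:40)
      if (sqrt(sum((frames[i, , f] - frames[j, , f])^2)) < 0.5)
        brute <- brute + w[f]
    expect_equal(P[i, j], brute, tolerance = 1e-12)
  }
  expect_equal(P, t(P))
  expect_true(all(P[!is.na(P)] >= 0 & P[!is.na(P)] <= 1))
})

test_that("interaction detection applies charge and phospho rules", {
  pseq <- sac6LoopSegment(phospho = TRUE)
  useq <- sac6LoopSegment(phospho = FALSE)
  n <- length(pseq)
  # geometry: pT103 (bead 5) permanently near K118 (bead 20)
  nF <- 10
  frames <- array(0, c(n, 3, nF))
  for (f in seq_len(nF)) {
    frames[, 1, f] <- seq_len(n) * 2        # everyone far apart
    frames[20, , f] <- frames[5, , f] + c(0.35, 0, 0)
  }
  traj <- new("Trajectory", times = seq_len(nF), coords = frames,
              metadata = list())
  ev <- detectInteractions(traj, NULL, pseq)
  sb <- ev[ev$kind == "salt_bridge", ]
  expect_true(any(sb$residue_i == 103 & sb$residue_j == 118 &
                    sb$prevalence == 1))
  # the same geometry without the phospho charge yields no 103 salt bridge
  ev0 <- detectInteractions(traj, NULL, useq)
  sb0 <- ev0[ev0$kind == "salt_bridge", ]
  expect_false(any(sb0$residue_i == 103 | sb0$residue_j == 103))

  # 30% of the weight in contact => prevalence 0.30
  frames2 <- frames
  for (f in 4:10) frames2[20, , f] <- c(100, 100, 100)
  traj2 <- new("Trajectory", times = seq_len(nF), coords = frames2,
               metadata = list())
  w <- rep(1 / nF, nF)
  ev2 <- detectInteractions(traj2, w, pseq, pairs = list(c(103, 118)))
  expect_equal(ev2$prevalence[ev2$kind == "salt_bridge"], 0.3,
               tolerance = 1e-9)
  expect_error(detectInteractions(traj2, w, pseq, pairs = list(c(103, 999))),
               "absent")
})

test_that("dual-condition maps interleave and recover their inputs", {
  set.seed(17)
  mk <- function(cond) {
    P <- matrix(runif(36), 6); P <- (P + t(P)) / 2
    for (i in 1:6) for (j in 1:6) if (abs(i - j) < 2) P[i, j] <- NA
    new("ContactMap", labels = paste0("R", 1:6), probabilities = P,
        condition = cond, cutoff = 0.45, exclusion = 2L)
  }
  a <- mk("phospho"); b <- mk("unphospho")
  M <- dualConditionMap(a, b)
  expect_equal(M[upper.tri(M)], a@probabilities[upper.tri(M)])
  expect_equal(M[lower.tri(M)], b@probabilities[lower.tri(M)])
  Msym <- dualConditionMap(a, a)
  expect_equal(Msym[upper.tri(Msym)], t(Msym)[upper.tri(Msym)])
  bad <- mk("unphospho"); bad@cutoff <- 0.6
  expect_error(dualConditionMap(a, bad), "share")
})

test_that("weights and cluster tables round-trip through their writers", {
  w <- new("FrameWeights", weights = c(0.1, 0.2, 0.3, 0.4),
           method = "time_dependent", temperature = 298)
  tmp <- withr::local_tempfile()
  writeWeights(w, times = c(0, 1, 2, 3) * 0.5, tmp)
  back <- readWeights(tmp)
  expect_equal(frameWeights(back$weights), frameWeights(w),
               tolerance = 1e-10)
  expect_equal(back$times, c(0, 0.5, 1, 1.5))

  cl <- new("ClusterSet", assignment = c(1L, 1L, 2L),
            populations = c(70, 30), freeEnergies = c(0, 2.1),
            representatives = c(1L, 3L), metric = "cv_space", cutoff = 1)
  tmp2 <- withr::local_tempfile()
  writeClusterTsv(cl, tmp2)
  tab <- read.delim(tmp2)
  expect_equal(tab$population_pct, c(70, 30))
  expect_equal(tab$representative_frame, c(1L, 3L))
})
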