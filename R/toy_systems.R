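# Synthetic-data stage: analytic landscapes with exactly known free-energy
# surfaces, the charged bead-chain surrogate of the peptide, the BAOAB
# Langevin sampler, and generators of bias/CV records with ground truth.

#' Quartic double-well landscape
#'
#' \eqn{U(x) = B ((x/a)^2 - 1)^2} with \eqn{a} = half the minima
#' separation: two equal minima at \eqn{\pm a} and a saddle exactly
#' `barrier` kJ/mol above them. The standard oracle for metadynamics
#' barrier-recovery checks.
#'
#' @param barrier barrier height, kJ/mol (> 0).
#' @param minimaSeparation distance between the two minima, CV units (> 0).
#' @param domain optional `c(lo, hi)`; default spans the minima generously.
#' @return an [AnalyticLandscape-class] (1D).
#' @export
#' @examples
#' dw <- makeDoubleWell(10, 2)
#' landscapeEnergy(dw, matrix(c(-1, 0, 1)))$energy  # 0, 10, 0
makeDoubleWell <- function(barrier, minimaSeparation, domain = NULL) {
  if (barrier <= 0 || minimaSeparation <= 0)
    stop("barrier and minima separation must be positive")
  a <- minimaSeparation / 2
  if (is.null(domain)) domain <- c(-2.2 * a, 2.2 * a)
  new("AnalyticLandscape", dimension = 1L, family = "double_well",
      parameters = list(barrier = barrier, half_separation = a),
      domain = matrix(domain, nrow = 2,
                      dimnames = list(c("lo", "hi"), NULL)))
}

#' Gaussian-mixture landscape
#'
#' \eqn{U(s) = -\sum_k A_k \exp(-\sum_d (s_d-\mu_{kd})^2/(2\sigma_{kd}^2))}:
#' inverted Gaussian wells of depth `depths` at `centers`. With well
#' separated components the minima sit at the centers and the free-energy
#' differences between basins are known in closed form.
#'
#' @param centers numeric matrix `[component, dim]` (a vector is taken as
#'   one column).
#' @param widths matrix like `centers`, per-component sigmas.
#' @param depths well depths A (kJ/mol, > 0).
#' @param domain 2 x dim matrix (rows lo, hi); default covers the centers.
#' @return an [AnalyticLandscape-class].
#' @export
makeGaussianMixture <- function(centers, widths, depths, domain = NULL) {
  centers <- as.matrix(centers)
  widths <- as.matrix(widths)
  if (!all(dim(widths) == dim(centers)) ||
      length(depths) != nrow(centers))
    stop("centers, widths and depths must agree in component count")
  if (any(widths <= 0) || any(depths <= 0))
    stop("widths and depths must be positive")
  d <- ncol(centers)
  if (is.null(domain)) {
    pad <- 4 * apply(widths, 2, max)
    domain <- rbind(apply(centers, 2, min) - pad,
                    apply(centers, 2, max) + pad)
  }
  new("AnalyticLandscape", dimension = as.integer(d),
      family = "gaussian_mixture",
      parameters = list(centers = centers, widths = widths,
                        depths = as.numeric(depths)),
      domain = matrix(domain, nrow = 2,
                      dimnames = list(c("lo", "hi"), NULL)))
}

#' Harmonic landscape
#'
#' \eqn{U(s) = \sum_d k_d (s_d - c_d)^2 / 2}. Used for equipartition and
#' Boltzmann-sampling checks, where variance and density are known exactly.
#'
#' @param stiffness per-dimension force constants (kJ/mol per CV unit^2).
#' @param center minimum position (default origin).
#' @param halfWidth domain half width around the center.
#' @return an [AnalyticLandscape-class].
#' @export
makeHarmonic <- function(stiffness, center = rep(0, length(stiffness)),
                         halfWidth = 10) {
  if (any(stiffness <= 0)) stop("stiffness must be positive")
  d <- length(stiffness)
  new("AnalyticLandscape", dimension = as.integer(d), family = "harmonic",
      parameters = list(stiffness = as.numeric(stiffness),
                        center = as.numeric(center)),
      domain = rbind(center - halfWidth, center + halfWidth))
}

#' Evaluate a landscape potential and its gradient
#'
#' @param landscape an [AnalyticLandscape-class].
#' @param points matrix `[point, dim]` of CV-space points.
#' @return list with `energy` (kJ/mol) and `gradient` matrices.
#' @export
landscapeEnergy <- function(landscape, points) {
  points <- as.matrix(points)
  cpp_landscape_eval(.landscapeAsList(landscape), points)
}

.landscapeAsList <- function(landscape) {
  list(family = landscape@family, dimension = landscape@dimension,
       parameters = landscape@parameters)
}

#' Exact free-energy surface of an analytic landscape
#'
#' For a potential defined directly in CV space the free-energy surface is
#' the potential itself up to an additive constant; the grid is shifted so
#' its minimum is exactly 0. Serves as ground truth for metadynamics
#' recovery tests.
#'
#' @param landscape an [AnalyticLandscape-class].
#' @param gridBins nodes per dimension.
#' @param axes optional list of explicit axis vectors (inside the domain).
#' @return an [FESGrid-class].
#' @export
analyticFES <- function(landscape, gridBins = 201L, axes = NULL) {
  d <- landscape@dimension
  if (is.null(axes))
    axes <- lapply(seq_len(d), function(j)
      seq(landscape@domain[1, j], landscape@domain[2, j],
          length.out = gridBins))
  for (j in seq_len(d))
    if (min(axes[[j]]) < landscape@domain[1, j] - 1e-9 ||
        max(axes[[j]]) > landscape@domain[2, j] + 1e-9)
      stop("grid axis ", j, " lies outside the landscape domain")
  pts <- as.matrix(expand.grid(axes))
  U <- landscapeEnergy(landscape, pts)$energy
  vals <- array(U, dim = vapply(axes, length, 1L))
  vals <- vals - min(vals)
  vals[vals < 0] <- 0  # guard fp noise so min is exactly 0
  new("FESGrid", axes = axes, values = vals,
      cvNames = paste0("cv", seq_len(d)))
}

#' Build the coarse-grained charged bead chain for a peptide
#'
#' One bead per residue; charges follow the sequence module's formal charge
#' table (so a phosphothreonine bead carries -2 e and lysine beads +1 e).
#' Two chains built from the same segment with and without the phospho flag
#' differ only in the phospho bead's charge.
#'
#' @param seq a [PeptideSeq-class].
#' @param mass bead mass, amu (average residue mass).
#' @param bondLength equilibrium C-alpha--C-alpha distance, nm.
#' @param bondStiffness bond force constant, kJ/mol/nm^2.
#' @param radius excluded-volume radius per bead, nm.
#' @param dielectric relative dielectric of the screened Coulomb term.
#' @param screeningLength Debye length, nm (1.0 nm ~ 100 mM ionic strength).
#' @param repulsionStiffness excluded-volume force constant, kJ/mol/nm^2.
#' @param phosphoCharge charge added per phospho group.
#' @return a [BeadChain-class].
#' @export
#' @examples
#' ch <- buildBeadChain(sac6LoopSegment(phospho = TRUE))
#' ch@charges[5]  # -2 (pT103)
buildBeadChain <- function(seq, mass = 110, bondLength = 0.38,
                           bondStiffness = 1000, radius = 0.25,
                           dielectric = 80, screeningLength = 1.0,
                           repulsionStiffness = 500, phosphoCharge = -2) {
  stopifnot(is(seq, "PeptideSeq"))
  n <- length(seq)
  new("BeadChain",
      masses = rep(mass, n),
      charges = perResidueCharges(seq, phosphoCharge),
      radii = rep(radius, n),
      bondLength = bondLength, bondStiffness = bondStiffness,
      dielectric = dielectric, screeningLength = screeningLength,
      repulsionStiffness = repulsionStiffness, sourceSeq = seq)
}

#' Fully extended (linear) starting conformation
#'
#' Beads collinear along x at bond-length spacing, centred at the origin --
#' the "starting from a linear conformation" initial condition.
#'
#' @param chain a [BeadChain-class].
#' @return matrix `[bead, xyz]` in nm.
#' @export
linearConformation <- function(chain) {
  n <- length(chain@masses)
  x <- (seq_len(n) - (n + 1) / 2) * chain@bondLength
  cbind(x = x, y = rep(0, n), z = rep(0, n))
}

#' Sampling configuration constructor
#'
#' @param temperature K (default 298, room temperature).
#' @param friction Langevin friction, 1/ps.
#' @param timestep ps. Must resolve the stiffest mode: for a bond of
#'   stiffness k and bead mass m the stability bound of the BAOAB scheme is
#'   roughly `dt < 2/sqrt(k/m)`; the defaults (k = 1000, m = 110, dt =
#'   0.005) sit ~130x below it.
#' @param nSteps integration steps.
#' @param seed RNG seed (drives `set.seed()`; identical seeds give
#'   bit-identical trajectories).
#' @param saveStride store a frame every this many steps.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(temperature = 298, friction = 1,
                             timestep = 0.005, nSteps = 10000L,
                             seed = 1L, saveStride = 100L) {
  new("SimulationConfig", temperature = temperature, friction = friction,
      timestep = timestep, nSteps = as.integer(nSteps),
      seed = as.integer(seed), saveStride = as.integer(saveStride))
}

# default CV-grid for a bias over a landscape's coordinates
.landscapeGrid <- function(landscape, bins = 201L) {
  list(lo = landscape@domain[1, ], hi = landscape@domain[2, ],
       n = rep(as.integer(bins), landscape@dimension))
}

# default CV-grid for the (Rg, contact-number) bias of a chain
.chainGrid <- function(chain, cvdefs, bins = c(161L, 161L)) {
  n <- length(chain@masses)
  rgMax <- (n - 1) * chain@bondLength / sqrt(12) * 1.15 + 0.2
  excl <- cvdefs$contact@exclusion
  maxPairs <- sum(pmax(n - seq(excl, n - 1), 0))
  list(lo = c(0, 0), hi = c(rgMax, maxPairs),
       n = as.integer(bins))
}

.emptyHillArgs <- function(d) {
  list(centers = matrix(0, 0, d), widths = matrix(0, 0, d),
       heights = numeric(0), times = numeric(0))
}

.biasHillArgs <- function(bias, d) {
  if (is.null(bias)) return(.emptyHillArgs(d))
  list(centers = bias@centers, widths = bias@widths,
       heights = bias@heights, times = bias@times)
}

#' Langevin sampling of a landscape or bead chain
#'
#' BAOAB Langevin dynamics at the configured temperature. An optional
#' static [BiasState-class] adds its bias force (through the CV chain rule
#' for chains) but no new hills are deposited; use [runMetadynamics()] for
#' adaptive biasing. Runs are reproducible: the RNG is seeded from
#' `config@seed`.
#'
#' @param system an [AnalyticLandscape-class] or [BeadChain-class].
#' @param config a [SimulationConfig-class].
#' @param bias optional [BiasState-class], applied as a static bias.
#' @param start starting point: CV vector for landscapes (default: first
#'   minimum), coordinate matrix for chains (default:
#'   [linearConformation()]).
#' @param cvdefs for chains, the CV definitions (default
#'   [chainCVDefinitions()]).
#' @param gridBins bias-grid nodes per CV (only used when `bias` given).
#' @return list with `trajectory` ([Trajectory-class]) and `cv`
#'   ([CVSeries-class]).
#' @export
setGeneric("langevinSample",
  function(system, config, bias = NULL, start = NULL, cvdefs = NULL,
           gridBins = NULL) standardGeneric("langevinSample"))

#' @rdname langevinSample
#' @export
setMethod("langevinSample", "AnalyticLandscape",
  function(system, config, bias = NULL, start = NULL, cvdefs = NULL,
           gridBins = NULL) {
    .runLandscape(system, config, bias = bias, metad = FALSE,
                  start = start, gridBins = gridBins %||% 201L)
  })

#' @rdname langevinSample
#' @export
setMethod("langevinSample", "BeadChain",
  function(system, config, bias = NULL, start = NULL, cvdefs = NULL,
           gridBins = NULL) {
    .runChain(system, config, bias = bias, metad = FALSE, start = start,
              cvdefs = cvdefs, gridBins = gridBins %||% c(161L, 161L))
  })

`%||%` <- function(a, b) if (is.null(a)) b else a

.defaultStart <- function(landscape) {
  p <- landscape@parameters
  switch(landscape@family,
         double_well = -p$half_separation,
         gaussian_mixture = as.numeric(p$centers[1, ]),
         harmonic = p$center)
}

.runLandscape <- function(landscape, config, bias, metad, start, gridBins,
                          t0 = 0) {
  d <- landscape@dimension
  if (is.null(start)) start <- .defaultStart(landscape)
  kT <- .kB * config@temperature
  grid <- .landscapeGrid(landscape, gridBins)
  ha <- .biasHillArgs(bias, d)
  wt <- if (!is.null(bias)) bias@wellTempered else FALSE
  set.seed(config@seed)
  res <- cpp_langevin_landscape(
    .landscapeAsList(landscape), as.numeric(start),
    config@nSteps, config@timestep, 1.0, config@friction, kT,
    config@saveStride,
    metad, if (metad) bias@depositionStride else 1L,
    if (metad) bias@baseHeight else 0,
    if (metad) bias@sigma else rep(0.1, d),
    wt, if (wt) bias@biasFactor else 2,
    grid$lo, grid$hi, grid$n,
    ha$centers, ha$widths, ha$heights, ha$times,
    t0, landscape@domain[1, ], landscape@domain[2, ], 1000)
  nF <- length(res$times)
  coords <- array(t(res$positions), dim = c(1, d, nF))
  traj <- new("Trajectory", times = res$times, coords = coords,
              metadata = list(system = "landscape",
                              family = landscape@family,
                              temperature = config@temperature,
                              seed = config@seed,
                              timestep = config@timestep,
                              saveStride = config@saveStride))
  cvNames <- paste0("cv", seq_len(d))
  cv <- new("CVSeries", times = res$times,
            values = matrix(res$positions, ncol = d), cvNames = cvNames)
  out <- list(trajectory = traj, cv = cv)
  if (metad) {
    out$bias <- new("BiasState",
                    centers = rbind(ha$centers, res$hill_centers),
                    widths = rbind(ha$widths, res$hill_widths),
                    heights = c(ha$heights, res$hill_heights),
                    times = c(ha$times, res$hill_times),
                    temperature = config@temperature,
                    wellTempered = bias@wellTempered,
                    biasFactor = bias@biasFactor,
                    baseHeight = bias@baseHeight, sigma = bias@sigma,
                    depositionStride = bias@depositionStride,
                    cvNames = cvNames)
  }
  out
}

.runChain <- function(chain, config, bias, metad, start, cvdefs, gridBins,
                      t0 = 0) {
  if (is.null(cvdefs)) cvdefs <- chainCVDefinitions(length(chain@masses))
  if (is.null(start)) start <- linearConformation(chain)
  sw <- cvdefs$contact@switching
  kT <- .kB * config@temperature
  grid <- .chainGrid(chain, cvdefs, gridBins)
  ha <- .biasHillArgs(bias, 2L)
  wt <- if (!is.null(bias)) bias@wellTempered else FALSE
  pref <- 138.935458 / chain@dielectric  # Coulomb constant / eps_r
  set.seed(config@seed)
  res <- cpp_langevin_chain(
    as.matrix(start), chain@masses, chain@charges, chain@radii,
    chain@bondLength, chain@bondStiffness,
    pref, chain@screeningLength, chain@repulsionStiffness,
    config@nSteps, config@timestep, config@friction, kT, config@saveStride,
    cvdefs$rg@massWeighted, sw$r0, sw$n, sw$m, cvdefs$contact@exclusion,
    metad, if (metad) bias@depositionStride else 1L,
    if (metad) bias@baseHeight else 0,
    if (metad) bias@sigma else c(0.05, 0.5),
    wt, if (wt) bias@biasFactor else 2,
    grid$lo, grid$hi, grid$n,
    ha$centers, ha$widths, ha$heights, ha$times, t0)
  traj <- new("Trajectory", times = res$times, coords = res$frames,
              metadata = list(system = "bead_chain",
                              sequence = formatPeptide(chain@sourceSeq),
                              temperature = config@temperature,
                              seed = config@seed,
                              timestep = config@timestep,
                              saveStride = config@saveStride))
  cvNames <- c("rg", "contact_number")
  cv <- new("CVSeries", times = res$times, values = res$cvs,
            cvNames = cvNames)
  out <- list(trajectory = traj, cv = cv)
  if (metad) {
    out$bias <- new("BiasState",
                    centers = rbind(ha$centers, res$hill_centers),
                    widths = rbind(ha$widths, res$hill_widths),
                    heights = c(ha$heights, res$hill_heights),
                    times = c(ha$times, res$hill_times),
                    temperature = config@temperature,
                    wellTempered = bias@wellTempered,
                    biasFactor = bias@biasFactor,
                    baseHeight = bias@baseHeight, sigma = bias@sigma,
                    depositionStride = bias@depositionStride,
                    cvNames = cvNames)
  }
  out
}

#' Synthetic biased CV records with exact ground-truth weights
#'
#' Draws CV samples from the instantaneously biased Boltzmann distribution
#' \eqn{p_t(s) \propto \exp(-\beta(U(s) + V(s,t)))} of an analytic
#' landscape under a prescribed hill schedule, and returns the exact
#' importance weights that unbias them:
#' \eqn{w \propto \exp(\beta V(s,t))\, Z_b(t)/Z_u} (normalized). With an
#' empty schedule the weights are exactly uniform; with a static schedule
#' they reduce to the umbrella-unbiasing closed form.
#'
#' @param landscape an [AnalyticLandscape-class] (1D).
#' @param schedule a [BiasState-class] holding the hill schedule (may be
#'   empty).
#' @param times frame times at which samples are drawn.
#' @param temperature K.
#' @param seed RNG seed.
#' @param gridBins grid resolution used for sampling and normalization.
#' @return list with `cv` ([CVSeries-class]), `bias` (the schedule),
#'   `weights` (ground-truth [FrameWeights-class]).
#' @export
synthBiasRecords <- function(landscape, schedule, times, temperature = 298,
                             seed = 1L, gridBins = 2001L) {
  if (landscape@dimension != 1L)
    stop("ground-truth record generation is implemented in 1D")
  set.seed(seed)
  beta <- 1 / (.kB * temperature)
  g <- seq(landscape@domain[1, 1], landscape@domain[2, 1],
           length.out = gridBins)
  h <- g[2] - g[1]
  U <- landscapeEnergy(landscape, matrix(g))$energy
  pu <- exp(-beta * (U - min(U)))
  Zu <- sum(pu) * h
  n <- length(times)
  s <- numeric(n)
  lw <- numeric(n)
  for (i in seq_len(n)) {
    V <- cpp_bias_eval(schedule@centers, schedule@widths, schedule@heights,
                       schedule@times, matrix(g), times[i], FALSE)$energy
    pb <- exp(-beta * (U - min(U) + V))
    Zb <- sum(pb) * h
    cell <- sample.int(gridBins, 1L, prob = pb)
    s[i] <- g[cell] + runif(1, -h / 2, h / 2)
    Vi <- cpp_bias_eval(schedule@centers, schedule@widths, schedule@heights,
                        schedule@times, matrix(s[i]), times[i],
                        FALSE)$energy
    lw[i] <- beta * Vi + log(Zb / Zu)
  }
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  list(cv = new("CVSeries", times = times, values = matrix(s, ncol = 1),
                cvNames = "cv1"),
       bias = schedule,
       weights = new("FrameWeights", weights = w, method = "ground_truth",
                     temperature = temperature))
}

#' Three-state weighted-clustering fixture
#'
#' Generates points from three well-separated Gaussian blobs with
#' multinomially drawn state labels, emulating an ensemble with known state
#' populations (default 68.6% / 18.3% / 13.1%). Recovered cluster
#' populations should match the targets to within multinomial sampling
#' error.
#'
#' @param n number of frames.
#' @param probs target state probabilities (sum to 1).
#' @param centers matrix `[state, dim]` of blob centers.
#' @param spread within-state standard deviation.
#' @param seed RNG seed.
#' @return list with `points` (matrix), `weights` (uniform
#'   [FrameWeights-class]), `states` (true labels), `probs`.
#' @export
threeStateFixture <- function(n = 1e5, probs = c(0.686, 0.183, 0.131),
                              centers = rbind(c(0, 0), c(6, 0), c(0, 6)),
                              spread = 0.4, seed = 1L) {
  stopifnot(abs(sum(probs) - 1) < 1e-9, nrow(centers) == length(probs))
  set.seed(seed)
  states <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  d <- ncol(centers)
  pts <- centers[states, , drop = FALSE] +
    matrix(rnorm(n * d, sd = spread), n, d)
  list(points = pts,
       weights = new("FrameWeights", weights = rep(1 / n, n),
                     method = "uniform", temperature = 298),
       states = states, probs = probs)
}
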