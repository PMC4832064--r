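# Ensemble analysis: frame reweighting, weighted conformational clustering,
# Boltzmann cluster free energies, contact-probability maps and
# salt-bridge / hydrogen-bond surrogate detection.

#' Recover unbiased frame weights from a biased trajectory
#'
#' Time-dependent-bias reweighting: each frame gets
#' \eqn{w_t \propto \exp(\beta [V(s_t, t) - c(t)])} where \eqn{V(s,t)} is
#' the instantaneous bias and the offset
#' \eqn{c(t) = -\frac{1}{\beta}\ln \frac{\int e^{-\beta(F(s)+V(s,t))} ds}
#' {\int e^{-\beta F(s)} ds}}
#' is evaluated on the free-energy grid, which makes weights from
#' different bias epochs comparable and absorbs any constant added to the
#' bias. With no hills the weights are exactly uniform; with
#' `method = "static_bias"` the full final bias is treated as
#' time-independent and the umbrella-unbiasing closed form
#' \eqn{w \propto \exp(\beta V(s_t))} is returned.
#'
#' @param cv a [CVSeries-class] of the biased run.
#' @param bias the [BiasState-class] accumulated during the run.
#' @param fes the reconstructed [FESGrid-class] (used only for c(t)).
#' @param temperature K; defaults to the bias state's.
#' @param method `"time_dependent"` (default) or `"static_bias"`.
#' @return a [FrameWeights-class], normalized to sum 1.
#' @export
reweightFrames <- function(cv, bias, fes = NULL,
                           temperature = bias@temperature,
                           method = c("time_dependent", "static_bias")) {
  method <- match.arg(method)
  n <- nFrames(cv)
  if (n == 0L) stop("empty CV series")
  if (nHills(bias) == 0L)
    return(new("FrameWeights", weights = rep(1 / n, n),
               method = "uniform", temperature = temperature))
  if (ncol(cv@values) != ncol(bias@centers))
    stop("CV series and bias disagree in CV count")
  beta <- 1 / (.kB * temperature)
  S <- cv@values
  if (method == "static_bias") {
    V <- biasEnergy(bias, S)
    lw <- beta * V
  } else {
    if (is.null(fes))
      stop("time-dependent reweighting needs the FES grid for c(t)")
    pts <- as.matrix(expand.grid(fes@axes))
    F <- as.numeric(fes@values)
    lZu <- .logSumExp(-beta * F)
    times <- cv@times
    ord <- order(times)
    m <- nHills(bias)
    Vgrid <- numeric(nrow(pts))
    hptr <- 0L
    ccur <- 0  # no hills yet: Z_b = Z_u
    lw <- numeric(n)
    for (i in ord) {
      t <- times[i]
      changed <- FALSE
      while (hptr < m && bias@times[hptr + 1L] <= t) {
        hptr <- hptr + 1L
        e <- rowSums(sweep(pts, 2, bias@centers[hptr, ])^2 /
                       matrix(2 * bias@widths[hptr, ]^2, nrow(pts),
                              ncol(pts), byrow = TRUE))
        Vgrid <- Vgrid + bias@heights[hptr] * exp(-e)
        changed <- TRUE
      }
      if (changed)
        ccur <- -(.logSumExp(-beta * (F + Vgrid)) - lZu) / beta
      Vi <- biasEnergy(bias, S[i, , drop = FALSE], t)
      lw[i] <- beta * (Vi - ccur)
    }
  }
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  new("FrameWeights", weights = w, method = method,
      temperature = temperature)
}

.logSumExp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Weighted GROMOS-style conformational clustering
#'
#' Leader clustering: repeatedly extract the frame with the most
#' neighbours within `cutoff` (ties broken toward the lowest frame index),
#' assign the centre and its neighbours to a cluster, remove them, and
#' repeat. Populations are the summed frame weights of the members,
#' reported in percent; clusters are ordered by descending population.
#'
#' @param x a [Trajectory-class] (for `metric = "rmsd"`, with optimal
#'   rigid-body superposition before each distance), a [CVSeries-class] or
#'   a plain point matrix (for `metric = "cv_space"`, Euclidean).
#' @param weights a [FrameWeights-class] or numeric vector (default
#'   uniform).
#' @param metric `"rmsd"` or `"cv_space"`.
#' @param cutoff neighbour cutoff: nm for rmsd (default 0.2 for the bead
#'   model), CV units otherwise.
#' @return a [ClusterSet-class] (free energies unfilled; see
#'   [clusterFreeEnergies()]).
#' @export
clusterConformations <- function(x, weights = NULL,
                                 metric = c("rmsd", "cv_space"),
                                 cutoff = 0.2) {
  metric <- match.arg(metric)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (is(x, "Trajectory")) {
    n <- nFrames(x)
  } else {
    x <- if (is(x, "CVSeries")) x@values else as.matrix(x)
    n <- nrow(x)
  }
  if (n == 0L) stop("empty trajectory")
  w <- if (is.null(weights)) rep(1 / n, n)
       else if (is(weights, "FrameWeights")) weights@weights
       else as.numeric(weights) / sum(weights)
  if (length(w) != n) stop("one weight per frame is required")
  res <- if (metric == "rmsd") {
    if (!is(x, "Trajectory"))
      stop("rmsd clustering needs a Trajectory")
    cpp_leader_cluster_rmsd(coords(x), w, cutoff)
  } else {
    cpp_leader_cluster_points(x, w, cutoff)
  }
  pops <- res$weights * 100
  ord <- order(-pops)  # stable: ties keep extraction order
  rank <- match(seq_along(ord), ord)
  new("ClusterSet",
      assignment = rank[res$assignment + 1L],
      populations = pops[ord],
      freeEnergies = rep(NA_real_, length(ord)),
      representatives = res$centers[ord] + 1L,
      metric = metric, cutoff = cutoff)
}

#' Boltzmann free energies of clusters
#'
#' \eqn{F_i = -k_B T \ln p_i}, shifted so the most populated cluster sits
#' at 0; the pairwise gap obeys
#' \eqn{\Delta F_{ij} = -k_B T \ln(p_j / p_i)} identically. For the
#' printed unphosphorylated populations 68.6% and 13.1% at 298 K this
#' gives a gap of about 4.1 kJ/mol.
#'
#' @param clusters a [ClusterSet-class].
#' @param temperature K.
#' @return the [ClusterSet-class] with `freeEnergies` filled
#'   (zero-population clusters get NA with a warning).
#' @export
#' @examples
#' populationFreeEnergyGap(c(68.6, 13.1))  # ~4.10 kJ/mol
clusterFreeEnergies <- function(clusters, temperature = 298) {
  p <- clusters@populations / 100
  if (any(p == 0)) {
    warning("zero-population cluster(s) excluded from free energies")
  }
  F <- ifelse(p > 0, -.kB * temperature * log(p), NA_real_)
  F <- F - F[1]  # most populated cluster at 0
  clusters@freeEnergies <- F
  clusters
}

#' Free-energy gap implied by two populations
#'
#' The inverse-Boltzmann relation \eqn{\Delta F = -k_B T \ln(p_2/p_1)}
#' applied to a pair of populations (any common unit).
#'
#' @param pops numeric vector of two populations (e.g. percent).
#' @param temperature K.
#' @return gap in kJ/mol (positive when `pops[1] > pops[2]`).
#' @export
populationFreeEnergyGap <- function(pops, temperature = 298) {
  stopifnot(length(pops) == 2, all(pops > 0))
  -.kB * temperature * log(pops[2] / pops[1])
}

.residueLabels <- function(seq) {
  paste0(ifelse(seq@phospho, "p", ""), seq@residues, residueNumbers(seq))
}

#' Weighted residue-pair contact-probability map
#'
#' Entry (i, j) is the weighted fraction of frames in which beads i and j
#' are closer than `cutoff`; symmetric, with the near-diagonal band
#' `|i - j| < exclusion` masked as NA.
#'
#' @param trajectory a [Trajectory-class].
#' @param weights a [FrameWeights-class] or numeric vector (default
#'   uniform).
#' @param seq optional [PeptideSeq-class] supplying residue labels.
#' @param cutoff contact cutoff, nm (default 0.45).
#' @param exclusion minimum `|i - j|` reported (default 2).
#' @param condition condition tag stored in the map.
#' @return a [ContactMap-class].
#' @export
contactProbabilityMap <- function(trajectory, weights = NULL, seq = NULL,
                                  cutoff = 0.45, exclusion = 2L,
                                  condition = "unspecified") {
  if (cutoff <= 0) stop("cutoff must be positive")
  xyz <- coords(trajectory)
  nB <- dim(xyz)[1]
  nF <- dim(xyz)[3]
  w <- if (is.null(weights)) rep(1 / nF, nF)
       else if (is(weights, "FrameWeights")) weights@weights
       else as.numeric(weights) / sum(weights)
  labels <- if (!is.null(seq)) .residueLabels(seq) else as.character(seq_len(nB))
  P <- matrix(NA_real_, nB, nB)
  for (i in seq_len(nB - 1)) {
    for (j in seq.int(i + 1, nB)) {
      if (j - i < exclusion) next
      d2 <- colSums((matrix(xyz[i, , ], nrow = dim(xyz)[2]) -
                       matrix(xyz[j, , ], nrow = dim(xyz)[2]))^2)
      p <- sum(w[d2 < cutoff^2])
      P[i, j] <- p
      P[j, i] <- p
    }
  }
  P[P > 1] <- 1  # guard against fp accumulation above 1
  new("ContactMap", labels = labels, probabilities = P,
      condition = condition, cutoff = cutoff,
      exclusion = as.integer(exclusion))
}

#' Default geometric criteria for interaction detection
#'
#' Salt bridge: oppositely (formally) charged beads within 0.5 nm.
#' Hydrogen-bond surrogate: a phospho bead within 0.35 nm of a bead whose
#' residue has a backbone amide (every residue except proline); the bead
#' model carries no angles, so this is a distance-only surrogate of the
#' donor-acceptor criterion.
#'
#' @param saltBridgeCutoff nm.
#' @param hydrogenBondCutoff nm.
#' @param minSeparation minimum sequence separation `|i - j|`.
#' @return a named list of rule parameters.
#' @export
interactionRules <- function(saltBridgeCutoff = 0.5,
                             hydrogenBondCutoff = 0.35,
                             minSeparation = 2L) {
  list(saltBridgeCutoff = saltBridgeCutoff,
       hydrogenBondCutoff = hydrogenBondCutoff,
       minSeparation = as.integer(minSeparation))
}

#' Detect salt bridges and hydrogen-bond surrogates
#'
#' Scans all residue pairs admitted by the rules, builds a per-frame
#' boolean contact series for each, and reports the weighted prevalence
#' (the weighted mean of the series). Pairs are returned sorted by
#' descending prevalence.
#'
#' @param trajectory a [Trajectory-class].
#' @param weights a [FrameWeights-class] or numeric vector.
#' @param seq the [PeptideSeq-class] matching the trajectory beads.
#' @param rules list from [interactionRules()].
#' @param pairs optional list of absolute residue-number pairs restricting
#'   the scan; an unknown residue number is an error.
#' @param phosphoCharge charge per phospho group for the salt-bridge rule.
#' @return data.frame with columns `kind`, `residue_i`, `residue_j`,
#'   `label_i`, `label_j`, `prevalence`; the per-frame logical series are
#'   attached as the `"series"` attribute (a list, one entry per row).
#' @export
detectInteractions <- function(trajectory, weights = NULL, seq,
                               rules = interactionRules(), pairs = NULL,
                               phosphoCharge = -2) {
  stopifnot(is(seq, "PeptideSeq"))
  xyz <- coords(trajectory)
  nB <- dim(xyz)[1]
  nF <- dim(xyz)[3]
  if (nB != length(seq)) stop("trajectory beads and sequence length differ")
  w <- if (is.null(weights)) rep(1 / nF, nF)
       else if (is(weights, "FrameWeights")) weights@weights
       else as.numeric(weights) / sum(weights)
  q <- perResidueCharges(seq, phosphoCharge)
  nums <- residueNumbers(seq)
  labels <- .residueLabels(seq)
  hasAmide <- seq@residues != "P"
  if (!is.null(pairs)) {
    want <- unique(unlist(pairs))
    if (!all(want %in% nums))
      stop("rule references residue number(s) absent from the sequence: ",
           paste(setdiff(want, nums), collapse = ", "))
  }
  rows <- list()
  series <- list()
  for (i in seq_len(nB - 1)) {
    for (j in seq.int(i + 1, nB)) {
      if (j - i < rules$minSeparation) next
      if (!is.null(pairs) &&
          !any(vapply(pairs, function(p)
            setequal(p, c(nums[i], nums[j])), TRUE))) next
      kinds <- character(0)
      if (q[i] * q[j] < 0) kinds <- c(kinds, "salt_bridge")
      if ((seq@phospho[i] && hasAmide[j]) ||
          (seq@phospho[j] && hasAmide[i]))
        kinds <- c(kinds, "hydrogen_bond")
      if (!length(kinds)) next
      d2 <- colSums((matrix(xyz[i, , ], nrow = dim(xyz)[2]) -
                       matrix(xyz[j, , ], nrow = dim(xyz)[2]))^2)
      for (kind in kinds) {
        cut <- if (kind == "salt_bridge") rules$saltBridgeCutoff
               else rules$hydrogenBondCutoff
        contact <- d2 < cut^2
        rows[[length(rows) + 1L]] <-
          data.frame(kind = kind, residue_i = nums[i], residue_j = nums[j],
                     label_i = labels[i], label_j = labels[j],
                     prevalence = sum(w[contact]),
                     stringsAsFactors = FALSE)
        series[[length(series) + 1L]] <- contact
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(kind = character(), residue_i = integer(),
                      residue_j = integer(), label_i = character(),
                      label_j = character(), prevalence = numeric())
    attr(out, "series") <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$prevalence)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "series") <- series[ord]
  out
}

#' Combine phospho and unphospho contact maps into one matrix
#'
#' Upper-left triangle (row < column) carries the phospho map, lower-right
#' triangle the unphospho map -- the two-condition display convention.
#'
#' @param mapPhospho,mapUnphospho [ContactMap-class] objects sharing
#'   labels, cutoff and exclusion.
#' @return matrix with residue labels as dimnames.
#' @export
dualConditionMap <- function(mapPhospho, mapUnphospho) {
  if (!identical(length(mapPhospho@labels), length(mapUnphospho@labels)) ||
      mapPhospho@cutoff != mapUnphospho@cutoff ||
      mapPhospho@exclusion != mapUnphospho@exclusion)
    stop("maps must share labels, cutoff and exclusion")
  n <- length(mapPhospho@labels)
  M <- matrix(NA_real_, n, n)
  up <- upper.tri(M)
  M[up] <- mapPhospho@probabilities[up]
  lo <- lower.tri(M)
  M[lo] <- mapUnphospho@probabilities[lo]
  dimnames(M) <- list(mapPhospho@labels, mapPhospho@labels)
  M
}

# ---- plain-text writers ---------------------------------------------------

#' Write frame weights as two-column text
#'
#' Columns: frame_time (ps), weight.
#'
#' @param weights a [FrameWeights-class].
#' @param times frame times matching the weights.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWeights <- function(weights, times, path) {
  stopifnot(length(times) == length(weights@weights))
  tab <- data.frame(frame_time = times, weight = weights@weights)
  write.table(format(tab, digits = 12, scientific = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read frame weights written by [writeWeights()]
#' @param path file path.
#' @param temperature K recorded in the returned object.
#' @return list with `weights` ([FrameWeights-class]) and `times`.
#' @export
readWeights <- function(path, temperature = 298) {
  tab <- read.table(path, header = TRUE)
  w <- tab$weight / sum(tab$weight)
  list(weights = new("FrameWeights", weights = w, method = "file",
                     temperature = temperature),
       times = tab$frame_time)
}

#' Write a cluster table as TSV
#'
#' Columns: cluster_id, population_pct, free_energy_kjmol,
#' representative_frame.
#'
#' @param clusters a [ClusterSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeClusterTsv <- function(clusters, path) {
  tab <- data.frame(cluster_id = seq_along(clusters@populations),
                    population_pct = clusters@populations,
                    free_energy_kjmol = clusters@freeEnergies,
                    representative_frame = clusters@representatives)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a contact map (or combined dual-condition matrix) as TSV
#'
#' Residue labels appear as the header row and first column.
#'
#' @param map a [ContactMap-class] or a labelled matrix from
#'   [dualConditionMap()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeContactTsv <- function(map, path) {
  M <- if (is(map, "ContactMap")) contactProbabilities(map) else map
  tab <- data.frame(residue = rownames(M), M, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
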