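# Metadynamics engine: bias bookkeeping, hill deposition, free-energy
# reconstruction, convergence diagnostics and the HILLS/FES text dialects.

#' Construct a metadynamics bias state
#'
#' An empty (or pre-seeded) hill list plus the deposition rule. In standard
#' mode every hill has height `baseHeight`; in well-tempered mode heights
#' decay as \eqn{w_0 \exp(-V(s,t)/(k_B \Delta T))} with
#' \eqn{\Delta T = (\gamma - 1) T}, and the free energy is the bias scaled
#' by \eqn{-(T+\Delta T)/\Delta T = -\gamma/(\gamma-1)}.
#'
#' @param cvNames CV labels (their count fixes the bias dimensionality).
#' @param temperature K.
#' @param wellTempered logical.
#' @param biasFactor \eqn{\gamma > 1}; required when well-tempered.
#' @param baseHeight initial hill height \eqn{w_0}, kJ/mol.
#' @param sigma per-CV Gaussian widths for deposited hills. Defaults: 0.05
#'   nm for a radius-of-gyration CV, 0.5 for a contact-number CV, 0.1
#'   otherwise.
#' @param depositionStride integration steps between depositions.
#' @return a [BiasState-class] with no hills.
#' @export
#' @examples
#' biasState("cv1", wellTempered = TRUE, biasFactor = 10)
biasState <- function(cvNames, temperature = 298, wellTempered = TRUE,
                      biasFactor = if (wellTempered) 10 else NA_real_,
                      baseHeight = 1.0, sigma = NULL,
                      depositionStride = 500L) {
  d <- length(cvNames)
  if (is.null(sigma))
    sigma <- ifelse(cvNames == "rg", 0.05,
                    ifelse(cvNames == "contact_number", 0.5, 0.1))
  new("BiasState",
      centers = matrix(0, 0, d), widths = matrix(0, 0, d),
      heights = numeric(0), times = numeric(0),
      temperature = temperature, wellTempered = wellTempered,
      biasFactor = as.numeric(biasFactor), baseHeight = baseHeight,
      sigma = as.numeric(sigma),
      depositionStride = as.integer(depositionStride), cvNames = cvNames)
}

#' Bias energy at CV points
#'
#' \eqn{V(s,t) = \sum_{t_k \le t} w_k \exp(-\sum_d (s_d - c_{k,d})^2 /
#' (2\sigma_{k,d}^2))}. Non-negative and non-decreasing in t at fixed s
#' (hills only add).
#'
#' @param state a [BiasState-class].
#' @param s CV point(s): vector or matrix `[point, cv]`.
#' @param t time cutoff (ps); hills deposited after `t` are excluded.
#'   Default includes all hills.
#' @return numeric vector of energies, kJ/mol.
#' @export
biasEnergy <- function(state, s, t = Inf) {
  s <- .asPoints(s, ncol(state@centers))
  cpp_bias_eval(state@centers, state@widths, state@heights, state@times,
                s, t, FALSE)$energy
}

#' @rdname biasEnergy
#' @return for `biasGradient`, a matrix `[point, cv]` of analytic
#'   derivatives dV/ds.
#' @export
biasGradient <- function(state, s, t = Inf) {
  s <- .asPoints(s, ncol(state@centers))
  cpp_bias_eval(state@centers, state@widths, state@heights, state@times,
                s, t, TRUE)$gradient
}

.asPoints <- function(s, d) {
  if (is.matrix(s)) {
    if (ncol(s) != d) stop("CV dimension mismatch: expected ", d, " columns")
    s
  } else {
    if (length(s) %% d != 0)
      stop("CV dimension mismatch: expected multiples of ", d, " values")
    matrix(s, ncol = d, byrow = TRUE)
  }
}

#' Deposit a hill at the current CV position
#'
#' Appends a Gaussian at `s` with the state's widths. Height is
#' `baseHeight` in standard mode and
#' \eqn{w_0 \exp(-V(s,t)/(k_B (\gamma - 1) T))} in well-tempered mode, so
#' the first hill at a fresh point has height exactly \eqn{w_0} and heights
#' at a revisited point are non-increasing.
#'
#' @param state a [BiasState-class].
#' @param s CV vector.
#' @param t deposition time (ps), not before the last hill.
#' @return the updated [BiasState-class].
#' @export
depositHill <- function(state, s, t) {
  d <- ncol(state@centers)
  s <- as.numeric(s)
  if (length(s) != d) stop("CV dimension mismatch")
  w <- state@baseHeight
  if (state@wellTempered) {
    V <- biasEnergy(state, s, t)
    w <- w * exp(-V / (.kB * (state@biasFactor - 1) * state@temperature))
  }
  state@centers <- rbind(state@centers, s)
  state@widths <- rbind(state@widths, state@sigma)
  state@heights <- c(state@heights, w)
  state@times <- c(state@times, t)
  validObject(state)
  state
}

#' Run metadynamics on a landscape or bead chain
#'
#' Couples the BAOAB Langevin sampler with hill deposition every
#' `depositionStride` steps of the bias state. Seed-deterministic: the same
#' (system, config, bias) gives identical trajectories and hill lists.
#'
#' @param system an [AnalyticLandscape-class] or [BeadChain-class].
#' @param config a [SimulationConfig-class].
#' @param bias a [BiasState-class] carrying the deposition rule; its CV
#'   count must match the system (landscape dimension, or 2 for chains:
#'   radius of gyration and contact number). May already contain hills, in
#'   which case the run continues from that bias.
#' @param start,cvdefs,gridBins as in [langevinSample()].
#' @return list with `trajectory`, `cv` and the final `bias`.
#' @export
runMetadynamics <- function(system, config, bias, start = NULL,
                            cvdefs = NULL, gridBins = NULL) {
  stopifnot(is(bias, "BiasState"))
  if (is(system, "AnalyticLandscape")) {
    if (ncol(bias@centers) != system@dimension)
      stop("bias CV count must equal the landscape dimension")
    .runLandscape(system, config, bias = bias, metad = TRUE, start = start,
                  gridBins = gridBins %||% 201L)
  } else if (is(system, "BeadChain")) {
    if (ncol(bias@centers) != 2L)
      stop("chain metadynamics biases the (rg, contact_number) CV pair")
    .runChain(system, config, bias = bias, metad = TRUE, start = start,
              cvdefs = cvdefs, gridBins = gridBins %||% c(161L, 161L))
  } else stop("unsupported system class ", class(system))
}

.gridAxes <- function(state, grid = NULL, bins = 100L) {
  d <- ncol(state@centers)
  if (is(grid, "FESGrid")) return(grid@axes)
  if (is.list(grid) && !is.null(grid)) return(grid)
  if (nHills(state) == 0) stop("cannot infer a grid from an empty hill list")
  lapply(seq_len(d), function(j) {
    lo <- min(state@centers[, j]) - 5 * max(state@widths[, j])
    hi <- max(state@centers[, j]) + 5 * max(state@widths[, j])
    seq(lo, hi, length.out = bins)
  })
}

#' Reconstruct the free-energy surface from the deposited bias
#'
#' Standard metadynamics: \eqn{F(s) = -V(s, t_{end})}. Well-tempered:
#' \eqn{F(s) = -\gamma/(\gamma-1)\, V(s, t_{end})} (the
#' \eqn{(T+\Delta T)/\Delta T} prefactor, which tends to 1 as
#' \eqn{\gamma \to \infty}). The surface is shifted so its minimum is
#' exactly 0.
#'
#' @param state a [BiasState-class] with at least one hill.
#' @param grid list of axis vectors, an [FESGrid-class] whose axes are
#'   reused, or NULL to span the hill centers +/- 5 sigma.
#' @param bins nodes per axis when the grid is inferred.
#' @param t time cutoff; hills after `t` are ignored.
#' @return an [FESGrid-class].
#' @export
reconstructFES <- function(state, grid = NULL, bins = 100L, t = Inf) {
  if (nHills(state) == 0) stop("empty hill list")
  axes <- .gridAxes(state, grid, bins)
  pts <- as.matrix(expand.grid(axes))
  V <- cpp_bias_eval(state@centers, state@widths, state@heights,
                     state@times, pts, t, FALSE)$energy
  fac <- .fesFactor(state)
  F <- -fac * V
  F <- F - min(F)
  F[F < 0] <- 0
  new("FESGrid", axes = axes,
      values = array(F, dim = vapply(axes, length, 1L)),
      cvNames = state@cvNames)
}

.fesFactor <- function(state) {
  if (state@wellTempered) state@biasFactor / (state@biasFactor - 1) else 1
}

#' Free-energy estimates from hill prefixes
#'
#' Rebuilds the (unshifted, sign-corrected) free-energy estimate
#' \eqn{F_k(s)} from the first k hills, for each requested k, by
#' incremental accumulation. Used by convergence diagnostics and
#' time-averaged barrier estimates.
#'
#' @param state a [BiasState-class].
#' @param grid list of axis vectors (see [reconstructFES()]).
#' @param at increasing hill counts k at which to record the estimate.
#' @param bins grid resolution when inferred.
#' @return matrix `[length(at), grid nodes]` of F values (not min-shifted),
#'   with the flattened grid in `expand.grid` order.
#' @export
hillPrefixFES <- function(state, grid = NULL, at = nHills(state),
                          bins = 100L) {
  m <- nHills(state)
  at <- sort(unique(as.integer(at)))
  if (!length(at) || min(at) < 1L || max(at) > m)
    stop("'at' must index existing hills")
  axes <- .gridAxes(state, grid, bins)
  pts <- as.matrix(expand.grid(axes))
  fac <- .fesFactor(state)
  V <- numeric(nrow(pts))
  out <- matrix(NA_real_, length(at), nrow(pts))
  ptr <- 1L
  for (k in seq_len(max(at))) {
    e <- rowSums((pts - matrix(state@centers[k, ], nrow(pts),
                               ncol(pts), byrow = TRUE))^2 /
                   matrix(2 * state@widths[k, ]^2, nrow(pts), ncol(pts),
                          byrow = TRUE))
    V <- V + state@heights[k] * exp(-e)
    if (ptr <= length(at) && k == at[ptr]) {
      out[ptr, ] <- -fac * V
      ptr <- ptr + 1L
    }
  }
  attr(out, "axes") <- axes
  out
}

#' Block convergence diagnostic
#'
#' Splits the hill list into `nBlocks` equal prefixes, rebuilds the FES
#' from each, and reports the maximum absolute deviation between
#' successive estimates over the low-free-energy region of the final
#' surface (F below `mask` kJ/mol), after aligning each estimate by its
#' mean over that region. Decaying deviations indicate a converged run.
#'
#' @param state a [BiasState-class].
#' @param grid list of axis vectors or NULL (inferred).
#' @param nBlocks number of prefixes (>= 2).
#' @param mask free-energy threshold (kJ/mol) defining the region scored.
#' @param bins grid resolution when inferred.
#' @return numeric vector of `nBlocks - 1` successive deviations (kJ/mol).
#' @export
blockConvergence <- function(state, grid = NULL, nBlocks = 5L, mask = 10,
                             bins = 100L) {
  m <- nHills(state)
  if (nBlocks < 2L) stop("nBlocks must be >= 2")
  if (m < nBlocks) stop("fewer hills than blocks")
  at <- unique(round(seq_len(nBlocks) * m / nBlocks))
  est <- hillPrefixFES(state, grid, at = at, bins = bins)
  final <- est[nrow(est), ]
  low <- final - min(final) < mask
  aligned <- est[, low, drop = FALSE]
  aligned <- aligned - rowMeans(aligned)
  vapply(seq_len(nrow(aligned) - 1L), function(b)
    max(abs(aligned[b + 1L, ] - aligned[b, ])), 0.0)
}

#' Time-averaged barrier estimate from a 1D metadynamics run
#'
#' For a symmetric double-well CV, estimates the barrier as
#' `F(at) - min(F)` from the hill-prefix free-energy estimate, averaged
#' over the last `fraction` of depositions. Averaging over late
#' depositions suppresses the hill-sized oscillation of standard
#' metadynamics around the converged profile.
#'
#' @param state a 1D [BiasState-class].
#' @param grid list with one axis vector (see [reconstructFES()]).
#' @param at CV position of the barrier top (default 0).
#' @param fraction trailing fraction of depositions averaged (default 0.2).
#' @return the averaged barrier estimate, kJ/mol.
#' @export
barrierEstimate <- function(state, grid = NULL, at = 0, fraction = 0.2) {
  if (ncol(state@centers) != 1L) stop("barrierEstimate expects a 1D bias")
  m <- nHills(state)
  ks <- seq.int(max(1L, ceiling((1 - fraction) * m)), m)
  est <- hillPrefixFES(state, grid, at = ks)
  axis <- attr(est, "axes")[[1]]
  itop <- which.min(abs(axis - at))
  mean(est[, itop] - apply(est, 1, min))
}

#' Write hills in the PLUMED-style HILLS dialect
#'
#' Header `#! FIELDS time <cv...> sigma_<cv...> height biasf`; one row per
#' hill, 6 decimals. `biasf` is the bias factor (1 for standard runs).
#'
#' @param state a [BiasState-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHills <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS time",
                   paste(state@cvNames, collapse = " "),
                   paste(paste0("sigma_", state@cvNames), collapse = " "),
                   "height biasf"), con)
  bf <- if (state@wellTempered) state@biasFactor else 1
  if (nHills(state) > 0) {
    tab <- cbind(state@times, state@centers, state@widths, state@heights,
                 bf)
    writeLines(apply(tab, 1, function(r)
      paste(sprintf("%.6f", r), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a HILLS-dialect file
#'
#' @param path file path.
#' @param temperature K assigned to the returned state.
#' @param depositionStride stride recorded in the returned state.
#' @return a [BiasState-class]; well-tempered if the file's `biasf`
#'   column exceeds 1.
#' @export
readHills <- function(path, temperature = 298, depositionStride = 500L) {
  lines <- readLines(path)
  hdr <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  if (!length(hdr)) stop("malformed HILLS: missing '#! FIELDS' header")
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", hdr[1])), "\\s+")[[1]]
  sig <- grep("^sigma_", fields)
  if (fields[1] != "time" || !length(sig) ||
      !all(c("height", "biasf") %in% fields))
    stop("malformed HILLS header: expected time, cv, sigma_cv, height, biasf")
  cvNames <- sub("^sigma_", "", fields[sig])
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(body))
    stop("empty HILLS file: no hills to read")
  tab <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (ncol(tab) != length(fields))
    stop("malformed HILLS row: column count does not match FIELDS")
  d <- length(cvNames)
  bf <- tab[1, match("biasf", fields)]
  wt <- isTRUE(bf > 1)
  new("BiasState",
      centers = tab[, 2:(1 + d), drop = FALSE],
      widths = tab[, sig, drop = FALSE],
      heights = tab[, match("height", fields)],
      times = tab[, 1],
      temperature = temperature, wellTempered = wt,
      biasFactor = if (wt) bf else NA_real_,
      baseHeight = max(tab[, match("height", fields)]),
      sigma = as.numeric(tab[1, sig]),
      depositionStride = as.integer(depositionStride), cvNames = cvNames)
}

#' Write a free-energy surface as a whitespace table
#'
#' One row per grid node: CV coordinates then F (kJ/mol); `#` header lines
#' carry the axis metadata.
#'
#' @param fes an [FESGrid-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFESTable <- function(fes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# FES:", paste(fes@cvNames, collapse = " "),
                   "free_energy_kjmol"), con)
  for (j in seq_along(fes@axes))
    writeLines(sprintf("# axis %s: min %.6f max %.6f nbins %d",
                       fes@cvNames[j], min(fes@axes[[j]]),
                       max(fes@axes[[j]]), length(fes@axes[[j]])), con)
  pts <- as.matrix(expand.grid(fes@axes))
  tab <- cbind(pts, as.numeric(fes@values))
  writeLines(apply(tab, 1, function(r)
    paste(sprintf("%.6f", r), collapse = " ")), con)
  invisible(path)
}

#' Read a free-energy surface table written by [writeFESTable()]
#'
#' @param path file path.
#' @return an [FESGrid-class].
#' @export
readFESTable <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# axis ", lines, value = TRUE)
  if (!length(meta)) stop("malformed FES table: missing axis metadata")
  cvNames <- sub("^# axis (\\S+):.*$", "\\1", meta)
  axes <- lapply(meta, function(l) {
    v <- as.numeric(sub("^.*min (\\S+) max (\\S+) nbins (\\d+)$",
                        "\\1 \\2 \\3", l) |> strsplit(" ") |> unlist())
    seq(v[1], v[2], length.out = v[3])
  })
  body <- lines[!startsWith(lines, "#")]
  tab <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  F <- tab[, ncol(tab)]
  F <- F - min(F)
  F[F < 0] <- 0
  new("FESGrid", axes = axes,
      values = array(F, dim = vapply(axes, length, 1L)), cvNames = cvNames)
}
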