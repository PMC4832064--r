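# S4 containers for the pipeline stages. Validity methods enforce the
# structural invariants each downstream stage relies on.

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "K", "L",
          "M", "F", "P", "S", "T", "W", "Y", "V")

#' Annotated peptide sequence
#'
#' One-letter residue codes with per-residue phospho flags and an absolute
#' numbering anchor, so that e.g. the fifth residue of a segment anchored at
#' 99 is residue 103.
#'
#' @slot residues character vector of one-letter amino-acid codes.
#' @slot phospho logical vector; `TRUE` only on S, T or Y residues.
#' @slot startNumber absolute residue number of the first residue.
#' @export
setClass("PeptideSeq",
  representation(residues = "character", phospho = "logical",
                 startNumber = "integer"))

setValidity("PeptideSeq", function(object) {
  if (length(object@residues) < 1L) return("sequence must have length >= 1")
  if (length(object@phospho) != length(object@residues))
    return("phospho flags and residues differ in length")
  bad <- setdiff(unique(object@residues), .AA1)
  if (length(bad))
    return(paste0("unknown residue code(s): ", paste(bad, collapse = ", ")))
  if (any(object@phospho & !(object@residues %in% c("S", "T", "Y"))))
    return("phospho flag set on a residue other than S, T or Y")
  if (length(object@startNumber) != 1L || is.na(object@startNumber))
    return("startNumber must be a single integer")
  TRUE
})

#' Analytic energy landscape with exactly known free-energy surface
#'
#' Oracle stage: a potential defined directly in CV space, whose free-energy
#' surface is the potential itself up to an additive constant. Families:
#' `double_well` (quartic, 1D), `gaussian_mixture` (sum of inverted
#' Gaussians, 1D/2D) and `harmonic` (1D/2D).
#'
#' @slot dimension 1 or 2.
#' @slot family one of `"double_well"`, `"gaussian_mixture"`, `"harmonic"`.
#' @slot parameters family-specific coefficient list (kJ/mol, CV units).
#' @slot domain numeric matrix with rows `lo`, `hi` and one column per
#'   dimension; soft walls confine sampling to this box.
#' @export
setClass("AnalyticLandscape",
  representation(dimension = "integer", family = "character",
                 parameters = "list", domain = "matrix"))

setValidity("AnalyticLandscape", function(object) {
  if (!object@dimension %in% 1:2) return("dimension must be 1 or 2")
  if (!object@family %in% c("double_well", "gaussian_mixture", "harmonic"))
    return("unknown landscape family")
  if (!all(dim(object@domain) == c(2L, object@dimension)))
    return("domain must be a 2 x dimension matrix (rows lo, hi)")
  if (any(object@domain[2, ] <= object@domain[1, ]))
    return("domain upper bounds must exceed lower bounds")
  TRUE
})

#' Coarse-grained charged bead chain
#'
#' One bead per residue at the C-alpha position; consecutive beads bonded
#' harmonically, non-bonded beads interact through soft excluded volume and
#' screened (Debye-Hueckel) Coulomb forces. Bead charges follow the
#' sequence-module formal charge table, so a phospho and an unphospho chain
#' built from the same segment differ only in the phospho bead's charge.
#'
#' @slot masses amu, per bead.
#' @slot charges elementary charges, per bead.
#' @slot radii excluded-volume radii (nm), per bead.
#' @slot bondLength equilibrium bond length (nm).
#' @slot bondStiffness bond force constant (kJ/mol/nm^2).
#' @slot dielectric relative dielectric constant of the screened Coulomb term.
#' @slot screeningLength Debye screening length (nm).
#' @slot repulsionStiffness excluded-volume force constant (kJ/mol/nm^2).
#' @slot sourceSeq the [PeptideSeq-class] the chain was built from.
#' @export
setClass("BeadChain",
  representation(masses = "numeric", charges = "numeric", radii = "numeric",
                 bondLength = "numeric", bondStiffness = "numeric",
                 dielectric = "numeric", screeningLength = "numeric",
                 repulsionStiffness = "numeric", sourceSeq = "PeptideSeq"))

setValidity("BeadChain", function(object) {
  n <- length(object@masses)
  if (n < 1L) return("chain needs at least one bead")
  if (length(object@charges) != n || length(object@radii) != n)
    return("masses, charges and radii must have one entry per bead")
  if (any(object@masses <= 0) || any(object@radii <= 0))
    return("masses and radii must be positive")
  if (object@bondLength <= 0 || object@bondStiffness <= 0)
    return("bond parameters must be positive")
  if (n != length(object@sourceSeq@residues))
    return("one bead per residue of the source sequence is required")
  TRUE
})

#' Langevin sampling configuration
#'
#' @slot temperature K.
#' @slot friction 1/ps.
#' @slot timestep ps.
#' @slot nSteps number of integration steps.
#' @slot seed RNG seed, recorded into outputs.
#' @slot saveStride frames are stored every `saveStride` steps.
#' @export
setClass("SimulationConfig",
  representation(temperature = "numeric", friction = "numeric",
                 timestep = "numeric", nSteps = "integer", seed = "integer",
                 saveStride = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@temperature < 0) return("temperature must be >= 0")
  for (s in c("friction", "timestep"))
    if (slot(object, s) <= 0) return(paste(s, "must be positive"))
  if (object@nSteps < 0L) return("nSteps must be >= 0")
  if (object@saveStride < 1L) return("saveStride must be >= 1")
  TRUE
})

#' Trajectory of a sampled system
#'
#' @slot times frame times (ps), uniformly spaced by
#'   `saveStride * timestep`.
#' @slot coords array `[bead, xyz-or-cv, frame]`.
#' @slot metadata list echoing the configuration (temperature, seed, ...).
#' @export
setClass("Trajectory",
  representation(times = "numeric", coords = "array", metadata = "list"))

setValidity("Trajectory", function(object) {
  if (length(dim(object@coords)) != 3L)
    return("coords must be a 3-way array [bead, coordinate, frame]")
  if (dim(object@coords)[3] != length(object@times))
    return("frame count of coords and times disagree")
  if (length(object@times) > 1) {
    dt <- diff(object@times)
    if (max(abs(dt - dt[1])) > 1e-8 * max(abs(dt), 1e-12))
      return("frame times must be uniformly spaced")
  }
  TRUE
})

#' Collective variable definition
#'
#' @slot kind `"radius_of_gyration"`, `"contact_number"`, `"distance"` or
#'   `"coordinate"` (the identity CV of analytic landscapes).
#' @slot selection 1-based bead indices the CV acts on.
#' @slot massWeighted logical; radius of gyration only.
#' @slot switching list `r0` (nm), `n`, `m` for the rational switching
#'   function; contact number only.
#' @slot exclusion minimum sequence separation `|i - j|` counted;
#'   contact number only.
#' @export
setClass("CVDefinition",
  representation(kind = "character", selection = "integer",
                 massWeighted = "logical", switching = "list",
                 exclusion = "integer"))

setValidity("CVDefinition", function(object) {
  if (!object@kind %in% c("radius_of_gyration", "contact_number",
                          "distance", "coordinate"))
    return("unknown CV kind")
  if (object@kind != "coordinate" && length(object@selection) < 1L)
    return("selection must be non-empty")
  if (object@kind == "contact_number") {
    sw <- object@switching
    if (!all(c("r0", "n", "m") %in% names(sw)))
      return("contact_number needs switching parameters r0, n, m")
    if (sw$r0 <= 0) return("r0 must be positive")
    if (!(sw$m > sw$n && sw$n > 0))
      return("switching exponents must satisfy m > n > 0")
    if (object@exclusion < 1L) return("exclusion must be >= 1")
    if (length(object@selection) < 2L)
      return("contact_number needs at least two beads")
  }
  if (object@kind == "distance" && length(object@selection) != 2L)
    return("distance CV needs exactly two beads")
  TRUE
})

#' Frame-aligned collective-variable time series
#'
#' @slot times ps, one per frame.
#' @slot values matrix `[frame, cv]`.
#' @slot cvNames column labels (also used in COLVAR headers).
#' @export
setClass("CVSeries",
  representation(times = "numeric", values = "matrix", cvNames = "character"))

setValidity("CVSeries", function(object) {
  if (nrow(object@values) != length(object@times))
    return("values and times differ in frame count")
  if (ncol(object@values) != length(object@cvNames))
    return("one name per CV column is required")
  if (any(!is.finite(object@values))) return("CV values must be finite")
  TRUE
})

#' Metadynamics bias state
#'
#' The accumulated bias \eqn{V(s,t) = \sum_{t_k \le t} w_k
#' \exp(-\sum_d (s_d - c_{k,d})^2 / (2\sigma_{k,d}^2))} as an ordered hill
#' list, plus the deposition rule parameters.
#'
#' @slot centers matrix `[hill, cv]` of Gaussian centers.
#' @slot widths matrix `[hill, cv]` of Gaussian sigmas.
#' @slot heights hill heights w (kJ/mol).
#' @slot times deposition times (ps), non-decreasing.
#' @slot temperature K.
#' @slot wellTempered logical; if `TRUE`, heights decay as
#'   \eqn{w_0 \exp(-V/(k_B \Delta T))} with \eqn{\Delta T = (\gamma-1) T}.
#' @slot biasFactor \eqn{\gamma > 1} (NA when not well-tempered).
#' @slot baseHeight \eqn{w_0} (kJ/mol).
#' @slot sigma per-CV widths used for newly deposited hills.
#' @slot depositionStride steps between depositions.
#' @slot cvNames CV labels.
#' @export
setClass("BiasState",
  representation(centers = "matrix", widths = "matrix", heights = "numeric",
                 times = "numeric", temperature = "numeric",
                 wellTempered = "logical", biasFactor = "numeric",
                 baseHeight = "numeric", sigma = "numeric",
                 depositionStride = "integer", cvNames = "character"))

setValidity("BiasState", function(object) {
  m <- nrow(object@centers)
  if (nrow(object@widths) != m || length(object@heights) != m ||
      length(object@times) != m)
    return("centers, widths, heights and times must agree in hill count")
  if (m > 0 && any(object@widths <= 0)) return("hill widths must be positive")
  if (m > 0 && any(object@heights < 0)) return("hill heights must be >= 0")
  if (m > 1 && any(diff(object@times) < 0))
    return("hills must be time-ordered")
  if (object@wellTempered && !(isTRUE(object@biasFactor > 1)))
    return("well-tempered mode requires bias factor gamma > 1")
  TRUE
})

#' Free-energy surface on a CV grid
#'
#' @slot axes list of uniform per-CV grid vectors.
#' @slot values F in kJ/mol, vector (1D) or matrix (2D) shaped like the
#'   axes; minimum shifted to exactly 0.
#' @slot cvNames axis labels.
#' @export
setClass("FESGrid",
  representation(axes = "list", values = "array", cvNames = "character"))

setValidity("FESGrid", function(object) {
  dims <- vapply(object@axes, length, 1L)
  if (!all(dim(object@values) == dims))
    return("values shape must match axis lengths")
  if (any(!is.finite(object@values))) return("F must be finite on the grid")
  if (abs(min(object@values)) > 1e-9)
    return("minimum must be shifted to exactly 0")
  TRUE
})

#' Normalized per-frame reweighting weights
#'
#' @slot weights non-negative, summing to 1.
#' @slot method `"uniform"`, `"static_bias"` or `"time_dependent"`.
#' @slot temperature K used for beta = 1/(kB T).
#' @export
setClass("FrameWeights",
  representation(weights = "numeric", method = "character",
                 temperature = "numeric"))

setValidity("FrameWeights", function(object) {
  if (any(!is.finite(object@weights)) || any(object@weights < 0))
    return("weights must be finite and non-negative")
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("weights must sum to 1 within 1e-9")
  TRUE
})

#' Weighted conformational clustering result
#'
#' @slot assignment 1-based cluster id per frame; clusters ordered by
#'   descending population.
#' @slot populations weighted population per cluster, percent.
#' @slot freeEnergies \eqn{F_i = -k_B T \ln p_i}, kJ/mol, shifted so the
#'   most populated cluster sits at 0 (NA until
#'   [clusterFreeEnergies()] fills them).
#' @slot representatives frame index of each cluster's centre.
#' @slot metric `"rmsd"` or `"cv_space"`.
#' @slot cutoff clustering cutoff (nm for rmsd, CV units otherwise).
#' @export
setClass("ClusterSet",
  representation(assignment = "integer", populations = "numeric",
                 freeEnergies = "numeric", representatives = "integer",
                 metric = "character", cutoff = "numeric"))

setValidity("ClusterSet", function(object) {
  k <- length(object@populations)
  if (length(object@representatives) != k)
    return("one representative per cluster required")
  if (length(object@assignment) &&
      (min(object@assignment) < 1L || max(object@assignment) > k))
    return("assignment refers to a missing cluster id")
  if (abs(sum(object@populations) - 100) > 1e-6)
    return("populations must sum to 100% within 1e-6")
  if (k > 1 && any(diff(object@populations) > 1e-12))
    return("clusters must be ordered by descending population")
  TRUE
})

#' Residue-pair contact-probability map
#'
#' @slot labels residue labels (code + absolute number).
#' @slot probabilities symmetric matrix of weighted contact probabilities in
#'   `[0, 1]`; diagonal band `|i - j| < exclusion` is NA.
#' @slot condition free-text condition tag (e.g. `"phospho"`).
#' @slot cutoff contact distance cutoff (nm).
#' @slot exclusion minimum `|i - j|` reported.
#' @export
setClass("ContactMap",
  representation(labels = "character", probabilities = "matrix",
                 condition = "character", cutoff = "numeric",
                 exclusion = "integer"))

setValidity("ContactMap", function(object) {
  p <- object@probabilities
  n <- length(object@labels)
  if (!all(dim(p) == c(n, n))) return("matrix must be labels x labels")
  off <- p[!is.na(p)]
  if (any(off < -1e-12 | off > 1 + 1e-12))
    return("probabilities must lie in [0, 1]")
  if (max(abs(p - t(p)), na.rm = TRUE) > 1e-9)
    return("matrix must be symmetric")
  TRUE
})
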