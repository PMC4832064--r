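# Generics and accessors. Slot access from user code should go through
# these rather than @.

#' @rdname PeptideSeq-accessors
#' @param x a [PeptideSeq-class]
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname PeptideSeq-accessors
#' @export
setGeneric("phosphoFlags", function(x) standardGeneric("phosphoFlags"))

#' @rdname PeptideSeq-accessors
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))

#' @rdname PeptideSeq-accessors
#' @export
setGeneric("startNumber", function(x) standardGeneric("startNumber"))

#' Accessors for annotated peptide sequences
#'
#' `residues()` returns the one-letter codes, `phosphoFlags()` the logical
#' phospho annotation, `residueNumbers()` the absolute numbering
#' (`startNumber + 0:(n-1)`) and `startNumber()` the anchor.
#'
#' @name PeptideSeq-accessors
#' @aliases residues,PeptideSeq-method phosphoFlags,PeptideSeq-method
#'   residueNumbers,PeptideSeq-method startNumber,PeptideSeq-method
#' @examples
#' p <- parsePeptide("APNS{pT}P", 99)
#' residueNumbers(p)[phosphoFlags(p)]  # 103
NULL

setMethod("residues", "PeptideSeq", function(x) x@residues)
setMethod("phosphoFlags", "PeptideSeq", function(x) x@phospho)
setMethod("residueNumbers", "PeptideSeq",
          function(x) x@startNumber + seq_along(x@residues) - 1L)
setMethod("startNumber", "PeptideSeq", function(x) x@startNumber)

#' @describeIn PeptideSeq-accessors number of residues
#' @export
setMethod("length", "PeptideSeq", function(x) length(x@residues))

#' Frame times of an object carrying a trajectory axis
#' @param x a [Trajectory-class] or [CVSeries-class]
#' @return numeric vector of times in ps
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
setMethod("frameTimes", "Trajectory", function(x) x@times)
setMethod("frameTimes", "CVSeries", function(x) x@times)

#' Coordinates of a trajectory
#' @param x a [Trajectory-class]
#' @return array `[bead, coordinate, frame]` in nm
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
setMethod("coords", "Trajectory", function(x) x@coords)

#' Number of frames
#' @param x a [Trajectory-class] or [CVSeries-class]
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
setMethod("nFrames", "Trajectory", function(x) length(x@times))
setMethod("nFrames", "CVSeries", function(x) length(x@times))

#' CV values of a series
#' @param x a [CVSeries-class]
#' @return matrix `[frame, cv]` with named columns
#' @export
setGeneric("cvValues", function(x) standardGeneric("cvValues"))
setMethod("cvValues", "CVSeries", function(x) {
  v <- x@values
  colnames(v) <- x@cvNames
  v
})

#' Hills of a bias state as a data frame
#' @param x a [BiasState-class]
#' @return data.frame with time, one center and sigma column per CV, and
#'   height
#' @export
setGeneric("hills", function(x) standardGeneric("hills"))
setMethod("hills", "BiasState", function(x) {
  d <- ncol(x@centers)
  out <- data.frame(time = x@times)
  for (j in seq_len(d)) out[[x@cvNames[j]]] <- x@centers[, j]
  for (j in seq_len(d)) out[[paste0("sigma_", x@cvNames[j])]] <- x@widths[, j]
  out$height <- x@heights
  out
})

#' @describeIn hills number of deposited hills
#' @export
setGeneric("nHills", function(x) standardGeneric("nHills"))
setMethod("nHills", "BiasState", function(x) length(x@heights))

#' Free-energy values and axes of a grid
#' @param x an [FESGrid-class]
#' @export
setGeneric("fesValues", function(x) standardGeneric("fesValues"))
setMethod("fesValues", "FESGrid", function(x) x@values)

#' @rdname fesValues
#' @export
setGeneric("fesAxes", function(x) standardGeneric("fesAxes"))
setMethod("fesAxes", "FESGrid", function(x) x@axes)

#' Normalized weights of a reweighting result
#' @param x a [FrameWeights-class]
#' @export
setGeneric("frameWeights", function(x) standardGeneric("frameWeights"))
setMethod("frameWeights", "FrameWeights", function(x) x@weights)

#' Cluster accessors
#' @param x a [ClusterSet-class]
#' @name ClusterSet-accessors
NULL

#' @rdname ClusterSet-accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
setMethod("assignments", "ClusterSet", function(x) x@assignment)

#' @rdname ClusterSet-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
setMethod("populations", "ClusterSet", function(x) x@populations)

#' @rdname ClusterSet-accessors
#' @export
setGeneric("freeEnergies", function(x) standardGeneric("freeEnergies"))
setMethod("freeEnergies", "ClusterSet", function(x) x@freeEnergies)

#' @rdname ClusterSet-accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
setMethod("representatives", "ClusterSet", function(x) x@representatives)

#' Contact probabilities of a map
#' @param x a [ContactMap-class]
#' @return symmetric matrix with residue labels as dimnames
#' @export
setGeneric("contactProbabilities",
           function(x) standardGeneric("contactProbabilities"))
setMethod("contactProbabilities", "ContactMap", function(x) {
  p <- x@probabilities
  dimnames(p) <- list(x@labels, x@labels)
  p
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "PeptideSeq", function(object) {
  n <- length(object@residues)
  cat(sprintf("PeptideSeq: %d residues, numbered %d-%d\n", n,
              object@startNumber, object@startNumber + n - 1L))
  cat("  ", formatPeptide(object), "\n", sep = "")
  np <- sum(object@phospho)
  if (np)
    cat("  phospho at:",
        paste0("p", object@residues[object@phospho],
               residueNumbers(object)[object@phospho], collapse = ", "),
        "\n")
  cat(sprintf("  net charge: %+g e\n", netCharge(object)))
})

setMethod("show", "AnalyticLandscape", function(object) {
  cat(sprintf("AnalyticLandscape: %s, %dD, domain [%s]\n", object@family,
              object@dimension,
              paste(sprintf("%g..%g", object@domain[1, ], object@domain[2, ]),
                    collapse = " x ")))
})

setMethod("show", "BeadChain", function(object) {
  cat(sprintf("BeadChain: %d beads, net charge %+g e, bond %g nm (k = %g)\n",
              length(object@masses), sum(object@charges),
              object@bondLength, object@bondStiffness))
  cat(sprintf("  Debye-Hueckel: eps_r = %g, screening length %g nm\n",
              object@dielectric, object@screeningLength))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d frames, %d beads x %d coords, t = %g..%g ps\n",
              d[3], d[1], d[2], object@times[1],
              object@times[length(object@times)]))
})

setMethod("show", "BiasState", function(object) {
  cat(sprintf("BiasState: %d hills over CVs (%s), %s\n",
              nHills(object), paste(object@cvNames, collapse = ", "),
              if (object@wellTempered)
                sprintf("well-tempered (gamma = %g)", object@biasFactor)
              else "standard"))
  cat(sprintf("  w0 = %g kJ/mol, T = %g K\n", object@baseHeight,
              object@temperature))
})

setMethod("show", "FESGrid", function(object) {
  dims <- vapply(object@axes, length, 1L)
  cat(sprintf("FESGrid over (%s): %s nodes, F range 0..%.3f kJ/mol\n",
              paste(object@cvNames, collapse = ", "),
              paste(dims, collapse = " x "), max(object@values)))
})

setMethod("show", "FrameWeights", function(object) {
  w <- object@weights
  ess <- 1 / sum(w^2)
  cat(sprintf("FrameWeights: %d frames, method '%s', effective sample size %.1f\n",
              length(w), object@method, ess))
})

setMethod("show", "ClusterSet", function(object) {
  k <- length(object@populations)
  cat(sprintf("ClusterSet: %d clusters from %d frames (%s, cutoff %g)\n",
              k, length(object@assignment), object@metric, object@cutoff))
  top <- head(seq_len(k), 5L)
  for (i in top)
    cat(sprintf("  #%d: %6.2f%%  F = %s kJ/mol  (rep frame %d)\n", i,
                object@populations[i],
                ifelse(is.na(object@freeEnergies[i]), "NA",
                       sprintf("%.2f", object@freeEnergies[i])),
                object@representatives[i]))
  if (k > 5L) cat(sprintf("  ... and %d more\n", k - 5L))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap (%s): %d residues, cutoff %g nm, |i-j| >= %d\n",
              object@condition, length(object@labels), object@cutoff,
              object@exclusion))
  p <- object@probabilities
  cat(sprintf("  max contact probability: %.3f\n", max(p, na.rm = TRUE)))
})
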