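# Collective variables: radius of gyration, contact number with a rational
# switching function, CV-series evaluation and the COLVAR text dialect.

#' Construct a collective-variable definition
#'
#' @param kind `"radius_of_gyration"`, `"contact_number"`, `"distance"` or
#'   `"coordinate"`.
#' @param selection 1-based bead indices.
#' @param massWeighted logical, radius of gyration only (default TRUE).
#' @param switching list `r0` (nm), `n`, `m`; contact number only. The
#'   defaults r0 = 0.65 nm, n = 6, m = 12 are typical C-alpha contact
#'   settings.
#' @param exclusion minimum `|i - j|` counted (contact number; default 3).
#' @return a [CVDefinition-class].
#' @export
cvDefinition <- function(kind, selection = integer(0), massWeighted = TRUE,
                         switching = list(r0 = 0.65, n = 6L, m = 12L),
                         exclusion = 3L) {
  new("CVDefinition", kind = kind, selection = as.integer(selection),
      massWeighted = massWeighted, switching = switching,
      exclusion = as.integer(exclusion))
}

#' Default CV pair for a bead chain
#'
#' The two CVs the free-energy surfaces are resolved on: mass-weighted
#' radius of gyration over all beads and the C-alpha contact number with
#' sequence exclusion `|i - j| >= 3`.
#'
#' @param nBeads number of beads in the chain.
#' @param r0,n,m switching-function parameters.
#' @param exclusion minimum sequence separation counted.
#' @return named list of two [CVDefinition-class] objects (`rg`,
#'   `contact`).
#' @export
chainCVDefinitions <- function(nBeads, r0 = 0.65, n = 6L, m = 12L,
                               exclusion = 3L) {
  sel <- seq_len(nBeads)
  list(rg = cvDefinition("radius_of_gyration", sel),
       contact = cvDefinition("contact_number", sel,
                              switching = list(r0 = r0, n = as.integer(n),
                                               m = as.integer(m)),
                              exclusion = exclusion))
}

#' Radius of gyration of one frame
#'
#' \eqn{R_g = \sqrt{\sum_i w_i |r_i - \bar r|^2 / \sum_i w_i}} with
#' \eqn{w_i} the masses when `massWeighted`, else 1. Invariant under rigid
#' rotation and translation.
#'
#' @param frame coordinate matrix `[bead, xyz]` (nm).
#' @param selection bead indices (default all).
#' @param masses per-bead masses (needed when `massWeighted`).
#' @param massWeighted logical.
#' @return Rg in nm.
#' @export
radiusOfGyration <- function(frame, selection = seq_len(nrow(frame)),
                             masses = rep(1, nrow(frame)),
                             massWeighted = TRUE) {
  if (!length(selection)) stop("empty selection")
  x <- frame[selection, , drop = FALSE]
  w <- if (massWeighted) masses[selection] else rep(1, length(selection))
  com <- colSums(x * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(x, 2, com)^2)) / sum(w))
}

#' Rational switching function
#'
#' \eqn{s(r) = (1 - (r/r_0)^n) / (1 - (r/r_0)^m)} with the removable
#' singularity at \eqn{r = r_0} evaluated by its limit \eqn{n/m}. Monotone
#' non-increasing for m > n > 0; s(0) = 1 and s decays as
#' \eqn{(r_0/r)^{m-n}} in the tail.
#'
#' @param r distances (nm), >= 0.
#' @param r0 switching radius (nm).
#' @param n,m exponents, m > n > 0.
#' @return dimensionless values in (0, 1].
#' @export
#' @examples
#' switchingValue(c(0, 0.65, 6.5), 0.65, 6, 12)  # 1, 0.5, ~1e-9
switchingValue <- function(r, r0 = 0.65, n = 6L, m = 12L) {
  if (r0 <= 0) stop("r0 must be positive")
  if (!(m > n && n > 0)) stop("exponents must satisfy m > n > 0")
  cpp_switching(as.numeric(r), r0, as.integer(n), as.integer(m))
}

#' Contact number of one frame
#'
#' Sum of the switching function over unordered bead pairs (i, j) in the
#' selection with `|i - j| >= exclusion`; each pair counts once.
#'
#' @param frame coordinate matrix `[bead, xyz]` (nm).
#' @param definition a `contact_number` [CVDefinition-class].
#' @return dimensionless contact number.
#' @export
contactNumber <- function(frame, definition) {
  stopifnot(is(definition, "CVDefinition"),
            definition@kind == "contact_number")
  sel <- definition@selection
  if (length(sel) < 2L) stop("selection smaller than 2")
  sw <- definition@switching
  res <- cpp_chain_cvs(frame[sel, , drop = FALSE],
                       rep(1, length(sel)), FALSE,
                       sw$r0, sw$n, sw$m, definition@exclusion)
  res$contact_number
}

#' Evaluate CV definitions along a trajectory
#'
#' @param trajectory a [Trajectory-class].
#' @param definitions list of [CVDefinition-class] objects (named names
#'   become the CV labels).
#' @param masses per-bead masses for mass-weighted CVs.
#' @return a [CVSeries-class], frame-aligned with the trajectory.
#' @export
evaluateCVSeries <- function(trajectory, definitions,
                             masses = rep(1, dim(coords(trajectory))[1])) {
  xyz <- coords(trajectory)
  nF <- dim(xyz)[3]
  nB <- dim(xyz)[1]
  vals <- matrix(NA_real_, nF, length(definitions))
  for (k in seq_along(definitions)) {
    def <- definitions[[k]]
    if (def@kind != "coordinate" &&
        (min(def@selection) < 1L || max(def@selection) > nB))
      stop("CV selection index out of range")
    vals[, k] <- switch(def@kind,
      radius_of_gyration = vapply(seq_len(nF), function(f)
        radiusOfGyration(xyz[, , f], def@selection, masses,
                         def@massWeighted), 0.0),
      contact_number = vapply(seq_len(nF), function(f)
        contactNumber(xyz[, , f], def), 0.0),
      distance = vapply(seq_len(nF), function(f)
        sqrt(sum((xyz[def@selection[1], , f] -
                    xyz[def@selection[2], , f])^2)), 0.0),
      coordinate = xyz[1, def@selection[1], ])
  }
  nm <- names(definitions)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- paste0("cv", seq_along(definitions))
  new("CVSeries", times = frameTimes(trajectory), values = vals,
      cvNames = nm)
}

#' Write a CV series in the COLVAR dialect
#'
#' Whitespace-separated columns with the header
#' `#! FIELDS time <cv names>`; time in ps, values to 6 decimals.
#'
#' @param cv a [CVSeries-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeColvar <- function(cv, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS time", paste(cv@cvNames, collapse = " ")),
             con)
  tab <- cbind(cv@times, cv@values)
  writeLines(apply(tab, 1, function(r)
    paste(sprintf("%.6f", r), collapse = " ")), con)
  invisible(path)
}

#' Read a COLVAR-dialect file
#'
#' Tolerant of additional comment lines starting with `#`.
#'
#' @param path file path.
#' @return a [CVSeries-class].
#' @export
readColvar <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  if (!length(hdr)) stop("malformed COLVAR: missing '#! FIELDS' header")
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", hdr[1])),
                     "\\s+")[[1]]
  if (fields[1] != "time") stop("malformed COLVAR: first field must be time")
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(body)) stop("COLVAR file has no data rows")
  tab <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (ncol(tab) != length(fields))
    stop("malformed COLVAR: column count does not match FIELDS")
  new("CVSeries", times = tab[, 1],
      values = tab[, -1, drop = FALSE], cvNames = fields[-1])
}
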