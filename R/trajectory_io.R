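# Trajectory text formats: XYZ (one block per frame, time on the comment
# line) and single-model-per-frame PDB.

#' Write a trajectory in XYZ format
#'
#' One block per frame: bead count, a comment line carrying the time
#' (`t= <ps>`), then one `<name> x y z` row per bead. Coordinates are
#' written in nm to 6 decimals.
#'
#' @param trajectory a [Trajectory-class] with 3D coordinates.
#' @param path output file path.
#' @param names per-bead atom names (default `CA`).
#' @return `path`, invisibly.
#' @export
writeXYZ <- function(trajectory, path,
                     names = rep("CA", dim(coords(trajectory))[1])) {
  xyz <- coords(trajectory)
  if (dim(xyz)[2] != 3L) stop("XYZ output needs 3D coordinates")
  nB <- dim(xyz)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(xyz)[3])) {
    writeLines(as.character(nB), con)
    writeLines(sprintf("t= %.6f", trajectory@times[f]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", names,
                       xyz[, 1, f], xyz[, 2, f], xyz[, 3, f]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory written by [writeXYZ()]
#'
#' @param path file path.
#' @return a [Trajectory-class].
#' @export
readXYZ <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  framelist <- list()
  times <- numeric(0)
  while (pos <= length(lines)) {
    nB <- as.integer(lines[pos])
    if (is.na(nB)) stop("malformed XYZ: expected a bead count at line ", pos)
    t <- suppressWarnings(as.numeric(sub("^.*t=\\s*", "", lines[pos + 1L])))
    rows <- strsplit(trimws(lines[(pos + 2L):(pos + 1L + nB)]), "\\s+")
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    framelist[[length(framelist) + 1L]] <- xyz
    times <- c(times, if (is.na(t)) length(times) else t)
    pos <- pos + 2L + nB
  }
  nF <- length(framelist)
  nB <- nrow(framelist[[1]])
  arr <- array(NA_real_, c(nB, 3, nF))
  for (f in seq_len(nF)) arr[, , f] <- framelist[[f]]
  new("Trajectory", times = times, coords = arr, metadata = list())
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, one C-alpha ATOM record per bead.
#' Coordinates are converted from nm to Angstrom as the format requires.
#'
#' @param trajectory a [Trajectory-class].
#' @param path output file path.
#' @param seq optional [PeptideSeq-class] supplying residue names and
#'   numbers.
#' @return `path`, invisibly.
#' @export
writePDBFrames <- function(trajectory, path, seq = NULL) {
  xyz <- coords(trajectory)
  if (dim(xyz)[2] != 3L) stop("PDB output needs 3D coordinates")
  nB <- dim(xyz)[1]
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           K = "LYS", L = "LEU", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  if (!is.null(seq)) {
    resn <- unname(aa3[seq@residues])
    resi <- residueNumbers(seq)
  } else {
    resn <- rep("GLY", nB)
    resi <- seq_len(nB)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(xyz)[3])) {
    writeLines(sprintf("MODEL %8d", f), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nB), resn, resi,
      xyz[, 1, f] * 10, xyz[, 2, f] * 10, xyz[, 3, f] * 10), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
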