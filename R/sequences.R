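# Sequence module: annotated peptides, formal charges, Cdk1 motif scanning
# and FASTA I/O in the {pX} phospho bracket dialect.

# Formal side-chain charges at cytosolic pH. Histidine is treated as
# neutral; the phospho group is fully deprotonated (-2) by default.
.chargeTable <- c(D = -1, E = -1, K = +1, R = +1)

#' Parse an annotated peptide string
#'
#' Accepts one-letter amino-acid codes with phospho residues wrapped in the
#' bracket dialect `{pX}` (e.g. `"APNS{pT}PIV"` marks a phosphothreonine).
#' The returned sequence is numbered consecutively from `startNumber`; for
#' the Sac6 loop segment anchored at Ala99 this places the Cdk1 site on
#' threonine 103.
#'
#' @param text annotated sequence string.
#' @param startNumber absolute residue number of the first residue.
#' @return a [PeptideSeq-class].
#' @export
#' @examples
#' seg <- parsePeptide("APNSTPIVSTAATGLQHKGKGTQAKII", 99)
#' length(seg)                       # 27
#' pseg <- parsePeptide("APNS{pT}PIVSTAATGLQHKGKGTQAKII", 99)
#' residueNumbers(pseg)[phosphoFlags(pseg)]  # 103
parsePeptide <- function(text, startNumber = 1L) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) stop("empty sequence")
  chars <- strsplit(text, "")[[1]]
  res <- character(0)
  pho <- logical(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "{") {
      close <- which(chars == "}" & seq_along(chars) > i)[1]
      if (is.na(close)) stop("unterminated phospho annotation '{'")
      tok <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      if (!grepl("^p[A-Z]$", tok))
        stop("malformed phospho annotation '{", tok, "}'; expected {pX}")
      aa <- substr(tok, 2L, 2L)
      if (!aa %in% c("S", "T", "Y"))
        stop("phospho annotation on non-phosphorylatable residue '", aa, "'")
      res <- c(res, aa)
      pho <- c(pho, TRUE)
      i <- close + 1L
    } else {
      ch <- toupper(ch)
      if (!ch %in% .AA1) stop("unknown residue letter '", ch, "'")
      res <- c(res, ch)
      pho <- c(pho, FALSE)
      i <- i + 1L
    }
  }
  new("PeptideSeq", residues = res, phospho = pho,
      startNumber = as.integer(startNumber))
}

#' Format a peptide back to its annotated string
#'
#' Inverse of [parsePeptide()]: phospho residues are written as `{pX}`.
#'
#' @param seq a [PeptideSeq-class].
#' @return character string.
#' @export
formatPeptide <- function(seq) {
  stopifnot(is(seq, "PeptideSeq"))
  out <- seq@residues
  out[seq@phospho] <- paste0("{p", out[seq@phospho], "}")
  paste(out, collapse = "")
}

#' Count occurrences of a residue
#'
#' @param seq a [PeptideSeq-class].
#' @param code one-letter amino-acid code.
#' @return integer count.
#' @export
#' @examples
#' countResidue(parsePeptide("APNSTPIVSTAATGLQHKGKGTQAKII", 99), "K")  # 3
countResidue <- function(seq, code) {
  stopifnot(is(seq, "PeptideSeq"))
  if (!is.character(code) || length(code) != 1L || !code %in% .AA1)
    stop("invalid residue code '", code, "'")
  sum(seq@residues == code)
}

#' Scan for Cdk1 phosphorylation consensus motifs
#'
#' The minimal cyclin-dependent-kinase consensus is S or T immediately
#' followed by P; the full consensus additionally requires K or R three
#' residues downstream (`[S/T]-P-x-[K/R]`). Overlapping hits are all
#' reported, sorted by position.
#'
#' @param seq a [PeptideSeq-class].
#' @param motifKind `"minimal"` (default, the definition used to identify
#'   T103/T366/T589 in Sac6) or `"full_consensus"`.
#' @param contextWidth residues of flanking context reported on each side.
#' @return data.frame with columns `position` (absolute number of the S/T),
#'   `residue`, `motif_kind` and `context`; zero rows when no site exists.
#' @export
#' @examples
#' seg <- parsePeptide("APNSTPIVSTAATGLQHKGKGTQAKII", 99)
#' scanCdk1Sites(seg)$position  # 103
scanCdk1Sites <- function(seq, motifKind = c("minimal", "full_consensus"),
                          contextWidth = 3L) {
  stopifnot(is(seq, "PeptideSeq"))
  motifKind <- match.arg(motifKind)
  r <- seq@residues
  n <- length(r)
  hit <- which(r %in% c("S", "T"))
  hit <- hit[hit < n & r[pmin(hit + 1L, n)] == "P"]
  if (motifKind == "full_consensus")
    hit <- hit[hit + 3L <= n & r[pmin(hit + 3L, n)] %in% c("K", "R")]
  nums <- residueNumbers(seq)
  ctx <- vapply(hit, function(i) {
    lo <- max(1L, i - contextWidth)
    hi <- min(n, i + contextWidth)
    paste(r[lo:hi], collapse = "")
  }, character(1))
  data.frame(position = nums[hit], residue = r[hit],
             motif_kind = rep(motifKind, length(hit)),
             context = ctx, stringsAsFactors = FALSE)
}

#' Formal net charge of a peptide
#'
#' Sums per-residue formal charges: D/E contribute -1, K/R +1, H 0, and
#' each phospho group adds `phosphoCharge` (default -2, fully deprotonated
#' at cytosolic pH). Termini are uncharged by default, appropriate for an
#' internal loop segment; `chargedTermini = TRUE` adds +1/-1.
#'
#' @param seq a [PeptideSeq-class].
#' @param phosphoCharge charge added per phospho group.
#' @param chargedTermini logical; add +1 (N) and -1 (C) terminal charges.
#' @return net charge in elementary charges.
#' @export
#' @examples
#' netCharge(parsePeptide("APNSTPIVSTAATGLQHKGKGTQAKII", 99))        # +3
#' netCharge(parsePeptide("APNS{pT}PIVSTAATGLQHKGKGTQAKII", 99))     # +1
netCharge <- function(seq, phosphoCharge = -2, chargedTermini = FALSE) {
  stopifnot(is(seq, "PeptideSeq"))
  q <- sum(perResidueCharges(seq, phosphoCharge))
  if (chargedTermini) q <- q + 1 - 1
  q
}

#' Per-residue formal charges
#'
#' The charge table behind [netCharge()] and the bead-chain builder.
#'
#' @inheritParams netCharge
#' @return numeric vector, one charge per residue.
#' @export
perResidueCharges <- function(seq, phosphoCharge = -2) {
  stopifnot(is(seq, "PeptideSeq"))
  q <- unname(.chargeTable[seq@residues])
  q[is.na(q)] <- 0
  q + ifelse(seq@phospho, phosphoCharge, 0)
}

#' Read an annotated FASTA file
#'
#' Multi-record FASTA whose sequence lines may carry the `{pX}` phospho
#' dialect. Duplicate identifiers trigger a warning but both records are
#' kept.
#'
#' @param path file path.
#' @param startNumber numbering anchor applied to every record (recycled).
#' @return named list of [PeptideSeq-class] objects.
#' @export
readPeptideFasta <- function(path, startNumber = 1L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1], ">"))
    stop("malformed FASTA: expected a '>' header first")
  hdr <- which(startsWith(lines, ">"))
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (anyDuplicated(ids))
    warning("duplicate FASTA identifiers kept: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  startNumber <- rep_len(as.integer(startNumber), length(hdr))
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    if (hdr[k] == ends[k]) stop("malformed FASTA: empty record '", ids[k], "'")
    body <- paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")
    out[[k]] <- parsePeptide(body, startNumber[k])
  }
  names(out) <- ids
  out
}

#' Write peptides to an annotated FASTA file
#'
#' Sequence lines wrap at 60 columns (annotation brackets count as
#' characters but are never split across lines).
#'
#' @param records named list of [PeptideSeq-class] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePeptideFasta <- function(records, path) {
  if (is(records, "PeptideSeq")) records <- list(peptide = records)
  ids <- names(records)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every record needs a name to use as its identifier")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(records)) {
    writeLines(paste0(">", ids[k]), con)
    toks <- records[[k]]@residues
    pho <- records[[k]]@phospho
    toks[pho] <- paste0("{p", toks[pho], "}")
    # greedy 60-column wrap over whole tokens
    line <- ""
    for (tok in toks) {
      if (nchar(line) + nchar(tok) > 60L) { writeLines(line, con); line <- "" }
      line <- paste0(line, tok)
    }
    if (nzchar(line)) writeLines(line, con)
  }
  invisible(path)
}

#' Export motif hits as TSV
#'
#' Columns: identifier, position, motif_kind, context.
#'
#' @param hitsList named list of data frames from [scanCdk1Sites()], one per
#'   sequence identifier.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMotifTsv <- function(hitsList, path) {
  rows <- lapply(names(hitsList), function(id) {
    h <- hitsList[[id]]
    if (!nrow(h)) return(NULL)
    cbind(identifier = id, h[, c("position", "motif_kind", "context")])
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(identifier = character(), position = integer(),
                      motif_kind = character(), context = character())
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Concatenate two annotated peptides
#'
#' The right-hand sequence is renumbered to continue the left-hand one.
#' Net charge is additive over this operation.
#'
#' @param a,b [PeptideSeq-class] objects.
#' @return a [PeptideSeq-class].
#' @export
concatPeptides <- function(a, b) {
  stopifnot(is(a, "PeptideSeq"), is(b, "PeptideSeq"))
  new("PeptideSeq", residues = c(a@residues, b@residues),
      phospho = c(a@phospho, b@phospho), startNumber = a@startNumber)
}

#' The simulated Sac6 loop segment
#'
#' Convenience constructor for the 27-residue disordered-loop segment of
#' the yeast fimbrin Sac6 N terminus (Ala99 onward,
#' `APNSTPIVSTAATGLQHKGKGTQAKII`), optionally phosphorylated on T103.
#'
#' @param phospho logical; phosphorylate T103.
#' @return a [PeptideSeq-class] anchored at residue 99.
#' @export
#' @examples
#' sac6LoopSegment(phospho = TRUE)
sac6LoopSegment <- function(phospho = FALSE) {
  if (phospho)
    parsePeptide("APNS{pT}PIVSTAATGLQHKGKGTQAKII", 99L)
  else
    parsePeptide("APNSTPIVSTAATGLQHKGKGTQAKII", 99L)
}
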