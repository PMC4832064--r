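# Sequence parsing, motif scanning, charges and FASTA round trips.

test_that("the printed loop segment parses with correct numbering", {
  seg <- parsePeptide(segmentText, 99)
  expect_s4_class(seg, "PeptideSeq")
  expect_equal(length(seg), 27L)
  expect_equal(residues(seg)[5], "T")
  expect_equal(residueNumbers(seg)[5], 103L)
  expect_equal(residueNumbers(seg), 99:125)
  expect_false(any(phosphoFlags(seg)))

  pseg <- parsePeptide("APNS{pT}PIVSTAATGLQHKGKGTQAKII", 99)
  expect_equal(residues(pseg), residues(seg))
  expect_equal(which(phosphoFlags(pseg)), 5L)
  expect_equal(residueNumbers(pseg)[phosphoFlags(pseg)], 103L)

  one <- parsePeptide("A", 1)
  expect_equal(length(one), 1L)
  expect_equal(residueNumbers(one), 1L)
})

test_that("parsing rejects malformed input", {
  expect_error(parsePeptide("", 1), "empty")
  expect_error(parsePeptide("AXB", 1), "unknown residue")
  expect_error(parsePeptide("A{pG}A", 1), "non-phosphorylatable")
  expect_error(parsePeptide("A{pT", 1), "unterminated")
})

test_that("parse/format round-trip is the identity on random sequences", {
  set.seed(42)
  for (rep in 1:25) {
    txt <- randomPeptideString(sample(1:60, 1), phosphoProb = 0.3)
    p <- parsePeptide(txt, sample(1:500, 1))
    expect_identical(formatPeptide(p), txt)
    p2 <- parsePeptide(formatPeptide(p), startNumber(p))
    expect_identical(residues(p2), residues(p))
    expect_identical(phosphoFlags(p2), phosphoFlags(p))
  }
})

test_that("residue counting matches a character tally", {
  seg <- parsePeptide(segmentText, 99)
  expect_equal(countResidue(seg, "K"), 3L)
  expect_equal(countResidue(seg, "W"), 0L)
  tally <- sum(strsplit(segmentText, "")[[1]] == "T")
  expect_equal(countResidue(seg, "T"), tally)
  expect_error(countResidue(seg, "Z"), "invalid residue")
})

test_that("minimal Cdk1 scan finds exactly T103 in the segment", {
  seg <- parsePeptide(segmentText, 99)
  hits <- scanCdk1Sites(seg, "minimal")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 103L)
  expect_equal(hits$residue, "T")
  expect_equal(nrow(scanCdk1Sites(parsePeptide("AAAAAA", 1))), 0L)
})

test_that("motif scan equals a brute-force position scan on random sequences", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(5:80, 1)
    txt <- randomPeptideString(n)
    p <- parsePeptide(txt, 1)
    r <- residues(p)
    brute <- which(r %in% c("S", "T") &
                     c(r[-1], "") == "P")
    expect_equal(scanCdk1Sites(p, "minimal")$position, brute)
    bruteFull <- brute[brute + 3 <= n & r[pmin(brute + 3, n)] %in% c("K", "R")]
    expect_equal(scanCdk1Sites(p, "full_consensus")$position, bruteFull)
  }
})

test_that("full consensus requires a basic residue at +3", {
  expect_equal(scanCdk1Sites(parsePeptide("ATPAKA", 1), "full_consensus")$position, 2L)
  expect_equal(nrow(scanCdk1Sites(parsePeptide("ATPAAA", 1), "full_consensus")), 0L)
})

test_that("net charge follows the fixed charge table", {
  seg <- parsePeptide(segmentText, 99)
  expect_equal(netCharge(seg), 3)          # 3 K, no D/E/R, H neutral
  pseg <- parsePeptide("APNS{pT}PIVSTAATGLQHKGKGTQAKII", 99)
  expect_equal(netCharge(pseg), netCharge(seg) - 2)
  expect_equal(netCharge(parsePeptide("GGGGG", 1)), 0)
  expect_equal(netCharge(seg, chargedTermini = TRUE), netCharge(seg))
})

test_that("net charge is additive over concatenation", {
  set.seed(11)
  for (rep in 1:20) {
    a <- parsePeptide(randomPeptideString(sample(1:40, 1), 0.2), 1)
    b <- parsePeptide(randomPeptideString(sample(1:40, 1), 0.2), 1)
    expect_equal(netCharge(concatPeptides(a, b)), netCharge(a) + netCharge(b))
  }
})

test_that("FASTA writing and reading round-trip, keeping annotation", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  seg <- parsePeptide("APNS{pT}PIVSTAATGLQHKGKGTQAKII", 99)
  other <- parsePeptide(randomPeptideString(130, 0.1), 1)
  writePeptideFasta(list(seg = seg, other = other), tmp)
  back <- readPeptideFasta(tmp, startNumber = c(99L, 1L))
  expect_named(back, c("seg", "other"))
  expect_identical(residues(back$seg), residues(seg))
  expect_identical(phosphoFlags(back$seg), phosphoFlags(seg))
  expect_identical(formatPeptide(back$other), formatPeptide(other))
  # record containing the printed segment parses like a direct parse
  expect_equal(scanCdk1Sites(back$seg)$position, 103L)
})

test_that("duplicate FASTA identifiers warn but are kept", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AAA", ">a", "GGG"), tmp)
  expect_warning(recs <- readPeptideFasta(tmp), "duplicate")
  expect_length(recs, 2L)
})

test_that("motif hits export to TSV with identifier context", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  seg <- parsePeptide(segmentText, 99)
  writeMotifTsv(list(segment = scanCdk1Sites(seg)), tmp)
  tab <- read.delim(tmp)
  expect_equal(tab$identifier, "segment")
  expect_equal(tab$position, 103L)
})
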