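# Regenerates inst/extdata/sac6_synthetic.fasta: a SYNTHETIC 642-residue
# stand-in for full-length yeast fimbrin (Sac6).  It is not the real
# accession sequence: the background alphabet excludes S, T and P so that
# the only minimal Cdk1 S/T-P motifs are the engineered ones, the genuine
# 27-residue loop segment occupies positions 99-125, and T-P dipeptides are
# placed so the minimal sites fall exactly at 103, 366 and 589.
set.seed(20160412)

bg <- c("A", "G", "L", "V", "I", "F", "N", "Q", "E", "D",
        "K", "R", "H", "M", "W", "Y", "C")
n <- 642L
seqv <- sample(bg, n, replace = TRUE)

segment <- strsplit("APNSTPIVSTAATGLQHKGKGTQAKII", "")[[1]]
seqv[99:125] <- segment
seqv[366] <- "T"; seqv[367] <- "P"
seqv[589] <- "T"; seqv[590] <- "P"
# keep +3 positions non-basic so the engineered sites stay minimal-only
seqv[369] <- "A"; seqv[592] <- "G"

lines <- c(">sac6_synthetic synthetic stand-in for full-length Sac6; real loop segment at 99-125; engineered minimal S/T-P sites at 103, 366, 589",
           vapply(split(seqv, ceiling(seq_len(n) / 60)),
                  paste, collapse = "", FUN.VALUE = ""))
writeLines(lines, "inst/extdata/sac6_synthetic.fasta")
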