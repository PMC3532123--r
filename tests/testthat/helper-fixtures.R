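# Shared in-code fixtures.

# The three worked examples printed with all their scores (a, b, c, d).
table3Counts <- function() {
  StrandCounts(a = c(11, 16, 8), b = c(2, 2, 2),
               c = c(20, 10, 16), d = c(0, 0, 0))
}

# The three call-conflict examples: per-strand counts and expected calls.
table1Counts <- function() {
  StrandCounts(a = c(5, 20, 15), b = c(5, 11, 9),
               c = c(10, 7, 7), d = c(1, 0, 0))
}

# A VariantSet whose SB scores are strictly increasing in `pos`:
# with a = 9, b = 1, d = 0 the score is (10 + c) / 10.
rankedVariantSet <- function(n = 100, sampleId = "S01") {
  VariantSet(chrom = "1", pos = seq_len(n), ref = "A", alt = "G",
             a = 9, b = 1, c = seq_len(n), d = 0, sampleId = sampleId)
}

# Minimal score table for the correlation helpers.
makeScoreTable <- function(scores, pos = seq_along(scores), chrom = "1") {
  chrom <- rep_len(chrom, length(scores))
  data.frame(chrom = chrom, pos = pos,
             key = paste(chrom, pos, sep = ":"),
             sb = scores, gatk_sb = scores, fisher = pmin(1, scores),
             stringsAsFactors = FALSE)
}

# Six hand-flagged variants for the Ti/Tv grid (see test-qc.R for the
# hand-computed expectations).
toyAnnotatedVariants <- function() {
  VariantSet(chrom = "1", pos = 1:6,
             ref = c("A", "C", "A", "G", "T", "C"),
             alt = c("G", "T", "C", "T", "C", "A"),
             a = 15, b = 5, c = 15, d = 5,
             inDbsnp = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
             onChip = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
             maf = c(0.05, 0.15, 0.05, 0.45, 0.25, 0.05))
}
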