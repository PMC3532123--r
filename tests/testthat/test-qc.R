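test_that("transition classification follows the substitution alphabet", {
  expect_true(isTransition("A", "G"))
  expect_false(isTransition("C", "A"))
  pairs <- expand.grid(ref = c("A", "C", "G", "T"),
                       alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  expect_equal(sum(isTransition(pairs$ref, pairs$alt)), 4L)
  expect_equal(nrow(pairs), 12L)
  expect_error(isTransition("N", "A"), "nucleotides")
})

test_that("titvRatio counts transitions over transversions", {
  expect_equal(titvRatio(c("A", "C", "A"), c("G", "T", "C")), 2)
  expect_true(is.na(titvRatio(c("A", "G"), c("G", "A"))))
  expect_error(titvRatio(character(0), character(0)), "empty")

  # binomial sampling with transition probability 0.75 concentrates near 3
  set.seed(11)
  n <- 10000
  ts <- runif(n) < 0.75
  ref <- rep("A", n)
  alt <- ifelse(ts, "G", "C")
  r <- titvRatio(ref, alt)
  expect_gt(r, 2.7)
  expect_lt(r, 3.3)
})

test_that("MAF binning is left-closed, right-open, last bin closed", {
  expect_equal(as.character(mafBin(0.05)), "0-0.1")
  expect_equal(as.character(mafBin(0.1)), "0.1-0.2")
  expect_equal(as.character(mafBin(0.2)), "0.2-0.3")
  expect_equal(as.character(mafBin(0.5)), "0.4-0.5")
  expect_equal(as.character(mafBin(0)), "0-0.1")
  expect_error(mafBin(0.6), "0, 0.5")
  expect_error(mafBin(-0.1), "0, 0.5")
})

test_that("the Ti/Tv grid matches a hand-enumerated fixture", {
  tab <- titvTable(toyAnnotatedVariants())
  cell <- function(s, b) tab[tab$subset == s & tab$maf_bin == b, ]
  ov <- cell("All Seq SNPs", "Overall")
  expect_equal(ov$n, 6L)
  expect_equal(ov$titv, 1)
  expect_equal(cell("All Seq SNPs", "0-0.1")$n, 3L)
  expect_equal(cell("All Seq SNPs", "0-0.1")$titv, 0.5)
  expect_true(is.na(cell("Overlapped SNPs", "Overall")$titv))  # no Tv
  expect_equal(cell("Overlapped SNPs", "Overall")$n, 2L)
  expect_equal(cell("Seq SNPs - Chip SNPs", "Overall")$titv, 1 / 3)
  expect_equal(cell("dbSNP SNPs in Seq", "Overall")$titv, 3)
  expect_equal(cell("dbSNP SNPs not on Chip", "Overall")$n, 2L)
  expect_equal(cell("dbSNP SNPs not on Chip", "Overall")$titv, 1)
})

test_that("the Ti/Tv grid satisfies its partition identities", {
  cohort <- suppressMessages(
    simulateCohort(simulationConfig(nSamples = 3, nSites = 800, seed = 4)))
  tab <- titvTable(cohortVariants(cohort))
  w <- function(s) tab$n[tab$subset == s]
  expect_equal(w("All Seq SNPs"),
               w("Overlapped SNPs") + w("Seq SNPs - Chip SNPs"))
  expect_equal(w("dbSNP SNPs not on Chip"),
               w("dbSNP SNPs in Seq") - w("Overlapped SNPs"))
  # each subset's bins sum to its Overall column
  for (s in unique(tab$subset)) {
    n <- tab$n[tab$subset == s]
    expect_equal(sum(n[1:5]), n[6])
  }
  # a cohort where everything is off-chip empties the Overlapped row
  all_off <- titvTable(
    cohortVariants(cohort)[!onChip(cohortVariants(cohort))])
  expect_true(all(all_off$n[all_off$subset == "Overlapped SNPs"] == 0L))
})

test_that("quantile stratification selects the score tails inclusively", {
  vs <- rankedVariantSet(100)           # SB strictly increasing with pos
  st <- stratifyByScore(vs, "sb", 0.1)
  pos <- GenomicRanges::start(variantRanges(vs))
  expect_equal(pos[st$low], 1:10)
  expect_equal(pos[st$high], 91:100)
  expect_length(intersect(st$low, st$high), 0L)

  # all-equal scores: empty strata with a warning
  flat <- VariantSet(chrom = "1", pos = 1:40, ref = "A", alt = "G",
                     a = 10, b = 2, c = 10, d = 2)
  expect_warning(stf <- stratifyByScore(flat, "sb", 0.1), "degenerate")
  expect_length(stf$low, 0L)
  expect_length(stf$high, 0L)

  # too few variants for meaningful quantiles
  expect_error(stratifyByScore(rankedVariantSet(10), "sb", 0.1),
               "at least")
  # undefined scores must be filtered first
  one_sided <- VariantSet(chrom = "1", pos = 1:30, ref = "A", alt = "G",
                          a = c(rep(10, 29), 5), b = 1,
                          c = c(rep(10, 29), 0), d = 0)
  expect_error(stratifyByScore(one_sided, "sb", 0.1), "filterStrandDepth")
})

test_that("per-sample stratification uses each sample's own quantiles", {
  vs1 <- rankedVariantSet(50, "S01")
  vs2 <- rankedVariantSet(100, "S02")
  both <- VariantSet(chrom = "1", pos = c(1:50, 1:100), ref = "A",
                     alt = "G", a = 9, b = 1,
                     c = c(1:50, 1:100), d = 0,
                     sampleId = rep(c("S01", "S02"), c(50, 100)))
  st <- stratifyByScore(both, "sb", 0.1, perSample = TRUE)
  expect_equal(nrow(st$thresholds), 2L)
  # each sample contributes its own bottom/top decile
  expect_equal(sum(sampleIds(both)[st$high] == "S01"), 5L)
  expect_equal(sum(sampleIds(both)[st$high] == "S02"), 10L)
})

test_that("the top SB stratum concentrates injected artifacts", {
  cohort <- suppressMessages(simulateCohort(
    simulationConfig(nSamples = 4, nSites = 2000, biasMode = "none",
                     seed = 3)))
  vs <- filterStrandDepth(cohortVariants(cohort))
  tr <- truthLabels(cohort)
  isArt <- tr$is_artifact[match(siteKeys(vs),
                                paste(tr$sample_id, tr$chrom, tr$pos,
                                      sep = ":"))]
  st <- stratifyByScore(vs, "sb", 0.1)
  captured <- sum(isArt[st$high]) / sum(isArt)
  expect_gte(captured, 0.7)
  # and significantly more artifacts in the top than the bottom stratum
  pt <- prop.test(c(sum(isArt[st$high]), sum(isArt[st$low])),
                  c(length(st$high), length(st$low)),
                  alternative = "greater")
  expect_lt(pt$p.value, 0.01)
})

test_that("het consistency compares chip heterozygotes to sequencing", {
  vs <- VariantSet(chrom = "1", pos = 1:10, ref = "A", alt = "G",
                   a = 15, b = 5, c = 15, d = 5, sampleId = "S01",
                   seqGenotype = c(rep("het", 8), "hom-alt", "hom-alt"))
  chip <- data.frame(sample = "S01", chrom = "1", pos = 1:10,
                     allele1 = "A", allele2 = "G")
  expect_equal(hetConsistencyRate(vs, chip), 0.8)
  # identical call sets
  expect_equal(hetConsistencyRate(vs[1:8], chip[1:8, ]), 1)
  # allele-level match: a different chip allele pair is inconsistent
  chip2 <- chip
  chip2$allele2[1:8] <- "T"
  expect_equal(hetConsistencyRate(vs, chip2), 0)
  expect_equal(hetConsistencyRate(vs, chip2, level = "zygosity"), 0.8)
  # chip homozygotes never enter the denominator
  chipHom <- data.frame(sample = "S01", chrom = "1", pos = 1:10,
                        allele1 = "A", allele2 = "A")
  expect_true(is.na(hetConsistencyRate(vs, chipHom)))
  # a 2% genotype error rate leaves 97-99% consistency at scale
  set.seed(21)
  n <- 5000
  g <- ifelse(runif(n) < 0.02, "hom-alt", "het")
  big <- VariantSet(chrom = "1", pos = seq_len(n), ref = "A", alt = "G",
                    a = 15, b = 5, c = 15, d = 5, sampleId = "S01",
                    seqGenotype = g)
  bigChip <- data.frame(sample = "S01", chrom = "1", pos = seq_len(n),
                        allele1 = "A", allele2 = "G")
  r <- hetConsistencyRate(big, bigChip)
  expect_gt(r, 0.97)
  expect_lt(r, 0.99)
})

test_that("consistency is invariant to record order and chrom labels", {
  cohort <- suppressMessages(simulateCohort(
    simulationConfig(nSamples = 2, nSites = 600,
                     chipOverlapFraction = 0.4, seed = 9)))
  vs <- cohortVariants(cohort)
  chip <- chipGenotypes(cohort)
  base <- hetConsistencyRate(vs, chip)
  set.seed(1)
  perm <- sample(length(vs))
  expect_equal(hetConsistencyRate(vs[perm], chip), base)
  # relabel the chromosome consistently in both tables
  df <- as.data.frame(vs)
  vs2 <- VariantSet(chrom = "chrX", pos = df$pos, ref = df$ref,
                    alt = df$alt, a = df$a, b = df$b, c = df$c, d = df$d,
                    sampleId = df$sample_id, seqGenotype = df$seq_genotype)
  chip2 <- chip
  chip2$chrom <- "chrX"
  expect_equal(hetConsistencyRate(vs2, chip2), base)
})

test_that("consistency quantile bins are balanced and honest", {
  # error-free genotypes give a flat curve at 1
  n <- 90
  vs <- VariantSet(chrom = "1", pos = seq_len(n), ref = "A", alt = "G",
                   a = 14, b = seq_len(n) %% 7 + 1, c = 15, d = 0,
                   sampleId = "S01", seqGenotype = "het")
  chip <- data.frame(sample = "S01", chrom = "1", pos = seq_len(n),
                     allele1 = "A", allele2 = "G")
  cq <- consistencyByQuantile(vs, chip, "sb", nBins = 20,
                              minStrandDepth = 10)
  expect_equal(nrow(cq), 20L)
  expect_true(all(cq$consistency == 1))
  # 90 sites over 20 bins: populations differ by at most one
  expect_lte(diff(range(cq$n)), 1L)
  expect_equal(sum(cq$n), n)
  # bins are ordered by score
  expect_true(all(diff(cq$score_max) >= 0))
  expect_error(consistencyByQuantile(vs, chip[0, ], "sb"),
               "no chip-heterozygous")
})

test_that("novel non-synonymous SNPs are counted from the flags", {
  vs <- VariantSet(chrom = "1", pos = 1:5, ref = "A", alt = "G",
                   a = 15, b = 5, c = 15, d = 5,
                   sampleId = c("S01", "S01", "S01", "S02", "S02"),
                   inDbsnp = c(FALSE, FALSE, TRUE, FALSE, TRUE),
                   functionalClass = c("non-synonymous", "non-synonymous",
                                       "non-synonymous", "synonymous",
                                       "non-synonymous"))
  expect_equal(countNovelNonsynonymous(vs), 2L)
  expect_equal(countNovelNonsynonymous(vs, perSample = TRUE),
               c(S01 = 2L, S02 = 0L))
  allDb <- vs[inDbsnp(vs)]
  expect_equal(countNovelNonsynonymous(allDb), 0L)
})

test_that("the generator calibrates novel non-synonymous counts", {
  cohort <- suppressMessages(simulateCohort(
    simulationConfig(nSamples = 10, nSites = 6000, artifactRate = 0,
                     biasMode = "none", seed = 11)))
  cnt <- countNovelNonsynonymous(cohortVariants(cohort), perSample = TRUE)
  expect_length(cnt, 10L)
  expect_gte(sum(cnt >= 200 & cnt <= 300), 9L)
})
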