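test_that("StrandCounts enforces its count invariants", {
  expect_s4_class(StrandCounts(11, 2, 20, 0), "StrandCounts")
  expect_error(StrandCounts(-1, 0, 5, 0), "non-negative")
  expect_error(StrandCounts(0, 0, 0, 0), "total depth")
  expect_error(StrandCounts(1, 5, 1, 5), "major/minor")
  expect_error(StrandCounts(1.5, 0, 3, 0), "whole numbers")
  sc <- StrandCounts(c(3, 4), c(1, 0), c(5, 6), c(0, 2))
  expect_length(sc[2], 1L)
  expect_equal(fwdDepth(sc), c(4L, 4L))
  expect_equal(revDepth(sc), c(5L, 8L))
  expect_equal(totalDepth(sc), c(9L, 12L))
})

test_that("reduceToBiallelic keeps the two best-supported alleles", {
  # worked example: G major, A minor
  r <- reduceToBiallelic(c("G", "A"), forward = c(11, 2),
                         reverse = c(20, 0))
  expect_equal(as.data.frame(r$counts),
               data.frame(a = 11L, b = 2L, c = 20L, d = 0L))
  expect_equal(r$major, "G")
  expect_equal(r$minor, "A")

  # monoallelic site
  r <- reduceToBiallelic("T", 8, 9)
  expect_equal(as.data.frame(r$counts),
               data.frame(a = 8L, b = 0L, c = 9L, d = 0L))
  expect_true(is.na(r$minor))

  # third allele discarded by rank of pooled counts
  r <- reduceToBiallelic(c("C", "T", "G"), forward = c(10, 4, 1),
                         reverse = c(10, 3, 0))
  expect_equal(as.data.frame(r$counts),
               data.frame(a = 10L, b = 4L, c = 10L, d = 3L))
  expect_equal(r$discarded, "G")

  # ties: reference preferred for major status, then alphabetical
  r <- reduceToBiallelic(c("A", "T"), c(5, 5), c(5, 5), ref = "T")
  expect_equal(r$major, "T")
  r <- reduceToBiallelic(c("T", "C"), c(5, 5), c(5, 5))
  expect_equal(r$major, "C")

  expect_error(reduceToBiallelic(character(0), integer(0), integer(0)),
               "uncovered")
  expect_error(reduceToBiallelic("A", 0, 0), "uncovered")
})

test_that("the three scores reproduce the printed worked examples", {
  sc <- table3Counts()
  expect_equal(round(sbScore(sc), 2), c(2.54, 1.56, 2.60))
  expect_equal(round(gatkSbScore(sc), 2)[1:2], c(0.16, 0.12))
  expect_equal(round(fisherScore(sc), 2), c(0.85, 0.48, 0.86))
})

test_that("scores match independently derived values", {
  # direct evaluation of the SB formula on the first conflict example
  expect_equal(sbScore(5, 5, 10, 1),
               abs(5 / 10 - 1 / 11) / (6 / 21), tolerance = 1e-12)
  expect_equal(round(sbScore(5, 5, 10, 1), 4), 1.4318)
  # equal minor fractions on both strands
  expect_equal(sbScore(10, 5, 10, 5), 0)
  # direct evaluation of the GATK-SB formula: (2/10 * 1) / (24/26)
  expect_equal(gatkSbScore(8, 2, 16, 0), 13 / 60, tolerance = 1e-12)
  expect_equal(round(gatkSbScore(8, 2, 16, 0), 4), 0.2167)
  # no minor allele: both cross terms vanish
  expect_equal(gatkSbScore(10, 0, 10, 0), 0)
  # hypergeometric enumeration for a = 16, b = 2, c = 10, d = 0:
  # feasible b in {0, 1, 2}, p = (153 + 45) / 378
  expect_equal(fisherScore(16, 2, 10, 0), 1 - 198 / 378, tolerance = 1e-12)
  expect_equal(fisherScore(10, 0, 10, 0), 0)
})

test_that("fisherExactTwoSided enumerates the exact two-sided p-value", {
  # single qualifying table out of 3 feasible: 78/528
  expect_equal(fisherExactTwoSided(11, 2, 20, 0), 78 / 528,
               tolerance = 1e-12)
  expect_equal(fisherExactTwoSided(8, 2, 16, 0), 45 / 325,
               tolerance = 1e-12)
  # degenerate margin: one feasible table
  expect_equal(fisherExactTwoSided(0, 0, 5, 0), 1)

  # cross-check against the base-R exact test on random tables
  set.seed(42)
  for (i in 1:200) {
    x <- rpois(4, sample(1:15, 1))
    if (sum(x) == 0) next
    expect_equal(fisherExactTwoSided(x[1], x[2], x[3], x[4]),
                 fisher.test(matrix(x, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
})

test_that("per-strand genotype calls reproduce the printed conflicts", {
  g <- strandGenotypes(table1Counts())
  expect_equal(g$forward, rep("heterozygous", 3))
  expect_equal(g$reverse, rep("homozygous", 3))
  expect_true(all(hasGenotypeConflict(table1Counts())))

  expect_equal(strandGenotype(7, 0), "homozygous")
  expect_equal(strandGenotype(5, 5), "heterozygous")
  # fraction passes but count fails (1 < 2)
  expect_equal(strandGenotype(3, 1), "homozygous")
  # zero strand depth is uncallable, and a conflict is then undetermined
  expect_true(is.na(strandGenotype(0, 0)))
  expect_true(is.na(hasGenotypeConflict(StrandCounts(5, 2, 0, 0))))
  # worked example scores high bias yet no call conflict (2/13 < 0.2)
  expect_false(hasGenotypeConflict(StrandCounts(11, 2, 20, 0)))
  expect_false(hasGenotypeConflict(StrandCounts(10, 10, 10, 10)))
  # thresholds are configurable
  expect_true(hasGenotypeConflict(StrandCounts(11, 2, 20, 0),
                                  minFraction = 0.1, minCount = 1))
})

test_that("unassessable sites are flagged, not scored", {
  sc <- StrandCounts(c(11, 5), c(2, 2), c(20, 0), c(0, 0))
  out <- strandBiasScores(sc)
  expect_equal(out$score_status, c("ok", "unbalanced_strand"))
  expect_true(is.na(out$sb[2]))
  expect_true(is.na(out$gatk_sb[2]))
  expect_false(is.na(out$sb[1]))
})

test_that("scores obey their symmetry and zero laws", {
  set.seed(7)
  for (i in 1:200) {
    x <- rpois(4, 8) + c(1L, 0L, 1L, 0L)   # both strands covered
    if (x[1] + x[3] < x[2] + x[4]) x <- x[c(2, 1, 4, 3)]
    a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
    # strand swap
    expect_equal(sbScore(a, b, cc, d), sbScore(cc, d, a, b))
    expect_equal(gatkSbScore(a, b, cc, d), gatkSbScore(cc, d, a, b))
    expect_equal(fisherScore(a, b, cc, d), fisherScore(cc, d, a, b))
    # fisher column swap
    expect_equal(fisherScore(a, b, cc, d), fisherScore(b, a, d, cc),
                 tolerance = 1e-12)
    # non-negativity and ranges
    expect_gte(sbScore(a, b, cc, d), 0)
    expect_gte(gatkSbScore(a, b, cc, d), 0)
    f <- fisherScore(a, b, cc, d)
    expect_true(f >= 0 && f <= 1)
  }
  # all three scores vanish without minor reads
  expect_equal(sbScore(9, 0, 14, 0), 0)
  expect_equal(gatkSbScore(9, 0, 14, 0), 0)
  expect_equal(fisherScore(9, 0, 14, 0), 0)
})

test_that("with d = 0 the SB score is non-increasing in the minor count", {
  # algebraically (a+b+c)/(a+b): more minor evidence on one strand makes
  # the observed asymmetry *less* extreme relative to the pooled fraction
  for (a in c(5L, 11L, 20L)) {
    cc <- 15L
    s <- sbScore(rep(a, a), 1:a, rep(cc, a), rep(0, a))
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("GATK-SB approaches max(b/a, d/c) for rare minor alleles", {
  for (b in 0:2) for (d in 0:2) {
    if (b == 0 && d == 0) next
    g <- gatkSbScore(1000, b, 1000, d)
    lim <- max(b / 1000, d / 1000)
    expect_lt(abs(g - lim) / lim, 0.05)
  }
})
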