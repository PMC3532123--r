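## Strand-bias scores on the 2x2 strand x allele table.
##
## All three scores are oriented so that 0 means no strand bias and larger
## values mean more severe bias.  Sites where one strand carries no reads
## cannot be assessed for call-level strand bias; SB and GATK-SB return NA
## there (a flagged non-value, distinct from 0), matching the per-strand
## depth filter applied throughout the downstream analyses.

.sbCore <- function(a, b, c, d) {
  fwd <- a + b
  rev <- c + d
  n <- fwd + rev
  out <- rep(NA_real_, length(a))
  ok <- fwd >= 1L & rev >= 1L
  minor <- b + d
  mono <- ok & minor == 0L
  out[mono] <- 0                        # no minor reads: no bias evidence
  i <- ok & minor > 0L
  out[i] <- abs(b[i] / fwd[i] - d[i] / rev[i]) / (minor[i] / n[i])
  out
}

.gatkSbCore <- function(a, b, c, d) {
  fwd <- a + b
  rev <- c + d
  n <- fwd + rev
  maj <- a + c
  out <- rep(NA_real_, length(a))
  i <- fwd >= 1L & rev >= 1L & maj >= 1L
  t1 <- (b[i] / fwd[i]) * (c[i] / rev[i])
  t2 <- (d[i] / rev[i]) * (a[i] / fwd[i])
  out[i] <- pmax(t1, t2) / (maj[i] / n[i])
  out
}

.fisherCore <- function(a, b, c, d) {
  out <- rep(NA_real_, length(a))
  i <- (a + b + c + d) >= 1L
  out[i] <- 1 - fisherExactTwoSided(a[i], b[i], c[i], d[i])
  out
}

#' SB strand-bias score
#'
#' The SB score compares the minor-allele fraction seen on the two strands,
#' normalised by the pooled minor-allele fraction:
#' \deqn{SB = \frac{|b/(a+b) - d/(c+d)|}{(b+d)/(a+b+c+d)}}
#' It ranges over \eqn{[0, \infty)}; 0 means the minor allele is equally
#' represented on both strands. A monoallelic site (`b + d = 0`) scores 0
#' (no bias evidence). If either strand carries no reads the score is `NA`:
#' such sites are unassessable rather than unbiased, and are normally removed
#' by the per-strand depth filter (see [filterStrandDepth()]).
#'
#' @param x A [StrandCounts] or [VariantSet] object, or a numeric vector of
#'   forward-major counts (in which case `b`, `c`, `d` must be given).
#' @param b,c,d Numeric vectors: forward-minor, reverse-major and
#'   reverse-minor counts (numeric interface only).
#' @param ... Passed between methods.
#'
#' @return Numeric vector of scores, `NA` where a strand is uncovered.
#'
#' @examples
#' sbScore(StrandCounts(11, 2, 20, 0))   # 2.54 at 2 d.p.
#' sbScore(11, 2, 20, 0)
#'
#' @seealso [gatkSbScore()], [fisherScore()], [strandBiasScores()]
#' @export
setMethod("sbScore", "StrandCounts", function(x, ...)
  .sbCore(x@a, x@b, x@c, x@d))

#' @rdname sbScore
#' @export
setMethod("sbScore", "numeric", function(x, b, c, d, ...)
  .sbCore(x, b, c, d))

#' GATK-style strand-bias score
#'
#' The maximum of the two cross-strand fraction products, normalised by the
#' pooled major-allele fraction:
#' \deqn{\max\left[\frac{b}{a+b}\frac{c}{c+d},\;
#'       \frac{d}{c+d}\frac{a}{a+b}\right] \Big/ \frac{a+c}{a+b+c+d}}
#' When the minor allele is rare on both strands (`b << a`, `d << c`) this
#' simplifies to approximately `max(b/a, d/c)` and stays small even when all
#' minor reads sit on one strand, which is why it ranks sites differently
#' from [sbScore()] and [fisherScore()].
#'
#' @inheritParams sbScore
#' @return Numeric vector of scores, `NA` where a strand (or the major
#'   allele) is uncovered.
#'
#' @examples
#' gatkSbScore(StrandCounts(11, 2, 20, 0))   # 0.16 at 2 d.p.
#'
#' @export
setMethod("gatkSbScore", "StrandCounts", function(x, ...)
  .gatkSbCore(x@a, x@b, x@c, x@d))

#' @rdname gatkSbScore
#' @export
setMethod("gatkSbScore", "numeric", function(x, b, c, d, ...)
  .gatkSbCore(x, b, c, d))

#' Fisher strand-bias score
#'
#' One minus the two-sided Fisher exact p-value of the strand x allele 2x2
#' table, so that (like the other two scores) larger values mean more bias.
#' Two-sidedness follows the minimum-likelihood rule: the p-value is the sum
#' of the probabilities of all tables with the observed margins whose
#' hypergeometric probability does not exceed the observed table's (see
#' [fisherExactTwoSided()]).
#'
#' @inheritParams sbScore
#' @return Numeric vector of scores in `[0, 1]`.
#'
#' @examples
#' fisherScore(StrandCounts(11, 2, 20, 0))   # 0.85 at 2 d.p.
#'
#' @export
setMethod("fisherScore", "StrandCounts", function(x, ...)
  .fisherCore(x@a, x@b, x@c, x@d))

#' @rdname fisherScore
#' @export
setMethod("fisherScore", "numeric", function(x, b, c, d, ...)
  .fisherCore(x, b, c, d))

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact enumeration over the hypergeometric support with fixed margins.
#' The two-sided p-value is the sum of the probabilities of all tables at
#' least as extreme as (i.e. no more probable than) the observed one, with a
#' relative tolerance of 1e-7 on the probability comparison to absorb
#' floating-point ties — the same convention as [stats::fisher.test()].
#'
#' @param a,b,c,d Numeric vectors of cell counts (`a`, `b` top row; `c`, `d`
#'   bottom row). Vectorised elementwise.
#' @param relErr Relative tolerance factor for the "no more probable than"
#'   comparison.
#'
#' @return Numeric vector of p-values in `(0, 1]`.
#'
#' @examples
#' fisherExactTwoSided(11, 2, 20, 0)   # 78/528
#'
#' @export
fisherExactTwoSided <- function(a, b, c, d, relErr = 1 + 1e-7) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    m <- a[i] + c[i]                    # first-column margin
    nn <- b[i] + d[i]                   # second-column margin
    k <- a[i] + b[i]                    # first-row margin
    lo <- max(0, k - nn)
    hi <- min(k, m)
    dens <- dhyper(lo:hi, m, nn, k)
    out[i] <- sum(dens[dens <= dens[a[i] - lo + 1] * relErr])
  }
  pmin(out, 1)
}

#' Per-strand genotype calls and genotype conflicts
#'
#' A strand's genotype is called from its own two allele counts alone: the
#' call is heterozygous when the strand's minor-allele fraction is at least
#' `minFraction` *and* the strand's minor-allele count is at least
#' `minCount`; otherwise homozygous. A strand with zero depth is uncallable
#' (`NA`). A position has a genotype conflict when the two strands' calls
#' disagree — the defining signature of strand bias in the calls.
#'
#' @param major,minor Numeric vectors of a single strand's major- and
#'   minor-allele read counts (for `strandGenotype`).
#' @param x A [StrandCounts] or [VariantSet] object.
#' @param minFraction Minimum strand minor-allele fraction for a
#'   heterozygous call (default 0.2).
#' @param minCount Minimum strand minor-allele read count for a heterozygous
#'   call (default 2).
#' @param ... Passed between methods.
#'
#' @return `strandGenotype()` returns a character vector of
#'   `"heterozygous"` / `"homozygous"` calls (`NA` where the strand has zero
#'   depth). `strandGenotypes()` returns a data frame with columns `forward`
#'   and `reverse`. `hasGenotypeConflict()` returns a logical vector, `NA`
#'   (undetermined) where either strand is uncovered.
#'
#' @examples
#' strandGenotype(major = 5, minor = 5)     # heterozygous
#' strandGenotype(major = 10, minor = 1)    # homozygous
#' hasGenotypeConflict(StrandCounts(15, 9, 7, 0))
#'
#' @export
strandGenotype <- function(major, minor, minFraction = 0.2, minCount = 2) {
  depth <- major + minor
  out <- rep(NA_character_, length(depth))
  i <- depth >= 1
  het <- i & (minor / depth >= minFraction) & (minor >= minCount)
  out[i] <- ifelse(het[i], "heterozygous", "homozygous")
  out
}

#' @rdname strandGenotype
#' @export
setMethod("strandGenotypes", "StrandCounts",
          function(x, minFraction = 0.2, minCount = 2, ...) {
  data.frame(
    forward = strandGenotype(x@a, x@b, minFraction, minCount),
    reverse = strandGenotype(x@c, x@d, minFraction, minCount))
})

#' @rdname strandGenotype
#' @export
setMethod("hasGenotypeConflict", "StrandCounts",
          function(x, minFraction = 0.2, minCount = 2, ...) {
  g <- strandGenotypes(x, minFraction, minCount)
  ifelse(is.na(g$forward) | is.na(g$reverse), NA, g$forward != g$reverse)
})

#' All three strand-bias scores with a status flag
#'
#' Computes [sbScore()], [gatkSbScore()] and [fisherScore()] for every
#' position and labels each position's assessability: `"ok"` when both
#' strands carry reads, `"unbalanced_strand"` when one strand is uncovered
#' (SB and GATK-SB are `NA` there; the Fisher score is still defined from
#' the full table but such sites are normally excluded by the depth filter).
#'
#' @param x A [StrandCounts] or [VariantSet] object.
#' @param ... Passed between methods.
#'
#' @return A data frame with columns `sb`, `gatk_sb`, `fisher`,
#'   `score_status`.
#'
#' @examples
#' strandBiasScores(StrandCounts(c(11, 10), c(2, 0), c(20, 10), c(0, 0)))
#'
#' @export
setMethod("strandBiasScores", "StrandCounts", function(x, ...) {
  status <- ifelse(fwdDepth(x) >= 1L & revDepth(x) >= 1L,
                   "ok", "unbalanced_strand")
  data.frame(sb = sbScore(x), gatk_sb = gatkSbScore(x),
             fisher = fisherScore(x), score_status = status)
})
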