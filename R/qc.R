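## Genotype-quality metrics: Ti/Tv ratios by MAF bin and variant subset,
## quantile stratification by strand-bias score, chip heterozygous
## concordance, and novel non-synonymous counting.

.MAFBIN_LABELS <- c("0-0.1", "0.1-0.2", "0.2-0.3", "0.3-0.4", "0.4-0.5")
.SCORE_KINDS <- c("sb", "gatk_sb", "fisher")

.scoreVector <- function(x, scoreKind) {
  scoreKind <- match.arg(scoreKind, .SCORE_KINDS)
  switch(scoreKind,
         sb = sbScore(x),
         gatk_sb = gatkSbScore(x),
         fisher = fisherScore(x))
}

#' Transitions, transversions and the Ti/Tv ratio
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine substitutions
#' (A<->G, C<->T); the other eight ordered substitutions are transversions.
#' The transition/transversion ratio of a call set is a standard quality
#' indicator: around 3.0 for SNPs inside exons, around 2.0 elsewhere, and
#' markedly lower for sets contaminated with false positives (random errors
#' push it towards 0.5).
#'
#' @param ref,alt Character vectors of single nucleotides, `ref != alt`.
#' @param x A character vector of reference alleles (paired with `alt`) or a
#'   [VariantSet].
#' @param ... Passed between methods.
#'
#' @return `isTransition()`: logical vector. `titvRatio()`: the ratio
#'   (transitions / transversions), or `NA` (undefined) when there are no
#'   transversions.
#'
#' @examples
#' isTransition("A", "G")
#' titvRatio(c("A", "C", "A"), c("G", "T", "C"))   # 2 Ti, 1 Tv -> 2
#'
#' @export
isTransition <- function(ref, alt) {
  if (!all(ref %in% .NUCS) || !all(alt %in% .NUCS))
    stop("alleles must be single nucleotides A/C/G/T")
  if (any(ref == alt))
    stop("ref and alt must differ")
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

#' @rdname isTransition
#' @export
setMethod("titvRatio", "character", function(x, alt, ...) {
  if (length(x) == 0L)
    stop("empty variant collection")
  ti <- sum(isTransition(x, alt))
  tv <- length(x) - ti
  if (tv == 0L) NA_real_ else ti / tv
})

#' @rdname isTransition
#' @export
setMethod("titvRatio", "VariantSet", function(x, ...) {
  titvRatio(refAllele(x), altAllele(x))
})

#' Bin a minor allele frequency into the five standard MAF classes
#'
#' Bins are left-closed, right-open — `[0, 0.1), [0.1, 0.2), ..., [0.4,
#' 0.5]` — with the final bin closed at 0.5.
#'
#' @param maf Numeric vector in `[0, 0.5]` (no `NA`).
#' @return A factor with levels `"0-0.1"`, `"0.1-0.2"`, `"0.2-0.3"`,
#'   `"0.3-0.4"`, `"0.4-0.5"`.
#' @examples
#' mafBin(c(0.05, 0.1, 0.5))
#' @export
mafBin <- function(maf) {
  if (anyNA(maf) || any(maf < 0 | maf > 0.5))
    stop("maf values must lie in [0, 0.5]")
  idx <- pmin(findInterval(maf, c(0, 0.1, 0.2, 0.3, 0.4)), 5L)
  factor(.MAFBIN_LABELS[idx], levels = .MAFBIN_LABELS)
}

#' Ti/Tv quality grid by MAF bin and variant subset
#'
#' Cross-tabulates the call set into five overlapping subsets — all
#' sequencing SNPs, those also on the genotyping chip ("overlapped"), those
#' not on the chip, those in dbSNP, and dbSNP SNPs not on the chip — by the
#' five MAF bins (plus an overall column), reporting the SNP count and Ti/Tv
#' ratio per cell. The subsets are computed by set algebra from the
#' `in_dbsnp` / `on_chip` flags, so the partition identities (All =
#' Overlapped + rest; dbSNP-not-on-chip = dbSNP - Overlapped) hold by
#' construction. Sites with missing MAF are excluded with a message.
#'
#' @param x A [VariantSet] whose sites carry `maf` and membership flags.
#'
#' @return A data frame with columns `subset`, `maf_bin` (five bins plus
#'   `"Overall"`), `n` and `titv` (`NA` when the cell has no transversions
#'   or no SNPs). See [writeTitvGrid()] for the grid-shaped serialisation.
#'
#' @examples
#' cohort <- simulateCohort(simulationConfig(nSamples = 2, nSites = 300))
#' head(titvTable(cohortVariants(cohort)))
#'
#' @export
titvTable <- function(x) {
  maf <- siteMaf(x)
  if (anyNA(maf)) {
    message("titvTable: excluding ", sum(is.na(maf)), " site(s) with ",
            "missing maf")
    x <- x[!is.na(maf)]
    maf <- siteMaf(x)
  }
  subsets <- list(
    "All Seq SNPs" = rep(TRUE, length(x)),
    "Overlapped SNPs" = onChip(x),
    "Seq SNPs - Chip SNPs" = !onChip(x),
    "dbSNP SNPs in Seq" = inDbsnp(x),
    "dbSNP SNPs not on Chip" = inDbsnp(x) & !onChip(x))
  bins <- mafBin(maf)
  binLevels <- c(.MAFBIN_LABELS, "Overall")
  ref <- refAllele(x)
  alt <- altAllele(x)
  rows <- lapply(names(subsets), function(sn) {
    inSub <- subsets[[sn]]
    cells <- lapply(binLevels, function(bl) {
      i <- inSub & (bl == "Overall" | bins == bl)
      n <- sum(i)
      tt <- if (n == 0L) NA_real_ else titvRatio(ref[i], alt[i])
      data.frame(subset = sn, maf_bin = bl, n = n, titv = tt)
    })
    do.call(rbind, cells)
  })
  out <- do.call(rbind, rows)
  out$maf_bin <- factor(out$maf_bin, levels = binLevels)
  rownames(out) <- NULL
  out
}

#' Stratify variants into low- and high-bias quantile sets
#'
#' Splits sites on the empirical quantiles of a strand-bias score: the
#' bottom `fraction` ("low or no strand bias") versus the top `fraction`
#' ("extreme strand bias", the recommended false-positive-candidate
#' threshold at the default `fraction = 0.1`). Thresholds use linear
#' interpolation; ties at a threshold are assigned inclusively to the
#' extreme set, and the two sets are kept disjoint. Stratification is
#' per-sample by default (each sample's own score distribution defines its
#' quantiles); `perSample = FALSE` pools the cohort. A degenerate (all-equal
#' or overlapping-threshold) score distribution yields empty strata with a
#' warning. Scores must be defined for every site: apply
#' [filterStrandDepth()] first.
#'
#' @param x A [VariantSet].
#' @param scoreKind One of `"sb"`, `"gatk_sb"`, `"fisher"`.
#' @param fraction Quantile fraction in `(0, 0.5]` (default 0.1).
#' @param perSample Stratify within each sample (default) or pooled.
#'
#' @return A list with `low` and `high` (integer indices into `x`),
#'   `thresholds` (per-sample data frame of cut points), `score_kind` and
#'   `fraction`.
#'
#' @examples
#' cohort <- simulateCohort(simulationConfig(nSamples = 1, nSites = 400))
#' vs <- filterStrandDepth(cohortVariants(cohort))
#' s <- stratifyByScore(vs, "sb")
#' length(s$low); length(s$high)
#'
#' @export
stratifyByScore <- function(x, scoreKind = c("sb", "gatk_sb", "fisher"),
                            fraction = 0.1, perSample = TRUE) {
  scoreKind <- match.arg(scoreKind)
  if (fraction <= 0 || fraction > 0.5)
    stop("'fraction' must lie in (0, 0.5]")
  score <- .scoreVector(x, scoreKind)
  if (anyNA(score))
    stop("undefined scores present; apply filterStrandDepth() first")
  groups <- if (perSample) split(seq_along(score), sampleIds(x))
            else list(pooled = seq_along(score))
  minN <- ceiling(2 / fraction)
  low <- integer(0)
  high <- integer(0)
  thr <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    s <- score[idx]
    if (length(s) < minN)
      stop("sample '", g, "' has ", length(s), " scored sites; at least ",
           minN, " are needed for fraction = ", fraction)
    qlo <- unname(quantile(s, fraction, type = 7))
    qhi <- unname(quantile(s, 1 - fraction, type = 7))
    if (qhi <= qlo) {
      warning("degenerate score distribution in sample '", g,
              "': strata left empty")
      return(data.frame(sample_id = g, low_cut = qlo, high_cut = qhi,
                        degenerate = TRUE))
    }
    low <<- c(low, idx[s <= qlo])
    high <<- c(high, idx[s >= qhi])
    data.frame(sample_id = g, low_cut = qlo, high_cut = qhi,
               degenerate = FALSE)
  })
  list(low = sort(low), high = sort(high),
       thresholds = do.call(rbind, thr),
       score_kind = scoreKind, fraction = fraction)
}

.chipHet <- function(chip) chip$allele1 != chip$allele2

#' Heterozygous concordance between sequencing calls and chip genotypes
#'
#' The consistency rate is the number of heterozygous SNPs with a consistent
#' genotype between the sequencing calls and the chip, divided by all
#' chip-heterozygous SNPs overlapped by the sequencing data. Only chip
#' heterozygotes enter the denominator: strand bias cannot push a true
#' homozygote to a false heterozygous call strongly enough to matter, so
#' heterozygous sites are where quality is at stake. In `"allele"` mode
#' (default) a match requires the sequencing call to be heterozygous with
#' the same allele pair as the chip; `"zygosity"` mode only requires a
#' heterozygous sequencing call.
#'
#' @param x A [VariantSet] of sequencing calls.
#' @param chip A chip genotype table as returned by [readChipGenotypes()]
#'   (columns `sample`, `chrom`, `pos`, `allele1`, `allele2`).
#' @param level `"allele"` or `"zygosity"`.
#'
#' @return The consistency rate in `[0, 1]`, or `NA` when no chip
#'   heterozygote is overlapped.
#'
#' @examples
#' cohort <- simulateCohort(simulationConfig(nSamples = 2, nSites = 500,
#'                                           chipOverlapFraction = 0.5))
#' hetConsistencyRate(cohortVariants(cohort), chipGenotypes(cohort))
#'
#' @export
hetConsistencyRate <- function(x, chip, level = c("allele", "zygosity")) {
  level <- match.arg(level)
  chip <- chip[.chipHet(chip), , drop = FALSE]
  if (nrow(chip) == 0L)
    return(NA_real_)
  keys <- siteKeys(x)
  chipKeys <- .keys(chip$sample, chip$chrom, chip$pos)
  hit <- match(chipKeys, keys)
  covered <- !is.na(hit)
  if (!any(covered))
    return(NA_real_)
  i <- hit[covered]
  seqHet <- seqGenotype(x)[i] == "het"
  if (level == "allele") {
    pairSeq <- paste(pmin(refAllele(x)[i], altAllele(x)[i]),
                     pmax(refAllele(x)[i], altAllele(x)[i]))
    pairChip <- paste(pmin(chip$allele1[covered], chip$allele2[covered]),
                      pmax(chip$allele1[covered], chip$allele2[covered]))
    ok <- seqHet & pairSeq == pairChip
  } else {
    ok <- seqHet
  }
  mean(ok)
}

#' Chip concordance along strand-bias score quantiles
#'
#' Reproduces the score-quantile versus consistency analysis: sites passing
#' the per-strand depth filter and overlapping a chip heterozygote are
#' ranked by a strand-bias score and divided into `nBins` equal-occupancy
#' quantile bins (default 20, i.e. 5% each); the heterozygous consistency
#' rate is reported per bin. A drop in the upper bins indicates that extreme
#' strand bias degrades genotype quality.
#'
#' @inheritParams hetConsistencyRate
#' @param scoreKind One of `"sb"`, `"gatk_sb"`, `"fisher"`.
#' @param nBins Number of quantile bins (default 20).
#' @param minStrandDepth Per-strand depth filter applied before binning
#'   (default 10).
#'
#' @return A data frame with one row per bin: `bin`, `n`, `consistency`
#'   (`NA` for an empty bin), `score_min`, `score_max`.
#'
#' @examples
#' cohort <- simulateCohort(simulationConfig(nSamples = 2, nSites = 2000,
#'                                           chipOverlapFraction = 0.5))
#' cq <- consistencyByQuantile(cohortVariants(cohort),
#'                             chipGenotypes(cohort), "sb")
#' head(cq)
#'
#' @export
consistencyByQuantile <- function(x, chip,
                                  scoreKind = c("sb", "gatk_sb", "fisher"),
                                  nBins = 20, minStrandDepth = 10,
                                  level = c("allele", "zygosity")) {
  scoreKind <- match.arg(scoreKind)
  level <- match.arg(level)
  x <- filterStrandDepth(x, minStrandDepth)
  chip <- chip[.chipHet(chip), , drop = FALSE]
  keys <- siteKeys(x)
  hit <- match(.keys(chip$sample, chip$chrom, chip$pos), keys)
  covered <- !is.na(hit)
  i <- hit[covered]
  if (length(i) == 0L)
    stop("no chip-heterozygous site passes the depth filter")
  score <- .scoreVector(x[i], scoreKind)
  seqHet <- seqGenotype(x)[i] == "het"
  if (level == "allele") {
    pairSeq <- paste(pmin(refAllele(x)[i], altAllele(x)[i]),
                     pmax(refAllele(x)[i], altAllele(x)[i]))
    pairChip <- paste(pmin(chip$allele1[covered], chip$allele2[covered]),
                      pmax(chip$allele1[covered], chip$allele2[covered]))
    ok <- seqHet & pairSeq == pairChip
  } else {
    ok <- seqHet
  }
  ord <- order(score, keys[i])           # deterministic tie-break
  r <- integer(length(ord))
  r[ord] <- seq_along(ord)
  bin <- ceiling(r * nBins / length(r))
  out <- do.call(rbind, lapply(seq_len(nBins), function(bnum) {
    j <- bin == bnum
    data.frame(bin = bnum, n = sum(j),
               consistency = if (any(j)) mean(ok[j]) else NA_real_,
               score_min = if (any(j)) min(score[j]) else NA_real_,
               score_max = if (any(j)) max(score[j]) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Count novel non-synonymous SNPs
#'
#' Exome sequencing is expected to yield only 200-300 novel non-synonymous
#' SNPs per person; a larger count indicates a high false-positive rate, so
#' this count is used as a quality indicator alongside Ti/Tv. A SNP counts
#' as novel non-synonymous when it is absent from dbSNP and its functional
#' class is `"non-synonymous"` (missing classes never count).
#'
#' @param x A [VariantSet].
#' @param perSample If `TRUE`, return a named vector of per-sample counts.
#'
#' @return Integer count (or named integer vector).
#' @examples
#' cohort <- simulateCohort(simulationConfig(nSamples = 2, nSites = 500))
#' countNovelNonsynonymous(cohortVariants(cohort), perSample = TRUE)
#' @export
countNovelNonsynonymous <- function(x, perSample = FALSE) {
  hit <- !inDbsnp(x) & !is.na(functionalClass(x)) &
    functionalClass(x) == "non-synonymous"
  if (!perSample)
    return(sum(hit))
  vapply(split(hit, sampleIds(x)), sum, integer(1))
}
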