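#' A set of variant sites with stranded allele counts and annotations
#'
#' `VariantSet` is the package's central container: a set of biallelic SNP
#' calls, each carrying its stranded allele counts (see [StrandCounts]),
#' reference/alternate alleles, the calling sample, membership flags (dbSNP,
#' genotyping chip), a functional class, an optional minor-allele-frequency
#' annotation and the sequencing genotype call. Positions are 1-based; the
#' sites are held as a width-1 [GenomicRanges::GRanges] (retrievable via
#' `variantRanges()`).
#'
#' If `seqGenotype` is not supplied it is derived from the pooled counts with
#' the same heterozygosity rule used per strand (pooled minor fraction >=
#' `hetMinFraction` and pooled minor count >= `hetMinCount` gives `"het"`,
#' otherwise `"hom-alt"` — a site present in a variant table is a call, so a
#' non-heterozygous call is homozygous for the alternate/major allele).
#'
#' Validity enforces: alleles in A/C/G/T with `ref != alt`; count invariants
#' as in [StrandCounts]; `on_chip` implies `in_dbsnp` (all SNPs on standard
#' genotyping chips are in dbSNP); `maf` in `[0, 0.5]` or `NA`.
#'
#' @param chrom Character vector of chromosome labels.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Reference and alternate alleles (single nucleotides).
#' @param a,b,c,d Stranded counts in major/minor orientation as in
#'   [StrandCounts].
#' @param sampleId Sample identifier(s); recycled.
#' @param inDbsnp,onChip Logical annotation flags; recycled.
#' @param functionalClass `"synonymous"`, `"non-synonymous"`, `"other"` or
#'   `NA`; recycled.
#' @param maf Minor allele frequency annotation in `[0, 0.5]` or `NA`;
#'   recycled.
#' @param seqGenotype Optional sequencing genotype call per site
#'   (`"hom-ref"`, `"het"` or `"hom-alt"`); derived from counts when `NULL`.
#' @param hetMinFraction,hetMinCount Pooled-count heterozygosity thresholds
#'   used when deriving `seqGenotype`.
#' @param x A `VariantSet` (accessors).
#' @param ... Unused.
#'
#' @return `VariantSet()` returns a `VariantSet`. Accessors return the
#'   corresponding per-site vectors; `strandCounts()` returns a
#'   [StrandCounts]; `variantRanges()` the underlying `GRanges`;
#'   `siteKeys()` a character key `sample:chrom:pos` unique per record.
#'
#' @examples
#' vs <- VariantSet(chrom = "7", pos = 43917013, ref = "A", alt = "G",
#'                  a = 11, b = 2, c = 20, d = 0)
#' sbScore(vs)
#' seqGenotype(vs)
#'
#' @aliases VariantSet-class
#' @export
VariantSet <- function(chrom, pos, ref, alt, a, b, c, d,
                       sampleId = "sample1", inDbsnp = FALSE, onChip = FALSE,
                       functionalClass = NA_character_, maf = NA_real_,
                       seqGenotype = NULL,
                       hetMinFraction = 0.2, hetMinCount = 2) {
  n <- length(pos)
  counts <- StrandCounts(a, b, c, d)
  if (is.null(seqGenotype))
    seqGenotype <- .pooledGenotype(counts, hetMinFraction, hetMinCount)
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    a = counts@a, b = counts@b, c = counts@c, d = counts@d,
    sample_id = rep_len(as.character(sampleId), n),
    in_dbsnp = rep_len(as.logical(inDbsnp), n),
    on_chip = rep_len(as.logical(onChip), n),
    functional_class = rep_len(as.character(functionalClass), n),
    maf = rep_len(as.numeric(maf), n),
    seq_genotype = rep_len(as.character(seqGenotype), n))
  new("VariantSet", sites = gr)
}

setClass("VariantSet", slots = c(sites = "GRanges"))

.NUCS <- c("A", "C", "G", "T")
.GENOTYPES <- c("hom-ref", "het", "hom-alt")
.FUNCLASSES <- c("synonymous", "non-synonymous", "other")

.pooledGenotype <- function(counts, minFraction = 0.2, minCount = 2) {
  minor <- counts@b + counts@d
  tot <- totalDepth(counts)
  ifelse(minor / tot >= minFraction & minor >= minCount, "het", "hom-alt")
}

setValidity("VariantSet", function(object) {
  m <- S4Vectors::mcols(object@sites)
  need <- c("ref", "alt", "a", "b", "c", "d", "sample_id", "in_dbsnp",
            "on_chip", "functional_class", "maf", "seq_genotype")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    return(paste("missing site columns:", paste(miss, collapse = ", ")))
  if (length(object@sites) == 0L)
    return(TRUE)
  if (!all(m$ref %in% .NUCS) || !all(m$alt %in% .NUCS))
    return("ref and alt must be single nucleotides A/C/G/T")
  if (any(m$ref == m$alt))
    return("ref and alt must differ")
  v <- validObject(new("StrandCounts", a = m$a, b = m$b, c = m$c, d = m$d),
                   test = TRUE)
  if (is.character(v))
    return(v)
  if (any(m$on_chip & !m$in_dbsnp))
    return("on_chip implies in_dbsnp")
  if (any(!is.na(m$maf) & (m$maf < 0 | m$maf > 0.5)))
    return("maf must lie in [0, 0.5]")
  if (!all(m$seq_genotype %in% .GENOTYPES))
    return("seq_genotype must be one of hom-ref, het, hom-alt")
  if (!all(is.na(m$functional_class) |
           m$functional_class %in% .FUNCLASSES))
    return("functional_class must be synonymous/non-synonymous/other or NA")
  if (anyDuplicated(.keys(m$sample_id, as.character(
        GenomicRanges::seqnames(object@sites)),
        GenomicRanges::start(object@sites))))
    return("duplicate (sample, chrom, pos) records")
  TRUE
})

.keys <- function(sample, chrom, pos) paste(sample, chrom, pos, sep = ":")

setMethod("length", "VariantSet", function(x) length(x@sites))

setMethod("[", "VariantSet", function(x, i, j, ..., drop = TRUE)
  initialize(x, sites = x@sites[i]))

setMethod("show", "VariantSet", function(object) {
  cat("VariantSet with", length(object), "site(s) from",
      length(unique(sampleIds(object))), "sample(s)\n")
  if (length(object))
    print(utils::head(as.data.frame(object), 6L))
  if (length(object) > 6L)
    cat("...", length(object) - 6L, "more\n")
})

#' @exportS3Method base::as.data.frame
as.data.frame.VariantSet <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  m <- as.data.frame(S4Vectors::mcols(x@sites))
  data.frame(chrom = as.character(GenomicRanges::seqnames(x@sites)),
             pos = GenomicRanges::start(x@sites), m,
             row.names = row.names, stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "VariantSet", as.data.frame.VariantSet)

#' @rdname VariantSet
#' @export
setMethod("strandCounts", "VariantSet", function(x, ...) {
  m <- S4Vectors::mcols(x@sites)
  new("StrandCounts", a = m$a, b = m$b, c = m$c, d = m$d)
})

#' @rdname VariantSet
#' @export
variantRanges <- function(x) x@sites

#' @rdname VariantSet
#' @export
sampleIds <- function(x) S4Vectors::mcols(x@sites)$sample_id

#' @rdname VariantSet
#' @export
refAllele <- function(x) S4Vectors::mcols(x@sites)$ref

#' @rdname VariantSet
#' @export
altAllele <- function(x) S4Vectors::mcols(x@sites)$alt

#' @rdname VariantSet
#' @export
inDbsnp <- function(x) S4Vectors::mcols(x@sites)$in_dbsnp

#' @rdname VariantSet
#' @export
onChip <- function(x) S4Vectors::mcols(x@sites)$on_chip

#' @rdname VariantSet
#' @export
functionalClass <- function(x) S4Vectors::mcols(x@sites)$functional_class

#' @rdname VariantSet
#' @export
siteMaf <- function(x) S4Vectors::mcols(x@sites)$maf

#' @rdname VariantSet
#' @export
seqGenotype <- function(x) S4Vectors::mcols(x@sites)$seq_genotype

#' @rdname VariantSet
#' @export
siteKeys <- function(x) {
  .keys(sampleIds(x), as.character(GenomicRanges::seqnames(x@sites)),
        GenomicRanges::start(x@sites))
}

#' @rdname sbScore
#' @export
setMethod("sbScore", "VariantSet", function(x, ...)
  sbScore(strandCounts(x)))

#' @rdname gatkSbScore
#' @export
setMethod("gatkSbScore", "VariantSet", function(x, ...)
  gatkSbScore(strandCounts(x)))

#' @rdname fisherScore
#' @export
setMethod("fisherScore", "VariantSet", function(x, ...)
  fisherScore(strandCounts(x)))

#' @rdname strandBiasScores
#' @export
setMethod("strandBiasScores", "VariantSet", function(x, ...)
  strandBiasScores(strandCounts(x)))

#' @rdname strandGenotype
#' @export
setMethod("strandGenotypes", "VariantSet",
          function(x, minFraction = 0.2, minCount = 2, ...)
  strandGenotypes(strandCounts(x), minFraction, minCount))

#' @rdname strandGenotype
#' @export
setMethod("hasGenotypeConflict", "VariantSet",
          function(x, minFraction = 0.2, minCount = 2, ...)
  hasGenotypeConflict(strandCounts(x), minFraction, minCount))

#' Filter sites by per-strand depth
#'
#' Strand-bias scores are only reliable when both strands are well covered;
#' the analyses here use a forward depth >= 10 and a reverse depth >= 10
#' filter before scoring, stratification and concordance.
#'
#' @param x A [VariantSet].
#' @param minStrandDepth Minimum read depth required on *each* strand
#'   (default 10).
#'
#' @return The filtered `VariantSet`.
#' @examples
#' vs <- VariantSet(chrom = "1", pos = 1:2, ref = "A", alt = "G",
#'                  a = c(11, 3), b = c(2, 1), c = c(20, 4), d = 0)
#' length(filterStrandDepth(vs))
#' @export
filterStrandDepth <- function(x, minStrandDepth = 10) {
  sc <- strandCounts(x)
  x[fwdDepth(sc) >= minStrandDepth & revDepth(sc) >= minStrandDepth]
}
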