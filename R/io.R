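## Readers and writers for the package's plain-text formats.
##
## counts TSV: one record per (sample, chrom, pos) with header
##   chrom pos ref alt a b c d in_dbsnp on_chip functional_class maf
##   sample_id seq_genotype
## NA is only permitted in maf, functional_class and seq_genotype.

.COUNTS_COLS <- c("chrom", "pos", "ref", "alt", "a", "b", "c", "d",
                  "in_dbsnp", "on_chip", "functional_class", "maf",
                  "sample_id", "seq_genotype")

#' Read and write stranded allele-count tables
#'
#' `readCounts()` reads the package's counts TSV (fixed column order, header
#' required; see Details) into a [VariantSet], reporting malformed lines by
#' file line number and refusing duplicate (sample, chrom, pos) records.
#' `writeCounts()` writes a `VariantSet` back; a written-then-read cohort
#' reproduces the original object.
#'
#' @details Columns: `chrom`, `pos` (1-based), `ref`, `alt`, stranded counts
#'   `a b c d` (forward-major, forward-minor, reverse-major, reverse-minor),
#'   flags `in_dbsnp` and `on_chip` (0/1), `functional_class`
#'   (`synonymous` / `non-synonymous` / `other` / `NA`), `maf` (or `NA`),
#'   `sample_id` and `seq_genotype` (the caller's genotype: `hom-ref`,
#'   `het`, `hom-alt`, or `NA` to re-derive it from the pooled counts).
#'   `NA` is only permitted in `maf`, `functional_class` and
#'   `seq_genotype`.
#'
#' @param path File path.
#' @param x A [VariantSet] to write.
#'
#' @return `readCounts()` returns a [VariantSet]; `writeCounts()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' vs <- VariantSet(chrom = "7", pos = 43917013, ref = "A", alt = "G",
#'                  a = 11, b = 2, c = 20, d = 0)
#' writeCounts(vs, f)
#' readCounts(f)
#' @export
readCounts <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE,
                   na.strings = NULL)
  if (!identical(colnames(df), .COUNTS_COLS))
    stop("counts file must have header columns: ",
         paste(.COUNTS_COLS, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("counts file contains a header but no records")
    return(VariantSet(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), sampleId = character(0),
                      seqGenotype = character(0)))
  }
  line <- seq_len(nrow(df)) + 1L        # header is line 1
  bad <- function(cond, why) {
    if (any(cond))
      stop("malformed counts record(s) at line(s) ",
           paste(line[cond], collapse = ", "), ": ", why)
  }
  num <- function(col) suppressWarnings(as.numeric(df[[col]]))
  for (col in c("a", "b", "c", "d")) {
    v <- num(col)
    bad(is.na(v) | v < 0 | v != round(v),
        paste0("'", col, "' must be a non-negative integer"))
  }
  posv <- num("pos")
  bad(is.na(posv) | posv < 1 | posv != round(posv),
      "'pos' must be a positive integer")
  bad(!(df$ref %in% .NUCS) | !(df$alt %in% .NUCS),
      "'ref'/'alt' must be nucleotides A/C/G/T")
  bad(df$ref == df$alt, "'ref' and 'alt' must differ")
  bad(!(df$in_dbsnp %in% c("0", "1")) | !(df$on_chip %in% c("0", "1")),
      "'in_dbsnp'/'on_chip' must be 0 or 1")
  bad(!(df$functional_class %in% c(.FUNCLASSES, "NA")),
      "'functional_class' must be synonymous/non-synonymous/other or NA")
  mafv <- suppressWarnings(as.numeric(ifelse(df$maf == "NA", NA, df$maf)))
  bad(df$maf != "NA" & (is.na(mafv) | mafv < 0 | mafv > 0.5),
      "'maf' must lie in [0, 0.5] or be NA")
  bad(df$sample_id == "" | df$chrom == "", "empty 'chrom' or 'sample_id'")
  bad(!(df$seq_genotype %in% c("hom-ref", "het", "hom-alt", "NA")),
      "'seq_genotype' must be hom-ref/het/hom-alt or NA")
  keys <- .keys(df$sample_id, df$chrom, df$pos)
  bad(duplicated(keys) | duplicated(keys, fromLast = TRUE),
      "duplicate (sample, chrom, pos) record")
  VariantSet(chrom = df$chrom, pos = as.integer(posv),
             ref = df$ref, alt = df$alt,
             a = num("a"), b = num("b"), c = num("c"), d = num("d"),
             sampleId = df$sample_id,
             inDbsnp = df$in_dbsnp == "1", onChip = df$on_chip == "1",
             functionalClass = ifelse(df$functional_class == "NA",
                                      NA_character_, df$functional_class),
             maf = mafv,
             seqGenotype = if (all(df$seq_genotype == "NA")) NULL
                           else df$seq_genotype)
}

#' @rdname readCounts
#' @export
writeCounts <- function(x, path) {
  df <- as.data.frame(x)
  out <- data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref,
                    alt = df$alt, a = df$a, b = df$b, c = df$c, d = df$d,
                    in_dbsnp = as.integer(df$in_dbsnp),
                    on_chip = as.integer(df$on_chip),
                    functional_class = ifelse(is.na(df$functional_class),
                                              "NA", df$functional_class),
                    maf = ifelse(is.na(df$maf), "NA",
                                 sprintf("%.17g", df$maf)),
                    sample_id = df$sample_id,
                    seq_genotype = df$seq_genotype)
  .writeAtomic(path, function(tmp)
    write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Read and write chip genotype tables
#'
#' TSV with header `sample`, `chrom`, `pos`, `allele1`, `allele2`; one row
#' per genotyped (sample, position). Duplicate keys and missing alleles are
#' errors (reported with line numbers).
#'
#' @param path File path.
#' @param chip A chip genotype data frame to write.
#' @return `readChipGenotypes()` returns the validated data frame.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeChipGenotypes(data.frame(sample = "S01", chrom = "1", pos = 100,
#'                               allele1 = "A", allele2 = "G"), f)
#' readChipGenotypes(f)
#' @export
readChipGenotypes <- function(path) {
  cols <- c("sample", "chrom", "pos", "allele1", "allele2")
  df <- read.delim(path, colClasses = "character", na.strings = NULL)
  if (!identical(colnames(df), cols))
    stop("chip file must have header columns: ",
         paste(cols, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L
  bad <- function(cond, why) {
    if (any(cond))
      stop("malformed chip record(s) at line(s) ",
           paste(line[cond], collapse = ", "), ": ", why)
  }
  posv <- suppressWarnings(as.numeric(df$pos))
  bad(is.na(posv) | posv < 1 | posv != round(posv),
      "'pos' must be a positive integer")
  bad(!(df$allele1 %in% .NUCS) | !(df$allele2 %in% .NUCS),
      "'allele1'/'allele2' must be nucleotides A/C/G/T")
  keys <- .keys(df$sample, df$chrom, df$pos)
  bad(duplicated(keys) | duplicated(keys, fromLast = TRUE),
      "duplicate (sample, chrom, pos) genotype")
  df$pos <- as.integer(posv)
  df
}

#' @rdname readChipGenotypes
#' @export
writeChipGenotypes <- function(chip, path) {
  .writeAtomic(path, function(tmp)
    write.table(chip, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Read stranded allele counts from a VCF
#'
#' Standard callers rarely report per-strand allele counts, but several emit
#' them as annotations. Two layouts are supported through `field`:
#' a DP4-style field of four integers in the order ref-forward, ref-reverse,
#' alt-forward, alt-reverse (e.g. `field = "DP4"`), or a pair of per-allele
#' depth fields `"fwd,rev"` (e.g. `field = "ADF,ADR"`, values ordered ref
#' then each alt) from which multi-allelic records are reduced to the two
#' best-supported alleles via [reduceToBiallelic()]. Records failing the VCF
#' FILTER and records with non-SNV alleles are skipped with a logged count.
#'
#' @param path Path to a VCF file.
#' @param field Annotation field name, or two comma-separated names for the
#'   per-allele forward/reverse layout.
#' @param source `"info"` (default) or `"geno"` (per-sample FORMAT field).
#' @param sample For `source = "geno"`, the sample column to use (default:
#'   first); also sets the `sample_id` of the result.
#'
#' @return A [VariantSet] (flags `FALSE`, `maf` `NA`; annotations are not
#'   carried by VCF input).
#' @examples
#' vcf <- system.file("extdata", "toy_dp4.vcf", package = "StrandBiasQC")
#' readVcfCounts(vcf)
#' @export
readVcfCounts <- function(path, field = "DP4",
                          source = c("info", "geno"), sample = NULL) {
  source <- match.arg(source)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  filt <- VariantAnnotation::filt(vcf)
  keep <- is.na(filt) | filt %in% c(".", "PASS", "")
  if (any(!keep))
    message("readVcfCounts: skipping ", sum(!keep),
            " record(s) failing FILTER")
  vcf <- vcf[keep]
  if (length(vcf) == 0L)
    stop("no records left after FILTER")
  fields <- strsplit(field, ",", fixed = TRUE)[[1L]]
  getField <- function(f) {
    tab <- if (source == "info") VariantAnnotation::info(vcf)
           else VariantAnnotation::geno(vcf)
    if (!f %in% names(tab))
      stop("field '", f, "' not present in VCF ", source)
    v <- tab[[f]]
    if (source == "geno") {
      smp <- if (is.null(sample)) 1L else sample
      if (length(dim(v)) == 3L)
        lapply(seq_len(dim(v)[1L]), function(i) as.integer(v[i, smp, ]))
      else
        lapply(seq_len(nrow(v)), function(i)
          as.integer(unlist(v[i, smp])))
    } else {
      if (is.matrix(v))
        lapply(seq_len(nrow(v)), function(i) as.integer(v[i, ]))
      else
        as.list(v)
    }
  }
  fieldData <- lapply(fields, getField)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altList <- lapply(as.list(VariantAnnotation::alt(vcf)), as.character)
  rr <- as.data.frame(SummarizedExperiment::rowRanges(vcf))
  sampleId <- if (!is.null(sample) && is.character(sample)) sample
              else if (ncol(vcf) >= 1L) colnames(vcf)[1L]
              else "sample1"

  snv <- vapply(seq_along(vcf), function(i)
    nchar(ref[i]) == 1L && all(nchar(altList[[i]]) == 1L) &&
      ref[i] %in% .NUCS && all(altList[[i]] %in% .NUCS), logical(1))
  if (any(!snv))
    message("readVcfCounts: skipping ", sum(!snv), " non-SNV record(s)")

  recs <- lapply(which(snv), function(i) {
    alts <- altList[[i]]
    if (length(fields) == 2L) {
      fwd <- as.integer(fieldData[[1L]][[i]])
      rev <- as.integer(fieldData[[2L]][[i]])
      alleles <- c(ref[i], alts)
      if (length(fwd) != length(alleles) || length(rev) != length(alleles))
        stop("record ", i, ": '", field, "' length does not match the ",
             "allele count")
    } else {
      v <- as.integer(fieldData[[1L]][[i]])
      if (length(v) != 4L)
        stop("record ", i, ": '", field, "' must carry 4 values ",
             "(ref-fwd, ref-rev, alt-fwd, alt-rev)")
      if (length(alts) > 1L)
        message("readVcfCounts: record ", i, " is multi-allelic; '",
                field, "' pools alt depths, using first alt allele")
      alleles <- c(ref[i], alts[1L])
      fwd <- v[c(1L, 3L)]
      rev <- v[c(2L, 4L)]
    }
    red <- reduceToBiallelic(alleles, fwd, rev, ref = ref[i])
    kept <- c(red$major, red$minor)
    altOut <- setdiff(kept[!is.na(kept)], ref[i])
    if (length(altOut) == 0L)           # monoallelic reference site
      altOut <- alts[1L]
    cdf <- as.data.frame(red$counts)
    data.frame(chrom = as.character(rr$seqnames[i]), pos = rr$start[i],
               ref = ref[i], alt = altOut[1L], cdf,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, recs)
  VariantSet(chrom = rec$chrom, pos = rec$pos, ref = rec$ref,
             alt = rec$alt, a = rec$a, b = rec$b, c = rec$c, d = rec$d,
             sampleId = sampleId)
}

#' Serialise a Ti/Tv quality table as a grid
#'
#' Writes the output of [titvTable()] in the conventional layout: one row
#' per subset, one column per MAF bin plus `Overall`, each cell
#' `count/ratio` with the ratio at 2 decimal places (`NA` when undefined).
#'
#' @param tab A data frame from [titvTable()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @examples
#' cohort <- simulateCohort(simulationConfig(nSamples = 2, nSites = 300))
#' f <- tempfile(fileext = ".tsv")
#' writeTitvGrid(titvTable(cohortVariants(cohort)), f)
#' @export
writeTitvGrid <- function(tab, path) {
  cell <- ifelse(is.na(tab$titv), paste0(tab$n, "/NA"),
                 sprintf("%d/%.2f", tab$n, tab$titv))
  wide <- tapply(cell, list(tab$subset, tab$maf_bin), identity)
  wide <- wide[unique(as.character(tab$subset)), , drop = FALSE]
  out <- data.frame(subset = rownames(wide), wide, check.names = FALSE)
  .writeAtomic(path, function(tmp)
    write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Analysis defaults
#'
#' The run-level settings shared by the analyses, with defaults matching the
#' study design: per-strand depth filter 10, extreme-score stratification
#' fraction 10%, pair-correlation selection fraction 20%, per-strand
#' heterozygosity rule (minor fraction 0.2, minor count 2) and 20
#' consistency quantile bins (5% each).
#'
#' @param minStrandDepth Per-strand depth filter.
#' @param stratFraction Extreme-score stratification fraction.
#' @param pairFraction Top fraction for pair correlation selection.
#' @param hetMinFraction,hetMinCount Per-strand heterozygous call rule.
#' @param quantileBins Number of consistency quantile bins.
#' @param seed RNG seed.
#' @return A list of class `run_config`.
#' @examples
#' runConfig()
#' @export
runConfig <- function(minStrandDepth = 10, stratFraction = 0.1,
                      pairFraction = 0.2, hetMinFraction = 0.2,
                      hetMinCount = 2, quantileBins = 20, seed = 1) {
  structure(list(minStrandDepth = minStrandDepth,
                 stratFraction = stratFraction,
                 pairFraction = pairFraction,
                 hetMinFraction = hetMinFraction,
                 hetMinCount = hetMinCount,
                 quantileBins = quantileBins, seed = seed),
            class = "run_config")
}

## atomic write: results appear only on success, never half-written
.writeAtomic <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), pattern = ".tmp_write_")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path)
  invisible(path)
}

## flat key=value config files for the simulate CLI
.readKeyValueConfig <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop("config file must contain key=value lines")
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) v else n
  })
  names(out) <- keys
  out
}
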