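## Cross-sample and cross-pipeline repeatability of strand bias.
##
## A sample's "score table" is a plain data frame with one row per scored
## position (chrom, pos, key) and the three score columns sb, gatk_sb,
## fisher, restricted to sites passing the per-strand depth filter.  If
## strand bias were a property of the genomic site, two samples' scores at
## the same positions would correlate; if it arises from per-sample sampling
## noise, pairwise correlations centre on zero.

#' Per-sample strand-bias score tables
#'
#' Splits a multi-sample [VariantSet] by sample and computes the three
#' strand-bias scores at every site passing the per-strand depth filter.
#'
#' @param x A [VariantSet].
#' @param minStrandDepth Per-strand depth filter (default 10).
#'
#' @return A named list (one element per sample) of data frames with columns
#'   `chrom`, `pos`, `key`, `sb`, `gatk_sb`, `fisher`. Positions are unique
#'   within a sample.
#'
#' @examples
#' cohort <- simulateCohort(simulationConfig(nSamples = 2, nSites = 300))
#' tabs <- scoreTables(cohortVariants(cohort))
#' names(tabs)
#'
#' @export
scoreTables <- function(x, minStrandDepth = 10) {
  x <- filterStrandDepth(x, minStrandDepth)
  df <- as.data.frame(x)
  sc <- strandBiasScores(x)
  df$key <- paste(df$chrom, df$pos, sep = ":")
  tab <- data.frame(chrom = df$chrom, pos = df$pos, key = df$key,
                    sb = sc$sb, gatk_sb = sc$gatk_sb, fisher = sc$fisher,
                    stringsAsFactors = FALSE)
  split(tab, df$sample_id)
}

#' Positions with the highest strand-bias scores in one sample
#'
#' Selects the top `fraction` of a sample's positions by a strand-bias
#' score: the `ceiling(fraction * n)` highest-scoring positions, with ties
#' at the cut included (so the selection is a deterministic function of the
#' score vector and may slightly exceed the nominal count).
#'
#' @param table One sample's score table (an element of [scoreTables()]).
#' @param scoreKind One of `"sb"`, `"gatk_sb"`, `"fisher"`.
#' @param fraction Fraction of positions to select, in `(0, 1]`
#'   (default 0.2).
#'
#' @return Character vector of position keys (`chrom:pos`).
#' @examples
#' tab <- data.frame(chrom = "1", pos = 1:10,
#'                   key = paste("1", 1:10, sep = ":"),
#'                   sb = 1:10, gatk_sb = 0, fisher = 0)
#' topFractionPositions(tab, "sb", 0.2)
#' @export
topFractionPositions <- function(table, scoreKind = c("sb", "gatk_sb",
                                                      "fisher"),
                                 fraction = 0.2) {
  scoreKind <- match.arg(scoreKind)
  if (nrow(table) == 0L)
    stop("empty score table")
  if (fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]")
  s <- table[[scoreKind]]
  k <- ceiling(fraction * length(s))
  cut <- sort(s, decreasing = TRUE)[k]
  table$key[s >= cut]
}

#' Pairwise strand-bias correlation for one sample pair
#'
#' Takes the positions in the top `fraction` of strand-bias scores in the
#' *selector* sample, intersects them with the positions scored in the
#' other sample (unscored positions are dropped, not zero-filled), and
#' computes the Pearson correlation of the two samples' scores there.
#' Selecting on one sample deliberately captures the scenario where the
#' selector shows strong bias: if the other sample does not reproduce it,
#' the correlation collapses. The operation is therefore asymmetric in its
#' arguments.
#'
#' @param selector,other Score tables (elements of [scoreTables()]).
#' @param scoreKind One of `"sb"`, `"gatk_sb"`, `"fisher"`.
#' @param fraction Top fraction selected in the selector (default 0.2).
#'
#' @return A list with `n` (shared positions used), `r` (Pearson
#'   correlation, `NA` when undefined) and `reason` (`NA` or why `r` is
#'   undefined).
#'
#' @examples
#' tab <- data.frame(chrom = "1", pos = 1:50,
#'                   key = paste("1", 1:50, sep = ":"),
#'                   sb = runif(50), gatk_sb = 0, fisher = 0)
#' pairBiasCorrelation(tab, tab, "sb")$r   # self-correlation = 1
#'
#' @export
pairBiasCorrelation <- function(selector, other,
                                scoreKind = c("sb", "gatk_sb", "fisher"),
                                fraction = 0.2) {
  scoreKind <- match.arg(scoreKind)
  sel <- topFractionPositions(selector, scoreKind, fraction)
  shared <- intersect(sel, other$key)
  if (length(shared) < 3L)
    return(list(n = length(shared), r = NA_real_,
                reason = "fewer than 3 shared positions"))
  xs <- selector[[scoreKind]][match(shared, selector$key)]
  ys <- other[[scoreKind]][match(shared, other$key)]
  if (var(xs) == 0 || var(ys) == 0)
    return(list(n = length(shared), r = NA_real_,
                reason = "zero variance"))
  list(n = length(shared), r = cor(xs, ys), reason = NA_character_)
}

#' All-pairs strand-bias correlations across a cohort
#'
#' Computes [pairBiasCorrelation()] for every unordered pair of samples
#' (`k` samples give `k(k-1)/2` pairs; 22 samples give 231). The selector
#' of each pair is the lexicographically smaller sample id;
#' `bothDirections = TRUE` instead averages the two directed correlations.
#' Per-pair undefined results are propagated as `NA` rows, never aborting
#' the batch.
#'
#' @param tables Named list of score tables from [scoreTables()].
#' @param scoreKind One of `"sb"`, `"gatk_sb"`, `"fisher"`.
#' @param fraction Top fraction for the selector (default 0.2).
#' @param bothDirections Average the two selector directions.
#'
#' @return A data frame with columns `selector`, `other`, `score_kind`,
#'   `n`, `r`, `reason`.
#'
#' @examples
#' cohort <- simulateCohort(simulationConfig(nSamples = 6, nSites = 300))
#' pc <- allPairsCorrelations(scoreTables(cohortVariants(cohort)), "sb")
#' nrow(pc)   # 15
#'
#' @export
allPairsCorrelations <- function(tables,
                                 scoreKind = c("sb", "gatk_sb", "fisher"),
                                 fraction = 0.2, bothDirections = FALSE) {
  scoreKind <- match.arg(scoreKind)
  ids <- sort(names(tables))
  if (length(ids) < 2L)
    stop("at least 2 samples are required")
  pairs <- utils::combn(ids, 2L)
  rows <- apply(pairs, 2L, function(p) {
    fwd <- pairBiasCorrelation(tables[[p[1L]]], tables[[p[2L]]],
                               scoreKind, fraction)
    if (bothDirections) {
      rev <- pairBiasCorrelation(tables[[p[2L]]], tables[[p[1L]]],
                                 scoreKind, fraction)
      r <- mean(c(fwd$r, rev$r), na.rm = TRUE)
      if (is.nan(r)) r <- NA_real_
      fwd <- list(n = min(fwd$n, rev$n), r = r,
                  reason = if (is.na(r)) "undefined in both directions"
                           else NA_character_)
    }
    data.frame(selector = p[1L], other = p[2L], score_kind = scoreKind,
               n = fwd$n, r = fwd$r, reason = fwd$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between two score sets for the same sample
#'
#' Pearson correlation over *all* positions scored in both sets (no
#' top-fraction selection), used to compare the same sample processed two
#' ways — e.g. two aligners or two post-processing pipelines. Symmetric in
#' its arguments.
#'
#' @param setA,setB Score tables (elements of [scoreTables()] or
#'   [perturbScores()]).
#' @param scoreKind One of `"sb"`, `"gatk_sb"`, `"fisher"`.
#'
#' @return A list with `n`, `r` (`NA` when undefined) and `reason`.
#' @examples
#' tab <- data.frame(chrom = "1", pos = 1:50,
#'                   key = paste("1", 1:50, sep = ":"),
#'                   sb = runif(50), gatk_sb = 0, fisher = 0)
#' scoreSetCorrelation(tab, tab, "sb")$r
#' @export
scoreSetCorrelation <- function(setA, setB,
                                scoreKind = c("sb", "gatk_sb", "fisher")) {
  scoreKind <- match.arg(scoreKind)
  shared <- intersect(setA$key, setB$key)
  if (length(shared) < 3L)
    return(list(n = length(shared), r = NA_real_,
                reason = "fewer than 3 shared positions"))
  xs <- setA[[scoreKind]][match(shared, setA$key)]
  ys <- setB[[scoreKind]][match(shared, setB$key)]
  if (var(xs) == 0 || var(ys) == 0)
    return(list(n = length(shared), r = NA_real_,
                reason = "zero variance"))
  list(n = length(shared), r = cor(xs, ys), reason = NA_character_)
}

#' Tukey box-plot summary of a correlation distribution
#'
#' Standard five-number box summary with 1.5 x IQR whiskers: quartiles by
#' linear interpolation, whiskers at the most extreme values within 1.5
#' interquartile ranges of the quartiles, remaining values listed as
#' outliers.
#'
#' @param values Numeric vector (at least one value; `NA` removed).
#'
#' @return A list with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers` and `n`.
#' @examples
#' boxSummary(c(1, 2, 3, 4, 5))
#' @export
boxSummary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    stop("no values to summarise")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  inLow <- values[values >= q[1L] - 1.5 * iqr]
  inHigh <- values[values <= q[3L] + 1.5 * iqr]
  wl <- min(inLow)
  wh <- max(inHigh)
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = wl, whisker_high = wh,
       outliers = values[values < wl | values > wh],
       n = length(values))
}
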