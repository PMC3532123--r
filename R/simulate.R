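## Synthetic exome-cohort generator.
##
## Emulates the data structure the strand-bias analyses consume: per-sample
## stranded allele counts at shared exome positions (negative-binomial depth,
## binomial strand assignment), a MAF spectrum with Hardy-Weinberg genotype
## draws, injected strand bias (minor-allele reads pushed onto one strand),
## false-positive artifact sites with a distorted Ti/Tv, a genotyping-chip
## truth table, and score-set perturbation emulating alternative processing
## pipelines.

#' Configuration for the synthetic cohort generator
#'
#' All knobs of [simulateCohort()] in one validated object. Defaults emulate
#' the study design the analyses target: 22 exome samples at ~45x depth,
#' balanced strands, a per-strand depth-10 filter downstream, true-site
#' transition probability 0.71 (Ti/Tv near 2.5) versus 0.33 at artifact
#' sites (Ti/Tv near 0.5), a small chip overlap, 2% chip genotyping error
#' and an expected 250 novel non-synonymous SNPs per sample.
#'
#' @param nSamples Number of samples (default 22).
#' @param nSites Number of candidate variant positions shared by the cohort
#'   (default 2000).
#' @param depthMean,depthSize Mean and size (dispersion) of the
#'   negative-binomial per-site total depth (defaults 45 and 10; the median
#'   tracks the mean closely).
#' @param strandBalance Cohort-average probability that a read maps to the
#'   forward strand (default 0.5).
#' @param strandBalanceSpread Half-width of the per-site strand balance:
#'   each locus draws its forward-read probability uniformly from
#'   `strandBalance +/- strandBalanceSpread` and keeps it across samples
#'   (default 0.25), emulating capture-driven strand-coverage heterogeneity
#'   that is a property of the locus, not the sample.
#' @param hetFraction Probability a variant-carrying genotype is
#'   heterozygous rather than homozygous-alternate (default 0.6).
#' @param mafShape1,mafShape2 Beta shape parameters of the site MAF
#'   spectrum, scaled to `[0, 0.5]` (defaults 0.7, 1.3: skewed to rare).
#' @param biasMode `"random"` (biased positions drawn independently per
#'   sample), `"systematic"` (one shared position set whose bias signature —
#'   minor fraction and favoured strand — is a locus property reproduced in
#'   every sample) or `"none"`. A biased record shows a strand-restricted
#'   minor allele at a modest minor fraction (drawn from `biasMinorRange`),
#'   the false-positive signature where per-strand genotype calls conflict;
#'   biased positions are emitted in every sample they are assigned to,
#'   whether or not the sample truly carries a variant there.
#' @param biasSiteFraction Fraction of positions receiving injected bias
#'   (default 0.02, so biased calls are a minority of each sample's call
#'   set and of any top-quantile stratum).
#' @param biasStrength Probability a minor-allele read on the unfavoured
#'   strand is reassigned to the favoured strand at a biased or artifact
#'   site (default 0.95; 1 restricts all minor reads to one strand).
#' @param biasMinorRange Range of the apparent minor-allele fraction at
#'   biased sites (default `c(0.1, 0.4)`); drawn per locus in systematic
#'   mode, per (sample, site) in random mode.
#' @param artifactRate Per-sample probability that a non-carrier position
#'   yields a false-positive artifact call (default 0.05). Artifact records
#'   are hom-ref in truth, carry a spurious strand-restricted minor allele
#'   (fraction `artifactAltFraction`), are called heterozygous, are flagged
#'   novel (not dbSNP / not chip) and draw their substitution type with
#'   `artifactTitvP`. Artifacts arise independently per sample — they do
#'   not repeat at the same positions across samples.
#' @param artifactAltFraction Per-read probability of the spurious allele at
#'   artifact sites (default 0.3).
#' @param artifactTitvP,trueTitvP Transition probability of the substitution
#'   type at artifact / true sites (defaults 0.33 and 0.71).
#' @param chipOverlapFraction Fraction of positions also present on the
#'   simulated genotyping chip (default 0.1; chip sites are drawn from
#'   dbSNP, non-artifact sites).
#' @param chipErrorRate Probability a chip genotype differs from truth
#'   (default 0.02).
#' @param novelNonsynRate Expected novel non-synonymous SNPs per sample
#'   among true sites (default 250; artifact sites can add more).
#' @param biasGenotypeErrorRate Probability that a biased heterozygous site
#'   is miscalled homozygous by the simulated caller (default 0.01) — the
#'   mechanism linking strand bias to genotype errors.
#' @param seqErrorRate Per-read error rate producing spurious minor reads at
#'   homozygous sites (default 0.002).
#' @param dbsnpFraction Probability a true non-novel site is in dbSNP
#'   (default 0.95).
#' @param pipelineNoiseSd Default score-perturbation SD for
#'   [perturbScores()] (default 0.05).
#' @param seed Integer RNG seed; identical config and seed give
#'   bit-identical cohorts.
#'
#' @return A `SimulationConfig` object.
#' @examples
#' simulationConfig(nSamples = 4, nSites = 500)
#' @aliases SimulationConfig-class
#' @export
simulationConfig <- function(nSamples = 22, nSites = 2000,
                             depthMean = 45, depthSize = 10,
                             strandBalance = 0.5, strandBalanceSpread = 0.25,
                             hetFraction = 0.6,
                             mafShape1 = 0.7, mafShape2 = 1.3,
                             biasMode = c("random", "systematic", "none"),
                             biasSiteFraction = 0.02, biasStrength = 0.95,
                             biasMinorRange = c(0.1, 0.4),
                             artifactRate = 0.05, artifactAltFraction = 0.3,
                             artifactTitvP = 0.33, trueTitvP = 0.71,
                             chipOverlapFraction = 0.1, chipErrorRate = 0.02,
                             novelNonsynRate = 250,
                             biasGenotypeErrorRate = 0.01,
                             seqErrorRate = 0.002, dbsnpFraction = 0.95,
                             pipelineNoiseSd = 0.05, seed = 1) {
  new("SimulationConfig",
      nSamples = as.integer(nSamples), nSites = as.integer(nSites),
      depthMean = depthMean, depthSize = depthSize,
      strandBalance = strandBalance,
      strandBalanceSpread = strandBalanceSpread,
      hetFraction = hetFraction,
      mafShape1 = mafShape1, mafShape2 = mafShape2,
      biasMode = match.arg(biasMode),
      biasSiteFraction = biasSiteFraction, biasStrength = biasStrength,
      biasMinorRange = biasMinorRange,
      artifactRate = artifactRate,
      artifactAltFraction = artifactAltFraction,
      artifactTitvP = artifactTitvP, trueTitvP = trueTitvP,
      chipOverlapFraction = chipOverlapFraction,
      chipErrorRate = chipErrorRate,
      novelNonsynRate = novelNonsynRate,
      biasGenotypeErrorRate = biasGenotypeErrorRate,
      seqErrorRate = seqErrorRate, dbsnpFraction = dbsnpFraction,
      pipelineNoiseSd = pipelineNoiseSd, seed = as.integer(seed))
}

setClass("SimulationConfig", slots = c(
  nSamples = "integer", nSites = "integer",
  depthMean = "numeric", depthSize = "numeric",
  strandBalance = "numeric", strandBalanceSpread = "numeric",
  hetFraction = "numeric",
  mafShape1 = "numeric", mafShape2 = "numeric",
  biasMode = "character",
  biasSiteFraction = "numeric", biasStrength = "numeric",
  biasMinorRange = "numeric",
  artifactRate = "numeric", artifactAltFraction = "numeric",
  artifactTitvP = "numeric", trueTitvP = "numeric",
  chipOverlapFraction = "numeric", chipErrorRate = "numeric",
  novelNonsynRate = "numeric", biasGenotypeErrorRate = "numeric",
  seqErrorRate = "numeric", dbsnpFraction = "numeric",
  pipelineNoiseSd = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nSamples < 1L || object@nSites < 1L)
    return("nSamples and nSites must be positive")
  probs <- c(object@strandBalance, object@hetFraction,
             object@biasSiteFraction, object@biasStrength,
             object@artifactRate, object@artifactAltFraction,
             object@artifactTitvP, object@trueTitvP,
             object@chipOverlapFraction, object@chipErrorRate,
             object@biasGenotypeErrorRate, object@seqErrorRate,
             object@dbsnpFraction)
  if (any(probs < 0 | probs > 1))
    return("all probability parameters must lie in [0, 1]")
  if (object@depthMean <= 0 || object@depthSize <= 0)
    return("depthMean and depthSize must be positive")
  if (object@strandBalanceSpread < 0 ||
      object@strandBalance - object@strandBalanceSpread < 0 ||
      object@strandBalance + object@strandBalanceSpread > 1)
    return("strandBalance +/- strandBalanceSpread must stay within [0, 1]")
  if (length(object@biasMinorRange) != 2L ||
      any(object@biasMinorRange < 0 | object@biasMinorRange > 0.5) ||
      diff(object@biasMinorRange) < 0)
    return("biasMinorRange must be an increasing pair within [0, 0.5]")
  if (object@mafShape1 <= 0 || object@mafShape2 <= 0)
    return("MAF beta shapes must be positive")
  if (!object@biasMode %in% c("random", "systematic", "none"))
    return("biasMode must be random, systematic or none")
  if (object@novelNonsynRate < 0 || object@pipelineNoiseSd < 0)
    return("novelNonsynRate and pipelineNoiseSd must be non-negative")
  TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSamples, "sample(s) x", object@nSites,
      "site(s); depth ~ NB(mu =", object@depthMean, ", size =",
      object@depthSize, ")\n  bias mode", object@biasMode,
      "(fraction", object@biasSiteFraction, ", strength",
      object@biasStrength, "); artifact rate", object@artifactRate,
      "; seed", object@seed, "\n")
})

#' A simulated cohort with truth labels
#'
#' Container returned by [simulateCohort()]: the stacked multi-sample
#' [VariantSet] of called sites, the chip genotype truth table, per-record
#' truth labels (true genotype, called genotype, artifact and bias flags)
#' covering every emitted site, and the generating [simulationConfig()].
#'
#' @param x A `SimulatedCohort`.
#' @return `cohortVariants()` returns the [VariantSet]; `chipGenotypes()`
#'   and `truthLabels()` data frames; `cohortConfig()` the config.
#' @aliases SimulatedCohort-class cohortVariants chipGenotypes truthLabels
#'   cohortConfig
#' @name SimulatedCohort
NULL

setClass("SimulatedCohort", slots = c(
  variants = "VariantSet", chip = "data.frame", truth = "data.frame",
  config = "SimulationConfig"))

#' @rdname SimulatedCohort
#' @export
cohortVariants <- function(x) x@variants

#' @rdname SimulatedCohort
#' @export
chipGenotypes <- function(x) x@chip

#' @rdname SimulatedCohort
#' @export
truthLabels <- function(x) x@truth

#' @rdname SimulatedCohort
#' @export
cohortConfig <- function(x) x@config

setMethod("show", "SimulatedCohort", function(object) {
  cat("SimulatedCohort:", length(object@variants), "called site(s) across",
      object@config@nSamples, "sample(s);", nrow(object@chip),
      "chip genotype(s)\n")
})

## Vectorised stranded-count sampler shared by simulateSite/simulateCohort.
## pAlt is the per-read probability of the alternate allele; biased entries
## have their minor-allele reads moved to the favoured strand with
## probability `strength` (favoured strand drawn at random unless given).
.simulateCounts <- function(depth, pAlt, strength, strandBalance,
                            favFwd = NULL) {
  np <- length(depth)
  if (length(strandBalance) == 1L)
    strandBalance <- rep(strandBalance, np)
  if (is.null(favFwd))
    favFwd <- runif(np) < 0.5
  nAlt <- rbinom(np, depth, pAlt)
  nRef <- depth - nAlt
  majIsAlt <- nAlt > nRef
  majN <- pmax(nAlt, nRef)
  minN <- pmin(nAlt, nRef)
  aF <- rbinom(np, majN, strandBalance)
  bF <- rbinom(np, minN, strandBalance)
  bF <- bF + rbinom(np, minN - bF, ifelse(favFwd, strength, 0)) -
    rbinom(np, bF, ifelse(favFwd, 0, strength))
  data.frame(a = aF, b = bF, c = majN - aF, d = minN - bF,
             maj_is_alt = majIsAlt)
}

#' Simulate stranded allele counts for single sites
#'
#' Low-level access to the read-sampling model used by [simulateCohort()]:
#' total depth is negative-binomial, each read carries the alternate allele
#' with a genotype-dependent probability (0.5 at heterozygous sites, the
#' sequencing error rate at homozygous sites, `artifactAltFraction` at
#' artifact sites) and lands on the forward strand with probability
#' `strandBalance`; at biased sites minor-allele reads on the unfavoured
#' strand are moved to the favoured strand with probability `biasStrength`.
#' Uses the current RNG state (seed the session for reproducibility).
#'
#' @param config A [simulationConfig()].
#' @param genotype `"het"` or `"hom"` (homozygous-alternate).
#' @param biased Inject strand bias at these sites.
#' @param artifact Simulate a false-positive artifact site (hom-ref truth
#'   with a strand-restricted spurious allele).
#' @param n Number of independent sites to draw.
#' @param ensureStrandCoverage Resample sites until both strands carry at
#'   least one read (useful when a per-strand depth filter is to be
#'   exercised).
#'
#' @return A [StrandCounts] of length `n`.
#' @examples
#' set.seed(1)
#' simulateSite(simulationConfig(), genotype = "het", biased = TRUE, n = 3)
#' @export
simulateSite <- function(config, genotype = c("het", "hom"), biased = FALSE,
                         artifact = FALSE, n = 1,
                         ensureStrandCoverage = FALSE) {
  genotype <- match.arg(genotype)
  stopifnot(is(config, "SimulationConfig"))
  pAlt <- if (artifact) config@artifactAltFraction
          else if (genotype == "het") 0.5
          else 1 - config@seqErrorRate
  strength <- if (biased || artifact) config@biasStrength else 0
  depth <- pmax(rnbinom(n, size = config@depthSize, mu = config@depthMean),
                if (ensureStrandCoverage) 2L else 1L)
  cnt <- .simulateCounts(depth, rep(pAlt, n), rep(strength, n),
                         config@strandBalance)
  if (ensureStrandCoverage) {
    for (iter in seq_len(100L)) {
      bad <- which(cnt$a + cnt$b == 0L | cnt$c + cnt$d == 0L)
      if (!length(bad))
        break
      cnt[bad, ] <- .simulateCounts(depth[bad], rep(pAlt, length(bad)),
                                    rep(strength, length(bad)),
                                    config@strandBalance)
    }
  }
  StrandCounts(cnt$a, cnt$b, cnt$c, cnt$d)
}

#' Simulate a multi-sample exome cohort with known truth
#'
#' Generates a cohort of per-sample variant calls with stranded allele
#' counts, a chip genotype truth table and full truth labels. Sites are
#' shared across samples; per-sample genotypes follow Hardy-Weinberg carrier
#' probabilities derived from each site's MAF annotation (heterozygous with
#' probability `hetFraction` given a carrier). Artifact sites are hom-ref in
#' truth but emitted as heterozygous calls in every sample, with a
#' strand-restricted spurious allele and a substitution type drawn with the
#' artifact transition probability. Biased positions are drawn per sample
#' (`biasMode = "random"`), shared across samples (`"systematic"`) or absent
#' (`"none"`). The chip covers a subset of dbSNP sites and reports the true
#' genotype with error rate `chipErrorRate`. The whole cohort is a
#' deterministic function of (config, seed).
#'
#' @param config A [simulationConfig()].
#' @param ensureStrandCoverage Resample entries until both strands carry at
#'   least one read.
#'
#' @return A [SimulatedCohort].
#' @examples
#' cohort <- simulateCohort(simulationConfig(nSamples = 3, nSites = 300))
#' cohort
#' @export
simulateCohort <- function(config, ensureStrandCoverage = FALSE) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  ns <- config@nSites
  nsamp <- config@nSamples

  ## --- site-level truth -------------------------------------------------
  pos <- seq_len(ns) * 137L
  ref <- sample(.NUCS, ns, replace = TRUE)
  alt <- .drawAlt(ref, config@trueTitvP)
  maf <- 0.5 * rbeta(ns, config@mafShape1, config@mafShape2)
  carrierP <- 1 - (1 - maf)^2

  ## novel non-synonymous true sites, sized so the expected per-sample
  ## count (among genuine variants) equals novelNonsynRate
  perm <- sample(ns)
  k <- 0L
  if (config@novelNonsynRate > 0) {
    cum <- cumsum(carrierP[perm])
    k <- if (any(cum >= config@novelNonsynRate))
      which(cum >= config@novelNonsynRate)[1L] else ns
    kmax <- floor(0.2 * ns)             # novel sites stay a minority
    if (k > kmax) {
      message("simulateCohort: nSites too small to reach novelNonsynRate = ",
              config@novelNonsynRate,
              "; novel non-synonymous sites capped at 20% of sites")
      k <- kmax
    }
  }
  novelNS <- perm[seq_len(k)]

  inDb <- logical(ns)
  rest <- setdiff(seq_len(ns), novelNS)
  inDb[rest] <- runif(length(rest)) < config@dbsnpFraction
  funClass <- character(ns)
  funClass[novelNS] <- "non-synonymous"
  dbRest <- rest[inDb[rest]]
  funClass[dbRest] <- sample(.FUNCLASSES, length(dbRest), replace = TRUE,
                             prob = c(0.35, 0.45, 0.2))
  novelRest <- rest[!inDb[rest]]
  funClass[novelRest] <- sample(c("synonymous", "other"),
                                length(novelRest), replace = TRUE,
                                prob = c(0.6, 0.4))
  chipCand <- which(inDb)
  nChip <- min(round(config@chipOverlapFraction * ns), length(chipCand))
  chipSites <- sort(sample(chipCand, nChip))
  onChipSite <- logical(ns)
  onChipSite[chipSites] <- TRUE

  ## locus-level strand coverage balance and bias signature: both are
  ## properties of the position (capture/alignment context), reproduced in
  ## every sample
  sbal <- runif(ns, config@strandBalance - config@strandBalanceSpread,
                config@strandBalance + config@strandBalanceSpread)
  favFwdSite <- sbal < 0.5              # artifact favours the weaker strand
  qBiasSite <- runif(ns, config@biasMinorRange[1L],
                     config@biasMinorRange[2L])
  biasedSite <- runif(ns) < config@biasSiteFraction

  ## --- per-sample genotypes --------------------------------------------
  N <- ns * nsamp
  siteIdx <- rep(seq_len(ns), times = nsamp)
  sampIdx <- rep(seq_len(nsamp), each = ns)
  sampleNames <- sprintf("S%02d", seq_len(nsamp))
  carrier <- runif(N) < carrierP[siteIdx]
  het <- carrier & runif(N) < config@hetFraction
  trueG <- ifelse(!carrier, "hom-ref", ifelse(het, "het", "hom-alt"))

  biased <- switch(config@biasMode,
    none = rep(FALSE, N),
    random = runif(N) < config@biasSiteFraction,
    systematic = rep(biasedSite, nsamp))
  ## artifacts are independent per-sample miscalls at non-carrier positions
  artEntry <- runif(N) < config@artifactRate & !carrier & !biased
  ## a biased or artifact position shows a (spurious) minor allele and is
  ## therefore emitted as a call in every sample it is assigned to
  present <- carrier | biased | artEntry
  biasedEff <- biased | artEntry
  qEntry <- if (config@biasMode == "random")
    runif(N, config@biasMinorRange[1L], config@biasMinorRange[2L])
  else qBiasSite[siteIdx]
  favFwd <- if (config@biasMode == "random")
    runif(N) < 0.5
  else favFwdSite[siteIdx]
  favFwd[artEntry] <- runif(sum(artEntry)) < 0.5
  ## artifact substitutions have their own (distorted) transition rate and
  ## novel status, drawn per record
  altEntry <- alt[siteIdx]
  altEntry[artEntry] <- .drawAlt(ref[siteIdx[artEntry]],
                                 config@artifactTitvP)
  inDbEntry <- inDb[siteIdx] & !artEntry
  onChipEntry <- onChipSite[siteIdx] & !artEntry
  funClassEntry <- funClass[siteIdx]
  funClassEntry[artEntry] <- sample(.FUNCLASSES, sum(artEntry),
                                    replace = TRUE, prob = c(0.3, 0.5, 0.2))

  ## --- stranded counts for emitted records ------------------------------
  p <- which(present)
  np <- length(p)
  qMin <- ifelse(artEntry[p], config@artifactAltFraction, qEntry[p])
  pAlt <- ifelse(artEntry[p] | biased[p],
                 ifelse(trueG[p] == "hom-alt", 1 - qMin, qMin),
                 ifelse(trueG[p] == "het", 0.5, 1 - config@seqErrorRate))
  strength <- ifelse(biasedEff[p], config@biasStrength, 0)
  depth <- pmax(rnbinom(np, size = config@depthSize, mu = config@depthMean),
                if (ensureStrandCoverage) 2L else 1L)
  bal <- sbal[siteIdx[p]]
  cnt <- .simulateCounts(depth, pAlt, strength, bal, favFwd[p])
  if (ensureStrandCoverage) {
    for (iter in seq_len(100L)) {
      bad <- which(cnt$a + cnt$b == 0L | cnt$c + cnt$d == 0L)
      if (!length(bad))
        break
      cnt[bad, ] <- .simulateCounts(depth[bad], pAlt[bad], strength[bad],
                                    bal[bad], favFwd[p][bad])
    }
  }

  calledG <- trueG[p]
  miscall <- calledG == "het" &
    runif(np) < ifelse(biasedEff[p], config@biasGenotypeErrorRate, 0)
  calledG[miscall] <- "hom-alt"
  calledG[artEntry[p] | (biased[p] & trueG[p] == "hom-ref")] <- "het"

  variants <- VariantSet(
    chrom = "1", pos = pos[siteIdx[p]],
    ref = ref[siteIdx[p]], alt = altEntry[p],
    a = cnt$a, b = cnt$b, c = cnt$c, d = cnt$d,
    sampleId = sampleNames[sampIdx[p]],
    inDbsnp = inDbEntry[p], onChip = onChipEntry[p],
    functionalClass = funClassEntry[p], maf = maf[siteIdx[p]],
    seqGenotype = calledG)

  ## --- chip truth table -------------------------------------------------
  if (nChip == 0L)
    stop("configuration implies zero heterozygous chip sites; ",
         "chip-based consistency would be undefined")
  ci <- which(onChipSite[siteIdx])
  chipG <- trueG[ci]
  flip <- runif(length(ci)) < config@chipErrorRate
  if (any(flip))
    chipG[flip] <- vapply(chipG[flip], function(g)
      sample(setdiff(.GENOTYPES, g), 1L), character(1))
  cref <- ref[siteIdx[ci]]
  calt <- alt[siteIdx[ci]]
  chip <- data.frame(
    sample = sampleNames[sampIdx[ci]],
    chrom = "1", pos = pos[siteIdx[ci]],
    allele1 = ifelse(chipG == "hom-alt", calt, cref),
    allele2 = ifelse(chipG == "hom-ref", cref, calt),
    stringsAsFactors = FALSE)
  if (nrow(chip) == 0L || !any(chip$allele1 != chip$allele2))
    stop("configuration implies zero heterozygous chip sites; ",
         "chip-based consistency would be undefined")

  truth <- data.frame(
    sample_id = sampleNames[sampIdx[p]],
    chrom = "1", pos = pos[siteIdx[p]],
    true_genotype = trueG[p], called_genotype = calledG,
    is_artifact = artEntry[p], is_biased = biasedEff[p],
    stringsAsFactors = FALSE)

  new("SimulatedCohort", variants = variants, chip = chip, truth = truth,
      config = config)
}

.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

.drawAlt <- function(ref, titvP) {
  ns <- length(ref)
  ts <- runif(ns) < titvP
  alt <- unname(.TS_PARTNER[ref])
  tvSets <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  tv <- !ts
  if (any(tv)) {
    pick <- runif(sum(tv)) < 0.5
    alt[tv] <- vapply(seq_len(sum(tv)), function(i)
      tvSets[[ref[tv][i]]][1L + pick[i]], character(1))
  }
  alt
}

#' Perturb score tables to emulate an alternative processing pipeline
#'
#' Returns a parallel score set with additive Gaussian noise and, for a
#' chosen fraction of positions, inflated scores — emulating a processing
#' pipeline (such as local realignment combined with BAQ) that introduces
#' additional SNPs with higher strand bias. SB and GATK-SB scores are
#' clamped at 0, the Fisher score to `[0, 1]`.
#'
#' @param tables A named list of score tables (from [scoreTables()]) or a
#'   single score table.
#' @param noiseSd SD of the additive noise (default 0.05).
#' @param extraBiasFraction Fraction of positions whose scores are inflated
#'   (default 0).
#' @param inflation Amount added to inflated SB / GATK-SB scores (Fisher is
#'   pushed towards 1 by the same amount, then clamped).
#'
#' @return The perturbed tables, same shape as the input. Uses the current
#'   RNG state.
#' @examples
#' tab <- data.frame(chrom = "1", pos = 1:20,
#'                   key = paste("1", 1:20, sep = ":"),
#'                   sb = runif(20), gatk_sb = runif(20),
#'                   fisher = runif(20))
#' set.seed(1)
#' pt <- perturbScores(tab, noiseSd = 0.05)
#' @export
perturbScores <- function(tables, noiseSd = 0.05, extraBiasFraction = 0,
                          inflation = 2) {
  single <- is.data.frame(tables)
  if (single)
    tables <- list(tables)
  out <- lapply(tables, function(tab) {
    n <- nrow(tab)
    infl <- rep(0, n)
    if (extraBiasFraction > 0 && n > 0) {
      idx <- sample(n, round(extraBiasFraction * n))
      infl[idx] <- inflation
    }
    tab$sb <- pmax(0, tab$sb + rnorm(n, 0, noiseSd) + infl)
    tab$gatk_sb <- pmax(0, tab$gatk_sb + rnorm(n, 0, noiseSd) + infl)
    tab$fisher <- pmin(1, pmax(0, tab$fisher + rnorm(n, 0, noiseSd) + infl))
    tab
  })
  if (single) out[[1L]] else out
}
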