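---
title: "Scoring strand bias and its effect on genotype quality"
author: "StrandBiasQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring strand bias and its effect on genotype quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StrandBiasQC)
```

## The problem

In Illumina short-read data the genotype supported by reads on the forward
strand sometimes disagrees with the genotype supported by reads on the
reverse strand at the same position — one strand looks heterozygous, the
other homozygous. This *strand bias* in the calls (distinct from
*unbalanced strand mapping*, where the two strands simply differ in depth)
is a marker for potential false-positive SNP calls, because a real variant
is carried by the DNA molecule, not by one sequencing strand.

`StrandBiasQC` quantifies this phenomenon and its downstream consequences.
Everything starts from the 2×2 table of read counts at one position,
cross-classifying allele by strand:

|          | major | minor |
|----------|-------|-------|
| forward  | $a$   | $b$   |
| reverse  | $c$   | $d$   |

where major/minor refer to the pooled counts (so $a + c \ge b + d$). When
reads support a third allele it is discarded before scoring
(`reduceToBiallelic()`): third alleles are almost always sequencing or
alignment errors, and the two best-supported alleles are kept, ties going
to the reference allele and then to alphabetical order.

## The three scores

All three scores are oriented so 0 means no bias:

* **SB** — the difference of the per-strand minor-allele fractions,
  normalised by the pooled minor fraction:
  $$\mathrm{SB} \;=\; \frac{\bigl|\,b/(a+b) \;-\; d/(c+d)\,\bigr|}
  {(b+d)/(a+b+c+d)}.$$
  Range $[0, \infty)$. As the minor allele becomes rare on both strands
  ($b \ll a$, $d \ll c$) SB grows without bound whenever the per-strand
  minor fractions differ — its extreme values live at low-minor-fraction,
  strand-restricted sites.
* **GATK-SB** — the maximum of the two cross-strand fraction products,
  normalised by the pooled major fraction:
  $$\max\!\left[\frac{b}{a+b}\frac{c}{c+d},\;
  \frac{d}{c+d}\frac{a}{a+b}\right] \Big/ \frac{a+c}{a+b+c+d}.$$
  In the same rare-minor limit this simplifies to roughly
  $\max(b/a,\, d/c)$, which stays *small* — so GATK-SB ranks exactly the
  sites SB flags most strongly as nearly unbiased. This divergence is not a
  bug: it is the central behavioural difference the package lets you
  measure.
* **Fisher score** — $1 - p$, where $p$ is the two-sided Fisher exact
  p-value of the table. Range $[0, 1]$.

`sbScore()` and `gatkSbScore()` return `NA` when one strand carries no
reads: such a site is *unassessable*, not unbiased, and the analyses
exclude it through the per-strand depth filter (default: at least 10 reads
on each strand, `filterStrandDepth()`).

### Numerical choices for the Fisher test

`fisherExactTwoSided()` enumerates the hypergeometric support with fixed
margins and sums the probabilities of all tables no more probable than the
observed one (the minimum-likelihood two-sided rule), with a relative
tolerance of $1 + 10^{-7}$ on the probability comparison to absorb
floating-point ties — the same convention as `stats::fisher.test`, which
the test suite uses as an independent cross-check alongside a direct
log-binomial enumeration. This rule reproduces the reference worked
examples (0.85, 0.48, 0.86 after rounding) exactly.

One worked-example curiosity: for the counts $(a,b,c,d) = (8,2,16,0)$ the
GATK-SB formula evaluates to 0.2167, which rounds to 0.22, while the
commonly quoted reference value for this example is 0.21 (a truncation);
that cell is therefore documented but not used as a reference value. Scores are stored at full precision;
comparisons against printed values round half-even to the printed digits.

## Per-strand genotypes and call conflicts

The defining symptom of strand bias is a per-strand call conflict. A
strand's genotype is called from its own two counts (`strandGenotype()`):
heterozygous iff the strand's minor fraction is ≥ `minFraction` (0.2) *and*
its minor count is ≥ `minCount` (2), otherwise homozygous; a strand with no
reads is uncallable. The rule is the simplest one consistent with all six
reference per-strand calls of the worked conflict examples, and both
thresholds are exposed. `hasGenotypeConflict()` reports disagreement
between the strands, `NA` when either strand is uncovered.

When a variant table carries no caller genotypes, `VariantSet()` derives
one from the *pooled* counts with the same rule; a site present in a
variant table is a call, so a non-heterozygous call is recorded as
homozygous-alternate.

## Genotype-quality analyses

* `titvTable()` stratifies the transition/transversion ratio by MAF bin
  (`[0,0.1), ..., [0.4,0.5]`, last bin closed) and by variant subset (all;
  on-chip; off-chip; dbSNP; dbSNP-not-on-chip), computed by set algebra
  from the flags so the partition identities hold structurally. Ti/Tv near
  3 is expected for exonic SNPs, near 2 genome-wide, and false positives
  drag it towards 0.5 (the random-substitution value); a cell with no
  transversions reports an undefined ratio (`NA`), never infinity.
* `stratifyByScore()` cuts the bottom and top `fraction` (default 10%) of
  the empirical score distribution, per sample by default (each subject's
  own distribution defines "extreme"), pooled optionally. Ties at a
  threshold go inclusively to the extreme stratum; an all-equal score
  vector yields empty strata with a warning. The top decile is the
  recommended false-positive-candidate set.
* `hetConsistencyRate()` is the fraction of chip-heterozygous,
  sequencing-covered positions whose sequencing call is also heterozygous
  — with the same allele pair by default (`level = "allele"`), or merely
  the same zygosity (`level = "zygosity"`); the reference definition does
  not fix this, so both are provided. Only chip heterozygotes enter the
  denominator: strand bias cannot realistically force a false heterozygous
  call at a true homozygote.
* `consistencyByQuantile()` bins the depth-filtered, chip-overlapping
  heterozygous sites into 20 equal-occupancy score-quantile bins (5% each)
  and reports per-bin consistency; a drop confined to the upper bins is the
  signature of bias-linked miscalls.
* `countNovelNonsynonymous()` counts calls absent from dbSNP with a
  non-synonymous annotation; exome sequencing should yield only about
  200–300 per person, so an excess flags false positives.

## Repeatability analyses

If strand bias were a property of the genomic site, two samples' scores at
the same positions would correlate. `pairBiasCorrelation()` selects the top
20% of positions by score in one sample of a pair (the *selector* — the
lexicographically smaller id by default, with an option to average both
directions), intersects with the positions scored in the other sample
(missing positions are dropped, not zero-filled: an unscored position
carries no bias evidence), and computes Pearson's r on the raw scores.
`allPairsCorrelations()` runs all $k(k-1)/2$ pairs — 231 for a 22-sample
cohort — and `boxSummary()` condenses the distribution (Tukey quartiles,
1.5×IQR whiskers). `scoreSetCorrelation()` compares two score sets for the
*same* sample (two aligners, two processing pipelines) over all shared
positions, with `perturbScores()` generating noise- and inflation-perturbed
pseudo-pipelines to exercise it.

## The synthetic cohort generator

`simulateCohort()` generates the full data structure the analyses consume,
so that every stage is testable without any external download:

* **Sites.** `nSites` positions with reference/alternate alleles
  (transition probability `trueTitvP` = 0.71, giving Ti/Tv ≈ 2.45), a MAF
  annotation drawn from a rare-skewed Beta on $[0, 0.5]$, dbSNP membership,
  functional classes, and a chip covering `chipOverlapFraction` of dbSNP
  sites. Each locus also draws a strand-coverage balance
  (0.5 ± `strandBalanceSpread`) that is shared by all samples, emulating
  capture-driven strand-coverage heterogeneity, which is a property of the
  locus rather than of the sample.
* **Genotypes.** Per sample and site, Hardy–Weinberg carrier probability
  $1-(1-f)^2$ from the site's MAF, heterozygous with probability
  `hetFraction` given a carrier. The novel non-synonymous site set is sized
  so the expected per-sample count equals `novelNonsynRate` (default 250).
* **Reads.** Total depth is negative-binomial (mean 45, matching ~45×
  median exome coverage); each read carries the alternate allele with a
  genotype-dependent probability (0.5 at heterozygotes, the sequencing
  error rate 0.002 at homozygotes) and lands on the forward strand with the
  locus's balance.
* **Artifacts.** False-positive calls arise independently per sample at
  non-carrier positions with probability `artifactRate`: hom-ref in truth,
  called heterozygous, a spurious strand-restricted minor allele at
  fraction `artifactAltFraction`, substitution type drawn with
  `artifactTitvP` (0.33, Ti/Tv ≈ 0.5) and flagged novel. Artifacts do
  *not* repeat across samples — repeatable artifacts would contradict the
  near-zero cross-sample bias correlation observed in real cohorts.
* **Injected bias.** A biased record shows a strand-restricted minor allele
  at a modest minor fraction (`biasMinorRange`, default 0.1–0.4) — the
  false-positive signature of the reference worked examples, where the
  bias-flagged sites have $b \ll a$ and $d = 0$ — and is emitted as a call
  in every sample it is assigned to. In `"random"` mode each sample draws
  its own biased positions and signatures; in `"systematic"` mode one
  position set, one minor fraction and one favoured strand (the locus's
  weaker strand) are locus properties reproduced in every sample. The
  restriction moves a minor-allele read from the unfavoured strand to the
  favoured one with probability `biasStrength` (0.95). This design was
  chosen because restricting the minor reads of a 50/50 heterozygote can
  never push SB beyond ≈ 2 while ordinary singleton sequencing errors reach
  SB 2–4.5, so only the low-minor-fraction signature makes systematic bias
  detectable by all scores; biased heterozygotes can additionally be
  miscalled homozygous with probability `biasGenotypeErrorRate` (0.01),
  the minimal mechanism linking bias to genotype errors (pure strand
  reassignment leaves pooled counts, and hence a pooled call, unchanged).
* **Chip truth.** Every chip position is genotyped in every sample; the
  chip reports the true genotype flipped with probability `chipErrorRate`
  (0.02).

Identical configuration and seed give bit-identical cohorts, and the truth
labels (genotype, artifact, bias) cover every emitted record.

Because GATK-SB stays small at restricted low-minor-fraction sites (the
$\max(b/a, d/c)$ limit), systematic-mode cohorts show strong cross-sample
score correlation under SB and the Fisher score but distinctly weaker
correlation under GATK-SB — the generator reproduces the discriminating
weakness of that score, not just its formula.

### What the generator does not emulate

Reads are summarised directly as counts: there is no read-level error
profile, no alignment, no indel realignment or base-quality recalibration,
no linkage between neighbouring sites, and MAF annotations are labels for
binning rather than enforced population frequencies. Passing tests
demonstrate that the *analyses* behave correctly on data with the assumed
structure; they cannot certify behaviour on artifacts these simplifications
exclude (alignment-context-dependent bias, for example).

### Problem sizes

The test suite runs cohorts of 2–22 samples over 200–20,000 sites, with
repeatability checks at 10 samples × 500 sites over 20 seeds and
concordance checks at 6 samples × 20,000 sites — sizes at which every
qualitative contrast (Ti/Tv separation, concordance drop < 1%,
random-vs-systematic correlation) is comfortably resolved while the whole
suite runs in about a minute.

## File formats and command line

The counts TSV (one record per sample/chrom/pos: alleles, the four
stranded counts, dbSNP/chip flags, functional class, MAF, caller genotype)
round-trips a cohort exactly; `readVcfCounts()` ingests VCFs carrying
DP4-style per-strand depths or per-allele ADF/ADR pairs, reducing
multi-allelic records and skipping filtered ones. `strandBiasCLI()` (and
the installed `inst/scripts/strandbias` wrapper) exposes `score`,
`stratify`, `titv`, `consistency`, `correlate`, `pipelines` and `simulate`
subcommands; logs go to standard error and outputs are written atomically.

## Known limitations

* Scores are count-based only; base and mapping qualities are not used to
  weight reads.
* The GATK-SB implementation reproduces the formula as defined here, not the
  annotations of current GATK releases (StrandOddsRatio, FisherStrand).
* The per-strand heterozygosity rule is a reconstruction constrained by
  the six reference calls; other callers use likelihood-based rules that can
  disagree near the thresholds.
* Real cohort sizes (~175,000 exome SNPs) are emulated at reduced site
  counts; absolute Ti/Tv values depend on the configured class mixture and
  only the qualitative contrasts are meaningful.
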