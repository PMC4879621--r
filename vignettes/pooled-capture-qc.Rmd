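---
title: "Evaluating targeted deep sequencing with pooled cell-line truth sets"
author: "PoolCapQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating targeted deep sequencing with pooled cell-line truth sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PoolCapQC)
```

## The model

Panel validation by cell-line pooling rests on one piece of arithmetic.
Constituent lines are deeply sequenced one by one, and each allele call is
classified from its observed allele frequency $f$:

* heterozygous when $0.40 \le f \le 0.60$ (boundaries included),
* homozygous when $f > 0.90$ (strict),
* excluded otherwise — ambiguous calls never enter a truth set.

For a pool with mixing ratios $r_i$ (non-negative, $\sum_i r_i = 1$), the
expected minor allele frequency of an allele is

$$\mathrm{MAF} = \sum_i r_i \, d_i, \qquad
d_i = \begin{cases} 0.5 & \text{het} \\ 1 & \text{hom} \\ 0 &
\text{otherwise,} \end{cases}$$

the diploid-dosage assumption. Ten equally mixed lines give a truth set
spanning 5% (a private het) up to 100% (hom in all lines). Indels are
handled differently on purpose: they originate from tumour lines whose
allele fractions need not sit at a diploid dosage, so the expected indel
MAF multiplies the ratio by the line's *observed* indel frequency instead.
All four thresholds (het window, hom cut, the 1% background cut and the
10% genotype cut below) are arguments with these defaults.

Three derived constructions do the scoring work:

**Background alleles.** The possible-allele universe is 4 nucleotides at
every targeted base, $4 \times \mathrm{span}$ pairs. An allele at frequency
$\le 1\%$ in *every* constituent is background; reads supporting it in the
pool can only be error or contamination. The mean of
$\mathrm{count}/\mathrm{depth}$ over all background alleles (zeros
included, computed after duplicate removal) is the sample's mean background
error rate. Unobserved alleles count as zero because the catalogue defines
the denominator; catalogued alleles at zero-depth positions are excluded
and reported, since their frequency is undefined rather than zero.

**Test/control contamination groups.** For co-captured samples, alleles
background in all samples form one shared control group — no contamination
pathway can touch them, so their rates track the intrinsic error under any
plexity. Alleles background in sample $s$ but a genotype allele
($f > 10\%$) in some other co-captured sample form $s$'s test group; a
molecule fraction $c$ of contamination raises their rates by roughly $c$
times the donor dosage. The contamination estimate is the difference of
test-group means, multiplex minus single-plex, with the control shift
reported as the sanity check. Rates are averaged per sample first and then
across samples; per-allele-first averaging is available by operating on the
per-sample table directly.

**MAF-binned sensitivity.** A truth record is detected iff a call matches
position, alternate allele and class exactly (indels on their left-aligned
`+SEQ`/`-SEQ` encoding — a matching rule has to be chosen, and exact
matching is the strictest defensible one). Bins are left-open right-closed
over $(0, 0.05, 0.10, 0.15, 1]$ by default, matching the strata in which
such assays are usually quoted; percentages are reported both as raw
fractions and rounded to integer percent.

## What the simulator emulates

The generator exists so every estimator can be exercised, with known truth,
at desk scale. Its model:

* **Genotypes.** Candidate variant sites are Poisson over the target
  (default density 0.01/bp — about one variant per 100 bp, a deliberately
  marker-dense panel so a 10-kb target yields ~100 truth variants); each
  line is independently absent/het/hom at each site (defaults 0.50 / 0.35 /
  0.15, giving pools a broad MAF spread including private hets at 5%). The
  reference base is the deterministic cycle `ACGT` by position
  (`syntheticReference()`), a synthetic stand-in that makes the
  allele universe well defined without storing sequence.
* **Library complexity.** The expected number of unique capturable
  molecules per fragment-length window is
  $\mathrm{mass} / 3.3\,\mathrm{pg} \times \varepsilon$: mass over the
  haploid-genome mass (the standard human constant, 0.0033 ng) gives genome
  copies, and a conversion efficiency $\varepsilon$ (default 0.01, the
  order of magnitude of ligation-plus-capture recovery) gives molecules.
  Counts are Poisson per window — the simplest model consistent with
  independent fragment capture. Over the 6.25–200 ng input range this puts
  a 10-kb target between ~900 and ~30,000 unique molecules.
* **Duplicates.** Read pairs are drawn *with replacement* from the unique
  molecules; every repeat draw beyond the first is a duplicate. No
  coordinate-collision duplicates are simulated, so duplicate truth is
  unambiguous, and the duplicate rate falls monotonically with input mass
  at fixed read count — the library-complexity law the read metrics must
  reproduce.
* **Reads.** Fixed-length 2×100 bp pairs with adjacent mates (fragments
  clamped inside their target region so both mates overlap the target); no
  base qualities or FASTQ. Off-target pairs land in a decoy interval and
  improper pairs are flagged at configured fractions.
* **Errors.** Each sequenced base substitutes with probability $e$,
  uniformly over the three non-template alleles — hence every background
  allele accumulates at rate $e/3$, the analytic anchor used in testing.
* **Contamination.** A fraction $c$ of on-target pairs is drawn from the
  co-captured samples' molecule pools — contamination at the molecule
  level, as pooled capture produces it. Sequencer index swapping is not
  modelled separately. Because contaminant draws come from a lightly
  sampled pool, they deduplicate less than the host's reads; the expected
  post-dedup donor fraction follows the occupancy form
  $M(1 - (1 - 1/M)^n)$ for $n$ draws over $M$ molecules, which is what the
  recovery tests check against.

What the simulator does **not** emulate, and hence what passing tests do
not show about real data: GC and palindrome coverage bias, capture
efficiency differences between probes, PCR-cycle-dependent duplication
structure (real duplicate rates entangle cycles and cluster chemistry;
here they are pure finite-complexity resampling), FFPE damage, base-quality
structure, and index swapping. Estimator *arithmetic* validated here
carries over; absolute performance numbers do not.

## Numerical and design choices

* **Filter priority.** A read failing several filters is counted once, in
  the first failing category of unmapped → duplicate → improper pair →
  off-target. Stacked-bar accounting only partitions if some order is
  fixed; this one follows the order in which a pipeline learns the facts.
* **Raw read depth** is defined as on-region bases of *all* reads before
  any filtering divided by the target span; down-sampling to a depth
  target selects the pair count whose expected raw depth matches.
  Down-sampling preserves pairs (both mates kept or dropped); read- vs
  pair-level subsampling is not distinguishable downstream of our metrics,
  and pair preservation keeps proper-pair semantics intact.
* **On-target** means at least 1 bp overlap with a target interval.
  Internally positions are 1-based (GRanges native); BED conversion happens
  at the I/O boundary via rtracklayer.
* **Boundary conventions** exactly as stated: het window closed, hom and
  genotype thresholds strict `>`, background `≤`.
* **Multi-allelic sites** in constituents stay as separate records per
  alternate allele; nothing merges them.
* **Concordance** applies no MAF floor by default.
* **Count thinning.** `estimateContamination(downsampleTo=)` equalizes
  data size by seeded binomial thinning of the count tables — the
  expectation-level equivalent of read-level down-sampling, which remains
  available upstream via `downsampleReads()` when read records exist.
* **Degenerate inputs.** Empty truth sets, empty distributions and
  overlapping bins error; zero-variant genomes, empty read tables and
  zero-depth positions are valid and handled explicitly.

## Problem sizes

The defaults used in examples, tests and the demo config — a 10-kb target,
10 lines, 2×100 bp reads, 20–50k read pairs per library, six input-mass
levels, about ten seeds for distributional checks — were chosen so the
full pipeline completes in minutes on a laptop while keeping Monte-Carlo
error well below the effect sizes under test (e.g. the $e/3$ background
anchor is measured with relative standard error under 1% at 50k pairs).

## A short tour

```{r tour, eval = FALSE}
rg   <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
g    <- simulateGenotypes(10, rg, variantDensity = 0.01, seed = 7)
pool <- PoolSpec(names(g))
cat  <- genotypeCatalog(g)

truth <- buildTruthSet(pool, cat)                  # SNV truth, MAF >= 5%
bg    <- buildBackgroundCatalog(cat, rg)           # ~3 alleles per base

ds <- simulateReads(pool, g, LibrarySimParams(50, 20000, seed = 11), rg)
fr <- filterReads(readRecords(ds, "sample1"))
coverageEfficiency(coverageProfile(fr$pass, rg), c(1, 100, 200, 500))

backgroundRates(alleleCounts(ds, "sample1"), bg)   # mean ~ e/3
calls <- naiveDetector(alleleCounts(ds, "sample1"))
detectionSensitivity(truth, calls)
```

## Known limitations

The naive detector is plumbing, not a caller: it thresholds fraction and
read count with no error model, so absolute sensitivities below ~5% MAF
mostly measure the detector, not the assay. The contamination estimator
assumes equal library parameters across co-captured samples; unequal
complexities change the occupancy correction. The synthetic reference has
uniform base composition, so composition-dependent error structure cannot
arise. And all coordinates live on however many contigs the target BED
declares — no assumptions about genome build are made or checked.
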