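---
title: "Methods: screening for genome edits and verifying parentage from amplicon resequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for genome edits and verifying parentage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gedscreen)
```

## The problem and the model

Racing authorities prohibit the creation of genetically modified horses.
CRISPR/Cas9 editing through nonhomologous end joining most efficiently
produces short INDELs on both chromosomes, so the detectable signature of an
engineered animal is a homozygous-alternative (HomoALT) or
compound-heterozygous (ALT1/ALT2) INDEL at a locus where no such variant
circulates in the population. Heterozygous artificial variants are
indistinguishable from natural heterozygous variation and are explicitly out
of reach for this kind of screen.

`gedscreen` operates downstream of read QC, alignment and variant calling:
its inputs are VCF calls (GT, and AD/DP when present), a per-site depth
table (the stand-in for BAM-derived depth), target regions in BED, a
known-population-variant list, an SNV panel table and pedigree files. The
screen applies three criteria in a fixed order — zygosity/class selection,
known-population exclusion, low-depth exclusion — and records for every
stage-1 call the first criterion that removed it, so the audit identity

stage-1 count = known exclusions + low-depth exclusions + final candidates

holds per sample and in aggregate.

## Variant normalization and population matching

Known-population membership is decided by exact equality of a normalized
`chrom:pos:ref:alt` key. Normalization is context-free minimal
representation: shared trailing bases are trimmed first, then shared leading
bases, keeping at least one base per allele and advancing the position per
leading base trimmed. It is idempotent and preserves the edited sequence
(property-tested by applying variants inside random flanking contexts). No
reference genome is needed, and no fuzzy or position-window matching is
attempted: the catalogue is treated as a presence/absence lookup. Zygosity
is deliberately not compared during catalogue matching — a variant seen in
the population in any state disqualifies the allele as evidence of editing.

Multi-allelic sites are kept as single records rather than split, because
ALT1/ALT2 detection needs both alternative alleles visible at one locus.
Overlapping pairs of heterozygous INDEL records in one sample are included
at stage 1 as "possible-compound" — a conservative reading of a compound
heterozygote split across records by the caller. Phase is ignored
everywhere; chromosome names are compared as exact strings, with a warning
when a panel and a VCF share none.

## Depth conventions

One depth standard runs through the pipeline: a quantity must be strictly
greater than 50 reads to support a call or a candidate.

* Genotyping: variant callers emit only non-reference sites, so REF/REF is
  recovered from site depth — no record and depth > 50 means HomoREF; no
  record and depth ≤ 50 means NoCall. A present record is trusted as the
  caller's output, again subject to depth > 50. When both a depth-table
  entry and a VCF `DP` exist, the depth table wins (it represents the
  BAM-derived measurement). The boundary is tested at 50 (NoCall) and 51
  (called).
* Candidate filtering: "low sequence depth" is not quantified where the
  screening criteria were formulated, so the same strict >50 rule is used,
  configurable via `min_candidate_depth`. A candidate with no depth record
  at all is treated as depth 0 and excluded, with a warning.
* Coverage QC: a region passes a threshold when its mean per-base depth is
  strictly greater than it; positions absent from the depth table count as
  depth 0. The mean (not the median) is the reporting statistic, matching
  how such panels are summarized; the median is available as an option.
  Percentages are rounded half-up to one decimal. Coverage is reported per
  sample and, separately, as the across-sample mean per region, since the
  original summary does not say which was used.

A heterozygous call whose minor-allele depth fraction falls below 0.10 is
flagged "allele-imbalance" but never re-called: allele-depth imbalance is a
documented cause of genotyping faults, and the flag supports panel pruning
without inventing a re-caller.

## Coding status and the amplicon-end blind spot

Whether a candidate overlaps an exon is informational by default
(`coding_only = TRUE` reproduces the narrower reading that restricts
candidacy to coding INDELs); the filtering criteria as stated do not gate on
it. Large deletions whose span ends within 25 bp of an amplicon boundary are
annotated as sitting in the upstream caller's soft-clip blind spot — the
documented failure mode by which a heterozygous 77-bp deletion placed 22 bp
from an amplicon end escapes calling entirely. The annotation is a
sensitivity caveat, not a filter; the margin default of 25 bp derives from
that 22-bp case.

## Parentage statistics

For a biallelic locus with REF frequency $p$ and $q = 1-p$:

$$\mathrm{He} = 2pq, \qquad
  \mathrm{PE1} = pq(1-pq), \qquad
  \mathrm{PE2} = 2p^2q^2.$$

PE1 is the classical one-parent-known exclusion power of a biallelic locus
(probability that a random nonparent is excluded in a trio test); PE2 is the
single-parent (motherless) exclusion power, the probability of the
opposite-homozygote configuration. These closed forms were chosen because
they reproduce the published per-locus statistics of the packaged panel and
its combined figures; they are additionally validated in the test suite by
Monte-Carlo simulation against their definitions (random nonparents under
Hardy–Weinberg, 10,000 replicates, three standard errors).

All three statistics are symmetric in $p \leftrightarrow q$ and maximal at
$p = 0.5$ (0.5, 0.1875, 0.125). Per-locus table columns are rounded half-up
to three decimals — published tables in forensic genetics round half up,
whereas base R rounds half to even. Combined powers
$1 - \prod_i(1 - \mathrm{PE}_i)$ are reported truncated toward zero at the
conventional printed precisions (10 decimals for PE1, 6 for PE2):
truncation is conservative for an exclusion-power claim.

One caveat follows from working with a published frequency column: the
packaged panel stores REF frequencies rounded to three decimals, while the
published per-locus statistics were evidently computed from unrounded count
fractions (several rows are reproduced exactly by fractions with
denominator 98, i.e. 49 diploids). Forward computation from the rounded
frequencies therefore deviates from a handful of published cells by up to
about 0.0009 — half-ULP error in $p$ propagates as roughly
$|2-4p| \cdot 0.0005$ into He. The package keeps the printed frequencies
verbatim rather than reverse-engineering counts, and its test suite states
the comparison at the half-ULP band so the discrepancy stays visible.

Mendelian consistency is decided per locus: a trio is consistent when the
child's alleles can be partitioned into one transmissible by the alleged
sire and one by the alleged dam; a duo when child and alleged parent share
at least one allele (opposite homozygotes are the only biallelic duo
exclusion). Both checkers are verified against exhaustive gamete
enumeration (27 trio, 9 duo genotype combinations). NoCall at a locus in
any tested member removes the locus from both tallies and is reported
separately, so consistent + inconsistent + no-call always equals the panel
size. Panel pruning is zero-tolerance: a locus inconsistent in any true
trio is dropped — the only policy consistent with pruning leaving zero
inconsistencies across all true trios. Declaring a nonparent is report-level
policy (default: at least one inconsistent locus); the package reports raw
counts.

## The synthetic-data generator

The generator exists so that every stage is testable without sequencing
data; its defaults encode the study conditions the pipeline is meant to
reproduce.

* **Genotypes.** Hardy–Weinberg at the packaged panel's 120 REF
  frequencies, alleles drawn independently (equivalent to genotype
  probabilities $p^2, 2pq, q^2$). Offspring receive one uniformly random
  allele per parent per locus, so true pedigrees are Mendelian-consistent by
  construction before faults.
* **Pedigree suite.** True trios plus pseudo-trios, half-pseudo-trios, true
  duos and pseudo-duos built from unrelated Hardy–Weinberg individuals,
  mirroring the published test design (29 true trios and five of each
  pseudo design).
* **Depth.** Lognormal per amplicon and sample, constant across the
  amplicon (PCR efficiency varies by primer, not by base), with a
  designated low-coverage fraction at a separate mean. The published
  coverage figure is qualitative about the distribution, so the lognormal
  family is a modelling choice; nothing downstream depends on it beyond the
  planted strata.
* **Edits.** The four packaged myostatin edits: 1-bp homozygous insertions
  at chr18:66607750 (C→CT), 66607753 (T→TA), 66609936 (T→TA) and a
  heterozygous 77-bp deletion anchored at chr18:66605476. Deleted-sequence
  context is a deterministic placeholder (the package ships no reference
  genome), labelled synthetic.
* **Faults.** Allele-bias faults flip a heterozygous call in a true-trio
  member to a homozygote chosen so the trio becomes inconsistent at that
  locus; low-depth faults push samples below the call threshold (NoCall)
  and miscall one marginal-depth member by allele dropout. Injecting 24
  fault loci into a 144-locus panel and pruning on the simulated true trios
  retains exactly the 120 clean loci.
* **Presets.** `validation-2022` pins the validation structure: 11 stage-1
  loci (three engineered insertions, four known HomoALT INDELs, one known
  ALT1/ALT2, three low-depth HomoALT INDELs), with the heterozygous
  deletion removed by the amplicon-end dropout; the screen must report
  exactly three candidates. `casework-2022` pins a clean batch: seven
  stage-1 loci, six known, one low-depth, zero candidates. Noise variants
  (SNVs of any zygosity, heterozygous INDELs) are generated at modest
  counts; the published per-sample variant totals are reproduced
  structurally, not numerically, since the underlying raw data are not
  available.

Everything is deterministic under a fixed seed, to the byte, including
emitted dataset directories.

What passing these tests shows — and does not show — about real data: the
generator produces clean biallelic genotypes, exact Hardy–Weinberg
founders, and depth that is constant within an amplicon. Real amplicon data
add PCR artefacts, whole-genome-amplification noise, multi-sample batch
effects and reference-bias subtleties that are not modelled; the tests
demonstrate the pipeline's logic and bookkeeping, not the wet-lab assay's
sensitivity.

## Numerical and design choices

* Coordinates are 1-based internally; BED input is converted at the read
  boundary only. VCF writing always sorts by (chromosome, position) and
  says so.
* Half-up rounding for all tabulated report columns
  (`floor(x·10^d + 0.5)/10^d` with a 10⁻⁹ guard); truncation toward zero
  for combined powers, with the same guard against binary representation
  landing just below an integer multiple.
* Exit codes of the pipeline runner: 0 clean, 2 candidates found, 1 error —
  chosen for scriptability in a screening-lab workflow.
* Problem sizes in the test suite (5,000 samples for Hardy–Weinberg
  goodness-of-fit, 10,000 Monte-Carlo replicates for exclusion-power
  convergence, 29-trio pedigree suites) are the package's chosen balance of
  statistical resolution against a suite that runs in well under a minute.
* The command-line surface is the R API plus `scripts/acceptance.R`; the
  pipeline runner takes a YAML config, and no separate shell binary is
  shipped.

## Known limitations

* Heterozygous artificial edits are out of scope by design; so are
  transgene detection, read-level simulation (no FASTQ), likelihood-based
  genotype calling, paternity-index (likelihood-ratio) computation and
  mitochondrial analysis.
* The known-population catalogue match is allele-exact; a novel
  representation of an old variant that survives normalization differences
  (e.g. complex substitutions) would not match.
* Depth arrives as a per-site table; the package never parses BAM/CRAM.
* Whole-genome-amplification artefacts are not modelled in the generator —
  no statistical description of them is available to emulate.
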