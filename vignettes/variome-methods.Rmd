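---
title: "Building a crop variome: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a crop variome: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(variome)
```

## The problem

Crop diversity panels — a few hundred accessions spanning the morphotypes of
a species such as a *Brassica* crop — are resequenced at moderate coverage
(around 10×) to build a *variome*: the genome-wide set of SNPs and small
InDels segregating in the population, annotated for functional consequence
and summarized per morphotype group. Most of the accessions in such panels
are doubled-haploid or inbred lines and therefore (nearly) homozygous, which
the variant filters exploit; a few genebank accessions are heterogeneous
and are exempted from the homozygosity filter.

This package implements the computational stages around the external
aligner/pileup step: paired-end read quality control, depth-table variant
filtering, gene-model-aware effect annotation, population summaries, and an
in-silico screen of SNP sites for KASP genotyping assays. It also ships a
synthetic-data generator that emits every input the pipeline consumes
together with a ground-truth manifest, so each stage can be validated
end to end without any external data.

## Read QC

A read pair is processed by five rules, in order; a removed pair is
attributed to the first rule that fires:

1. **N-fraction** — remove the pair if either mate has strictly more than
   5% `N` bases.
2. **Mean quality** — remove if either mate's arithmetic mean Phred quality
   is strictly below 20. The mean is computed on the untrimmed read, since
   trimming is listed after this rule.
3. **3′ trimming** — remove the maximal 3′-terminal run of bases with
   quality strictly below 13; the first base (scanning from the 3′ end) with
   quality ≥ 13 and everything 5′ of it is retained. Internal low-quality
   bases are never touched, so the retained read is always a prefix of the
   input read.
4. **Length floor** — remove the pair if either trimmed mate is shorter than
   40 bases.
5. **Duplicate removal** — among pairs with identical (trimmed mate-1,
   trimmed mate-2) sequences, keep only the first encountered. Qualities are
   ignored in the duplicate key: PCR duplicates of one amplicon share
   sequence, not base-call noise. Comparing trimmed rather than raw
   sequences is a choice; duplication is listed after trimming, and
   trimming is quality-driven so true duplicates usually trim identically.

All boundary comparisons are strict, exactly as the thresholds are stated
(`>5%`, `<20`, `<13`, `<40`).

## Variant filtering from allele depths

The hand-off from alignment is deliberately an allele-depth table — per
accession and site, the number of reads supporting the reference allele
(D~R~) and the alternative allele (D~A~). The aligner and pileup caller are
external tools; everything those stages contribute that the filters consume
is contained in these two numbers.

Per accession and site:

* **Candidacy**: the site is a candidate variant when
  D~A~/(D~R~+D~A~) > 0.10, emulating a caller configured to report a
  variant when more than 10% of reads disagree with the reference.
* **Confident alleles**: an allele is trusted only with ≥ 3 supporting
  reads; a candidate with no confident allele is discarded as unreliable.
* **Zygosity**: with r = D~R~/(D~R~+D~A~), the site is heterozygous when
  0.2 < r < 0.8. The source material prints this criterion with inverted
  inequalities (unsatisfiable as written); the open interval is the reading
  that retains the boundary cases as homozygous, consistent with the intent
  of keeping data for homozygous lines. Both cutoffs are configurable.
* **Homozygosity retention**: heterozygous calls are dropped for
  homozygous-line accessions; genebank accessions keep them.

A site that is *not* a candidate in some accession still contributes a
confident reference genotype there (D~R~ ≥ 3) when another accession makes
the site a variant. Without this, accessions not carrying a variant would
be scored missing rather than reference, and population allele frequencies
would be computed over carriers only — a nonsensical denominator.

The population **MAF filter** counts alleles over accessions (a homozygous
genotype is one vote, a heterozygous genotype half a vote per allele;
missing genotypes leave the denominator) and removes rows with minor allele
frequency strictly below 0.05. The floor is stated for SNPs; applying it to
InDels is available behind `include_indels` and off by default.

## Effect annotation

Variants are classified against one representative transcript per gene into
a partition: for SNPs \{nonSyn, Syn, splice, intron, UTR5, UTR3,
intergenic\}, for InDels \{frameshift, nonframeshift, splice, intron, UTR5,
UTR3, intergenic\}. Decisions embedded in the classifier:

* The **splice window** is the 8 intronic bases adjacent to each
  exon–intron junction; it is a subdivision of introns, so a coding SNP
  near a junction is CDS (Syn/nonSyn), never splice.
* Coding SNPs are translated codon-wise under the **standard genetic code**
  with no initiator-codon special casing; stop gain/loss is folded into
  nonSyn (there is no separate category).
* Coding InDels are frameshift unless their length is a multiple of 3 —
  no start-codon special cases.
* An InDel is located by its **leftmost affected base** (the base after the
  VCF anchor); if any affected base overlaps CDS the variant is promoted to
  CDS. The synthetic generator never plants boundary-spanning InDels, so
  this precedence only matters for real inputs.
* **Functional** variants are non-synonymous or splice SNPs, and coding or
  splice InDels. Two identities hold by construction and are asserted in
  the tests: categories partition the variant set (counts sum to the
  total), and functional counts equal the sum of their member categories.

Annotation is strand-symmetric: reverse-complementing the genome, flipping
the gene models and remapping the variants yields the identical category
multiset. This is used as a consistency check.

## Population summaries

* **Group polymorphism**: a variant is polymorphic within a morphotype
  group when ≥ 2 distinct non-missing genotypes occur among the group's
  accessions. Missing is ignored rather than treated as a state — the
  alternative would let a single genotyped accession plus a missing one
  count as diversity. A single-accession group is never polymorphic.
* **Windowed tracks**: non-overlapping fixed windows from position 1;
  per window, SNP/InDel/functional counts and mean heterozygosity. The
  heterozygosity estimator is the fraction of heterozygous zygosity calls
  among non-missing calls over all accessions × sites in the window,
  computed on *pre-filter* observations when a depth table is supplied:
  for homozygous lines, heterozygous evidence exists only before the
  retention filter. The window width defaults to 500 kb at genome scale;
  the pipeline's synthetic default is 10 kb so that a 50 kb toy genome has
  several windows.
* **InDel lengths**: signed histograms (insertions positive, deletions
  negative, never zero), genome-wide and CDS-only. With a coding mix tilted
  toward non-frameshift variants, CDS mass concentrates on multiples of 3,
  mirroring the selection signature seen in real coding InDels.

## KASP site selection

A SNP is accepted for KASP assay design when (1) each 50-bp flank occurs
exactly once genome-wide — exact matching on both strands; uniqueness is
implemented exactly rather than via alignment heuristics so that decisions
are deterministic and checkable against an exhaustive substring scan — and
(2) no other variant lies within 50 bp. SNPs closer than 51 bp to a
chromosome end are rejected up front. InDels are never candidates
themselves but do count as co-located variants.

## The synthetic-data generator

The generator emulates the study design the pipeline targets, not the
sequencing platform:

* **Genome and gene models**: i.i.d. random DNA with non-overlapping genes
  written into the background. Every gene has ≥ 2 exons, introns ≥ 20 bp
  (so the two 8-bp splice windows of an intron never collide), non-empty
  UTRs, and a spliced CDS that starts with ATG, ends in a stop and has no
  internal stop — guaranteed by constructing the CDS from non-stop codons
  and writing it into the chromosome.
* **Population**: morphotype groups of homozygous lines (optionally plus
  genebank accessions, which may be heterozygous). Planted variants get a
  requested category (verified at planting time), per-group alternative-
  allele frequencies drawn from a configurable spectrum (uniform on
  (0.05, 0.95) by default — wide group differentiation, as morphotype
  panels show), and per-accession genotypes drawn from those frequencies.
  The default SNP:InDel ratio (0.881) and category mix follow the marginal
  proportions of a real crop variome table. InDel lengths span −10..+10,
  1-bp events dominant, multiples of 3 for non-frameshift requests.
* **Reads**: fragments sampled uniformly from the accession's true
  haplotype at the requested coverage, 100-bp mates, Phred+33, base-call
  errors substituted at the requested rate with correspondingly lowered
  qualities. QC failures are planted explicitly (N-rich mates, low-mean-
  quality mates, low-quality 3′ tails leaving < 40 bases, exact duplicate
  pairs) and recorded in the manifest; fragment starts are drawn without
  replacement so no clean pair is an accidental duplicate.
* **Allele depths**: per-site depth is Poisson around the mean coverage
  (or exactly fixed, for closed-form checks); each read reports the true
  allele unless it errs. Error-only false-positive sites are injected at a
  configurable per-bp rate so the filter cascade has something to remove.
  Every accession gets a row at every planted-variant site with nonzero
  depth — including homozygous-reference accessions — emulating a
  population-aware pileup lookup; purely error-supported sites appear only
  when at least one alternative read occurs.

What the generator does **not** model: insert-size distributions, alignment
artifacts, mapping ambiguity in repeats, indel-realignment errors,
triplicated sub-genomes, multi-allelic sites, or any platform-specific
error structure (the binomial/Poisson model is a stand-in, not a claim
about real sequencer behaviour). Passing tests therefore demonstrate the
correctness of the *rules* — boundaries, orderings, identities, recovery
under the stated noise model — not performance on real libraries.

## Numerical and degenerate-input choices

* All random stages take an explicit integer seed; identical configuration
  and seed reproduce byte-identical files (wall times are kept out of the
  on-disk run report for this reason).
* Variants are VCF-style, 1-based, one anchor base for InDels, always
  left-aligned (`normalize_variant()` trims shared bases and shifts through
  repeat context).
* Zero-depth observations, zero-length mates, desynchronized FASTQ mates,
  conflicting reference alleles at one position, empty populations and
  infeasible gene packing all raise immediate, named errors.
* All-missing genotype rows are removed (and only they) regardless of the
  MAF floor. Multi-allelic rows are out of scope; the generator never emits
  them.

## Problem sizes

The shipped tests and the acceptance script run a 50 kb single-chromosome
genome with 10 genes, 3 groups × 5 homozygous accessions, 500 planted
variants, 10× depth and 1% error — small enough to re-run everywhere in
seconds to minutes, large enough that every category, rule and boundary is
exercised. The same functions scale to larger simulations by changing the
configuration only.
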