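# variome

Build a population **variome** — the genome-wide set of SNPs and small
InDels segregating in a resequenced crop diversity panel — from paired-end
reads and per-accession allele depths, the way large *Brassica*-style
germplasm studies do it.

Such panels consist of a few hundred accessions spanning the morphotypes of
a species, mostly doubled-haploid or inbred (homozygous) lines plus a few
heterogeneous genebank accessions, resequenced at roughly 10× coverage.
`variome` implements every computational stage around the external
aligner/pileup step:

* **Read QC** — paired-end FASTQ filtering: remove pairs with > 5% `N` in a
  mate, mean Phred quality < 20 in a mate, 3′-trim bases with quality < 13,
  drop pairs trimmed below 40 bases, and de-duplicate identical pairs
  (first kept). All comparisons strict, applied in that order.
* **Variant filtering** — from allele-depth tables (D_R, D_A per
  accession × site): a site is a candidate when D_A/(D_R+D_A) > 0.10; an
  allele is confident with ≥ 3 reads; with r = D_R/(D_R+D_A) a call is
  heterozygous when 0.2 < r < 0.8 and such calls are dropped for
  homozygous-line accessions; population rows with minor allele frequency
  < 0.05 are removed (het genotypes count half a vote, missing leaves the
  denominator).
* **Effect annotation** — against one transcript per gene: SNPs become
  nonSyn/Syn (codon translation, standard genetic code), splice (intronic,
  within 8 bp of an exon–intron junction), intron, UTR5, UTR3 or
  intergenic; InDels become frameshift/nonframeshift (length mod 3),
  splice, intron, UTR5, UTR3 or intergenic. Functional = \{nonSyn, splice\}
  for SNPs, \{frameshift, nonframeshift, splice\} for InDels.
* **Population summaries** — per-morphotype polymorphic-locus counts (total
  and functional), windowed heterozygosity/density tracks (BED-like), and
  signed InDel length histograms (genome-wide and CDS-only).
* **KASP site selection** — accept a SNP for assay design only if both
  50-bp flanks are unique genome-wide (exact match, both strands) and no
  other variant lies within 50 bp.
* **Synthetic data** — a generator for a toy multi-chromosome genome, gene
  models (GFF3), a structured accession population, gzipped FASTQ pairs
  with planted QC failures, and allele-depth tables with planted variants
  and error-only false-positive sites — all tied to a ground-truth manifest
  that serves as the oracle for every downstream stage.

## Worked example

```r
library(variome)

sim <- generate_reference(n_chromosomes = 1, chrom_length = 50000,
                          n_genes = 10, seed = 1)
pop <- generate_population(sim$ref, sim$genes, n_groups = 3,
                           accessions_per_group = 5, n_variants = 500,
                           seed = 2)
obs <- emit_population_depths(sim$ref, pop$truth, seed = 3,
                              depth = 10, error_rate = 0.01)
m <- filter_variants(obs, pop$accessions)
m
#> genotype_matrix: 498 variants x 15 accessions

ann <- annotate_variants(m$variants, sim$genes, sim$ref)
ann
#> annotation_table: 498 variants
#> SNP categories:
#>     nonSyn        Syn     splice     intron       UTR5       UTR3 intergenic
#>         29         49          0         63         91         67        139
#>      Total
#>        438
#> InDel categories:
#>    frameshift nonframeshift        splice        intron          UTR5
#>             1             3             0             9            15
#>          UTR3    intergenic         Total
#>            13            19            60

count_polymorphic_by_group(m, ann)
#>   morphotype n_accessions snp_polymorphic snp_functional_polymorphic
#> 1    group01            5             317                         22
#> 2    group02            5             300                         20
#> 3    group03            5             309                         17
#>   indel_polymorphic indel_functional_polymorphic
#> 1                49                            4
#> 2                47                            4
#> 3                41                            2

kc <- select_kasp_candidates(m$variants[m$variants$class == "SNP", ],
                             sim$ref, m$variants)
table(kc$status)
#>                 accepted rejected_cosited_variant
#>                      101                      337
```

Of 500 planted variants, 498 survive the filter cascade (the two lost are
rare alleles below the 0.05 MAF floor); the category table partitions them
exactly (438 + 60 = 498), and 101 of the retained SNPs have clean, unique
50-bp flanks suitable for KASP primer design — on a dense 50 kb toy genome
most rejections are co-sited variants, as expected.

The whole chain can also be run as one configured pipeline, from R
(`run_variome_pipeline()`) or the shell:

```sh
Rscript inst/scripts/variome.R all --config run.yaml
```

Stages exchange FASTA/GFF3/FASTQ/TSV/VCF files in an output directory, so
any stage can be re-run alone or replaced by real external tools (BWA +
samtools) on non-synthetic data.

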