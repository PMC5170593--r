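#' Generate a synthetic reference genome with gene models
#'
#' Builds a small multi-chromosome genome of i.i.d. random DNA and places
#' non-overlapping protein-coding genes on it, one transcript per gene. Every
#' gene has at least two exons (so introns and splice windows exist),
#' non-empty 5' and 3' UTRs, introns of at least 20 bp (the two 8-bp splice
#' windows of one intron never collide), a spliced CDS whose length is a
#' multiple of 3, starting with ATG, ending in a stop codon and free of
#' internal stops. Gene sequences are written into the chromosome background
#' so translation guarantees hold by construction.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length length of each chromosome in bp (>= 10000).
#' @param n_genes total number of genes to place across chromosomes.
#' @param seed integer seed; the same call with the same seed yields
#'   byte-identical FASTA/GFF3 output.
#' @return a list with elements `ref` (named [Biostrings::DNAStringSet]) and
#'   `genes` (a `gene_models` object).
#' @examples
#' sim <- generate_reference(1, 50000, 10, seed = 1)
#' sim$genes
#' @export
generate_reference <- function(n_chromosomes, chrom_length, n_genes, seed) {
  if (chrom_length < 10000L) stopf("chrom_length must be >= 10000 bp")
  if (n_chromosomes < 1L || n_genes < 1L) stopf("need >=1 chromosome and gene")
  set.seed(seed)

  chrom_names <- sprintf("chr%02d", seq_len(n_chromosomes))
  per_chrom <- diff(round(seq(0, n_genes, length.out = n_chromosomes + 1)))

  chrom_seqs <- character(n_chromosomes)
  genes <- list()
  gene_no <- 0L
  for (ci in seq_len(n_chromosomes)) {
    bases <- strsplit(random_dna(chrom_length), "")[[1]]
    nk <- per_chrom[ci]
    plans <- lapply(seq_len(nk), function(k)
      plan_gene(sprintf("gene%03d", gene_no + k), chrom_names[ci]))
    total <- sum(vapply(plans, `[[`, 1, "glen"))
    # 200 bp end margins and >=150 bp between genes, slack spread randomly
    slack <- chrom_length - 400L - total - if (nk > 1) 150L * (nk - 1L) else 0L
    if (slack < 0L)
      stopf(paste0("infeasible packing: %d genes (%d bp of gene span) do not ",
                   "fit on %s (%d bp chromosome)"),
            nk, total, chrom_names[ci], chrom_length)
    w <- runif(nk + 1L)
    gaps <- as.integer(slack * w / sum(w))
    cursor <- 200L + gaps[1]
    for (k in seq_len(nk)) {
      gene_no <- gene_no + 1L
      g <- realize_gene(plans[[k]], cursor)
      # write transcript bases into the background at exon positions
      txg <- tx_to_genome(g)
      tx_chars <- strsplit(plans[[k]]$tx_seq, "")[[1]]
      if (g$strand == "-") tx_chars <- comp_base(tx_chars)
      bases[txg] <- tx_chars
      genes[[gene_no]] <- g
      cursor <- g$tx_end + 150L + gaps[k + 1L]
    }
    chrom_seqs[ci] <- paste(bases, collapse = "")
  }
  ref <- Biostrings::DNAStringSet(setNames(chrom_seqs, chrom_names))
  gm <- new_gene_models(genes)
  validate_gene_models(gm, ref)
  list(ref = ref, genes = gm)
}

# Draw a transcript layout: UTR lengths, CDS codons, exon/intron lengths,
# strand, and the literal transcript sequence (guaranteeing ATG .. stop).
plan_gene <- function(gene_id, chrom) {
  utr5_len <- sample(30:80, 1)
  utr3_len <- sample(30:80, 1)
  n_codons <- sample(40:120, 1)           # incl. start and terminal stop
  cds_len <- 3L * n_codons
  tx_len <- utr5_len + cds_len + utr3_len
  n_exons <- sample(2:4, 1)
  # split tx_len into n_exons parts, each >= 30 bp
  cuts <- sort(sample(seq(30L, tx_len - 30L), n_exons - 1L))
  exon_lens <- diff(c(0L, cuts, tx_len))
  while (any(exon_lens < 30L)) {
    cuts <- sort(sample(seq(30L, tx_len - 30L), n_exons - 1L))
    exon_lens <- diff(c(0L, cuts, tx_len))
  }
  intron_lens <- sample(20:200, n_exons - 1L, replace = TRUE)
  strand <- sample(c("+", "-"), 1)

  codons <- c("ATG",
              sample(setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS),
                     n_codons - 2L, replace = TRUE),
              sample(STOP_CODONS, 1))
  tx_seq <- paste0(random_dna(utr5_len), paste(codons, collapse = ""),
                   random_dna(utr3_len))
  # transcript sequence is in transcript orientation; exon lengths are in
  # genomic order, so reverse them for minus-strand genes
  genomic_exon_lens <- if (strand == "-") rev(exon_lens) else exon_lens
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       utr5_len = utr5_len, cds_len = cds_len, tx_len = tx_len,
       exon_lens = genomic_exon_lens, intron_lens = intron_lens,
       tx_seq = tx_seq, glen = tx_len + sum(intron_lens))
}

# Place a planned gene at a genomic start coordinate and derive regions.
realize_gene <- function(plan, start) {
  n_exons <- length(plan$exon_lens)
  exons <- matrix(0L, n_exons, 2)
  pos <- start
  for (i in seq_len(n_exons)) {
    exons[i, ] <- c(pos, pos + plan$exon_lens[i] - 1L)
    pos <- exons[i, 2] + 1L
    if (i < n_exons) pos <- pos + plan$intron_lens[i]
  }
  # CDS occupies spliced coordinates utr5_len+1 .. utr5_len+cds_len
  g0 <- list(chrom = plan$chrom, strand = plan$strand, exons = exons)
  txg <- tx_to_genome(g0)
  cds_g <- txg[(plan$utr5_len + 1L):(plan$utr5_len + plan$cds_len)]
  derive_gene_regions(plan$gene_id, plan$chrom, plan$strand, exons,
                      cds_span = range(cds_g))
}

# Genomic positions of the spliced transcript, in transcript order (5'->3').
tx_to_genome <- function(gene) {
  pos <- unlist(lapply(seq_len(nrow(gene$exons)), function(i)
    seq.int(gene$exons[i, 1], gene$exons[i, 2])))
  if (gene$strand == "-") rev(pos) else pos
}
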