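# Independent brute-force oracles. These deliberately re-derive every rule
# from its plain statement, without touching the package's vectorized paths.

# Full-protein retranslation: mutate the chromosome, rebuild the entire
# spliced CDS, translate, and compare proteins.
oracle_snp_effect <- function(chrom_seq, gene, pos, ref_allele, alt_allele) {
  stopifnot(substr(chrom_seq, pos, pos) == ref_allele)
  mut <- chrom_seq
  substr(mut, pos, pos) <- alt_allele
  protein <- function(s) {
    pieces <- apply(gene$cds, 1, function(iv) substr(s, iv[1], iv[2]))
    cds <- paste(pieces, collapse = "")
    if (gene$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    # plain codon-table translation: no initiator-codon special casing
    as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                       no.init.codon = TRUE,
                                       if.fuzzy.codon = "X"))
  }
  if (protein(chrom_seq) == protein(mut)) "Syn" else "nonSyn"
}

# Literal evaluation of the three printed depth rules for one accession.
oracle_cascade_decision <- function(D_R, D_A, homozygous_line) {
  candidate <- D_A / (D_R + D_A) > 0.10
  confident <- character(0)
  if (D_R >= 3) confident <- c(confident, "ref")
  if (D_A >= 3) confident <- c(confident, "alt")
  r <- D_R / (D_R + D_A)
  zyg <- if (r > 0.2 && r < 0.8) "het" else if (r <= 0.2) "hom_alt" else "hom_ref"
  # a kept *variant* call: candidate, reliably covered, and resolving to a
  # non-reference genotype the accession is allowed to carry
  keep_variant <- candidate && length(confident) > 0 &&
    ((zyg == "hom_alt" && "alt" %in% confident) ||
       (zyg == "het" && !homozygous_line))
  list(candidate = candidate, confident = confident, zygosity = zyg,
       keep = keep_variant)
}

# Naive quadratic reference implementation of the five read-QC rules.
oracle_read_qc <- function(ids, s1, q1, s2, q2,
                           max_n = 0.05, min_q = 20, floor = 13, min_len = 40) {
  n <- length(ids)
  trim_len <- function(q) {
    k <- length(q)
    while (k >= 1 && q[k] < floor) k <- k - 1
    k
  }
  nfrac <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(ch == "N") / length(ch)
  }
  keep <- rep(TRUE, n)
  t1 <- character(n); t2 <- character(n)
  for (i in seq_len(n)) {
    if (nfrac(s1[i]) > max_n || nfrac(s2[i]) > max_n) { keep[i] <- FALSE; next }
    if (mean(q1[[i]]) < min_q || mean(q2[[i]]) < min_q) { keep[i] <- FALSE; next }
    k1 <- trim_len(q1[[i]]); k2 <- trim_len(q2[[i]])
    t1[i] <- substr(s1[i], 1, k1); t2[i] <- substr(s2[i], 1, k2)
    if (k1 < min_len || k2 < min_len) keep[i] <- FALSE
  }
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(i - 1)) {
      if (keep[j] && t1[i] == t1[j] && t2[i] == t2[j]) { keep[i] <- FALSE; break }
    }
  }
  ids[keep]
}

# Exhaustive substring scan: occurrences of a k-mer in the genome, both
# strands, by direct position-by-position comparison.
oracle_kmer_occurrences <- function(kmer, ref) {
  k <- nchar(kmer)
  total <- 0L
  for (chrom in names(ref)) {
    s <- as.character(ref[[chrom]])
    rc <- as.character(Biostrings::reverseComplement(ref[[chrom]]))
    for (str in c(s, rc)) {
      starts <- seq_len(nchar(str) - k + 1L)
      total <- total + sum(substring(str, starts, starts + k - 1L) == kmer)
    }
  }
  total
}
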