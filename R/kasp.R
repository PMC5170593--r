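#' Flank uniqueness for a candidate KASP SNP
#'
#' Extracts the two `flank`-bp sequences immediately left and right of the
#' SNP and searches each as an exact match across the whole reference, on
#' both strands. A flank is unique when it occurs exactly once genome-wide
#' (its own locus).
#'
#' @param chrom,pos the SNP position (1-based).
#' @param ref reference genome ([Biostrings::DNAStringSet]).
#' @param flank flank length in bp (default 50).
#' @return list with `status` (`"unique"`, `"nonunique"` or `"near_edge"`),
#'   `left` and `right` flank sequences (`NA` when near an edge).
#' @export
flank_unique <- function(chrom, pos, ref, flank = 50L) {
  len <- Biostrings::width(ref)[match(chrom, names(ref))]
  if (is.na(len)) stopf("unknown chromosome: %s", chrom)
  if (pos < flank + 1L || pos > len - flank)
    return(list(status = "near_edge", left = NA_character_,
                right = NA_character_))
  left <- subseq_chr(ref, chrom, pos - flank, pos - 1L)
  right <- subseq_chr(ref, chrom, pos + 1L, pos + flank)
  status <- if (genome_occurrences(left, ref) == 1L &&
                genome_occurrences(right, ref) == 1L) "unique" else "nonunique"
  list(status = status, left = left, right = right)
}

# Exact occurrence count of a k-mer across all chromosomes, both strands.
genome_occurrences <- function(kmer, ref) {
  pat <- Biostrings::DNAString(kmer)
  rc <- Biostrings::reverseComplement(pat)
  fwd <- sum(Biostrings::vcountPattern(pat, ref))
  rev <- sum(Biostrings::vcountPattern(rc, ref))
  fwd + rev
}

#' Flank cleanliness: no co-located variants
#'
#' @param chrom,pos the candidate SNP.
#' @param all_variants data.frame of all population variants (columns chrom,
#'   pos); may include the candidate itself.
#' @param flank window half-width in bp (default 50).
#' @return `TRUE` when no other variant lies within `[pos - flank,
#'   pos + flank]` (the candidate's own position excluded).
#' @export
flank_clean <- function(chrom, pos, all_variants, flank = 50L) {
  hits <- all_variants$chrom == chrom &
    all_variants$pos >= pos - flank & all_variants$pos <= pos + flank &
    all_variants$pos != pos
  !any(hits)
}

#' Select SNP sites suitable for KASP assay design
#'
#' Applies, in order: the edge guard (both flanks must be fully on the
#' chromosome), the flank-uniqueness criterion and the no-co-located-variant
#' criterion. InDels are not candidates (KASP assays here are designed for
#' SNPs only) but do count as co-located variants. The first failing
#' criterion is recorded.
#'
#' @param snps data.frame of candidate SNPs (chrom, pos, ref, alt).
#' @param ref reference genome.
#' @param all_variants data.frame of all population variants (chrom, pos).
#' @param flank flank length in bp (default 50).
#' @return data.frame: chrom, pos, ref, alt, status in \{accepted,
#'   rejected_near_edge, rejected_nonunique_flank, rejected_cosited_variant\},
#'   left_flank, right_flank (sequences for accepted candidates).
#' @export
select_kasp_candidates <- function(snps, ref, all_variants, flank = 50L) {
  if (nrow(snps) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      status = character(), left_flank = character(),
                      right_flank = character(), stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(snps)), function(i) {
    s <- snps[i, ]
    fu <- flank_unique(s$chrom, s$pos, ref, flank)
    status <- if (fu$status == "near_edge") "rejected_near_edge"
    else if (fu$status == "nonunique") "rejected_nonunique_flank"
    else if (!flank_clean(s$chrom, s$pos, all_variants, flank))
      "rejected_cosited_variant"
    else "accepted"
    data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
               status = status,
               left_flank = if (status == "accepted") fu$left else NA_character_,
               right_flank = if (status == "accepted") fu$right else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
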