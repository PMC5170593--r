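#' Variant effect annotation against gene models
#'
#' Variants are classified into the category partition used for crop variome
#' summaries. SNPs take one of \{nonSyn, Syn, splice, intron, UTR5, UTR3,
#' intergenic\}; InDels one of \{frameshift, nonframeshift, splice, intron,
#' UTR5, UTR3, intergenic\}. "splice" is the subdivision of introns within
#' 8 bp of an exon-intron junction (measured on the intronic side only);
#' coding SNPs are synonymous or non-synonymous by codon translation
#' (stop gain/loss counts as non-synonymous); coding InDels are frameshift
#' unless their length is a multiple of 3. A SNP in CDS that also lies near a
#' junction is CDS, not splice. Functional variants are non-synonymous or
#' splice SNPs, and coding-sequence or splice InDels.
#'
#' @name effect_annotation
NULL

SNP_CATEGORIES <- c("nonSyn", "Syn", "splice", "intron", "UTR5", "UTR3",
                    "intergenic")
INDEL_CATEGORIES <- c("frameshift", "nonframeshift", "splice", "intron",
                      "UTR5", "UTR3", "intergenic")
FUNCTIONAL_SNP <- c("nonSyn", "splice")
FUNCTIONAL_INDEL <- c("frameshift", "nonframeshift", "splice")
SPLICE_WINDOW <- 8L

#' Variant class from VCF-style ref/alt alleles
#'
#' @param ref,alt character vectors of reference and alternative alleles.
#' @return "SNP" where both alleles are single bases, else "InDel".
#' @export
variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "InDel")
}

in_intervals <- function(pos, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(FALSE)
  any(pos >= iv[, 1] & pos <= iv[, 2])
}

#' Locate a position relative to gene models
#'
#' Resolves the genomic region of a single position: intergenic if it
#' overlaps no transcript span; otherwise CDS, splice (intronic, within the
#' 8-bp window of either flanking junction), intron, UTR5 or UTR3.
#'
#' @param chrom,pos chromosome name and 1-based position.
#' @param genes a `gene_models` object.
#' @return list with `gene_id` (or `NA`) and `region`.
#' @export
locate_position <- function(chrom, pos, genes) {
  for (g in genes) {
    if (g$chrom != chrom || pos < g$tx_start || pos > g$tx_end) next
    if (in_intervals(pos, g$cds)) return(list(gene_id = g$gene_id, region = "CDS"))
    if (in_intervals(pos, g$utr5)) return(list(gene_id = g$gene_id, region = "UTR5"))
    if (in_intervals(pos, g$utr3)) return(list(gene_id = g$gene_id, region = "UTR3"))
    # intronic: distance to the nearest junction, intronic side
    n <- nrow(g$exons)
    for (i in seq_len(n - 1L)) {
      intron_start <- g$exons[i, 2] + 1L
      intron_end <- g$exons[i + 1L, 1] - 1L
      if (pos >= intron_start && pos <= intron_end) {
        d <- min(pos - intron_start, intron_end - pos) + 1L
        region <- if (d <= SPLICE_WINDOW) "splice" else "intron"
        return(list(gene_id = g$gene_id, region = region))
      }
    }
    return(list(gene_id = g$gene_id, region = "intron"))  # unreachable for valid models
  }
  list(gene_id = NA_character_, region = "intergenic")
}

# Region of a variant: SNPs by their position; InDels by the leftmost
# affected base (first base after the anchor), promoted to CDS if any
# affected base overlaps a CDS interval.
locate_variant <- function(chrom, pos, ref, alt, genes) {
  cls <- variant_class(ref, alt)
  if (cls == "SNP") return(locate_position(chrom, pos, genes))
  del_len <- max(nchar(ref) - nchar(alt), 0L)
  span <- if (del_len > 0) (pos + 1L):(pos + del_len) else pos + 1L
  loc <- locate_position(chrom, span[1], genes)
  if (loc$region != "CDS") {
    for (g in genes) {
      if (g$chrom != chrom) next
      if (any(vapply(span, in_intervals, TRUE, iv = g$cds))) {
        return(list(gene_id = g$gene_id, region = "CDS"))
      }
    }
  }
  loc
}

#' Classify a coding SNP as synonymous or non-synonymous
#'
#' Builds the spliced CDS in transcript orientation (reverse-complemented for
#' minus-strand genes), substitutes the alternative allele and translates the
#' affected codon under the standard genetic code.
#'
#' @param chrom,pos,ref,alt the SNP (1-based; single-base alleles).
#' @param gene the gene record whose CDS contains `pos`.
#' @param refgen reference genome ([Biostrings::DNAStringSet]).
#' @return `"Syn"` or `"nonSyn"`.
#' @export
classify_snp_cds <- function(chrom, pos, ref, alt, gene, refgen) {
  obs <- subseq_chr(refgen, chrom, pos, pos)
  if (obs != ref)
    stopf("reference allele mismatch at %s:%d (expected %s, genome has %s)",
          chrom, pos, ref, obs)
  cpos <- cds_positions(gene)
  i <- match(pos, cpos)
  if (is.na(i)) stopf("position %s:%d not in CDS of %s", chrom, pos, gene$gene_id)
  cds <- spliced_cds(refgen, gene)
  alt_t <- if (gene$strand == "-") comp_base(alt) else alt
  ci <- (i - 1L) %/% 3L
  codon <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
  mut <- codon
  substr(mut, i - 3L * ci, i - 3L * ci) <- alt_t
  aa0 <- Biostrings::GENETIC_CODE[[codon]]
  aa1 <- Biostrings::GENETIC_CODE[[mut]]
  if (aa0 == aa1) "Syn" else "nonSyn"
}

#' Classify a coding InDel by the frameshift rule
#'
#' @param ref,alt VCF-style alleles with one anchor base.
#' @return `"nonframeshift"` if the length change is a multiple of 3, else
#'   `"frameshift"`.
#' @export
classify_indel_cds <- function(ref, alt) {
  len <- abs(nchar(alt) - nchar(ref))
  if (len == 0L) stopf("not an InDel: ref and alt have equal length")
  if (len %% 3L == 0L) "nonframeshift" else "frameshift"
}

#' Annotate variants against gene models
#'
#' Applies [locate_position()]/[locate_variant()] and the coding classifiers
#' to every variant, producing one category per variant plus the marginal
#' count tables (SNP and InDel, in the column order nonSyn/Syn or
#' frameshift/nonframeshift, splice, intron, UTR5, UTR3, intergenic, Total).
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param genes a `gene_models` object.
#' @param refgen reference genome ([Biostrings::DNAStringSet]).
#' @return an `annotation_table`: list with `variants` (input plus `class`,
#'   `gene_id`, `category`, `functional`) and `counts` (named list of the two
#'   marginal vectors).
#' @export
annotate_variants <- function(variants, genes, refgen) {
  n <- nrow(variants)
  cls <- variant_class(variants$ref, variants$alt)
  gene_id <- character(n); category <- character(n)
  gene_index <- setNames(seq_along(genes), vapply(genes, `[[`, "", "gene_id"))
  for (i in seq_len(n)) {
    v <- variants[i, ]
    if (!v$chrom %in% names(refgen))
      stopf("unknown chromosome: %s", v$chrom)
    loc <- locate_variant(v$chrom, v$pos, v$ref, v$alt, genes)
    gene_id[i] <- loc$gene_id
    if (loc$region == "CDS") {
      g <- genes[[gene_index[[loc$gene_id]]]]
      category[i] <- if (cls[i] == "SNP")
        classify_snp_cds(v$chrom, v$pos, v$ref, v$alt, g, refgen)
      else classify_indel_cds(v$ref, v$alt)
    } else {
      category[i] <- loc$region
    }
  }
  functional <- ifelse(cls == "SNP", category %in% FUNCTIONAL_SNP,
                       category %in% FUNCTIONAL_INDEL)
  ann <- cbind(variants[, c("chrom", "pos", "ref", "alt")],
               data.frame(class = cls, gene_id = gene_id,
                          category = category, functional = functional,
                          stringsAsFactors = FALSE))
  structure(list(variants = ann, counts = category_counts(ann)),
            class = "annotation_table")
}

# Marginal count vectors in variome-table column order.
category_counts <- function(ann) {
  snp <- table(factor(ann$category[ann$class == "SNP"], levels = SNP_CATEGORIES))
  ind <- table(factor(ann$category[ann$class == "InDel"], levels = INDEL_CATEGORIES))
  list(SNP = c(as.vector(snp), Total = sum(snp)) |>
         setNames(c(SNP_CATEGORIES, "Total")),
       InDel = c(as.vector(ind), Total = sum(ind)) |>
         setNames(c(INDEL_CATEGORIES, "Total")))
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("annotation_table:", nrow(x$variants), "variants\n")
  cat("SNP categories:\n"); print(x$counts$SNP)
  cat("InDel categories:\n"); print(x$counts$InDel)
  invisible(x)
}

#' Write an annotation table and its marginals to TSV
#'
#' @param ann an `annotation_table`.
#' @param path per-variant TSV path; marginals go to `<path>.counts.tsv`.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(ann, path) {
  write_tsv(ann$variants, path)
  counts <- rbind(
    data.frame(class = "SNP", category = names(ann$counts$SNP),
               n = as.vector(ann$counts$SNP)),
    data.frame(class = "InDel", category = names(ann$counts$InDel),
               n = as.vector(ann$counts$InDel)))
  write_tsv(counts, paste0(path, ".counts.tsv"))
  invisible(path)
}
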