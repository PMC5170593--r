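#' Reverse-complement a whole study
#'
#' Mirrors a reference genome (every chromosome reverse-complemented),
#' remaps its gene models (intervals reflected, strands flipped) and,
#' optionally, a variant table (alleles reverse-complemented, positions
#' reflected, then re-normalized to left-aligned anchored representation).
#' Annotation is strand-symmetric, so the mirrored study must yield the same
#' category multiset -- useful as an internal consistency check.
#'
#' @param ref reference genome ([Biostrings::DNAStringSet]).
#' @param genes a `gene_models` object.
#' @param variants optional data.frame (chrom, pos, ref, alt).
#' @return list with mirrored `ref`, `genes` and (if given) `variants`.
#' @export
mirror_study <- function(ref, genes, variants = NULL) {
  lens <- setNames(Biostrings::width(ref), names(ref))
  mref <- Biostrings::reverseComplement(ref)
  names(mref) <- names(ref)

  mgenes <- lapply(genes, function(g) {
    L <- lens[[g$chrom]]
    flip <- function(iv) {
      out <- cbind(L - iv[, 2] + 1L, L - iv[, 1] + 1L)
      out[order(out[, 1]), , drop = FALSE]
    }
    derive_gene_regions(g$gene_id, g$chrom,
                        strand = if (g$strand == "+") "-" else "+",
                        exons = flip(g$exons),
                        cds_span = c(L - g$cds_span[2] + 1L,
                                     L - g$cds_span[1] + 1L))
  })
  mgenes <- new_gene_models(mgenes)

  mv <- NULL
  if (!is.null(variants)) {
    mv <- variants
    for (i in seq_len(nrow(mv))) {
      L <- lens[[mv$chrom[i]]]
      nr <- nchar(mv$ref[i])
      pos <- L - (mv$pos[i] + nr - 1L) + 1L
      refm <- revcomp(mv$ref[i])
      altm <- revcomp(mv$alt[i])
      if (nr > 1 || nchar(altm) > 1) {
        nm <- normalize_variant(as.character(mref[[mv$chrom[i]]]), pos, refm, altm)
        pos <- nm$pos; refm <- nm$ref; altm <- nm$alt
      }
      mv$pos[i] <- pos; mv$ref[i] <- refm; mv$alt[i] <- altm
    }
  }
  list(ref = mref, genes = mgenes, variants = mv)
}
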