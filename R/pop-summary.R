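#' Per-morphotype polymorphic-locus counts
#'
#' A variant is polymorphic within a group when at least two distinct
#' non-missing genotypes occur among the group's accessions (missing is
#' ignored, not a state). Functional columns restrict to functional
#' categories: non-synonymous and splice for SNPs; frameshift,
#' non-frameshift and splice for InDels. A single-accession group can never
#' be polymorphic.
#'
#' @param m a `genotype_matrix`.
#' @param ann an `annotation_table` covering the same variants (matched by
#'   chrom/pos/ref/alt).
#' @param meta accession metadata data.frame; defaults to the matrix's own.
#' @return data.frame: morphotype, n_accessions, snp_polymorphic,
#'   snp_functional_polymorphic, indel_polymorphic,
#'   indel_functional_polymorphic.
#' @export
count_polymorphic_by_group <- function(m, ann, meta = m$accessions) {
  if (any(table(meta$morphotype) == 0) || nrow(meta) == 0)
    stopf("group with zero accessions")
  akey <- paste(ann$variants$chrom, ann$variants$pos, ann$variants$ref,
                ann$variants$alt)
  mkey <- paste(m$variants$chrom, m$variants$pos, m$variants$ref,
                m$variants$alt)
  idx <- match(mkey, akey)
  if (anyNA(idx)) stopf("annotation table does not cover all matrix variants")
  category <- ann$variants$category[idx]
  functional <- ann$variants$functional[idx]
  cls <- m$variants$class

  groups <- unique(meta$morphotype)
  out <- lapply(groups, function(grp) {
    accs <- meta$accession[meta$morphotype == grp]
    sub <- m$genotypes[, accs, drop = FALSE]
    poly <- apply(sub, 1, function(g) {
      g <- g[g != "missing"]
      length(unique(g)) >= 2
    })
    data.frame(morphotype = grp, n_accessions = length(accs),
               snp_polymorphic = sum(poly & cls == "SNP"),
               snp_functional_polymorphic = sum(poly & cls == "SNP" & functional),
               indel_polymorphic = sum(poly & cls == "InDel"),
               indel_functional_polymorphic = sum(poly & cls == "InDel" & functional),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Windowed genome tracks
#'
#' Cuts each chromosome into fixed, non-overlapping windows starting at
#' position 1 and reports, per window: mean heterozygosity (fraction of
#' heterozygous calls among non-missing calls over all accessions x sites in
#' the window), SNP count, InDel count and functional-variant count. When a
#' pre-filter allele-observation table is supplied, heterozygosity is
#' computed from the zygosity classification of those observations --
#' heterozygous evidence in homozygous lines exists only before filtering;
#' otherwise it falls back to het genotypes in the matrix.
#'
#' @param m a `genotype_matrix`.
#' @param ann matching `annotation_table`.
#' @param obs optional allele-observation data.frame (chrom, pos, accession,
#'   D_R, D_A) for pre-filter heterozygosity.
#' @param window window width in bp (default 500000).
#' @param chrom_lengths named integer vector of chromosome lengths; defaults
#'   to the largest observed position per chromosome.
#' @param t thresholds for the zygosity classification of `obs`.
#' @return BED-like data.frame: chrom, start (0-based), end (half-open),
#'   heterozygosity, n_snp, n_indel, n_functional.
#' @export
windowed_tracks <- function(m, ann, obs = NULL, window = 500000L,
                            chrom_lengths = NULL, t = filter_thresholds()) {
  if (window <= 0) stopf("window must be > 0")
  akey <- paste(ann$variants$chrom, ann$variants$pos, ann$variants$ref,
                ann$variants$alt)
  mkey <- paste(m$variants$chrom, m$variants$pos, m$variants$ref,
                m$variants$alt)
  functional <- ann$variants$functional[match(mkey, akey)]

  if (is.null(chrom_lengths)) {
    pos_all <- c(m$variants$pos, obs$pos)
    chr_all <- c(m$variants$chrom, obs$chrom)
    chrom_lengths <- tapply(pos_all, chr_all, max)
  }
  rows <- lapply(names(chrom_lengths), function(chrom) {
    n_win <- ceiling(chrom_lengths[[chrom]] / window)
    start0 <- (seq_len(n_win) - 1L) * window
    end <- pmin(start0 + window, chrom_lengths[[chrom]])
    vsel <- m$variants$chrom == chrom
    wv <- pmin((m$variants$pos[vsel] - 1L) %/% window + 1L, n_win)
    cnt <- function(flag) tabulate(wv[flag], nbins = n_win)
    het <- rep(NA_real_, n_win)
    if (!is.null(obs)) {
      osel <- obs$chrom == chrom
      if (any(osel)) {
        wo <- pmin((obs$pos[osel] - 1L) %/% window + 1L, n_win)
        zyg <- classify_zygosity(obs$D_R[osel], obs$D_A[osel], t)
        het_n <- tabulate(wo[zyg == "het"], nbins = n_win)
        tot_n <- tabulate(wo, nbins = n_win)
        het <- ifelse(tot_n > 0, het_n / tot_n, 0)
      } else het <- rep(0, n_win)
    } else if (nrow(m$variants) > 0) {
      sub <- m$genotypes[vsel, , drop = FALSE]
      het_n <- tabulate(wv[rep(seq_along(wv), ncol(sub))][sub == "het"], nbins = n_win)
      nm_n <- tabulate(wv[rep(seq_along(wv), ncol(sub))][sub != "missing"], nbins = n_win)
      het <- ifelse(nm_n > 0, het_n / nm_n, 0)
    } else het <- rep(0, n_win)
    data.frame(chrom = chrom, start = start0, end = end,
               heterozygosity = het,
               n_snp = cnt(m$variants$class[vsel] == "SNP"),
               n_indel = cnt(m$variants$class[vsel] == "InDel"),
               n_functional = cnt(functional[vsel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' InDel length distributions
#'
#' Signed lengths: insertions positive, deletions negative, never 0. Two
#' histograms: all InDels, and those located in coding sequence (frameshift
#' or non-frameshift category).
#'
#' @param ann an `annotation_table`.
#' @return data.frame: length, n_all, n_cds.
#' @export
indel_length_distribution <- function(ann) {
  v <- ann$variants[ann$variants$class == "InDel", ]
  len <- nchar(v$alt) - nchar(v$ref)
  if (any(len == 0)) stopf("zero-length InDel entry")
  in_cds <- v$category %in% c("frameshift", "nonframeshift")
  lv <- sort(unique(len))
  data.frame(length = lv,
             n_all = vapply(lv, function(l) sum(len == l), 1L),
             n_cds = vapply(lv, function(l) sum(len == l & in_cds), 1L))
}
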