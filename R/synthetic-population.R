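#' Left-align and trim a VCF-style variant
#'
#' Normalizes a variant to its minimal, left-aligned representation on the
#' reference: shared trailing/leading bases are trimmed and anchored InDels
#' are shifted left through repeat context, keeping one anchor base.
#'
#' @param chrom_seq chromosome sequence as a single string.
#' @param pos,ref,alt the variant (1-based, VCF-style).
#' @return list with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(chrom_seq, pos, ref, alt) {
  repeat {
    changed <- FALSE
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 &&
        substr(ref, nr, nr) == substr(alt, na, na) && !(nr == 1 && na == 1)) {
      ref <- substr(ref, 1, nr - 1L); alt <- substr(alt, 1, na - 1L)
      changed <- TRUE
    }
    if (nchar(ref) == 0 || nchar(alt) == 0) {
      if (pos <= 1L) stopf("cannot left-align variant at chromosome start")
      pos <- pos - 1L
      b <- substr(chrom_seq, pos, pos)
      ref <- paste0(b, ref); alt <- paste0(b, alt)
      changed <- TRUE
    }
    if (!changed) break
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

# Default SNP/InDel category mixes: proportions of the B. rapa-style variome
# table (nonSyn, Syn, splice, intron, UTR5, UTR3, intergenic).
default_category_mix <- function() {
  snp <- c(nonSyn = 160639, Syn = 298671, splice = 680, intron = 320898,
           UTR5 = 402207, UTR3 = 297313, intergenic = 769065)
  ind <- c(frameshift = 4467, nonframeshift = 10728, splice = 1710,
           intron = 68514, UTR5 = 81779, UTR3 = 56341, intergenic = 82441)
  list(SNP = snp / sum(snp), InDel = ind / sum(ind))
}

draw_group_freq <- function(spec, n) {
  kind <- spec$kind %||% "uniform"
  switch(kind,
         uniform = runif(n, spec$min %||% 0.05, spec$max %||% 0.95),
         fixed = rep(spec$value, n),
         beta = stats::rbeta(n, spec$shape1, spec$shape2),
         stopf("unknown maf_spectrum kind: %s", kind))
}

# Maximal genomic intervals per region category.
region_intervals <- function(genes, ref, margin = 60L) {
  iv <- list(CDS = NULL, splice = NULL, intron = NULL,
             UTR5 = NULL, UTR3 = NULL, intergenic = NULL)
  add <- function(cat, chrom, m) {
    if (is.null(m) || nrow(m) == 0) return()
    iv[[cat]] <<- rbind(iv[[cat]],
                        data.frame(chrom = chrom, start = m[, 1], end = m[, 2],
                                   stringsAsFactors = FALSE))
  }
  for (g in genes) {
    add("CDS", g$chrom, g$cds)
    add("UTR5", g$chrom, g$utr5)
    add("UTR3", g$chrom, g$utr3)
    n <- nrow(g$exons)
    for (i in seq_len(n - 1L)) {
      is <- g$exons[i, 2] + 1L; ie <- g$exons[i + 1L, 1] - 1L
      add("splice", g$chrom, rbind(c(is, is + SPLICE_WINDOW - 1L),
                                   c(ie - SPLICE_WINDOW + 1L, ie)))
      if (ie - SPLICE_WINDOW >= is + SPLICE_WINDOW)
        add("intron", g$chrom, rbind(c(is + SPLICE_WINDOW, ie - SPLICE_WINDOW)))
    }
  }
  for (chrom in names(ref)) {
    len <- Biostrings::width(ref[names(ref) == chrom])
    spans <- do.call(rbind, lapply(genes, function(g)
      if (g$chrom == chrom) c(g$tx_start, g$tx_end) else NULL))
    cursor <- margin + 1L
    gaps <- NULL
    if (!is.null(spans)) {
      spans <- spans[order(spans[, 1]), , drop = FALSE]
      for (i in seq_len(nrow(spans))) {
        if (spans[i, 1] - 1L >= cursor) gaps <- rbind(gaps, c(cursor, spans[i, 1] - 1L))
        cursor <- max(cursor, spans[i, 2] + 1L)
      }
    }
    if (len - margin >= cursor) gaps <- rbind(gaps, c(cursor, len - margin))
    add("intergenic", chrom, gaps)
  }
  iv
}

sample_interval_pos <- function(iv, span_len) {
  ok <- iv[(iv$end - iv$start + 1L) >= span_len, , drop = FALSE]
  if (nrow(ok) == 0) return(NULL)
  w <- ok$end - ok$start + 1L - span_len + 1L
  row <- ok[sample.int(nrow(ok), 1, prob = w), ]
  list(chrom = row$chrom, pos = row$start + sample.int(row$end - row$start + 2L - span_len, 1) - 1L)
}

indel_length <- function(category) {
  if (category == "nonframeshift") {
    mag <- sample(c(3L, 6L, 9L), 1, prob = c(0.6, 0.3, 0.1))
  } else if (category == "frameshift") {
    mags <- c(1L, 2L, 4L, 5L, 7L, 8L, 10L)
    mag <- sample(mags, 1, prob = 0.5^seq_along(mags))
  } else {
    mag <- sample(1:10, 1, prob = 0.5^(1:10))
  }
  mag * sample(c(-1L, 1L), 1)
}

#' Generate a synthetic accession population with planted variants
#'
#' Plants `n_variants` SNPs and InDels of known functional category on a
#' synthetic reference, assigns per-morphotype-group alternative-allele
#' frequencies drawn from `maf_spectrum`, and draws per-accession true
#' genotypes: homozygous-line accessions are always homozygous; genebank
#' accessions draw two alleles and may be heterozygous. InDel lengths span
#' -10..+10 bp (never 0); coding InDels are multiples of 3 exactly when their
#' requested category is non-frameshift. All planted variants are emitted
#' left-aligned with one anchor base and have unique, non-overlapping spans.
#'
#' @param ref,genes output of [generate_reference()].
#' @param n_groups number of morphotype groups.
#' @param accessions_per_group accessions per group (> 0).
#' @param n_variants number of variants to plant.
#' @param category_mix list with named proportion vectors `SNP` and `InDel`
#'   over the category partitions (defaults emulate a crop variome table).
#' @param maf_spectrum list describing the per-group alternative-allele
#'   frequency distribution: `list(kind = "uniform", min, max)`,
#'   `list(kind = "fixed", value)` or `list(kind = "beta", shape1, shape2)`.
#' @param seed integer seed.
#' @param p_snp probability a planted variant is a SNP (default 0.881, the
#'   SNP:InDel ratio of the emulated study design).
#' @param genebank_per_group genebank (possibly heterozygous) accessions per
#'   group, appended after the homozygous lines.
#' @return list with `accessions` (metadata data.frame) and `truth`
#'   (a `truth_manifest`).
#' @export
generate_population <- function(ref, genes, n_groups, accessions_per_group,
                                n_variants, category_mix = NULL,
                                maf_spectrum = NULL, seed,
                                p_snp = 0.881, genebank_per_group = 0L) {
  if (accessions_per_group < 1L) stopf("accessions_per_group must be >= 1 (empty population)")
  if (n_groups < 1L) stopf("n_groups must be >= 1")
  set.seed(seed)
  category_mix <- category_mix %||% default_category_mix()
  maf_spectrum <- maf_spectrum %||% list(kind = "uniform", min = 0.05, max = 0.95)
  stopifnot(abs(sum(category_mix$SNP) - 1) < 1e-8,
            abs(sum(category_mix$InDel) - 1) < 1e-8)

  groups <- sprintf("group%02d", seq_len(n_groups))
  per_group <- accessions_per_group + genebank_per_group
  meta <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    data.frame(
      accession = sprintf("%s_acc%02d", groups[g], seq_len(per_group)),
      morphotype = groups[g],
      zygosity_class = rep(c("homozygous_line", "genebank"),
                           c(accessions_per_group, genebank_per_group)),
      stringsAsFactors = FALSE)
  }))

  iv <- region_intervals(genes, ref)
  gene_index <- setNames(seq_along(genes), vapply(genes, `[[`, "", "gene_id"))
  occupied <- new.env(parent = emptyenv())
  is_free <- function(chrom, span) {
    !any(vapply(span, function(p) !is.null(occupied[[paste0(chrom, ":", p)]]), TRUE))
  }
  claim <- function(chrom, span) {
    for (p in span) occupied[[paste0(chrom, ":", p)]] <- TRUE
  }

  cls <- ifelse(runif(n_variants) < p_snp, "SNP", "InDel")
  cats <- character(n_variants)
  cats[cls == "SNP"] <- sample(names(category_mix$SNP), sum(cls == "SNP"),
                               replace = TRUE, prob = category_mix$SNP)
  cats[cls == "InDel"] <- sample(names(category_mix$InDel), sum(cls == "InDel"),
                                 replace = TRUE, prob = category_mix$InDel)

  vars <- vector("list", n_variants)
  for (i in seq_len(n_variants)) {
    vars[[i]] <- place_variant(cls[i], cats[i], iv, genes, gene_index, ref,
                               is_free, claim)
  }
  variants <- do.call(rbind, vars)
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, ]
  rownames(variants) <- NULL

  nv <- nrow(variants)
  group_freq <- matrix(draw_group_freq(maf_spectrum, nv * n_groups),
                       nrow = nv, dimnames = list(NULL, groups))
  genotypes <- matrix("ref", nv, nrow(meta),
                      dimnames = list(NULL, meta$accession))
  for (a in seq_len(nrow(meta))) {
    p <- group_freq[, meta$morphotype[a]]
    if (meta$zygosity_class[a] == "homozygous_line") {
      genotypes[, a] <- ifelse(runif(nv) < p, "alt", "ref")
    } else {
      n_alt <- rbinom(nv, 2L, p)
      genotypes[, a] <- c("ref", "het", "alt")[n_alt + 1L]
    }
  }
  dose <- matrix(c(ref = 0, het = 0.5, alt = 1)[genotypes], nv)
  f <- rowMeans(dose)
  variants$maf <- pmin(f, 1 - f)

  truth <- structure(list(
    variants = variants, group_freq = group_freq, genotypes = genotypes,
    accessions = meta,
    qc_failures = data.frame(accession = character(), pair_id = character(),
                             kind = character(), duplicate_of = character(),
                             stringsAsFactors = FALSE),
    params = list(seed = seed, n_groups = n_groups,
                  accessions_per_group = accessions_per_group,
                  genebank_per_group = genebank_per_group,
                  n_variants = n_variants, p_snp = p_snp,
                  maf_spectrum = maf_spectrum)),
    class = "truth_manifest")
  list(accessions = meta, truth = truth)
}

place_variant <- function(cls, category, iv, genes, gene_index, ref,
                          is_free, claim) {
  for (attempt in seq_len(400L)) {
    if (cls == "SNP") {
      region <- if (category %in% c("nonSyn", "Syn")) "CDS" else category
      if (is.null(iv[[region]]) || nrow(iv[[region]]) == 0)
        stopf("no eligible genomic positions for category %s", category)
      hit <- sample_interval_pos(iv[[region]], 1L)
      if (is.null(hit)) stopf("no eligible genomic positions for category %s", category)
      refb <- subseq_chr(ref, hit$chrom, hit$pos, hit$pos)
      altb <- sample(setdiff(DNA_BASES, refb), 1)
      if (region == "CDS") {
        loc <- locate_position(hit$chrom, hit$pos, genes)
        g <- genes[[gene_index[[loc$gene_id]]]]
        got <- classify_snp_cds(hit$chrom, hit$pos, refb, altb, g, ref)
        if (got != category) next
      }
      span <- hit$pos
      if (!is_free(hit$chrom, span)) next
      claim(hit$chrom, span)
      return(data.frame(chrom = hit$chrom, pos = hit$pos, ref = refb,
                        alt = altb, class = "SNP", length = 0L,
                        category = category,
                        gene_id = if (region == "CDS") g$gene_id else
                          locate_position(hit$chrom, hit$pos, genes)$gene_id,
                        stringsAsFactors = FALSE))
    }
    # InDel
    region <- if (category %in% c("frameshift", "nonframeshift")) "CDS" else category
    if (is.null(iv[[region]]) || nrow(iv[[region]]) == 0)
      stopf("no eligible genomic positions for category %s", category)
    len <- indel_length(category)
    mag <- abs(len)
    span_need <- if (len < 0) mag + 1L else 2L  # anchor + affected bases in-region
    hit <- sample_interval_pos(iv[[region]], span_need)
    if (is.null(hit)) next
    chrom_seq <- as.character(ref[[hit$chrom]])
    if (len < 0) {
      raw_ref <- substr(chrom_seq, hit$pos, hit$pos + mag)
      raw_alt <- substr(chrom_seq, hit$pos, hit$pos)
    } else {
      raw_ref <- substr(chrom_seq, hit$pos, hit$pos)
      raw_alt <- paste0(raw_ref, random_dna(mag))
    }
    nm <- normalize_variant(chrom_seq, hit$pos, raw_ref, raw_alt)
    loc <- locate_variant(hit$chrom, nm$pos, nm$ref, nm$alt, genes)
    got <- if (loc$region == "CDS") classify_indel_cds(nm$ref, nm$alt) else loc$region
    if (got != category) next
    span <- nm$pos:(nm$pos + max(nchar(nm$ref), 2L) - 1L)
    if (!is_free(hit$chrom, span)) next
    claim(hit$chrom, span)
    return(data.frame(chrom = hit$chrom, pos = nm$pos, ref = nm$ref,
                      alt = nm$alt, class = "InDel", length = len,
                      category = category, gene_id = loc$gene_id,
                      stringsAsFactors = FALSE))
  }
  stopf("could not place a variant of category %s after 400 attempts", category)
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat(sprintf("truth_manifest: %d planted variants (%d SNP, %d InDel), %d accessions, %d groups\n",
              nrow(x$variants), sum(x$variants$class == "SNP"),
              sum(x$variants$class == "InDel"), nrow(x$accessions),
              length(unique(x$accessions$morphotype))))
  if (nrow(x$qc_failures) > 0)
    cat(sprintf("  planted QC failures: %d read pairs\n", nrow(x$qc_failures)))
  invisible(x)
}

#' Write a truth manifest to TSV files
#'
#' @param truth a `truth_manifest`.
#' @param dir output directory (created if needed). Writes
#'   `manifest_variants.tsv` (with per-group frequencies), `manifest_genotypes.tsv`,
#'   `accessions.tsv` and `manifest_qc_failures.tsv`.
#' @return `dir`, invisibly.
#' @export
write_manifest_tsv <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- cbind(truth$variants,
             setNames(as.data.frame(truth$group_freq),
                      paste0("freq_", colnames(truth$group_freq))))
  write_tsv(v, file.path(dir, "manifest_variants.tsv"))
  g <- cbind(truth$variants[, c("chrom", "pos")], as.data.frame(truth$genotypes))
  write_tsv(g, file.path(dir, "manifest_genotypes.tsv"))
  write_tsv(truth$accessions, file.path(dir, "accessions.tsv"))
  write_tsv(truth$qc_failures, file.path(dir, "manifest_qc_failures.tsv"))
  invisible(dir)
}
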