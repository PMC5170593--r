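#' Variant-filter thresholds
#'
#' Houses the filtering constants of the depth-based cascade: candidacy
#' requires strictly more than `min_alt_fraction` of reads supporting the
#' alternative allele (the `bcftools view -p 0.9` behaviour); an allele is
#' confident when covered by at least `min_allele_depth` reads; a site is
#' classified heterozygous when the reference-read ratio
#' r = D_R / (D_R + D_A) lies strictly inside (`het_low`, `het_high`);
#' population rows with minor allele frequency strictly below `min_maf` are
#' removed.
#'
#' @param min_alt_fraction candidacy threshold on D_A / (D_R + D_A)
#'   (default 0.10).
#' @param min_allele_depth reads needed for a confident allele (default 3).
#' @param het_low,het_high open heterozygosity interval on r (defaults 0.2,
#'   0.8; the boundaries are assigned homozygous).
#' @param min_maf minor-allele-frequency floor (default 0.05).
#' @return a `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_alt_fraction = 0.10, min_allele_depth = 3L,
                              het_low = 0.2, het_high = 0.8, min_maf = 0.05) {
  stopifnot(het_low > 0, het_low < het_high, het_high < 1)
  structure(list(min_alt_fraction = min_alt_fraction,
                 min_allele_depth = min_allele_depth,
                 het_low = het_low, het_high = het_high, min_maf = min_maf),
            class = "filter_thresholds")
}

#' Alternative-read candidacy rule
#'
#' @param D_R,D_A reference / alternative read depths (vectors).
#' @param t a [filter_thresholds()] object.
#' @return logical: `TRUE` where D_A / (D_R + D_A) is strictly greater than
#'   the candidacy threshold.
#' @export
call_candidates <- function(D_R, D_A, t = filter_thresholds()) {
  tot <- D_R + D_A
  if (any(tot == 0)) stopf("observation with zero total depth")
  D_A / tot > t$min_alt_fraction
}

#' Confident alleles at a site
#'
#' @inheritParams call_candidates
#' @return data.frame with logical columns `ref` (D_R at or above the depth
#'   floor) and `alt` (D_A at or above it); a site where both are `FALSE` is
#'   discarded as unreliable.
#' @export
confident_alleles <- function(D_R, D_A, t = filter_thresholds()) {
  data.frame(ref = D_R >= t$min_allele_depth, alt = D_A >= t$min_allele_depth)
}

#' Zygosity classification from the reference-read ratio
#'
#' @inheritParams call_candidates
#' @return character vector in \{"hom_ref", "het", "hom_alt"\}: het where
#'   het_low < r < het_high (open interval); hom_alt where r is at or below
#'   het_low; hom_ref where r is at or above het_high.
#' @export
classify_zygosity <- function(D_R, D_A, t = filter_thresholds()) {
  tot <- D_R + D_A
  if (any(tot < 1)) stopf("observation with zero total depth")
  r <- D_R / tot
  ifelse(r > t$het_low & r < t$het_high, "het",
         ifelse(r <= t$het_low, "hom_alt", "hom_ref"))
}

#' Per-accession reliable variant calls
#'
#' Runs the per-site pipeline for one accession's observations: candidate
#' sites with a non-empty confident-allele set are genotyped by zygosity;
#' heterozygous sites are dropped for homozygous-line accessions (genebank
#' accessions keep them). Non-candidate sites contribute a confident
#' reference genotype when the reference allele is sufficiently covered --
#' this is what lets the population merge assign "ref" rather than missing
#' to accessions not carrying a variant.
#'
#' @param obs data.frame of allele observations for one accession (columns
#'   chrom, pos, ref, alt, D_R, D_A).
#' @param zygosity_class `"homozygous_line"` or `"genebank"`.
#' @param t a [filter_thresholds()] object.
#' @return `obs` with a `genotype` column in \{"ref", "alt", "het",
#'   "missing"\} and a `variant_call` logical (TRUE where the accession
#'   itself supports a non-reference allele).
#' @export
filter_accession_variants <- function(obs, zygosity_class = "homozygous_line",
                                      t = filter_thresholds()) {
  if (nrow(obs) == 0) {
    obs$genotype <- character(0); obs$variant_call <- logical(0)
    return(obs)
  }
  cand <- call_candidates(obs$D_R, obs$D_A, t)
  conf <- confident_alleles(obs$D_R, obs$D_A, t)
  zyg <- classify_zygosity(obs$D_R, obs$D_A, t)

  genotype <- rep("missing", nrow(obs))
  # non-candidate sites: reference evidence only
  genotype[!cand & conf$ref] <- "ref"
  # candidate sites with at least one confident allele
  ok <- cand & (conf$ref | conf$alt)
  genotype[ok & zyg == "hom_alt" & conf$alt] <- "alt"
  genotype[ok & zyg == "hom_ref" & conf$ref] <- "ref"
  is_het <- ok & zyg == "het"
  if (zygosity_class == "genebank") {
    genotype[is_het] <- "het"
  }  # homozygous lines: het sites stay missing (dropped)
  obs$genotype <- genotype
  obs$variant_call <- genotype %in% c("alt", "het")
  obs
}

#' Merge per-accession calls into a population genotype matrix
#'
#' Takes the union of variant sites across accessions (a site enters the
#' matrix when at least one accession makes a non-reference call there),
#' keyed by normalized (chrom, pos, ref, alt). Accessions with no confident
#' call at a site are `missing`.
#'
#' @param calls data.frame as returned by [filter_accession_variants()],
#'   rows for all accessions (column `accession` required).
#' @param accessions accession metadata data.frame (columns `accession`,
#'   `morphotype`, `zygosity_class`); fixes the column order.
#' @return a `genotype_matrix`: list with `variants` (chrom, pos, ref, alt,
#'   class) and `genotypes` (character matrix variants x accessions).
#' @export
merge_population <- function(calls, accessions) {
  vkey <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  sites <- unique(calls[calls$variant_call,
                        c("chrom", "pos", "ref", "alt"), drop = FALSE])
  if (nrow(sites) == 0) {
    return(new_genotype_matrix(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), class = character()),
      matrix(character(), 0, nrow(accessions),
             dimnames = list(NULL, accessions$accession)), accessions))
  }
  dup_pos <- unique(sites[duplicated(sites[c("chrom", "pos")]),
                          c("chrom", "pos")])
  if (nrow(dup_pos) > 0) {
    conflict <- merge(sites, dup_pos)
    if (any(tapply(conflict$ref, paste(conflict$chrom, conflict$pos),
                   function(r) length(unique(r))) > 1))
      stopf("conflicting reference alleles at one position in merge input")
  }
  sites <- sites[order(sites$chrom, sites$pos, sites$alt), ]
  rownames(sites) <- NULL
  sites$class <- variant_class(sites$ref, sites$alt)

  geno <- matrix("missing", nrow(sites), nrow(accessions),
                 dimnames = list(NULL, accessions$accession))
  key <- vkey(sites)
  for (acc in accessions$accession) {
    sub <- calls[calls$accession == acc & calls$genotype != "missing", ]
    if (!nrow(sub)) next
    idx <- match(vkey(sub), key)
    hit <- !is.na(idx)
    geno[idx[hit], acc] <- sub$genotype[hit]
    # reference evidence recorded against a different alt at the same
    # position still fixes the genotype to ref for that site
    refsub <- sub[sub$genotype == "ref", ]
    if (nrow(refsub)) {
      pidx <- which(paste(sites$chrom, sites$pos) %in%
                      paste(refsub$chrom, refsub$pos))
      pidx <- pidx[geno[pidx, acc] == "missing"]
      if (length(pidx)) geno[pidx, acc] <- "ref"
    }
  }
  new_genotype_matrix(sites, geno, accessions)
}

new_genotype_matrix <- function(variants, genotypes, accessions) {
  structure(list(variants = variants, genotypes = genotypes,
                 accessions = accessions), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d accessions\n",
              nrow(x$variants), ncol(x$genotypes)))
  invisible(x)
}

#' Minor allele frequencies of a genotype matrix
#'
#' Allele counting is over accessions: a homozygous genotype is one vote for
#' its allele, a heterozygous genotype half a vote for each; missing
#' genotypes are excluded from the denominator.
#'
#' @param m a `genotype_matrix`.
#' @return numeric vector of per-row MAF (`NaN` for all-missing rows).
#' @export
maf <- function(m) {
  dose <- matrix(c(ref = 0, het = 0.5, alt = 1, missing = NA_real_)[m$genotypes],
                 nrow(m$variants))
  f <- rowMeans(dose, na.rm = TRUE)
  pmin(f, 1 - f)
}

#' Population MAF filter
#'
#' Removes rows whose minor allele frequency is strictly below `min_maf`,
#' and rows with all genotypes missing. By default only SNP rows are subject
#' to the frequency floor (the convention of the emulated study); set
#' `include_indels = TRUE` to filter InDel rows too.
#'
#' @param m a `genotype_matrix`.
#' @param t a [filter_thresholds()] object.
#' @param include_indels apply the MAF floor to InDels as well (default
#'   `FALSE`).
#' @return the filtered `genotype_matrix`.
#' @export
maf_filter <- function(m, t = filter_thresholds(), include_indels = FALSE) {
  if (nrow(m$variants) == 0) return(m)
  fr <- maf(m)
  all_missing <- is.nan(fr)
  low <- !all_missing & fr < t$min_maf
  if (!include_indels) low <- low & m$variants$class == "SNP"
  drop <- all_missing | low
  keep <- !drop
  v <- m$variants[keep, , drop = FALSE]
  rownames(v) <- NULL
  new_genotype_matrix(v, m$genotypes[keep, , drop = FALSE], m$accessions)
}

#' Run the full depth-table filter cascade
#'
#' Convenience wrapper: per-accession filtering, population merge, and the
#' MAF filter, for a combined allele-observation table.
#'
#' @param obs data.frame with columns chrom, pos, ref, alt, accession, D_R,
#'   D_A.
#' @param accessions accession metadata data.frame.
#' @param t a [filter_thresholds()] object.
#' @param include_indels passed to [maf_filter()].
#' @return a filtered `genotype_matrix`.
#' @export
filter_variants <- function(obs, accessions, t = filter_thresholds(),
                            include_indels = FALSE) {
  calls <- do.call(rbind, lapply(seq_len(nrow(accessions)), function(i) {
    acc <- accessions$accession[i]
    sub <- obs[obs$accession == acc, , drop = FALSE]
    filter_accession_variants(sub, accessions$zygosity_class[i], t)
  }))
  maf_filter(merge_population(calls, accessions), t,
             include_indels = include_indels)
}

#' Write a genotype matrix to TSV
#'
#' @param m a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix_tsv <- function(m, path) {
  write_tsv(cbind(m$variants, as.data.frame(m$genotypes)), path)
}

#' Write a genotype matrix as a population VCF
#'
#' One row per retained variant with per-accession GT genotypes (0/0, 0/1,
#' 1/1, ./.).
#'
#' @param m a `genotype_matrix`.
#' @param path output path.
#' @param ref optional reference genome, used for contig header lines.
#' @return `path`, invisibly.
#' @export
write_population_vcf <- function(m, path, ref = NULL) {
  gt <- matrix(c(ref = "0/0", het = "0/1", alt = "1/1",
                 missing = "./.")[m$genotypes],
               nrow(m$variants), dimnames = dimnames(m$genotypes))
  header <- c("##fileformat=VCFv4.2",
              "##source=variome",
              if (!is.null(ref))
                sprintf("##contig=<ID=%s,length=%d>", names(ref),
                        Biostrings::width(ref)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  body <- apply(cbind(m$variants$chrom, m$variants$pos, ".", m$variants$ref,
                      m$variants$alt, ".", "PASS", ".", "GT", gt),
                1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
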