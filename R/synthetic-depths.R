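#' Simulate per-accession allele-depth observations
#'
#' Emits the table an alignment + pileup stage would hand to the variant
#' filters: per accession x site reference and alternative read depths
#' (D_R, D_A). At every planted-variant site the accession gets a row
#' whenever its total site depth is at least 1 (emulating a population-aware
#' pileup lookup, so homozygous-reference accessions contribute confident
#' reference evidence to the population merge); depths are drawn consistent
#' with the true genotype, the sequencing depth model and `error_rate`. In
#' addition, false-positive candidate sites -- positions where only
#' sequencing errors support an alternative allele -- are injected at
#' `fp_site_rate` per bp and recorded whenever at least one alternative read
#' occurs, so the downstream filter cascade has something to remove.
#'
#' @param accession accession id.
#' @param ref reference genome.
#' @param truth a `truth_manifest`.
#' @param depth mean fold coverage (> 0).
#' @param error_rate per-read allele error probability (in [0, 0.1)).
#' @param fp_site_rate expected error-only candidate sites per bp.
#' @param seed integer seed.
#' @param depth_model `"poisson"` (site depth ~ Poisson(depth)) or `"fixed"`
#'   (every site at exactly `depth` reads).
#' @return data.frame with columns chrom, pos, ref, alt, accession, D_R, D_A.
#' @export
emit_allele_depths <- function(accession, ref, truth, depth = 10,
                               error_rate = 0.01, fp_site_rate = 0.001,
                               seed, depth_model = c("poisson", "fixed")) {
  if (error_rate < 0 || error_rate >= 0.1) stopf("error_rate must be in [0, 0.1)")
  if (depth <= 0) stopf("depth must be > 0")
  depth_model <- match.arg(depth_model)
  set.seed(seed)

  v <- truth$variants
  g <- truth$genotypes[, accession]
  n <- nrow(v)
  N <- if (depth_model == "poisson") rpois(n, depth) else rep.int(as.integer(depth), n)
  DA <- integer(n)
  is_alt <- g == "alt"; is_het <- g == "het"
  DA[is_alt] <- rbinom(sum(is_alt), N[is_alt], 1 - error_rate)
  DA[is_het] <- rbinom(sum(is_het), N[is_het], 0.5)
  DA[!is_alt & !is_het] <- rbinom(sum(!is_alt & !is_het), N[!is_alt & !is_het],
                                  error_rate)
  planted <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                        accession = accession, D_R = N - DA, D_A = DA,
                        stringsAsFactors = FALSE)[N >= 1L, , drop = FALSE]

  # error-only false-positive candidate sites
  lens <- setNames(Biostrings::width(ref), names(ref))
  n_fp <- rpois(1, fp_site_rate * sum(lens))
  fp <- NULL
  if (n_fp > 0) {
    chrom <- sample(names(lens), n_fp, replace = TRUE, prob = lens / sum(lens))
    pos <- vapply(chrom, function(ch) sample.int(lens[[ch]], 1), 1L)
    taken <- paste0(v$chrom, ":", v$pos)
    keep <- !paste0(chrom, ":", pos) %in% taken & !duplicated(paste0(chrom, ":", pos))
    chrom <- chrom[keep]; pos <- pos[keep]
    if (length(pos)) {
      Nf <- if (depth_model == "poisson") rpois(length(pos), depth) else
        rep.int(as.integer(depth), length(pos))
      DAf <- rbinom(length(pos), Nf, error_rate)
      ok <- DAf >= 1L
      if (any(ok)) {
        refb <- mapply(function(ch, p) subseq_chr(ref, ch, p, p),
                       chrom[ok], pos[ok], USE.NAMES = FALSE)
        altb <- vapply(refb, function(b) sample(setdiff(DNA_BASES, b), 1), "",
                       USE.NAMES = FALSE)
        fp <- data.frame(chrom = chrom[ok], pos = pos[ok], ref = refb,
                         alt = altb, accession = accession,
                         D_R = Nf[ok] - DAf[ok], D_A = DAf[ok],
                         stringsAsFactors = FALSE)
      }
    }
  }
  out <- rbind(planted, fp)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Simulate allele depths for a whole population
#'
#' Calls [emit_allele_depths()] once per accession with per-accession seeds
#' derived from `seed`.
#'
#' @inheritParams emit_allele_depths
#' @param ... passed on to [emit_allele_depths()].
#' @return one combined data.frame of allele observations.
#' @export
emit_population_depths <- function(ref, truth, seed, ...) {
  accs <- truth$accessions$accession
  do.call(rbind, lapply(seq_along(accs), function(i)
    emit_allele_depths(accs[i], ref, truth, seed = seed + 7L * i, ...)))
}
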