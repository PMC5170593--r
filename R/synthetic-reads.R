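#' Simulate paired-end reads for one accession
#'
#' Samples read pairs from the accession's true haplotype (the reference with
#' its planted variants applied; heterozygous genebank variants sit on one of
#' two haplotypes sampled per fragment), injects base-call errors at
#' `error_rate` with correspondingly lowered quality scores, and plants the
#' four kinds of QC failure at the requested per-pair rates: `n_rich` (one
#' mate with >5% N), `low_mean_q` (one mate with mean quality < 20),
#' `short_after_trim` (a 3'-terminal run of sub-13 qualities long enough that
#' fewer than 40 bases remain), and `duplicate` (an exact copy of an earlier
#' clean pair). Fragment start positions are sampled without replacement so
#' no two distinct pairs are accidental duplicates. Output is Phred+33 FASTQ
#' (gzipped when the path ends in `.gz`).
#'
#' @param accession accession id (a column of the truth genotypes).
#' @param ref reference genome ([Biostrings::DNAStringSet]).
#' @param truth a `truth_manifest`.
#' @param out1,out2 output FASTQ paths for mate 1 / mate 2.
#' @param depth target fold coverage (> 0).
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error probability (in [0, 0.1)).
#' @param qc_failure_rates named numeric vector with entries `n_rich`,
#'   `low_mean_q`, `short_after_trim`, `duplicate` (per-pair probabilities).
#' @param seed integer seed.
#' @param fragment_length outer fragment span of a pair (insert-library size).
#' @return list with `files`, `n_pairs` and `qc_failures` (data.frame of
#'   planted failures: pair id, kind, duplicate_of).
#' @export
emit_reads <- function(accession, ref, truth, out1, out2, depth = 10,
                       read_length = 100L, error_rate = 0.01,
                       qc_failure_rates = c(n_rich = 0, low_mean_q = 0,
                                            short_after_trim = 0, duplicate = 0),
                       seed, fragment_length = 350L) {
  if (error_rate < 0 || error_rate >= 0.1) stopf("error_rate must be in [0, 0.1)")
  if (depth <= 0) stopf("depth must be > 0")
  if (read_length > min(Biostrings::width(ref)))
    stopf("read_length %d exceeds the shortest chromosome", read_length)
  set.seed(seed)

  haps <- accession_haplotypes(accession, ref, truth)
  chrom_lens <- vapply(haps[[1]], nchar, 1L)
  frag <- max(2L * read_length, min(fragment_length, min(chrom_lens)))
  n_pairs <- round(depth * sum(chrom_lens) / (2 * read_length))

  chrom_of <- sample(names(chrom_lens), n_pairs, replace = TRUE,
                     prob = chrom_lens / sum(chrom_lens))
  starts <- integer(n_pairs)
  for (chrom in unique(chrom_of)) {
    idx <- which(chrom_of == chrom)
    pool <- chrom_lens[[chrom]] - frag + 1L
    if (pool < length(idx)) stopf("chromosome %s too short for %d fragments",
                                  chrom, length(idx))
    starts[idx] <- sample.int(pool, length(idx))
  }
  hap_of <- sample(1:2, n_pairs, replace = TRUE)

  seq1 <- seq2 <- character(n_pairs)
  for (h in 1:2) {
    for (chrom in unique(chrom_of)) {
      idx <- which(chrom_of == chrom & hap_of == h)
      if (!length(idx)) next
      s <- haps[[h]][[chrom]]
      seq1[idx] <- substring(s, starts[idx], starts[idx] + read_length - 1L)
      seq2[idx] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(substring(s, starts[idx] + frag - read_length,
                                           starts[idx] + frag - 1L))))
    }
  }

  mk_quals <- function() {
    matrix(sample(34:40, n_pairs * read_length, replace = TRUE),
           nrow = read_length)
  }
  q1 <- mk_quals(); q2 <- mk_quals()
  res1 <- inject_errors(seq1, q1, error_rate); q1 <- res1$qual
  res2 <- inject_errors(seq2, q2, error_rate); q2 <- res2$qual

  # plant QC failures (mutually exclusive, at most one kind per pair)
  rates <- qc_failure_rates[c("n_rich", "low_mean_q", "short_after_trim",
                              "duplicate")]
  rates[is.na(rates)] <- 0
  u <- runif(n_pairs)
  cum <- cumsum(rates)
  kind <- rep("clean", n_pairs)
  kind[u < cum[1]] <- "n_rich"
  kind[u >= cum[1] & u < cum[2]] <- "low_mean_q"
  kind[u >= cum[2] & u < cum[3]] <- "short_after_trim"
  kind[u >= cum[3] & u < cum[4]] <- "duplicate"

  ids <- sprintf("%s_p%06d", accession, seq_len(n_pairs))
  dup_of <- rep(NA_character_, n_pairs)
  for (i in which(kind != "clean")) {
    mate <- sample(1:2, 1)
    if (kind[i] == "n_rich") {
      n_n <- ceiling(0.10 * read_length)
      posN <- sample.int(read_length, n_n)
      s <- if (mate == 1) res1$seq[i] else res2$seq[i]
      ch <- strsplit(s, "")[[1]]; ch[posN] <- "N"
      if (mate == 1) res1$seq[i] <- paste(ch, collapse = "") else
        res2$seq[i] <- paste(ch, collapse = "")
    } else if (kind[i] == "low_mean_q") {
      qv <- sample(8:18, read_length, replace = TRUE)
      if (mate == 1) q1[, i] <- qv else q2[, i] <- qv
    } else if (kind[i] == "short_after_trim") {
      keep <- min(39L, read_length - 1L)
      qv <- c(rep(38L, keep), rep(12L, read_length - keep))
      if (mate == 1) q1[, i] <- qv else q2[, i] <- qv
    } else if (kind[i] == "duplicate") {
      earlier <- which(kind == "clean" & seq_len(n_pairs) < i)
      if (!length(earlier)) { kind[i] <- "clean"; next }
      j <- if (length(earlier) == 1) earlier else sample(earlier, 1)
      res1$seq[i] <- res1$seq[j]; res2$seq[i] <- res2$seq[j]
      q1[, i] <- q1[, j]; q2[, i] <- q2[, j]
      dup_of[i] <- ids[j]
    }
  }
  res1$qual <- q1; res2$qual <- q2

  write_fastq(ids, res1$seq, q1, out1)
  write_fastq(ids, res2$seq, q2, out2)

  planted <- kind != "clean"
  qcf <- data.frame(accession = rep(accession, sum(planted)),
                    pair_id = ids[planted],
                    kind = kind[planted], duplicate_of = dup_of[planted],
                    stringsAsFactors = FALSE)
  list(files = c(out1, out2), n_pairs = n_pairs, qc_failures = qcf)
}

# Apply the accession's planted variants to the reference: haplotype 1 carries
# homozygous-alt variants; haplotype 2 additionally carries heterozygous ones.
accession_haplotypes <- function(accession, ref, truth) {
  g <- truth$genotypes[, accession]
  build <- function(keep) {
    out <- lapply(names(ref), function(chrom) as.character(ref[[chrom]]))
    names(out) <- names(ref)
    v <- truth$variants[keep, , drop = FALSE]
    if (nrow(v)) {
      v <- v[order(v$chrom, -v$pos), ]  # right-to-left keeps coordinates valid
      for (i in seq_len(nrow(v))) {
        s <- out[[v$chrom[i]]]
        out[[v$chrom[i]]] <- paste0(
          substr(s, 1L, v$pos[i] - 1L), v$alt[i],
          substr(s, v$pos[i] + nchar(v$ref[i]), nchar(s)))
      }
    }
    out
  }
  list(build(g == "alt"), build(g %in% c("alt", "het")))
}

# Substitute wrong bases at error positions and lower their qualities.
inject_errors <- function(seqs, quals, error_rate) {
  if (error_rate > 0 && length(seqs)) {
    rl <- nchar(seqs[1])
    err <- which(matrix(runif(length(seqs) * rl) < error_rate, nrow = rl),
                 arr.ind = TRUE)
    if (nrow(err)) {
      for (k in seq_len(nrow(err))) {
        i <- err[k, 2]; p <- err[k, 1]
        b <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, b), 1)
        quals[p, i] <- sample(3:12, 1)
      }
    }
  }
  list(seq = seqs, qual = quals)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param ids read names.
#' @param seqs character vector of sequences.
#' @param quals integer matrix (positions x reads) or list of integer vectors.
#' @param path output path; gzipped when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  if (is.matrix(quals)) quals <- lapply(seq_len(ncol(quals)), function(i) quals[, i])
  qstr <- vapply(quals, function(q) intToUtf8(q + 33L), "")
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)),
    Biostrings::PhredQuality(qstr))
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into sequences and integer qualities
#'
#' @param path FASTQ path (plain or gzipped).
#' @return list with `id`, `seq` (character) and `qual` (list of integer
#'   vectors).
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping (empty) metadata columns on conversion
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(id = names(x), seq = as.character(x),
       qual = as.list(as(Biostrings::quality(x), "IntegerList")))
}
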