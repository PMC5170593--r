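#' Read-QC thresholds
#'
#' Houses the four paired-end filtering constants: a pair is removed when
#' either mate has more than `max_n_fraction` N bases, or a mean Phred
#' quality below `min_mean_quality` (computed before trimming); 3' bases with
#' quality below `trim_quality_floor` are trimmed off, and the pair is
#' removed when either trimmed mate is shorter than `min_length_after_trim`.
#' All comparisons are strict.
#'
#' @param max_n_fraction maximum tolerated N fraction per mate (default 0.05).
#' @param min_mean_quality minimum mean Phred quality per mate (default 20).
#' @param trim_quality_floor 3' trimming stops at the first base (from the 3'
#'   end) with quality at or above this (default 13).
#' @param min_length_after_trim minimum mate length after trimming, in bases
#'   (default 40).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_n_fraction = 0.05, min_mean_quality = 20,
                          trim_quality_floor = 13, min_length_after_trim = 40) {
  stopifnot(max_n_fraction > 0, max_n_fraction <= 1, min_mean_quality > 0,
            trim_quality_floor > 0, min_length_after_trim > 0)
  structure(list(max_n_fraction = max_n_fraction,
                 min_mean_quality = min_mean_quality,
                 trim_quality_floor = trim_quality_floor,
                 min_length_after_trim = min_length_after_trim),
            class = "qc_thresholds")
}

#' N-fraction rule
#'
#' @param seq1,seq2 mate sequences (single strings).
#' @param t a [qc_thresholds()] object.
#' @return `TRUE` to keep the pair, `FALSE` to remove it (N fraction strictly
#'   greater than the threshold in either mate).
#' @export
n_fraction_rule <- function(seq1, seq2, t = qc_thresholds()) {
  if (nchar(seq1) == 0 || nchar(seq2) == 0) stopf("zero-length mate")
  frac <- function(s) sum(strsplit(s, "")[[1]] == "N") / nchar(s)
  !(frac(seq1) > t$max_n_fraction || frac(seq2) > t$max_n_fraction)
}

#' Mean-quality rule
#'
#' Computed on the untrimmed read; the pair is removed when either mate's
#' arithmetic mean quality is strictly below the threshold.
#'
#' @param qual1,qual2 integer Phred vectors of the two mates.
#' @param t a [qc_thresholds()] object.
#' @return `TRUE` to keep, `FALSE` to remove.
#' @export
mean_quality_rule <- function(qual1, qual2, t = qc_thresholds()) {
  !(mean(qual1) < t$min_mean_quality || mean(qual2) < t$min_mean_quality)
}

#' 3' quality trimming
#'
#' Removes the maximal 3'-terminal run of bases with quality below the floor;
#' scanning from the 3' end, the first base with quality at or above the
#' floor and everything 5' of it is retained. Sequence and qualities are
#' trimmed in lock-step; internal low-quality bases are untouched.
#'
#' @param seq sequence string.
#' @param qual integer Phred vector, same length as `seq`.
#' @param t a [qc_thresholds()] object.
#' @return list with trimmed `seq`, `qual` and `trimmed` (bases removed).
#' @export
trim_three_prime <- function(seq, qual, t = qc_thresholds()) {
  n <- length(qual)
  keep <- trim_keep_length(qual, t$trim_quality_floor)
  list(seq = substr(seq, 1L, keep), qual = qual[seq_len(keep)],
       trimmed = n - keep)
}

trim_keep_length <- function(qual, floor) {
  ok <- which(qual >= floor)
  if (length(ok)) ok[length(ok)] else 0L
}

#' Run the paired-end read-QC cascade on a FASTQ pair
#'
#' Applies, in order: the N-fraction rule, the mean-quality rule, 3' quality
#' trimming with the post-trim length floor, and duplicate removal (among
#' pairs with identical trimmed mate-1 and mate-2 sequences, the
#' first-encountered pair is kept). Each removed pair is attributed to the
#' first rule that fires. Retained (possibly trimmed) pairs are written to
#' the output files in input order.
#'
#' @param in1,in2 input FASTQ paths (mates in sync).
#' @param out1,out2 output FASTQ paths; `NULL` to skip writing.
#' @param t a [qc_thresholds()] object.
#' @return a `qc_report`: counts per rule, ids of removed pairs with the rule
#'   that removed them, total bases trimmed, and the conservation identity
#'   pairs_in = retained + sum(removed).
#' @export
run_read_qc <- function(in1, in2, out1 = NULL, out2 = NULL,
                        t = qc_thresholds()) {
  r1 <- read_fastq(in1)
  r2 <- read_fastq(in2)
  if (length(r1$id) != length(r2$id)) stopf("desynchronized mates: %d vs %d records",
                                            length(r1$id), length(r2$id))
  id1 <- sub("/[12]$| .*$", "", r1$id)
  id2 <- sub("/[12]$| .*$", "", r2$id)
  if (!all(id1 == id2)) stopf("desynchronized mates: id mismatch at record %d",
                              which(id1 != id2)[1])
  if (any(nchar(r1$seq) == 0 | nchar(r2$seq) == 0)) stopf("zero-length mate")
  n <- length(id1)
  rule <- rep("retained", n)

  nfrac <- function(seq) {
    vapply(seq, function(s) sum(strsplit(s, "")[[1]] == "N"), 1L,
           USE.NAMES = FALSE) / nchar(seq)
  }
  bad_n <- nfrac(r1$seq) > t$max_n_fraction | nfrac(r2$seq) > t$max_n_fraction
  rule[bad_n] <- "n_rich"

  m1 <- vapply(r1$qual, mean, 1); m2 <- vapply(r2$qual, mean, 1)
  bad_q <- m1 < t$min_mean_quality | m2 < t$min_mean_quality
  rule[rule == "retained" & bad_q] <- "low_mean_q"

  keep1 <- vapply(r1$qual, trim_keep_length, 1L, floor = t$trim_quality_floor)
  keep2 <- vapply(r2$qual, trim_keep_length, 1L, floor = t$trim_quality_floor)
  bad_len <- keep1 < t$min_length_after_trim | keep2 < t$min_length_after_trim
  rule[rule == "retained" & bad_len] <- "short_after_trim"

  alive <- rule == "retained"
  ts1 <- substr(r1$seq, 1L, keep1); ts2 <- substr(r2$seq, 1L, keep2)
  key <- paste(ts1, ts2, sep = "|")
  dup <- alive & duplicated(ifelse(alive, key, paste0("dead", seq_len(n))))
  rule[dup] <- "duplicate"

  kept <- which(rule == "retained")
  bases_trimmed <- sum(nchar(r1$seq[kept]) - keep1[kept]) +
    sum(nchar(r2$seq[kept]) - keep2[kept])
  if (!is.null(out1)) {
    write_fastq(r1$id[kept], ts1[kept],
                lapply(kept, function(i) r1$qual[[i]][seq_len(keep1[i])]), out1)
    write_fastq(r2$id[kept], ts2[kept],
                lapply(kept, function(i) r2$qual[[i]][seq_len(keep2[i])]), out2)
  }
  removed <- data.frame(pair_id = id1[rule != "retained"],
                        rule = rule[rule != "retained"],
                        stringsAsFactors = FALSE)
  structure(list(
    pairs_in = n,
    removed_counts = c(n_rich = sum(rule == "n_rich"),
                       low_mean_q = sum(rule == "low_mean_q"),
                       short_after_trim = sum(rule == "short_after_trim"),
                       duplicate = sum(rule == "duplicate")),
    pairs_retained = length(kept),
    bases_trimmed = bases_trimmed,
    removed = removed,
    thresholds = t), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d pairs in, %d retained (%d bases trimmed)\n",
              x$pairs_in, x$pairs_retained, x$bases_trimmed))
  print(x$removed_counts)
  invisible(x)
}

#' Write a QC report to TSV
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report_tsv <- function(report, path) {
  df <- data.frame(
    metric = c("pairs_in", names(report$removed_counts), "pairs_retained",
               "bases_trimmed"),
    value = c(report$pairs_in, unname(report$removed_counts),
              report$pairs_retained, report$bases_trimmed))
  write_tsv(df, path)
}
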