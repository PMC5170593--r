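#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rpois runif setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

# random DNA string of length n (depends on the current RNG state)
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# substring of a chromosome, 1-based closed
subseq_chr <- function(ref, chrom, start, end) {
  as.character(Biostrings::subseq(ref[[chrom]], start = start, end = end))
}

#' Write a reference genome to FASTA
#'
#' @param ref a named [Biostrings::DNAStringSet] of chromosome sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(ref, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file path.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_reference_fasta <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
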