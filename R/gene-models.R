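#' Gene models: one representative transcript per gene
#'
#' A `gene_models` object is a list of gene records. Each record holds the
#' gene id, chromosome, strand, the ordered exon intervals (1-based, closed),
#' the genomic CDS span, and derived interval sets: per-exon CDS pieces and
#' 5'/3' UTR pieces in transcript orientation. All coordinates are genomic;
#' "5' UTR" means 5' of the CDS along the transcript, so on the minus strand
#' it lies at higher genomic coordinates.
#'
#' @name gene_models
NULL

new_gene_models <- function(genes) {
  structure(genes, class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d chromosome(s)\n",
              length(x), length(unique(vapply(x, `[[`, "", "chrom")))))
  invisible(x)
}

#' @export
`[.gene_models` <- function(x, i) new_gene_models(unclass(x)[i])

# Derive per-exon CDS and UTR interval matrices from exons + genomic CDS span.
# exons: matrix with columns start,end sorted by start. cds_span: c(start,end).
derive_gene_regions <- function(gene_id, chrom, strand, exons, cds_span) {
  stopifnot(ncol(exons) == 2, all(exons[, 1] <= exons[, 2]))
  exons <- matrix(as.integer(exons), ncol = 2)
  cds_span <- as.integer(cds_span)
  if (is.unsorted(exons[, 1])) stopf("exons of %s not sorted", gene_id)
  cds <- utr <- NULL
  for (i in seq_len(nrow(exons))) {
    s <- exons[i, 1]; e <- exons[i, 2]
    cs <- max(s, cds_span[1]); ce <- min(e, cds_span[2])
    if (cs <= ce) cds <- rbind(cds, c(cs, ce))
    if (s < cds_span[1]) utr <- rbind(utr, c(s, min(e, cds_span[1] - 1), 5L))
    if (e > cds_span[2]) utr <- rbind(utr, c(max(s, cds_span[2] + 1), e, 3L))
  }
  if (is.null(cds)) stopf("gene %s: CDS span outside exons", gene_id)
  # the "5" tag above is genomic-left of the CDS; swap on minus strand
  side <- if (strand == "+") utr[, 3] else ifelse(utr[, 3] == 5L, 3L, 5L)
  utr5 <- utr[side == 5L, 1:2, drop = FALSE]
  utr3 <- utr[side == 3L, 1:2, drop = FALSE]
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       exons = exons, cds_span = cds_span, cds = cds,
       utr5 = utr5, utr3 = utr3,
       tx_start = exons[1, 1], tx_end = exons[nrow(exons), 2])
}

validate_gene_models <- function(genes, ref = NULL) {
  for (g in genes) {
    if (nrow(g$exons) >= 2) {
      gaps <- g$exons[-1, 1] - g$exons[-nrow(g$exons), 2] - 1L
      if (any(gaps < 20L))
        stopf("gene %s: intron shorter than 20 bp", g$gene_id)
    }
    cds_len <- sum(g$cds[, 2] - g$cds[, 1] + 1L)
    if (cds_len %% 3L != 0L)
      stopf("gene %s: spliced CDS length %d not a multiple of 3",
            g$gene_id, cds_len)
    if (!is.null(ref)) {
      cds_seq <- spliced_cds(ref, g)
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq)))
      if (substr(aa, 1, 1) != "M")
        stopf("gene %s: CDS does not start with ATG", g$gene_id)
      body <- substr(aa, 1, nchar(aa) - 1L)
      if (grepl("\\*", body))
        stopf("gene %s: internal stop codon", g$gene_id)
    }
  }
  invisible(TRUE)
}

# Spliced CDS sequence in transcript orientation (reverse-complemented for -).
spliced_cds <- function(ref, gene) {
  pieces <- apply(gene$cds, 1, function(iv)
    subseq_chr(ref, gene$chrom, iv[1], iv[2]))
  s <- paste(pieces, collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

# Genomic positions of the spliced CDS, in transcript order.
cds_positions <- function(gene) {
  pos <- unlist(lapply(seq_len(nrow(gene$cds)), function(i)
    seq.int(gene$cds[i, 1], gene$cds[i, 2])))
  if (gene$strand == "-") rev(pos) else pos
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, exon, CDS, five_prime_UTR and three_prime_UTR features
#' (1-based closed intervals) through rtracklayer.
#'
#' @param genes a `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    tx_id <- paste0(g$gene_id, ".1")
    add <- function(type, iv, id, parent, phase = NA_integer_) {
      data.frame(chrom = g$chrom, start = iv[, 1], end = iv[, 2],
                 strand = g$strand, type = type, ID = id, Parent = parent,
                 phase = phase, stringsAsFactors = FALSE)
    }
    # GFF3 phase: bases to skip at the start (transcript orientation) of each
    # CDS piece to hit the next codon boundary
    cds_tx <- if (g$strand == "+") g$cds else g$cds[rev(seq_len(nrow(g$cds))), , drop = FALSE]
    lens <- cds_tx[, 2] - cds_tx[, 1] + 1L
    phase_tx <- (3L - c(0L, cumsum(lens)[-length(lens)]) %% 3L) %% 3L
    cds_phase <- if (g$strand == "+") phase_tx else rev(phase_tx)
    rows <- c(rows, list(
      add("gene", matrix(c(g$tx_start, g$tx_end), 1), g$gene_id, NA),
      add("mRNA", matrix(c(g$tx_start, g$tx_end), 1), tx_id, g$gene_id),
      add("exon", g$exons, paste0(tx_id, ".exon", seq_len(nrow(g$exons))), tx_id),
      add("CDS", g$cds, paste0(tx_id, ".cds", seq_len(nrow(g$cds))), tx_id,
          phase = cds_phase)))
    if (nrow(g$utr5) > 0)
      rows <- c(rows, list(add("five_prime_UTR", g$utr5,
                               paste0(tx_id, ".utr5.", seq_len(nrow(g$utr5))), tx_id)))
    if (nrow(g$utr3) > 0)
      rows <- c(rows, list(add("three_prime_UTR", g$utr3,
                               paste0(tx_id, ".utr3.", seq_len(nrow(g$utr3))), tx_id)))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA_character_, df$Parent)
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects one mRNA per gene with exon and CDS children, the layout
#' [write_gene_models_gff3()] produces. UTRs are re-derived from exons and the
#' CDS span, so annotation does not depend on UTR features being present.
#'
#' @param path GFF3 file path.
#' @return a `gene_models` object.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, "")
  mrna <- df[df$type == "mRNA", ]
  genes <- vector("list", nrow(mrna))
  for (i in seq_len(nrow(mrna))) {
    tx <- mrna[i, ]
    kids <- df[!is.na(df$Parent) & df$Parent == tx$ID, ]
    exons <- kids[kids$type == "exon", c("start", "end")]
    exons <- as.matrix(exons[order(exons$start), ])
    cds <- kids[kids$type == "CDS", c("start", "end")]
    cds_span <- c(min(cds$start), max(cds$end))
    genes[[i]] <- derive_gene_regions(
      gene_id = tx$Parent, chrom = as.character(tx$seqnames),
      strand = as.character(tx$strand), exons = exons, cds_span = cds_span)
  }
  genes <- genes[order(vapply(genes, `[[`, "", "chrom"),
                       vapply(genes, function(g) g$tx_start, 1))]
  new_gene_models(genes)
}
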