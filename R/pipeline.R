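#' Run the variome pipeline end to end
#'
#' Orchestrates the stages behind one configuration: simulate (reference +
#' gene models + population + reads + allele depths) -> read QC -> variant
#' filtering -> effect annotation -> population summaries -> KASP site
#' selection. Stages communicate only via files in standard formats (FASTA,
#' GFF3, FASTQ, TSV, VCF) under the output directory, so any stage can be
#' re-run independently or replaced by external tools on real data.
#' Re-running with an identical configuration and seed reproduces
#' byte-identical outputs.
#'
#' @param config a configuration list, or the path to a YAML file with the
#'   same structure. Recognized keys (all optional unless noted):
#'   \describe{
#'     \item{outdir}{output directory (required).}
#'     \item{seed}{integer master seed (required).}
#'     \item{genome}{`n_chromosomes`, `chrom_length`, `n_genes`.}
#'     \item{population}{`n_groups`, `accessions_per_group`, `n_variants`,
#'       `genebank_per_group`, `p_snp`, `maf_spectrum`.}
#'     \item{reads}{`emit` (`"none"`, `"first"` or `"all"` accessions),
#'       `depth`, `read_length`, `error_rate`, `qc_failure_rates`.}
#'     \item{depths}{`depth`, `error_rate`, `fp_site_rate`, `depth_model`.}
#'     \item{qc}{arguments for [qc_thresholds()].}
#'     \item{filter}{arguments for [filter_thresholds()] plus
#'       `include_indels`.}
#'     \item{window}{window width for [windowed_tracks()] (default 10000).}
#'     \item{kasp_flank}{KASP flank length (default 50).}
#'   }
#' @param stages character vector of stages to run, in order.
#' @return a `run_report`: per-stage record counts, parameter echo and
#'   wall time.
#' @export
run_variome_pipeline <- function(config,
                                 stages = c("simulate", "readqc", "callfilter",
                                            "annotate", "summarize", "kasp")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outdir)) stopf("config$outdir is required")
  if (is.null(config$seed)) stopf("config$seed is required")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  tset <- do.call(qc_thresholds, config$qc %||% list())
  fcfg <- config$filter %||% list()
  include_indels <- isTRUE(fcfg$include_indels)
  fcfg$include_indels <- NULL
  fset <- do.call(filter_thresholds, fcfg)

  report <- list()
  stamp <- function(stage, t0, ...) {
    report[[stage]] <<- c(list(...),
                          list(elapsed_s = round(as.numeric(Sys.time()) - t0, 3)))
  }
  path <- function(...) file.path(outdir, ...)

  if ("simulate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    gcfg <- config$genome %||% list()
    pcfg <- config$population %||% list()
    sim <- generate_reference(gcfg$n_chromosomes %||% 1L,
                              gcfg$chrom_length %||% 50000L,
                              gcfg$n_genes %||% 10L, seed = seed)
    pop <- generate_population(sim$ref, sim$genes,
                               n_groups = pcfg$n_groups %||% 3L,
                               accessions_per_group = pcfg$accessions_per_group %||% 5L,
                               n_variants = pcfg$n_variants %||% 500L,
                               maf_spectrum = pcfg$maf_spectrum,
                               seed = seed + 1L,
                               p_snp = pcfg$p_snp %||% 0.881,
                               genebank_per_group = pcfg$genebank_per_group %||% 0L)
    write_reference_fasta(sim$ref, path("reference.fa"))
    write_gene_models_gff3(sim$genes, path("genes.gff3"))
    truth <- pop$truth

    rcfg <- config$reads %||% list()
    emit <- rcfg$emit %||% "first"
    if (emit != "none") {
      dir.create(path("reads"), showWarnings = FALSE)
      accs <- if (emit == "all") pop$accessions$accession
      else pop$accessions$accession[1]
      for (k in seq_along(accs)) {
        res <- emit_reads(accs[k], sim$ref, truth,
                          out1 = path("reads", paste0(accs[k], "_1.fastq.gz")),
                          out2 = path("reads", paste0(accs[k], "_2.fastq.gz")),
                          depth = rcfg$depth %||% 10,
                          read_length = rcfg$read_length %||% 100L,
                          error_rate = rcfg$error_rate %||% 0.01,
                          qc_failure_rates = unlist(rcfg$qc_failure_rates %||%
                            c(n_rich = 0.01, low_mean_q = 0.01,
                              short_after_trim = 0.01, duplicate = 0.01)),
                          seed = seed + 100L + k)
        truth$qc_failures <- rbind(truth$qc_failures, res$qc_failures)
      }
    }
    dcfg <- config$depths %||% list()
    depths <- emit_population_depths(sim$ref, truth, seed = seed + 1000L,
                                     depth = dcfg$depth %||% 10,
                                     error_rate = dcfg$error_rate %||% 0.01,
                                     fp_site_rate = dcfg$fp_site_rate %||% 0.001,
                                     depth_model = dcfg$depth_model %||% "poisson")
    write_tsv(depths, path("depths.tsv"))
    write_manifest_tsv(truth, outdir)
    stamp("simulate", t0, n_genes = length(sim$genes),
          n_variants_planted = nrow(truth$variants),
          n_accessions = nrow(pop$accessions),
          n_depth_rows = nrow(depths))
  }

  if ("readqc" %in% stages) {
    t0 <- as.numeric(Sys.time())
    fq1 <- sort(list.files(path("reads"), "_1\\.fastq(\\.gz)?$", full.names = TRUE))
    dir.create(path("qc"), showWarnings = FALSE)
    tot_in <- tot_kept <- 0L
    for (f1 in fq1) {
      f2 <- sub("_1\\.fastq", "_2.fastq", f1)
      b1 <- basename(f1); b2 <- basename(f2)
      qcrep <- run_read_qc(f1, f2, path("qc", b1), path("qc", b2), tset)
      write_qc_report_tsv(qcrep, path("qc", sub("_1\\.fastq.*$", "_qc_report.tsv", b1)))
      tot_in <- tot_in + qcrep$pairs_in; tot_kept <- tot_kept + qcrep$pairs_retained
    }
    stamp("readqc", t0, n_fastq_pairs = length(fq1), pairs_in = tot_in,
          pairs_retained = tot_kept)
  }

  if ("callfilter" %in% stages) {
    t0 <- as.numeric(Sys.time())
    depths <- read_tsv(path("depths.tsv"))
    meta <- read_tsv(path("accessions.tsv"))
    m <- filter_variants(depths, meta, fset, include_indels = include_indels)
    write_genotype_matrix_tsv(m, path("genotype_matrix.tsv"))
    write_population_vcf(m, path("population.vcf"),
                         ref = read_reference_fasta(path("reference.fa")))
    stamp("callfilter", t0, depth_rows_in = nrow(depths),
          variants_retained = nrow(m$variants))
  }

  if ("annotate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    m <- read_genotype_matrix_tsv(path("genotype_matrix.tsv"),
                                  read_tsv(path("accessions.tsv")))
    genes <- read_gene_models_gff3(path("genes.gff3"))
    ref <- read_reference_fasta(path("reference.fa"))
    ann <- annotate_variants(m$variants, genes, ref)
    write_annotation_tsv(ann, path("annotations.tsv"))
    stamp("annotate", t0, variants_in = nrow(m$variants),
          variants_annotated = nrow(ann$variants))
  }

  if ("summarize" %in% stages) {
    t0 <- as.numeric(Sys.time())
    meta <- read_tsv(path("accessions.tsv"))
    m <- read_genotype_matrix_tsv(path("genotype_matrix.tsv"), meta)
    ann <- read_annotation_tsv(path("annotations.tsv"))
    obs <- read_tsv(path("depths.tsv"))
    ref <- read_reference_fasta(path("reference.fa"))
    grp <- count_polymorphic_by_group(m, ann, meta)
    win <- windowed_tracks(m, ann, obs = obs,
                           window = config$window %||% 10000L,
                           chrom_lengths = setNames(Biostrings::width(ref),
                                                    names(ref)),
                           t = fset)
    hist <- indel_length_distribution(ann)
    write_tsv(grp, path("group_diversity.tsv"))
    write_tsv(win, path("window_tracks.tsv"))
    write_tsv(hist, path("indel_lengths.tsv"))
    stamp("summarize", t0, n_groups = nrow(grp), n_windows = nrow(win))
  }

  if ("kasp" %in% stages) {
    t0 <- as.numeric(Sys.time())
    meta <- read_tsv(path("accessions.tsv"))
    m <- read_genotype_matrix_tsv(path("genotype_matrix.tsv"), meta)
    ref <- read_reference_fasta(path("reference.fa"))
    snps <- m$variants[m$variants$class == "SNP", ]
    kc <- select_kasp_candidates(snps, ref, m$variants,
                                 flank = config$kasp_flank %||% 50L)
    write_tsv(kc, path("kasp_candidates.tsv"))
    stamp("kasp", t0, snps_in = nrow(snps),
          accepted = sum(kc$status == "accepted"))
  }

  rep <- structure(list(stages = report, config = config,
                        version = as.character(utils::packageVersion("variome"))),
                   class = "run_report")
  write_run_report_tsv(rep, path("run_report.tsv"))
  rep
}

#' @export
print.run_report <- function(x, ...) {
  cat("variome run_report (version", x$version, ")\n")
  for (s in names(x$stages)) {
    vals <- x$stages[[s]]
    cat(sprintf("  %-10s %s\n", s,
                paste(names(vals), unlist(vals), sep = "=", collapse = " ")))
  }
  invisible(x)
}

# wall time stays in the in-memory report only, so that two runs with the
# same config and seed leave byte-identical files behind
write_run_report_tsv <- function(rep, path) {
  rows <- do.call(rbind, lapply(names(rep$stages), function(s) {
    v <- rep$stages[[s]]
    v$elapsed_s <- NULL
    data.frame(stage = s, metric = names(v), value = unlist(lapply(v, as.character)),
               stringsAsFactors = FALSE)
  }))
  write_tsv(rows, path)
}

#' Read a genotype matrix written by [write_genotype_matrix_tsv()]
#'
#' @param path TSV path.
#' @param accessions accession metadata data.frame fixing column order.
#' @return a `genotype_matrix`.
#' @export
read_genotype_matrix_tsv <- function(path, accessions) {
  df <- read_tsv(path)
  fixed <- c("chrom", "pos", "ref", "alt", "class")
  geno <- as.matrix(df[, setdiff(names(df), fixed), drop = FALSE])
  colnames(geno) <- setdiff(names(df), fixed)
  geno <- geno[, accessions$accession, drop = FALSE]
  new_genotype_matrix(df[, fixed], geno, accessions)
}

#' Read an annotation table written by [write_annotation_tsv()]
#'
#' @param path per-variant TSV path.
#' @return an `annotation_table`.
#' @export
read_annotation_tsv <- function(path) {
  v <- read_tsv(path)
  structure(list(variants = v, counts = category_counts(v)),
            class = "annotation_table")
}
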