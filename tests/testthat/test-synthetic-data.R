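test_that("generated gene models satisfy all structural invariants", {
  study <- tiny_study()
  expect_gte(length(study$genes), 8)
  for (g in study$genes) {
    expect_gte(nrow(g$exons), 2)
    gaps <- g$exons[-1, 1] - g$exons[-nrow(g$exons), 2] - 1L
    expect_true(all(gaps >= 20))
    cds_len <- sum(g$cds[, 2] - g$cds[, 1] + 1L)
    expect_identical(cds_len %% 3L, 0L)
    expect_gt(nrow(g$utr5), 0)
    expect_gt(nrow(g$utr3), 0)
    # CDS endpoints inside exons
    expect_true(any(g$cds_span[1] >= g$exons[, 1] & g$cds_span[1] <= g$exons[, 2]))
    expect_true(any(g$cds_span[2] >= g$exons[, 1] & g$cds_span[2] <= g$exons[, 2]))
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(variome:::spliced_cds(study$ref, g))))
    expect_identical(substr(aa, 1, 1), "M")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  expect_true(all(vapply(study$ref, function(s)
    !grepl("[^ACGT]", as.character(s)), TRUE)))
})

test_that("reference generation is byte-deterministic for a fixed seed", {
  d <- withr::local_tempdir()
  for (run in 1:2) {
    sim <- generate_reference(1, 12000, 3, seed = 5)
    write_reference_fasta(sim$ref, file.path(d, sprintf("ref%d.fa", run)))
    write_gene_models_gff3(sim$genes, file.path(d, sprintf("genes%d.gff3", run)))
  }
  expect_identical(readLines(file.path(d, "ref1.fa")),
                   readLines(file.path(d, "ref2.fa")))
  expect_identical(readLines(file.path(d, "genes1.gff3")),
                   readLines(file.path(d, "genes2.gff3")))
})

test_that("infeasible gene packing raises an explicit error", {
  expect_error(generate_reference(1, 10000, 500, seed = 1),
               "infeasible packing")
})

test_that("planted variant categories are faithful to the annotator", {
  study <- tiny_study()
  ann <- annotate_variants(study$truth$variants, study$genes, study$ref)
  expect_identical(ann$variants$category, study$truth$variants$category)
})

test_that("a pure non-synonymous request plants only non-synonymous SNPs", {
  study <- tiny_study()
  mix <- list(SNP = c(nonSyn = 1, Syn = 0, splice = 0, intron = 0, UTR5 = 0,
                      UTR3 = 0, intergenic = 0),
              InDel = c(frameshift = 1, nonframeshift = 0, splice = 0,
                        intron = 0, UTR5 = 0, UTR3 = 0, intergenic = 0))
  pop <- generate_population(study$ref, study$genes, 2, 3, 60,
                             category_mix = mix, seed = 7, p_snp = 1)
  expect_true(all(pop$truth$variants$category == "nonSyn"))
  # independent check: full-protein retranslation for every planted SNP
  for (i in seq_len(nrow(pop$truth$variants))) {
    v <- pop$truth$variants[i, ]
    g <- Filter(function(g) g$gene_id == v$gene_id, unclass(study$genes))[[1]]
    expect_identical(
      oracle_snp_effect(as.character(study$ref[[v$chrom]]), g, v$pos, v$ref, v$alt),
      "nonSyn")
  }
})

test_that("population generation validates its inputs", {
  study <- tiny_study()
  expect_error(generate_population(study$ref, study$genes, 2, 0, 10, seed = 1),
               "empty population")
})

test_that("a fixed allele-frequency spectrum propagates to population MAF", {
  study <- tiny_study()
  pop <- generate_population(study$ref, study$genes, n_groups = 2,
                             accessions_per_group = 40, n_variants = 80,
                             maf_spectrum = list(kind = "fixed", value = 0.5),
                             seed = 9)
  # 80 accessions per variant at p = 0.5: realized MAF stays near 0.5 up to
  # binomial sampling noise (sd of the allele frequency ~ 0.056)
  expect_gt(mean(pop$truth$variants$maf), 0.44)
  expect_true(all(pop$truth$variants$maf >= 0.3))
})

test_that("homozygous lines never receive heterozygous true genotypes", {
  study <- tiny_study()
  hom <- study$accessions$accession[study$accessions$zygosity_class == "homozygous_line"]
  expect_false(any(study$truth$genotypes[, hom] == "het"))
  pop <- generate_population(study$ref, study$genes, 2, 3, 50, seed = 33,
                             genebank_per_group = 2)
  meta <- pop$accessions
  hom <- meta$accession[meta$zygosity_class == "homozygous_line"]
  expect_false(any(pop$truth$genotypes[, hom] == "het"))
  gb <- meta$accession[meta$zygosity_class == "genebank"]
  expect_gt(sum(pop$truth$genotypes[, gb] == "het"), 0)
})

test_that("read emission has the requested coverage and clean reads pass QC", {
  study <- tiny_study()
  d <- withr::local_tempdir()
  acc <- study$accessions$accession[1]
  res <- emit_reads(acc, study$ref, study$truth,
                    file.path(d, "c1.fq"), file.path(d, "c2.fq"),
                    depth = 4, read_length = 100, error_rate = 0,
                    qc_failure_rates = c(n_rich = 0, low_mean_q = 0,
                                         short_after_trim = 0, duplicate = 0),
                    seed = 21)
  glen <- sum(Biostrings::width(study$ref))
  expect_lt(abs(res$n_pairs - 4 * glen / 200), 5)
  expect_identical(nrow(res$qc_failures), 0L)
  qcrep <- run_read_qc(file.path(d, "c1.fq"), file.path(d, "c2.fq"))
  expect_identical(qcrep$pairs_retained, as.integer(res$n_pairs))
})

test_that("planted duplicate counts are recorded in the manifest", {
  study <- tiny_study()
  d <- withr::local_tempdir()
  res <- emit_reads(study$accessions$accession[2], study$ref, study$truth,
                    file.path(d, "d1.fq"), file.path(d, "d2.fq"),
                    depth = 4, read_length = 100, error_rate = 0,
                    qc_failure_rates = c(duplicate = 0.1), seed = 22)
  n_dup <- sum(res$qc_failures$kind == "duplicate")
  expect_gt(n_dup, 0.05 * res$n_pairs)
  expect_lt(n_dup, 0.15 * res$n_pairs)
  expect_true(all(res$qc_failures$duplicate_of[res$qc_failures$kind == "duplicate"]
                  %in% sprintf("%s_p%06d", study$accessions$accession[2],
                               seq_len(res$n_pairs))))
})

test_that("read emission rejects impossible parameters", {
  study <- tiny_study()
  expect_error(emit_reads("x", study$ref, study$truth, "a", "b",
                          read_length = 10^6, seed = 1), "read_length")
  expect_error(emit_reads("x", study$ref, study$truth, "a", "b",
                          error_rate = 0.5, seed = 1), "error_rate")
})

test_that("error-free depth emission reflects true genotypes exactly", {
  study <- tiny_study()
  acc <- study$accessions$accession[1]
  obs <- emit_allele_depths(acc, study$ref, study$truth, depth = 10,
                            error_rate = 0, fp_site_rate = 0, seed = 31)
  key <- paste(obs$chrom, obs$pos)
  tkey <- paste(study$truth$variants$chrom, study$truth$variants$pos)
  g <- study$truth$genotypes[match(key, tkey), acc]
  expect_true(all(obs$D_R[g == "alt"] == 0))
  expect_true(all(obs$D_A[g == "ref"] == 0))
})

test_that("error-only sites follow the binomial tail at fixed depth", {
  study <- tiny_study()
  set.seed(41)
  # emulate 10,000 error-only sites directly through the emitter by running
  # it on a genotype-free accession view with a high fp rate
  obs <- do.call(rbind, lapply(1:8, function(k)
    emit_allele_depths(study$accessions$accession[1], study$ref, study$truth,
                       depth = 10, error_rate = 0.01, fp_site_rate = 0.03,
                       seed = 500 + k, depth_model = "fixed")))
  tkey <- paste(study$truth$variants$chrom, study$truth$variants$pos)
  fp <- obs[!paste(obs$chrom, obs$pos) %in% tkey, ]
  # emitted fp sites are conditioned on D_A >= 1
  p_emit <- 1 - stats::dbinom(0, 10, 0.01)
  p_ge3 <- stats::pbinom(2, 10, 0.01, lower.tail = FALSE)
  # ~12,000 candidate error sites, of which a fraction 1-(1-e)^10 ~ 0.096
  # shows at least one alternative read and is emitted
  expect_gt(nrow(fp), 800)
  expect_lt(abs(mean(fp$D_A >= 3) - p_ge3 / p_emit), 3 * sqrt(p_ge3 / p_emit / nrow(fp)) + 0.002)
})
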