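mini_matrix <- function(geno_rows, classes = rep("SNP", nrow(geno_rows)),
                        categories = rep("intergenic", nrow(geno_rows)),
                        morphotypes = rep("g1", ncol(geno_rows))) {
  meta <- data.frame(accession = sprintf("a%02d", seq_len(ncol(geno_rows))),
                     morphotype = morphotypes,
                     zygosity_class = "homozygous_line", stringsAsFactors = FALSE)
  colnames(geno_rows) <- meta$accession
  v <- data.frame(chrom = "chr01", pos = seq_len(nrow(geno_rows)) * 10L,
                  ref = "A", alt = "C", class = classes, stringsAsFactors = FALSE)
  v$ref[classes == "InDel"] <- "AT"
  m <- variome:::new_genotype_matrix(v, geno_rows, meta)
  ann <- structure(list(
    variants = cbind(v[, c("chrom", "pos", "ref", "alt", "class")],
                     data.frame(gene_id = NA, category = categories,
                                functional = ifelse(classes == "SNP",
                                                    categories %in% c("nonSyn", "splice"),
                                                    categories %in% c("frameshift", "nonframeshift", "splice")),
                                stringsAsFactors = FALSE))),
    class = "annotation_table")
  ann$counts <- variome:::category_counts(ann$variants)
  list(m = m, ann = ann, meta = meta)
}

test_that("group polymorphism requires two distinct non-missing genotypes", {
  x <- mini_matrix(rbind(rep("alt", 5),                    # monomorphic
                         c("ref", "alt", "missing", "ref", "ref"),
                         c("ref", "missing", "missing", "ref", "ref")))
  tab <- count_polymorphic_by_group(x$m, x$ann, x$meta)
  expect_identical(tab$snp_polymorphic, 1L)
  expect_identical(tab$snp_functional_polymorphic, 0L)
})

test_that("a single-accession group reports zero polymorphic loci", {
  x <- mini_matrix(cbind(c("ref", "alt"), c("alt", "ref")),
                   morphotypes = c("solo", "other"))
  tab <- count_polymorphic_by_group(x$m, x$ann, x$meta)
  expect_identical(tab$snp_polymorphic, c(0L, 0L))
  expect_error(count_polymorphic_by_group(x$m, x$ann, x$meta[0, ]),
               "zero accessions")
})

test_that("group counts equal a naive recount from the truth manifest", {
  study <- tiny_study()
  m <- truth_matrix(study)
  ann <- annotate_variants(m$variants, study$genes, study$ref)
  tab <- count_polymorphic_by_group(m, ann)

  fun_snp <- study$truth$variants$category %in% c("nonSyn", "splice") &
    study$truth$variants$class == "SNP"
  fun_ind <- study$truth$variants$category %in%
    c("frameshift", "nonframeshift", "splice") &
    study$truth$variants$class == "InDel"
  for (k in seq_len(nrow(tab))) {
    accs <- study$accessions$accession[study$accessions$morphotype == tab$morphotype[k]]
    poly <- apply(study$truth$genotypes[, accs, drop = FALSE], 1, function(g)
      length(unique(g[g != "missing"])) >= 2)
    expect_identical(tab$snp_polymorphic[k],
                     sum(poly & study$truth$variants$class == "SNP"))
    expect_identical(tab$snp_functional_polymorphic[k], sum(poly & fun_snp))
    expect_identical(tab$indel_polymorphic[k],
                     sum(poly & study$truth$variants$class == "InDel"))
    expect_identical(tab$indel_functional_polymorphic[k], sum(poly & fun_ind))
  }
  # monotonicity: adding an accession never decreases a group's count
  grown <- study$accessions
  grown$morphotype[grown$morphotype == grown$morphotype[nrow(grown)]] <-
    tab$morphotype[1]
  tab2 <- count_polymorphic_by_group(m, ann, grown)
  expect_gte(tab2$snp_polymorphic[tab2$morphotype == tab$morphotype[1]],
             tab$snp_polymorphic[1])
})

test_that("window tracks conserve chromosome totals", {
  study <- tiny_study()
  m <- truth_matrix(study)
  ann <- annotate_variants(m$variants, study$genes, study$ref)
  lens <- setNames(Biostrings::width(study$ref), names(study$ref))
  win <- windowed_tracks(m, ann, window = 4000L, chrom_lengths = lens)
  for (chrom in names(lens)) {
    expect_identical(sum(win$n_snp[win$chrom == chrom]),
                     sum(m$variants$class == "SNP" & m$variants$chrom == chrom))
    expect_identical(sum(win$n_indel[win$chrom == chrom]),
                     sum(m$variants$class == "InDel" & m$variants$chrom == chrom))
  }
  expect_identical(sum(win$n_functional), sum(ann$variants$functional))
  expect_true(all(win$end - win$start <= 4000))
})

test_that("windows without variants are zero and het is zero without het calls", {
  x <- mini_matrix(rbind(c("ref", "alt", "ref", "ref", "ref")))
  win <- windowed_tracks(x$m, x$ann, window = 100L,
                         chrom_lengths = c(chr01 = 1000L))
  expect_identical(nrow(win), 10L)
  expect_identical(win$n_snp, c(1L, rep(0L, 9L)))

  study <- tiny_study()
  obs <- emit_population_depths(study$ref, study$truth, seed = 71,
                                depth = 10, error_rate = 0, fp_site_rate = 0)
  m <- truth_matrix(study)
  ann <- annotate_variants(m$variants, study$genes, study$ref)
  win2 <- windowed_tracks(m, ann, obs = obs, window = 5000L,
                          chrom_lengths = setNames(Biostrings::width(study$ref),
                                                   names(study$ref)))
  expect_true(all(win2$heterozygosity == 0))  # homozygous lines, no errors
})

test_that("InDel length histograms recount planted lengths exactly", {
  study <- tiny_study()
  m <- truth_matrix(study)
  ann <- annotate_variants(m$variants, study$genes, study$ref)
  h <- indel_length_distribution(ann)
  planted <- study$truth$variants$length[study$truth$variants$class == "InDel"]
  expect_identical(sum(h$n_all), length(planted))
  for (l in h$length)
    expect_identical(h$n_all[h$length == l], sum(planted == l))
  expect_false(any(h$length == 0))
  cds_n <- sum(ann$counts$InDel[c("frameshift", "nonframeshift")])
  expect_identical(sum(h$n_cds), cds_n)
})

test_that("a 3n-heavy coding mix concentrates CDS histogram mass on multiples of 3", {
  study <- tiny_study()
  mix <- list(SNP = c(nonSyn = 1, Syn = 0, splice = 0, intron = 0, UTR5 = 0,
                      UTR3 = 0, intergenic = 0),
              InDel = c(frameshift = 0.1, nonframeshift = 0.5, splice = 0,
                        intron = 0.1, UTR5 = 0.1, UTR3 = 0.1, intergenic = 0.1))
  pop <- generate_population(study$ref, study$genes, 2, 3, 200,
                             category_mix = mix, seed = 91, p_snp = 0)
  m <- variome:::new_genotype_matrix(
    pop$truth$variants[, c("chrom", "pos", "ref", "alt", "class")],
    pop$truth$genotypes, pop$accessions)
  ann <- annotate_variants(m$variants, study$genes, study$ref)
  h <- indel_length_distribution(ann)
  mult3 <- h$length %% 3 == 0
  prop_cds <- sum(h$n_cds[mult3]) / sum(h$n_cds)
  prop_all <- sum(h$n_all[mult3]) / sum(h$n_all)
  expect_gt(prop_cds, prop_all)
})
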