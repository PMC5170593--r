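mk_obs <- function(D_R, D_A, chrom = "chr01", pos = seq_along(D_R),
                   accession = "acc") {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C",
             accession = accession, D_R = D_R, D_A = D_A,
             stringsAsFactors = FALSE)
}

test_that("candidacy requires strictly more than 10% alternative reads", {
  expect_false(call_candidates(9, 1))    # exactly 10%
  expect_true(call_candidates(8, 2))
  expect_true(call_candidates(0, 5))
  expect_error(call_candidates(0, 0), "zero total depth")
})

test_that("confident alleles need at least 3 supporting reads", {
  expect_identical(confident_alleles(0, 3), data.frame(ref = FALSE, alt = TRUE))
  expect_identical(confident_alleles(2, 2), data.frame(ref = FALSE, alt = FALSE))
  expect_identical(confident_alleles(5, 5), data.frame(ref = TRUE, alt = TRUE))
})

test_that("zygosity uses the open 0.2/0.8 interval with boundaries homozygous", {
  expect_identical(classify_zygosity(5, 5), "het")
  expect_identical(classify_zygosity(1, 9), "hom_alt")
  expect_identical(classify_zygosity(2, 8), "hom_alt")   # r = 0.2 boundary
  expect_identical(classify_zygosity(8, 2), "hom_ref")   # r = 0.8 boundary
  expect_identical(classify_zygosity(9, 1), "hom_ref")
})

test_that("zygosity heterozygosity is symmetric in D_R and D_A", {
  set.seed(3)
  a <- sample(0:20, 200, TRUE); b <- sample(0:20, 200, TRUE)
  keep <- a + b > 0
  a <- a[keep]; b <- b[keep]
  expect_identical(classify_zygosity(a, b) == "het",
                   classify_zygosity(b, a) == "het")
})

test_that("per-accession filtering drops het sites for homozygous lines only", {
  obs <- mk_obs(c(5, 5, 0), c(5, 5, 10))
  hom <- filter_accession_variants(obs[c(1, 3), ], "homozygous_line")
  expect_identical(hom$genotype, c("missing", "alt"))
  gb <- filter_accession_variants(obs[2, ], "genebank")
  expect_identical(gb$genotype, "het")
})

test_that("population merge unions sites and marks absent calls missing", {
  meta <- data.frame(accession = c("a1", "a2", "a3"),
                     morphotype = "g1", zygosity_class = "homozygous_line",
                     stringsAsFactors = FALSE)
  obs <- rbind(mk_obs(0, 10, pos = 100, accession = "a1"),
               mk_obs(9, 1, pos = 100, accession = "a2"),
               mk_obs(10, 0, pos = 100, accession = "a3"))
  calls <- do.call(rbind, lapply(c("a1", "a2", "a3"), function(a)
    filter_accession_variants(obs[obs$accession == a, ], "homozygous_line")))
  m <- merge_population(calls, meta)
  expect_identical(nrow(m$variants), 1L)
  expect_identical(unname(m$genotypes[1, ]), c("alt", "ref", "ref"))

  # insufficient depth on both alleles: missing
  obs2 <- rbind(obs, mk_obs(1, 1, pos = 200, accession = "a2"),
                mk_obs(0, 8, pos = 200, accession = "a1"))
  calls2 <- do.call(rbind, lapply(c("a1", "a2", "a3"), function(a)
    filter_accession_variants(obs2[obs2$accession == a, ], "homozygous_line")))
  m2 <- merge_population(calls2, meta)
  expect_identical(m2$genotypes[m2$variants$pos == 200, "a2"][[1]], "missing")

  # empty input
  m0 <- merge_population(calls[0, ], meta)
  expect_identical(nrow(m0$variants), 0L)

  # conflicting reference alleles at one position
  bad <- calls
  bad2 <- bad[1, ]; bad2$ref <- "G"; bad2$accession <- "a2"
  expect_error(merge_population(rbind(bad, bad2), meta),
               "conflicting reference alleles")
})

test_that("the MAF filter is strict at 0.05 with accession-wise counting", {
  meta <- data.frame(accession = sprintf("a%03d", 1:199), morphotype = "g",
                     zygosity_class = "homozygous_line", stringsAsFactors = FALSE)
  v <- data.frame(chrom = "chr01", pos = c(10L, 20L, 30L), ref = "A", alt = "C",
                  class = "SNP", stringsAsFactors = FALSE)
  geno <- rbind(c(rep("alt", 9), rep("ref", 190)),
                c(rep("alt", 10), rep("ref", 189)),
                c(rep("alt", 100), rep("ref", 99)))
  colnames(geno) <- meta$accession
  m <- variome:::new_genotype_matrix(v, geno, meta)
  expect_equal(maf(m), c(9 / 199, 10 / 199, 99 / 199), tolerance = 1e-12)
  kept <- maf_filter(m)
  expect_identical(kept$variants$pos, c(20L, 30L))
})

test_that("het genotypes count half an allele and missing leaves the denominator", {
  meta <- data.frame(accession = c("a", "b", "c", "d"), morphotype = "g",
                     zygosity_class = "genebank", stringsAsFactors = FALSE)
  v <- data.frame(chrom = "c", pos = 1L, ref = "A", alt = "C", class = "SNP")
  geno <- matrix(c("het", "ref", "alt", "missing"), 1,
                 dimnames = list(NULL, meta$accession))
  m <- variome:::new_genotype_matrix(v, geno, meta)
  expect_equal(maf(m), 0.5, tolerance = 1e-12)  # (0.5 + 0 + 1) / 3
})

test_that("all-missing rows are removed and InDel filtering is opt-in", {
  meta <- data.frame(accession = c("a", "b"), morphotype = "g",
                     zygosity_class = "homozygous_line", stringsAsFactors = FALSE)
  v <- data.frame(chrom = "c", pos = c(1L, 2L), ref = c("A", "AT"),
                  alt = c("C", "A"), class = c("SNP", "InDel"),
                  stringsAsFactors = FALSE)
  geno <- rbind(c("missing", "missing"), c("alt", "ref"))
  colnames(geno) <- meta$accession
  m <- variome:::new_genotype_matrix(v, geno, meta)
  kept <- maf_filter(m)
  expect_identical(kept$variants$pos, 2L)
  # rare InDel: kept by default, removed when include_indels = TRUE
  geno2 <- rbind(c("alt", "ref"), c("alt", "ref"))
  colnames(geno2) <- meta$accession
  meta30 <- data.frame(accession = sprintf("a%02d", 1:30), morphotype = "g",
                       zygosity_class = "homozygous_line", stringsAsFactors = FALSE)
  geno30 <- rbind(c("alt", rep("ref", 29)), c("alt", rep("ref", 29)))
  colnames(geno30) <- meta30$accession
  m30 <- variome:::new_genotype_matrix(v, geno30, meta30)
  expect_identical(nrow(maf_filter(m30)$variants), 1L)
  expect_identical(nrow(maf_filter(m30, include_indels = TRUE)$variants), 0L)
})

test_that("raising depth or MAF thresholds never increases retained variants", {
  study <- tiny_study()
  obs <- emit_population_depths(study$ref, study$truth, seed = 61,
                                depth = 8, error_rate = 0.01)
  n_kept <- function(t) nrow(filter_variants(obs, study$accessions, t)$variants)
  base <- n_kept(filter_thresholds())
  expect_lte(n_kept(filter_thresholds(min_allele_depth = 5)), base)
  expect_lte(n_kept(filter_thresholds(min_maf = 0.15)), base)
  expect_lte(n_kept(filter_thresholds(min_allele_depth = 5, min_maf = 0.15)),
             n_kept(filter_thresholds(min_allele_depth = 5)))
})

test_that("cascade decisions match brute-force evaluation of the printed rules", {
  set.seed(99)
  n <- 10000L
  D_R <- sample(0:15, n, TRUE)
  D_A <- sample(0:15, n, TRUE)
  keep <- D_R + D_A > 0
  D_R <- D_R[keep]; D_A <- D_A[keep]
  for (zclass in c("homozygous_line", "genebank")) {
    got <- filter_accession_variants(mk_obs(D_R, D_A), zclass)
    oracle <- vapply(seq_along(D_R), function(i)
      oracle_cascade_decision(D_R[i], D_A[i], zclass == "homozygous_line")$keep,
      TRUE)
    expect_identical(got$variant_call, oracle)
    zyg_oracle <- vapply(seq_along(D_R), function(i)
      oracle_cascade_decision(D_R[i], D_A[i], TRUE)$zygosity, "")
    expect_identical(classify_zygosity(D_R, D_A), zyg_oracle)
  }
})
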