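# Shared fixtures, generated once per test run.
.fixtures <- new.env()

tiny_study <- function() {
  if (is.null(.fixtures$tiny)) {
    sim <- generate_reference(2, 25000, 8, seed = 101)
    pop <- generate_population(sim$ref, sim$genes, n_groups = 3,
                               accessions_per_group = 4, n_variants = 200,
                               seed = 102)
    .fixtures$tiny <- list(ref = sim$ref, genes = sim$genes,
                           accessions = pop$accessions, truth = pop$truth)
  }
  .fixtures$tiny
}

truth_matrix <- function(study) {
  variome:::new_genotype_matrix(
    study$truth$variants[, c("chrom", "pos", "ref", "alt", "class")],
    study$truth$genotypes, study$accessions)
}

# Write an in-memory set of read pairs to a FASTQ pair.
write_pair_files <- function(ids, s1, q1, s2, q2, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  f1 <- file.path(dir, "r1.fastq"); f2 <- file.path(dir, "r2.fastq")
  write_fastq(ids, s1, q1, f1)
  write_fastq(ids, s2, q2, f2)
  c(f1, f2)
}
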