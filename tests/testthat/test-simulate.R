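# a small configuration keeps the generator tests fast; the full-scale
# reference simulation is exercised by the acceptance suite
small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_chroms = 2L, chrom_length = 60000L,
             n_library_reads = 20000L, n_genes_per_chrom = 20L,
             n_known_mirnas = 8L, n_clusters = 6L, n_bisulfite_clones = 8L,
             ...)
}

test_that("every generator is deterministic under a fixed seed", {
  s1 <- simulate_study(small_config(seed = 9))
  s2 <- simulate_study(small_config(seed = 9))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$lib_mut, s2$lib_mut)
  expect_identical(s1$expr$matrix, s2$expr$matrix)
  expect_identical(s1$bisulfite$clones, s2$bisulfite$clones)
  s3 <- simulate_study(small_config(seed = 10))
  expect_false(identical(s1$genome, s3$genome))
})

test_that("libraries hold exactly the configured read total", {
  cfg <- small_config(seed = 11)
  study <- simulate_study(cfg)
  expect_equal(attr(study$lib_mut, "total_clean") +
                 attr(study$lib_mut, "n_rejected") +
                 attr(study$lib_mut, "n_out_of_range"),
               cfg$n_library_reads)
  expect_equal(attr(study$lib_mut, "n_rejected"), 0L)
  expect_equal(attr(study$lib_mut, "n_out_of_range"), 0L)
})

test_that("every emitted read maps back to the genome exactly", {
  study <- simulate_study(small_config(seed = 12))
  pl <- map_reads(study$lib_mut, build_index(study$genome))
  expect_true(all(pl$reads$n_hits >= 1))
})

test_that("planted features lie within genome bounds and truth mirrors spec", {
  cfg <- small_config(seed = 13)
  study <- simulate_study(cfg)
  lens <- nchar(study$genome)
  ann <- study$annotation
  expect_true(all(ann$start >= 0 & ann$end <= lens[ann$chrom]))
  tr <- study$truth
  expect_equal(nrow(tr$clusters), cfg$n_clusters)
  expect_true(all(tr$clusters$end <= lens[tr$clusters$chrom]))
  expect_false(any(duplicated(tr$clusters[, c("chrom", "start")])))
  expect_true(all(tr$meth[, -(1:4)] >= 0 & tr$meth[, -(1:4)] <= 1))
  expect_equal(ncol(study$expr$matrix), 2L * cfg$n_replicates_expr)
})

test_that("planted known miRNA hairpin loci fold back into hairpins", {
  study <- simulate_study(small_config(seed = 14))
  loci <- study$truth$mirna_loci
  for (i in sample(nrow(loci), 3)) {
    pre <- substr(study$genome[[loci$chrom[i]]], loci$start[i] + 1L,
                  loci$end[i])
    fr <- fold_rna(pre)
    expect_gte(fr$n_pairs, nchar(loci$mature_seq[i]) - 2)
  }
})

test_that("a null study plants nothing differential", {
  cfg <- small_config(seed = 15, null_study = TRUE)
  study <- simulate_study(cfg)
  expect_true(all(study$truth$mirnas$ratio == 1))
  expect_true(all(study$truth$degs$log2_effect == 0))
  expect_true(all(study$truth$clusters$bias_fold == 1))
})

test_that("bisulfite clone methylation tracks the planted probability", {
  # planted p = 0.5 with perfect conversion: called percent falls in the
  # exact binomial interval around 50%
  cfg <- sim_config(seed = 16, n_bisulfite_clones = 30, conversion_rate = 1)
  gsim <- list(genome = c(chr1 = random_seq(1500)),
               bisulfite_loci = data.frame(
                 locus_id = "half", chrom = "chr1", start = 200L, end = 500L,
                 cg_wt = .5, chg_wt = .5, chh_wt = .5,
                 cg_mut = .5, chg_mut = .5, chh_mut = .5,
                 stringsAsFactors = FALSE))
  set.seed(16)
  bs <- simulate_bisulfite_clones(cfg, gsim)
  ref <- bs$loci$ref_seq[1]
  al <- lapply(bs$clones$half$mut, align_clone, locus_ref = ref)
  sites <- call_sites(al, ref, "half")
  covered <- sites[sites$state != "uncovered", ]
  x <- sum(covered$state == "methylated")
  ci <- stats::binom.test(x, nrow(covered))$conf.int
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
})
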