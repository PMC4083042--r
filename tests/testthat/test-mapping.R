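test_that("exact mapping agrees with an exhaustive substring scan", {
  set.seed(7)
  genome <- c(chrA = random_seq(4000), chrB = random_seq(4000))
  # plant one read once per chromosome
  planted <- random_seq(21)
  substr(genome[["chrA"]], 501, 521) <- planted
  substr(genome[["chrB"]], 1201, 1221) <- planted
  reads <- c(planted,
             substr(genome[["chrA"]], 100, 123),
             revcomp(substr(genome[["chrB"]], 2000, 2020)),
             random_seq(22))                       # almost surely absent
  lib <- collapse_reads(reads)
  pl <- map_reads(lib, build_index(genome))
  for (i in seq_len(nrow(lib))) {
    oh <- oracle_scan_hits(lib$seq[i], genome)
    mh <- pl$hits[pl$hits$read_id == i, c("chrom", "start", "end", "strand")]
    rownames(mh) <- rownames(oh) <- NULL
    expect_equal(mh, oh, info = lib$seq[i])
  }
  expect_equal(sum(pl$reads$n_hits[lib$seq == planted]), 2L)
})

test_that("palindromic reads are canonicalized to the plus strand", {
  pal <- paste0(strrep("ACGT", 5), revcomp(strrep("ACGT", 5)))  # 40nt... too long
  pal <- "ACGTACGATCGATCGTACGT"
  pal <- paste0(substr(pal, 1, 10), revcomp(substr(pal, 1, 10)))
  expect_identical(pal, revcomp(pal))
  genome <- c(chr1 = paste0(random_seq(200), pal, random_seq(200)))
  lib <- collapse_reads(pal)
  pl <- map_reads(lib, build_index(genome))
  expect_equal(nrow(pl$hits), 1L)
  expect_equal(pl$hits$strand, "+")
})

test_that("mapping the reverse-complemented library only swaps hit strands", {
  set.seed(8)
  genome <- c(c1 = random_seq(3000))
  reads <- vapply(1:20, function(i) {
    s <- sample(2000, 1)
    substr(genome[["c1"]], s, s + 20)
  }, character(1))
  lib <- collapse_reads(reads)
  lib_rc <- collapse_reads(revcomp(rep(lib$seq, lib$count)))
  idx <- build_index(genome)
  h1 <- map_reads(lib, idx)$hits
  h2 <- map_reads(lib_rc, idx)$hits
  # join on interval: strands must be swapped, all else equal
  k1 <- paste(h1$chrom, h1$start, h1$end)
  k2 <- paste(h2$chrom, h2$start, h2$end)
  expect_setequal(k1, k2)
  m <- match(k1, k2)
  pal <- lib$seq[h1$read_id] == revcomp(lib$seq[h1$read_id])
  expect_true(all((h1$strand != h2$strand[m])[!pal]))
})

test_that("size profile weights by count and bins 18-26 plus other", {
  lib <- collapse_reads(c(rep(random_seq(24), 10),
                          rep(random_seq(21), 5), rep(random_seq(30), 2)))
  sp <- profile_sizes(lib)
  expect_equal(sp$count[sp$length == "24"], 10)
  expect_equal(sp$fraction[sp$length == "24"], 10 / 15)
  expect_equal(sp$fraction[sp$length == "21"], 5 / 15)
  expect_equal(sp$count[sp$length == "other"], 2)
  expect_equal(sum(sp$fraction, na.rm = TRUE), 1)
  expect_equal(sum(sp$count), sum(lib$count))      # mass conservation
})

test_that("category assignment follows the priority rule with one category per read", {
  genome <- c(chr1 = random_seq(2000))
  r1 <- substr(genome[["chr1"]], 101, 121)   # overlaps TE and gene
  r2 <- substr(genome[["chr1"]], 501, 521)   # miRNA locus beats all
  r3 <- substr(genome[["chr1"]], 1501, 1521) # nothing annotated
  lib <- collapse_reads(c(rep(r1, 3), r2, r3, random_seq(20)))
  ann <- data.frame(
    feature_id = c("te1", "g1", "mir1", "rrna1"),
    chrom = "chr1", start = c(90L, 90L, 490L, 490L),
    end = c(200L, 200L, 540L, 540L), strand = "+",
    feature_class = c("TE", "gene", "known_miRNA_locus", "rRNA"),
    go = "", stringsAsFactors = FALSE)
  pl <- map_reads(lib, build_index(genome))
  cp <- profile_categories(pl, ann)
  expect_equal(cp$count[cp$category == "TE"], 3)
  expect_equal(cp$count[cp$category == "known_miRNA_locus"], 1)
  expect_equal(cp$count[cp$category == "gene"], 0)
  expect_equal(cp$count[cp$category == "unannotated"], 2)  # r3 + unmapped
  expect_equal(sum(cp$count), sum(lib$count))
  expect_equal(sum(cp$fraction), 1)
})
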