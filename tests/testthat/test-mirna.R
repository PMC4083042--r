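# small constructed libraries: totals come from the collapsed counts
mk_lib <- function(...) {
  reads <- c(...)
  collapse_reads(reads)
}

test_that("isomiR counting is 5'-anchored with at most 2 nt of 3' slack", {
  mature <- "TACTGAATCGGACCTAGCTAT"           # 21 nt
  lib <- mk_lib(
    rep(mature, 5),
    rep(substr(mature, 1, 19), 3),            # 3' trim 2 -> counted
    rep(paste0(mature, "GT"), 2),             # 3' extension 2 -> counted
    rep(substr(mature, 1, 18), 4),            # trim 3 -> not counted
    rep(substr(mature, 2, 21), 7))            # 5' trim -> not counted
  cat <- data.frame(name = "m1", family = "m1", mature_seq = mature)
  q <- quantify_known(lib, mk_lib(rep(mature, 5)), cat)
  expect_equal(q$count_mut, 10)
  expect_equal(q$count_wt, 5)
})

test_that("planted expression ratios classify into the three patterns", {
  m_up <- random_seq(21); m_dn <- random_seq(21); m_eq <- random_seq(21)
  filler_m <- replicate(300, random_seq(25))  # pad library totals
  filler_w <- replicate(300, random_seq(25))
  cat <- data.frame(name = c("up1", "dn1", "eq1"),
                    family = c("up1", "dn1", "eq1"),
                    mature_seq = c(m_up, m_dn, m_eq))
  lib_mut <- mk_lib(rep(m_up, 180), rep(m_dn, 20), rep(m_eq, 100), filler_m)
  lib_wt <- mk_lib(rep(m_up, 20), rep(m_dn, 112), rep(m_eq, 100), filler_w)
  q <- quantify_known(lib_mut, lib_wt, cat)
  expect_equal(q$pattern, c("up", "down", "unchanged"))
  expect_equal(attr(q, "test"), "count-test")
  # swapping genotypes maps up <-> down and fixes unchanged
  q2 <- quantify_known(lib_wt, lib_mut, cat)
  expect_equal(q2$pattern, c("down", "up", "unchanged"))
  # pattern partition: one pattern per entry
  expect_true(all(table(q$name) == 1))
  expect_equal(sum(q$pattern %in% c("up", "down", "unchanged")), nrow(cat))
})

test_that("a t-test path activates with replicated libraries", {
  m <- random_seq(21)
  cat <- data.frame(name = "m", family = "m", mature_seq = m)
  mk <- function(n) mk_lib(rep(m, n), replicate(50, random_seq(24)))
  q <- quantify_known(list(mk(100), mk(110)), list(mk(10), mk(12)), cat)
  expect_equal(attr(q, "test"), "welch-t")
  expect_equal(q$pattern, "up")
})

test_that("family stems parse from catalogue names", {
  expect_equal(mirna_family(c("osa-miR395p", "osa-miR395s", "osa-miR167j",
                              "weird")), c("miR395", "miR395", "miR167", "weird"))
})

test_that("family divergence reports only families split in both directions", {
  q <- data.frame(
    name = c("a1", "a2", "b1", "b2", "c1"),
    family = c("A", "A", "B", "B", "C"),
    pattern = c("up", "down", "up", "unchanged", "up"),
    stringsAsFactors = FALSE)
  fd <- family_divergence(q)
  expect_equal(fd$family, "A")
  expect_equal(fd$members_up, "a1")
  expect_equal(fd$members_down, "a2")
})

test_that("a planted hairpin with 5p-dominant reads is discovered with guide 5p", {
  set.seed(31)
  mature <- random_seq(21)
  star <- strsplit(revcomp(mature), "")[[1]]
  star[5] <- setdiff(c("A", "C", "G", "T"), star[5])[1]
  star <- paste0(star, collapse = "")
  hairpin <- paste0(mature, random_seq(12), star)
  genome <- c(chr1 = paste0(random_seq(2500), hairpin, random_seq(2500)))
  hp_start <- 2500L                            # 0-based mature start
  lib <- collapse_reads(c(rep(mature, 30), rep(star, 8)))
  pl <- map_reads(lib, build_index(genome))
  ann <- data.frame(feature_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), feature_class = character(0),
                    go = character(0))
  nov <- discover_novel(pl, ann, genome)
  expect_equal(nrow(nov), 1L)
  expect_lte(nov$start, hp_start)
  expect_gte(nov$end, hp_start + nchar(hairpin))
  expect_equal(nov$mature_arm, "5p")
  expect_equal(nov$guide_arm, "5p")
  expect_gt(nov$reads_5p, nov$reads_3p)
  expect_equal(nov$mature_seq, mature)
})

test_that("candidates never overlap annotated structural or known miRNA loci", {
  set.seed(32)
  mature <- random_seq(21)
  star <- strsplit(revcomp(mature), "")[[1]]
  star[3] <- setdiff(c("A", "C", "G", "T"), star[3])[1]
  hairpin <- paste0(mature, random_seq(10), paste0(star, collapse = ""))
  genome <- c(chr1 = paste0(random_seq(1000), hairpin, random_seq(1000)))
  lib <- collapse_reads(rep(mature, 20))
  pl <- map_reads(lib, build_index(genome))
  ann <- data.frame(feature_id = "mir-known", chrom = "chr1",
                    start = 990L, end = 1070L, strand = "+",
                    feature_class = "known_miRNA_locus", go = "",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(discover_novel(pl, ann, genome)), 0L)
})
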