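make_hits <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

test_that("hits are assigned to the window containing their 5'-most base", {
  genome <- c(chr1 = strrep("A", 500))
  hits <- make_hits(
    read_id = c(1L, 2L, 3L),
    chrom = "chr1",
    start = c(199L, 200L, 180L), end = c(220L, 221L, 201L),
    strand = c("+", "+", "-"),                 # minus: 5' base is end - 1
    count = c(1L, 1L, 1L), length = c(21L, 21L, 21L))
  wp <- count_windows(fake_placements(hits), genome)
  expect_equal(wp$raw_count[wp$start == 100], 1)   # + hit at 199
  expect_equal(wp$raw_count[wp$start == 200], 2)   # + hit at 200, - hit 5'=200
  expect_equal(sum(wp$raw_count), 3)
})

test_that("multi-mapped reads contribute full count at every hit", {
  genome <- c(chr1 = strrep("A", 300), chr2 = strrep("A", 300))
  hits <- make_hits(read_id = 1L, chrom = c("chr1", "chr2"),
                    start = c(10L, 110L), end = c(31L, 131L), strand = "+",
                    count = 3L, length = 21L)
  wp <- count_windows(fake_placements(hits), genome)
  expect_equal(sum(wp$raw_count), 6)
})

test_that("random hit sets match the brute-force per-position oracle", {
  set.seed(11)
  for (rep in 1:3) {
    genome <- c(g1 = random_seq(3000), g2 = random_seq(2000))
    reads <- vapply(1:20, function(i) {
      ch <- sample(names(genome), 1)
      L <- sample(18:26, 1)
      s <- sample(nchar(genome[[ch]]) - L, 1)
      r <- substr(genome[[ch]], s, s + L - 1)
      if (runif(1) < 0.5) revcomp(r) else r
    }, character(1))
    lib <- collapse_reads(reads)
    wp <- count_windows(map_reads(lib, build_index(genome)), genome)
    oc <- oracle_window_counts(lib, genome)
    for (ch in names(genome)) {
      expect_equal(wp$raw_count[wp$chrom == ch], oc[[ch]])
    }
  }
})

test_that("windows tile every chromosome without gaps", {
  genome <- c(a = strrep("A", 250), b = strrep("A", 400))
  wp <- count_windows(fake_placements(make_hits(
    read_id = integer(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), count = integer(0),
    length = integer(0))), genome)
  for (ch in names(genome)) {
    w <- wp[wp$chrom == ch, ]
    expect_equal(w$start, seq(0, nchar(genome[[ch]]) - 1, by = 100))
    expect_equal(w$end[-nrow(w)], w$start[-1])     # contiguous
    expect_equal(w$end[nrow(w)], nchar(genome[[ch]]))
  }
  expect_error(count_windows(fake_placements(make_hits(
    read_id = integer(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), count = integer(0),
    length = integer(0))), genome, size_range = c(10, 26)), "size_range")
})

test_that("a sub-width step assigns hits to every covering window", {
  genome <- c(chr1 = strrep("A", 300))
  hits <- make_hits(read_id = 1L, chrom = "chr1", start = 120L, end = 141L,
                    strand = "+", count = 2L, length = 21L)
  wp <- count_windows(fake_placements(hits), genome, width = 100L, step = 50L)
  expect_equal(wp$raw_count[wp$start %in% c(50L, 100L)], c(2, 2))
  expect_equal(sum(wp$raw_count), 4)
})

test_that("RPM normalization is counts per million clean reads", {
  genome <- c(chr1 = strrep("A", 100))
  wp <- count_windows(fake_placements(make_hits(
    read_id = 1L, chrom = "chr1", start = 0L, end = 21L, strand = "+",
    count = 10L, length = 21L)), genome)
  expect_equal(normalize_rpm(wp, 1e6)$rpm, 10)
  expect_equal(normalize_rpm(wp, 2e5)$rpm, 50)
  expect_error(normalize_rpm(wp, 0), "positive")
})

test_that("fold values follow the log2 median-ratio formula with inclusive cut-off", {
  g <- data.frame(chrom = "chr1", start = c(0L, 100L, 200L),
                  end = c(100L, 200L, 300L))
  mk <- function(rpm) {
    p <- cbind(g, raw_count = rpm, rpm = rpm)
    class(p) <- c("window_profile", "data.frame")
    p
  }
  dc <- call_differential(mk(c(8, 5, 0)), mk(c(2, 5, 0)), pseudocount = 0)
  expect_equal(dc$fold_value[1], 2)            # X = 4Y: exactly 2, passes
  expect_true(dc$passes[1])
  expect_equal(dc$fold_value[2], 0)            # X = Y
  expect_false(dc$passes[2])
  expect_false(dc$passes[3])                   # X = Y = 0 never called
  expect_equal(dc$direction[1], "up")
})

test_that("swapping genotypes negates fold values; scaling leaves them fixed", {
  set.seed(3)
  g <- data.frame(chrom = "chr1", start = seq(0L, 900L, 100L),
                  end = seq(100L, 1000L, 100L))
  mk <- function(rpm) {
    p <- cbind(g, raw_count = rpm, rpm = rpm)
    class(p) <- c("window_profile", "data.frame")
    p
  }
  x <- rpois(10, 20); y <- rpois(10, 20)
  d1 <- call_differential(mk(x), mk(y))
  d2 <- call_differential(mk(y), mk(x))
  expect_equal(d1$fold_value, -d2$fold_value)
  expect_equal(d1$passes, d2$passes)
  # scale invariance with c = 0 on nonzero windows
  nz <- x > 0 & y > 0
  d3 <- call_differential(mk(x * 7), mk(y * 7), pseudocount = 0)
  d4 <- call_differential(mk(x), mk(y), pseudocount = 0)
  expect_equal(d3$fold_value[nz], d4$fold_value[nz])
})

test_that("median across multiple libraries per genotype is used", {
  g <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  mk <- function(rpm) {
    p <- cbind(g, raw_count = rpm, rpm = rpm)
    class(p) <- c("window_profile", "data.frame")
    p
  }
  dc <- call_differential(list(mk(10), mk(20), mk(90)), list(mk(5)),
                          pseudocount = 0)
  expect_equal(dc$X, 20)                       # median of 10, 20, 90
  expect_equal(dc$fold_value, 2)
})

test_that("size subsetting uses a closed 20-24 range and is monotone", {
  genome <- c(chr1 = strrep("A", 200))
  hits <- make_hits(read_id = 1:4, chrom = "chr1",
                    start = c(0L, 10L, 20L, 30L),
                    end = c(19L, 30L, 44L, 55L), strand = "+",
                    count = 1L, length = c(19L, 20L, 24L, 25L))
  pl <- fake_placements(hits)
  sub <- subset_by_size(pl, c(20L, 24L))
  expect_equal(sort(sub$reads$length), c(20L, 24L))
  w_full <- count_windows(pl, genome)
  w_sub <- count_windows(sub, genome, size_range = c(20L, 24L))
  expect_true(all(w_sub$raw_count <= w_full$raw_count))
})

test_that("chromosome tracks are ordered and complete", {
  g <- data.frame(chrom = rep(c("chr2", "chr1"), each = 5),
                  start = rep(seq(0L, 400L, 100L), 2),
                  end = rep(seq(100L, 500L, 100L), 2))
  dc <- cbind(g, X = 1, Y = 1, fold_value = rnorm(10),
              direction = "up", passes = FALSE)
  class(dc) <- c("differential_clusters", "data.frame")
  tr <- chromosome_track(dc)
  expect_named(tr, c("chr1", "chr2"))
  expect_length(tr$chr1$position, 5)
  expect_true(all(diff(tr$chr1$position) > 0))
})
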