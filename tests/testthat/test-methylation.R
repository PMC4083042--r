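test_that("cytosine contexts follow the CG > CHG > CHH trinucleotide rule", {
  ctx <- cytosine_contexts("CCAGG")
  expect_equal(ctx$context[ctx$position == 0], "CHH")
  expect_equal(ctx$context[ctx$position == 1], "CHG")
  ctx2 <- cytosine_contexts("ACGT")
  expect_equal(ctx2, data.frame(position = 1L, context = "CG"))
  # end-of-locus Cs with undefined context are excluded
  expect_equal(nrow(cytosine_contexts("AAC")), 0L)     # C at last position
  expect_equal(nrow(cytosine_contexts("ACA")), 0L)     # CH? runs off the end
  expect_equal(cytosine_contexts("ACG")$context, "CG") # CG needs only +1
})

test_that("context partition matches a pattern-matching oracle on random refs", {
  set.seed(51)
  for (i in 1:200) {
    ref <- random_seq(sample(20:60, 1))
    got <- cytosine_contexts(ref)
    want <- oracle_contexts(ref)
    expect_equal(got$position, want$position, info = ref)
    expect_equal(got$context, want$context, info = ref)
  }
})

test_that("bisulfite alignment scores match a brute-force DP oracle", {
  set.seed(52)
  for (i in 1:20) {
    ref <- random_seq(sample(15:28, 1))
    clone <- strsplit(ref, "")[[1]]
    # random conversions, mutations, deletion
    conv <- clone == "C" & runif(length(clone)) < 0.5
    clone[conv] <- "T"
    if (runif(1) < 0.5) {
      p <- sample(length(clone), 1)
      clone[p] <- sample(c("A", "C", "G", "T"), 1)
    }
    if (runif(1) < 0.3) clone <- clone[-sample(length(clone), 1)]
    clone <- paste0(clone, collapse = "")
    al <- smrnapipe:::align_clone_one(clone, ref)
    expect_equal(al$score, -oracle_bisulfite_cost(clone, ref), info = ref)
  }
})

test_that("clone alignment handles identity, full conversion and orientation", {
  set.seed(53)
  ref <- random_seq(120)
  expect_equal(align_clone(ref, ref)$score, 0)
  conv <- chartr("C", "T", ref)
  al <- align_clone(conv, ref)
  expect_equal(al$score, 0)
  expect_true(al$accepted)
  # reverse-orientation clones are recognized
  al_rev <- align_clone(revcomp(conv), ref)
  expect_equal(al_rev$orientation, "rev")
  expect_true(al_rev$accepted)
  # garbage clones are rejected
  expect_false(align_clone(random_seq(120), ref)$accepted)
})

test_that("site calling maps clone bases to methylation states", {
  ref <- "ACGTCCGG"
  al <- align_clone("ACGTCTGG", ref)       # one C read as T
  sites <- call_sites(list(al), ref, "L")
  expect_equal(sites$state[sites$position == 1], "methylated")   # CG kept C
  expect_equal(sites$state[sites$position == 5], "unmethylated") # C -> T
  expect_true(all(sites$context %in% c("CG", "CHG", "CHH")))
})

test_that("percent methylation, Wilson intervals and genotype deltas compute", {
  ref <- paste0(strrep("ACGT", 20), "AA")    # 20 CG sites
  al <- align_clone(ref, ref)
  sites <- call_sites(rep(list(al), 30), ref, "L")
  sm <- summarize_locus(sites, "mut")
  expect_equal(sm$percent[sm$context == "CG"], 100)
  expect_equal(sm$n_total[sm$context == "CG"], 600)
  expect_true(is.na(sm$percent[sm$context == "CHH"]))    # no CHH sites
  # all-converted clone: exactly 0
  al0 <- align_clone(chartr("C", "T", ref), ref)
  s0 <- call_sites(rep(list(al0), 30), ref, "L")
  sw <- summarize_locus(s0, "wt")
  expect_equal(sw$percent[sw$context == "CG"], 0)
  d <- diff_genotypes(sm, sw)
  expect_equal(d$delta_points[d$context == "CG"], 100)
  expect_true(is.na(d$delta_points[d$context == "CHH"]))
  expect_lt(d$p_value[d$context == "CG"], 1e-10)
})

test_that("fully methylated and fully converted simulations give 100% and 0%", {
  config <- sim_config(seed = 5, n_bisulfite_clones = 10, conversion_rate = 1)
  gsim <- list(genome = c(chr1 = random_seq(1000)),
               bisulfite_loci = data.frame(
                 locus_id = c("all", "none"), chrom = "chr1",
                 start = c(100L, 500L), end = c(400L, 800L),
                 cg_wt = c(1, 0), chg_wt = c(1, 0), chh_wt = c(1, 0),
                 cg_mut = c(1, 0), chg_mut = c(1, 0), chh_mut = c(1, 0),
                 stringsAsFactors = FALSE))
  set.seed(5)
  bs <- simulate_bisulfite_clones(config, gsim)
  # fully methylated: clones identical to the reference
  expect_true(all(bs$clones$all$wt == bs$loci$ref_seq[1]))
  # fully converted: every C reads T
  expect_true(all(bs$clones$none$wt ==
                    chartr("C", "T", bs$loci$ref_seq[2])))
  for (lid in c("all", "none")) {
    ref <- bs$loci$ref_seq[bs$loci$locus_id == lid]
    al <- lapply(bs$clones[[lid]]$wt, align_clone, locus_ref = ref)
    sm <- summarize_locus(call_sites(al, ref, lid), "wt")
    expect_equal(sm$percent[!is.na(sm$percent)],
                 rep(if (lid == "all") 100 else 0,
                     sum(!is.na(sm$percent))))
  }
})

test_that("the lollipop report draws one glyph per site per clone", {
  ref <- "ACGTCCGGAA"
  al <- align_clone(ref, ref)
  sites <- call_sites(list(al, al), ref, "L")
  f <- withr::local_tempfile()
  lollipop_report(sites, f)
  lines <- readLines(f)
  n_sites <- length(unique(sites$position))
  expect_length(lines, 4L)                   # header, context key, 2 clones
  expect_match(lines[3], sprintf("^c1\\s+\\*{%d}$", n_sites))
})
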