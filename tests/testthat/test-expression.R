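mk_design <- function(nrep = 3) {
  data.frame(sample = c(paste0("m", 1:nrep), paste0("w", 1:nrep)),
             genotype = rep(c("mut", "wt"), each = nrep),
             replicate = rep(1:nrep, 2), stringsAsFactors = FALSE)
}

test_that("identical matrices give zero DEGs and a full direction partition", {
  set.seed(41)
  half <- matrix(rnorm(50 * 3, 8), 50, 3)
  mat <- cbind(half, half)
  dimnames(mat) <- list(sprintf("g%02d", 1:50), mk_design()$sample)
  degs <- call_degs(mat, mk_design())
  expect_equal(sum(degs$direction != "unchanged"), 0)
  degs_w <- call_degs(mat, mk_design(), method = "welch")
  expect_equal(degs_w$p_value, rep(1, 50))        # zero variance, equal means
  expect_equal(sum(degs_w$direction != "unchanged"), 0)
  expect_equal(sum(degs$direction == "up") + sum(degs$direction == "down") +
                 sum(degs$direction == "unchanged"), nrow(mat))
})

test_that("planted shifts are detected with the right direction", {
  set.seed(42)
  mat <- matrix(rnorm(200 * 6, 8, 0.25), 200, 6)
  dimnames(mat) <- list(sprintf("g%03d", 1:200), mk_design()$sample)
  mat[1:5, 1:3] <- mat[1:5, 1:3] + 1.5
  mat[6:8, 1:3] <- mat[6:8, 1:3] - 1.5
  degs <- call_degs(mat, mk_design())
  expect_equal(degs$direction[1:5], rep("up", 5))
  expect_equal(degs$direction[6:8], rep("down", 3))
  expect_lt(sum(degs$direction[-(1:8)] != "unchanged"), 3)
  expect_equal(degs$log2fc[1:5],
               unname(rowMeans(mat[1:5, 1:3]) - rowMeans(mat[1:5, 4:6])))
})

test_that("replicate requirements are enforced", {
  mat <- matrix(rnorm(10 * 2), 10, 2,
                dimnames = list(letters[1:10], c("m1", "w1")))
  design <- data.frame(sample = c("m1", "w1"), genotype = c("mut", "wt"))
  expect_error(call_degs(mat, design), "2 replicates")
})

test_that("chromosomal chi-square uses expressed-gene-density expectations", {
  # observed proportional to expected: statistic 0, p 1
  degs <- data.frame(
    gene_id = sprintf("g%02d", 1:40),
    chrom = rep(c("chr1", "chr2"), each = 20),
    direction = rep(c("up", "unchanged", "up", "unchanged"), each = 10),
    stringsAsFactors = FALSE)
  ct <- chrom_distribution_test(degs)
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p_value, 1)
  expect_equal(ct$df, 1L)
  expect_equal(sum(ct$table$observed), sum(degs$direction != "unchanged"))
  expect_equal(sum(ct$table$expected), sum(degs$direction != "unchanged"))
})

test_that("the chi-square test is invariant under chromosome relabeling", {
  set.seed(43)
  degs <- data.frame(
    gene_id = sprintf("g%03d", 1:300),
    chrom = sample(paste0("chr", 1:4), 300, TRUE,
                   prob = c(.4, .3, .2, .1)),
    direction = sample(c("up", "down", "unchanged"), 300, TRUE),
    stringsAsFactors = FALSE)
  ct1 <- chrom_distribution_test(degs)
  relabel <- c(chr1 = "w", chr2 = "x", chr3 = "y", chr4 = "z")
  degs2 <- degs; degs2$chrom <- unname(relabel[degs$chrom])
  ct2 <- chrom_distribution_test(degs2)
  expect_equal(ct1$statistic, ct2$statistic)
  expect_equal(ct1$p_value, ct2$p_value)
})

test_that("planted chromosomal enrichment is strongly significant at 1000 DEGs", {
  set.seed(44)
  # 6000 expressed genes even across 12 chromosomes; 1000 DEGs packed
  # preferentially onto 3 chromosomes
  chroms <- sprintf("chr%02d", 1:12)
  gene_chrom <- rep(chroms, each = 500)
  de <- rep(FALSE, 6000)
  w <- ifelse(gene_chrom %in% chroms[1:3], 8, 1)
  de[sample(6000, 1000, prob = w)] <- TRUE
  degs <- data.frame(gene_id = sprintf("g%04d", 1:6000), chrom = gene_chrom,
                     direction = ifelse(de, "up", "unchanged"),
                     stringsAsFactors = FALSE)
  ct <- chrom_distribution_test(degs)
  expect_lt(ct$p_value, 1e-6)
})

test_that("BH q-values are monotone along sorted p-values", {
  set.seed(45)
  mat <- matrix(rnorm(100 * 6, 8, 0.3), 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), mk_design()$sample))
  mat[1:10, 1:3] <- mat[1:10, 1:3] + 1
  degs <- call_degs(mat, mk_design())
  o <- order(degs$p_value)
  expect_true(all(diff(degs$q_value[o]) >= -1e-12))
})

test_that("GO proportions divide DE genes by expressed genes per category", {
  degs <- data.frame(
    gene_id = sprintf("g%02d", 1:12),
    direction = c(rep("up", 2), rep("unchanged", 10)),
    stringsAsFactors = FALSE)
  go <- data.frame(
    gene_id = c(sprintf("g%02d", 1:10), "g01", "g11", "g12"),
    go = c(rep("catA", 10), "catB", "catB", "catB"),
    stringsAsFactors = FALSE)
  gp <- go_proportions(degs, go)
  expect_equal(gp$proportion[gp$category == "catA"], 0.2)     # 2 DE of 10
  expect_equal(gp$proportion[gp$category == "catB"], 1 / 3)   # g01 in both
  expect_equal(gp$category, c("catA", "catB"))                # by abundance
  go2 <- data.frame(gene_id = "g05", go = "catC")
  gp2 <- go_proportions(degs, go2)
  expect_equal(gp2$proportion, 0)                             # no DE genes
})
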