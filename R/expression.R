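# Differential-expression summarization from a replicate log2 expression
# table, chromosomal-distribution chi-square test, and GO-category
# proportions.  The per-gene test (Welch t + BH + |log2fc| >= 1) is a
# declared stand-in for unstated microarray statistics; all three knobs
# are arguments.

#' Call differentially expressed genes
#'
#' Per-gene test of mutant vs wild-type log2 intensities across
#' replicates, Benjamini-Hochberg adjustment over all tested genes,
#' direction by the sign of the mutant - wild-type log2 fold change among
#' genes with \code{q_value <= alpha} and \code{|log2fc| >= min_lfc}.
#'
#' The default test is the moderated t (limma \code{lmFit}/\code{eBayes}):
#' with the few replicates typical of these designs, per-gene variance
#' estimates are too noisy for a plain t-test to retain power after FDR
#' adjustment, and empirical-Bayes variance shrinkage across genes is the
#' field-standard remedy.  \code{method = "welch"} selects an unmoderated
#' Welch t-test instead (a gene with zero variance in both groups and
#' equal means gets p = 1).
#'
#' @param matrix genes x samples numeric matrix of log2 intensities
#'   (rownames = gene ids).
#' @param design data.frame with columns \code{sample} (matching matrix
#'   columns) and \code{genotype} (\code{"mut"} / \code{"wt"}).
#' @param annotation optional annotation data.frame used to attach each
#'   gene's chromosome.
#' @param alpha FDR level on the BH-adjusted q-value.
#' @param min_lfc minimum |log2 fold change| for a call.
#' @param method \code{"moderated"} (default) or \code{"welch"}.
#' @return data.frame of \code{DEGRecord}s: \code{gene_id}, \code{chrom},
#'   \code{mean_mut}, \code{mean_wt}, \code{log2fc}, \code{p_value},
#'   \code{q_value}, \code{direction}.
#' @export
call_degs <- function(matrix, design, annotation = NULL, alpha = 0.05,
                      min_lfc = 1, method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(is.matrix(matrix), all(design$sample %in% colnames(matrix)))
  mut <- matrix[, design$sample[design$genotype == "mut"], drop = FALSE]
  wt <- matrix[, design$sample[design$genotype == "wt"], drop = FALSE]
  if (ncol(mut) < 2L || ncol(wt) < 2L)
    stop("at least 2 replicates per genotype are required")
  if (method == "moderated") {
    dm <- cbind(intercept = 1,
                mut = as.integer(design$genotype == "mut"))
    fit <- limma::eBayes(limma::lmFit(matrix[, design$sample, drop = FALSE],
                                      dm))
    pv <- fit$p.value[, "mut"]
    pv[is.na(pv)] <- 1
  } else {
    pv <- vapply(seq_len(nrow(matrix)), function(i) {
      x <- mut[i, ]; y <- wt[i, ]
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
      }
      stats::t.test(x, y)$p.value
    }, numeric(1))
  }
  qv <- stats::p.adjust(pv, method = "BH")
  lfc <- rowMeans(mut) - rowMeans(wt)
  dir <- rep("unchanged", nrow(matrix))
  sig <- qv <= alpha & abs(lfc) >= min_lfc
  dir[sig & lfc > 0] <- "up"
  dir[sig & lfc < 0] <- "down"
  chrom <- rep(NA_character_, nrow(matrix))
  if (!is.null(annotation)) {
    m <- match(rownames(matrix), annotation$feature_id)
    chrom <- annotation$chrom[m]
  }
  data.frame(gene_id = rownames(matrix), chrom = chrom,
             mean_mut = rowMeans(mut), mean_wt = rowMeans(wt),
             log2fc = lfc, p_value = pv, q_value = qv, direction = dir,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Chi-square test of DEG distribution across chromosomes
#'
#' Expected counts are weighted by the per-chromosome density of expressed
#' (tested) genes: \code{expected_i = total_DEGs * n_expressed_i /
#' n_expressed}; a length-weighted expectation is available via
#' \code{weights = "length"} with a supplied genome.
#'
#' @param degs data.frame from \code{\link{call_degs}}.
#' @param weights \code{"expressed"} (default) or \code{"length"}.
#' @param genome named character vector (required for length weighting).
#' @return list of class \code{chrom_dist_test}: \code{table} (chrom,
#'   observed, expected), \code{statistic}, \code{df}, \code{p_value},
#'   \code{excluded} (chromosomes dropped for zero expectation).
#' @export
chrom_distribution_test <- function(degs, weights = c("expressed", "length"),
                                    genome = NULL) {
  weights <- match.arg(weights)
  degs <- degs[!is.na(degs$chrom), , drop = FALSE]
  chroms <- sort(unique(degs$chrom))
  de <- degs$direction != "unchanged"
  obs <- vapply(chroms, function(ch) sum(de & degs$chrom == ch), numeric(1))
  w <- if (weights == "expressed") {
    vapply(chroms, function(ch) sum(degs$chrom == ch), numeric(1))
  } else {
    if (is.null(genome)) stop("length weighting requires a genome")
    nchar(genome)[chroms]
  }
  total <- sum(obs)
  expd <- total * w / sum(w)
  excluded <- chroms[expd == 0]
  keep <- expd > 0
  obs <- obs[keep]; expd <- expd[keep]; chroms <- chroms[keep]
  stat <- sum((obs - expd)^2 / expd)
  df <- length(chroms) - 1L
  structure(list(
    table = data.frame(chrom = chroms, observed = unname(obs),
                       expected = unname(expd), stringsAsFactors = FALSE),
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
    excluded = excluded
  ), class = "chrom_dist_test")
}

#' @export
print.chrom_dist_test <- function(x, ...) {
  cat(sprintf("Chi-square test of DEG chromosomal distribution\n"))
  cat(sprintf("  X-squared = %.4g, df = %d, p-value = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (length(x$excluded))
    cat("  excluded (zero expectation):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' GO-category proportions of differentially expressed genes
#'
#' For each GO category present among expressed genes: the number of DE
#' genes in the category divided by the total number of expressed genes
#' mapped to it.  A gene mapping to several categories counts once in
#' each.  Descriptive only; no enrichment p-values are computed.
#'
#' @param degs data.frame from \code{\link{call_degs}} (its gene set
#'   defines "expressed").
#' @param go_table data.frame with columns \code{gene_id} and \code{go}
#'   (one row per gene-category pair, or comma-separated categories).
#' @return data.frame \code{category}, \code{n_de_in_category},
#'   \code{n_expressed_in_category}, \code{proportion}, ordered by
#'   category abundance (descending).
#' @export
go_proportions <- function(degs, go_table) {
  if (any(grepl(",", go_table$go))) {
    reps <- strsplit(go_table$go, ",", fixed = TRUE)
    go_table <- data.frame(
      gene_id = rep(go_table$gene_id, lengths(reps)),
      go = unlist(reps), stringsAsFactors = FALSE)
  }
  go_table <- go_table[nzchar(go_table$go), , drop = FALSE]
  go_table <- go_table[go_table$gene_id %in% degs$gene_id, , drop = FALSE]
  de_genes <- degs$gene_id[degs$direction != "unchanged"]
  cats <- unique(go_table$go)
  n_expr <- vapply(cats, function(cg) {
    length(unique(go_table$gene_id[go_table$go == cg]))
  }, numeric(1))
  n_de <- vapply(cats, function(cg) {
    length(unique(intersect(go_table$gene_id[go_table$go == cg], de_genes)))
  }, numeric(1))
  out <- data.frame(category = cats, n_de_in_category = unname(n_de),
                    n_expressed_in_category = unname(n_expr),
                    proportion = unname(n_de / n_expr),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_expressed_in_category, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
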