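# Base-pair-maximization secondary-structure prediction (Nussinov-style
# dynamic programming) with weighted pairs.  The model scores each pair
# (GC 3, AU 2, GU 1 model units, maximized) rather than using a full
# nearest-neighbour thermodynamic model; the reported fold_score is the
# negated optimum so that lower = more stable, and is labelled "mfe" in
# report columns in that model-unit sense.

PAIR_SCORES <- c(GC = 3, AU = 2, GU = 1)

pair_score_matrix <- function(pair_scores = PAIR_SCORES) {
  b <- c("A", "C", "G", "T")
  P <- matrix(0, 4, 4, dimnames = list(b, b))
  P["G", "C"] <- P["C", "G"] <- pair_scores[["GC"]]
  P["A", "T"] <- P["T", "A"] <- pair_scores[["AU"]]
  P["G", "T"] <- P["T", "G"] <- pair_scores[["GU"]]
  P
}

#' Fold an RNA/DNA sequence by weighted base-pair maximization
#'
#' Dynamic programming over Watson-Crick + GU wobble pairs with a minimum
#' hairpin loop of \code{min_loop} unpaired bases.  The recursion
#' decomposes every subsequence by the pairing partner of its last base;
#' traceback is deterministic (a pairing decomposition is preferred over
#' leaving the last base unpaired on score ties, and the smallest partner
#' index wins among tied pairings).
#'
#' @param seq nucleotide string (U is converted to T); length at most
#'   \code{max_len}.
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @param pair_scores named vector of pair scores (model units, positive).
#' @param max_len maximum sequence length accepted.
#' @return list of class \code{rna_fold}: \code{structure} (dot-bracket),
#'   \code{fold_score} (negated optimal score; 0 for no pairs),
#'   \code{n_pairs}, and \code{pairs} (integer partner vector, NA where
#'   unpaired).
#' @export
fold_rna <- function(seq, min_loop = 3L, pair_scores = PAIR_SCORES,
                     max_len = 400L) {
  s <- strsplit(normalize_seq(seq), "")[[1]]
  n <- length(s)
  if (n < 1L || n > max_len)
    stop("sequence length ", n, " out of range [1, ", max_len, "]")
  P <- pair_score_matrix(pair_scores)
  code <- match(s, c("A", "C", "G", "T"))
  if (anyNA(code)) stop("sequence contains non-ACGT characters")
  M <- matrix(0, n, n)
  if (n >= min_loop + 2L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i, j - 1L]            # j unpaired
        ks <- i:(j - min_loop - 1L)
        sc <- P[cbind(code[ks], code[j])]
        valid <- sc > 0
        if (any(valid)) {
          kv <- ks[valid]
          left <- numeric(length(kv))
          gt <- kv > i
          if (any(gt)) left[gt] <- M[cbind(i, kv[gt] - 1L)]
          inner <- M[cbind(kv + 1L, j - 1L)]
          best <- max(best, left + inner + sc[valid])
        }
        M[i, j] <- best
      }
    }
  }
  # deterministic traceback
  partner <- rep(NA_integer_, n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    while (j - i > min_loop) {
      target <- M[i, j]
      ks <- i:(j - min_loop - 1L)
      sc <- P[cbind(code[ks], code[j])]
      found <- FALSE
      for (kk in seq_along(ks)) {
        if (sc[kk] <= 0) next
        k <- ks[kk]
        left <- if (k > i) M[i, k - 1L] else 0
        if (left + M[k + 1L, j - 1L] + sc[kk] == target) {
          partner[k] <- j; partner[j] <- k
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          i <- k + 1L; j <- j - 1L
          found <- TRUE
          break
        }
      }
      if (!found) j <- j - 1L           # j unpaired
    }
  }
  db <- rep(".", n)
  paired <- which(!is.na(partner))
  db[paired[partner[paired] > paired]] <- "("
  db[paired[partner[paired] < paired]] <- ")"
  structure(list(
    structure = paste0(db, collapse = ""),
    fold_score = -M[1L, n],
    n_pairs = length(paired) / 2,
    pairs = partner
  ), class = "rna_fold")
}
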