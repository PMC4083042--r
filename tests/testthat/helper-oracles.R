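# Independent oracles used across the suite.  Each is a deliberately
# naive implementation kept separate from the package's code paths.

# exhaustive substring scan: all exact hits of `seq` on both strands
oracle_scan_hits <- function(seq, genome) {
  out <- list()
  for (ch in names(genome)) {
    for (str in c("+", "-")) {
      q <- if (str == "+") seq else revcomp(seq)
      m <- gregexpr(q, genome[[ch]], fixed = TRUE)[[1]]
      # gregexpr misses overlapping hits; rescan from each hit + 1
      pos <- integer(0); from <- 1L
      while (TRUE) {
        p <- regexpr(q, substr(genome[[ch]], from, nchar(genome[[ch]])),
                     fixed = TRUE)
        if (p == -1L) break
        pos <- c(pos, from + p - 1L)
        from <- from + p
      }
      if (length(pos)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = pos - 1L, end = pos - 1L + nchar(seq),
          strand = str, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  h <- do.call(rbind, out)
  if (seq == revcomp(seq)) {            # palindromes: one record per site
    h <- h[h$strand == "+", , drop = FALSE]
  }
  h[order(h$chrom, h$start, h$strand), , drop = FALSE]
}

# brute-force per-position window assignment of a library's hits
oracle_window_counts <- function(lib, genome, width = 100L,
                                 size_range = c(18L, 26L)) {
  counts <- list()
  for (ch in names(genome)) {
    counts[[ch]] <- numeric(ceiling(nchar(genome[[ch]]) / width))
  }
  for (i in seq_len(nrow(lib))) {
    L <- lib$length[i]
    if (L < size_range[1] || L > size_range[2]) next
    h <- oracle_scan_hits(lib$seq[i], genome)
    for (k in seq_len(nrow(h))) {
      p5 <- if (h$strand[k] == "+") h$start[k] else h$end[k] - 1L
      w <- p5 %/% width + 1L
      counts[[h$chrom[k]]][w] <- counts[[h$chrom[k]]][w] + lib$count[i]
    }
  }
  counts
}

# exhaustive enumeration of all legal secondary structures (min loop 3),
# returning the best total pair score
oracle_fold_best <- function(seq, min_loop = 3L,
                             scores = c(GC = 3, AU = 2, GU = 1)) {
  s <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  ps <- function(a, b) {
    k <- paste0(sort(c(a, b)), collapse = "")
    switch(k, "CG" = scores[["GC"]], "AT" = scores[["AU"]],
           "GT" = scores[["GU"]], 0)
  }
  n <- length(s)
  best <- function(i, j) {
    if (j - i < min_loop + 1L) return(0)
    b <- best(i + 1L, j)                       # i unpaired
    for (k in (i + min_loop + 1L):j) {
      sc <- ps(s[i], s[k])
      if (sc > 0) {
        b <- max(b, sc + best(i + 1L, k - 1L) +
                   (if (k < j) best(k + 1L, j) else 0))
      }
    }
    b
  }
  if (n < min_loop + 2L) return(0)
  best(1L, n)
}

# regex-style context oracle over a reference string
oracle_contexts <- function(ref) {
  s <- strsplit(ref, "")[[1]]
  n <- length(s)
  out <- data.frame(position = integer(0), context = character(0))
  for (i in which(s == "C")) {
    ctx <- NA_character_
    if (i < n && s[i + 1L] == "G") ctx <- "CG"
    else if (i + 2L <= n) ctx <- if (s[i + 2L] == "G") "CHG" else "CHH"
    if (!is.na(ctx)) out <- rbind(out, data.frame(position = i - 1L,
                                                  context = ctx))
  }
  out
}

# brute-force global alignment cost under the bisulfite rule (recursive
# with memoisation; small sequences only)
oracle_bisulfite_cost <- function(clone, ref) {
  a <- strsplit(clone, "")[[1]]; b <- strsplit(ref, "")[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(NA_real_, n + 1L, m + 1L)
  D[1L, ] <- (0:m) * 2; D[, 1L] <- (0:n) * 2
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (a[i] == b[j] || (b[j] == "C" && a[i] == "T")) 0 else 1
      D[i + 1L, j + 1L] <- min(D[i, j] + sub, D[i, j + 1L] + 2,
                               D[i + 1L, j] + 2)
    }
  }
  D[n + 1L, m + 1L]
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# build a read_placements object directly from a hits table (unit tests)
fake_placements <- function(hits, reads = NULL) {
  if (is.null(reads)) {
    ids <- sort(unique(hits$read_id))
    reads <- data.frame(seq = strrep("A", hits$length[match(ids, hits$read_id)]),
                        count = hits$count[match(ids, hits$read_id)],
                        length = hits$length[match(ids, hits$read_id)])
    reads$n_hits <- as.integer(table(factor(hits$read_id, levels = ids)))
  }
  structure(list(reads = reads, hits = hits), class = "read_placements")
}
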