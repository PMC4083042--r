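# Known-miRNA quantification with the three-pattern (up/down/unchanged)
# classification, family opposite-direction detection, and novel miRNA
# discovery by stem-loop prediction with 5p/3p guide-strand assignment.

#' Parse the family stem from a miRNA name
#'
#' \code{"osa-miR395p"} and \code{"osa-miR395s"} both yield
#' \code{"miR395"}; names without a recognizable stem are their own
#' family.
#'
#' @param name character vector of miRNA names.
#' @return character vector of family stems.
#' @export
mirna_family <- function(name) {
  m <- regmatches(name, regexpr("miR[0-9]+", name))
  out <- name
  has <- grepl("miR[0-9]+", name)
  out[has] <- regmatches(name[has], regexpr("miR[0-9]+", name[has]))
  out
}

#' Read a mature-miRNA catalogue
#'
#' Accepts FASTA (headers = names) or a TSV with columns \code{name} and
#' \code{mature_seq}.  Sequences are normalized to the DNA alphabet.
#'
#' @param path input file.
#' @param fmt \code{"fasta"} or \code{"tsv"}.
#' @return data.frame \code{name}, \code{family}, \code{mature_seq}.
#' @export
read_mirna_catalog <- function(path, fmt = c("fasta", "tsv")) {
  fmt <- match.arg(fmt)
  if (fmt == "fasta") {
    seqs <- read_fasta(path)
    df <- data.frame(name = names(seqs), mature_seq = unname(seqs),
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    df$mature_seq <- normalize_seq(df$mature_seq)
  }
  if (anyDuplicated(df$name)) stop("duplicate miRNA names in catalogue")
  bad <- nchar(df$mature_seq) < 19L | nchar(df$mature_seq) > 25L
  if (any(bad)) stop("mature sequence length outside 19-25 nt: ",
                     df$name[bad][1L])
  df$family <- mirna_family(df$name)
  df[, c("name", "family", "mature_seq")]
}

# isomiR rule: a read counts toward a mature sequence iff it is identical
# at the 5' end and differs only by a 3' trim/extension of <= `slack` nt
isomir_count <- function(lib, mature, slack = 2L) {
  L <- nchar(mature)
  sel <- lib$length >= L - slack & lib$length <= L + slack
  if (!any(sel)) return(0L)
  reads <- lib$seq[sel]
  counts <- lib$count[sel]
  m <- pmin(nchar(reads), L)
  hit <- substring(reads, 1L, m) == substring(mature, 1L, m)
  sum(counts[hit])
}

#' Quantify known miRNAs and classify expression patterns
#'
#' A read counts toward a catalogue entry iff it matches the mature
#' sequence exactly or with a 3' trim/extension of at most 2 nt (isomiR
#' rule); counts are RPM-normalized on each library's total clean reads.
#' With one library per genotype, significance is assessed with a
#' two-sided binomial count test of the mutant read count against its
#' expectation under equal abundance given both library totals
#' ("count-test"); with >= 2 libraries per genotype a Welch t-test on
#' per-library RPM is used instead.  Patterns: \code{up} iff ratio >= 2
#' and significant, \code{down} iff ratio <= 0.5 and significant, else
#' \code{unchanged}.
#'
#' @param libs_mut an \code{smrna_library} or list of them (mutant).
#' @param libs_wt same for wild type.
#' @param catalog data.frame from \code{\link{read_mirna_catalog}}.
#' @param pseudocount RPM pseudocount for the ratio.
#' @param alpha significance level.
#' @param ratio_cutoff fold cut-off for up/down (default 2).
#' @param isomir_slack maximum 3' trim/extension in nt.
#' @return data.frame \code{name}, \code{family}, \code{count_mut},
#'   \code{count_wt}, \code{rpm_mut}, \code{rpm_wt}, \code{ratio},
#'   \code{p_value}, \code{pattern}, \code{shared_mature}, plus attribute
#'   \code{test} naming the test used.
#' @export
quantify_known <- function(libs_mut, libs_wt, catalog, pseudocount = 0.5,
                           alpha = 0.05, ratio_cutoff = 2,
                           isomir_slack = 2L) {
  if (inherits(libs_mut, "data.frame")) libs_mut <- list(libs_mut)
  if (inherits(libs_wt, "data.frame")) libs_wt <- list(libs_wt)
  tot_mut <- vapply(libs_mut, function(l) attr(l, "total_clean") %||% sum(l$count),
                    numeric(1))
  tot_wt <- vapply(libs_wt, function(l) attr(l, "total_clean") %||% sum(l$count),
                   numeric(1))
  cnt_mut <- vapply(catalog$mature_seq, function(m) {
    sum(vapply(libs_mut, isomir_count, numeric(1), mature = m,
               slack = isomir_slack))
  }, numeric(1))
  cnt_wt <- vapply(catalog$mature_seq, function(m) {
    sum(vapply(libs_wt, isomir_count, numeric(1), mature = m,
               slack = isomir_slack))
  }, numeric(1))
  rpm_mut <- cnt_mut * 1e6 / sum(tot_mut)
  rpm_wt <- cnt_wt * 1e6 / sum(tot_wt)
  use_ttest <- length(libs_mut) >= 2L && length(libs_wt) >= 2L
  pv <- vapply(seq_len(nrow(catalog)), function(i) {
    if (use_ttest) {
      xm <- vapply(seq_along(libs_mut), function(k) {
        isomir_count(libs_mut[[k]], catalog$mature_seq[i], isomir_slack) *
          1e6 / tot_mut[k]
      }, numeric(1))
      xw <- vapply(seq_along(libs_wt), function(k) {
        isomir_count(libs_wt[[k]], catalog$mature_seq[i], isomir_slack) *
          1e6 / tot_wt[k]
      }, numeric(1))
      if (stats::sd(c(xm, xw)) == 0) return(1)
      stats::t.test(xm, xw)$p.value
    } else {
      n <- cnt_mut[i] + cnt_wt[i]
      if (n == 0) return(1)
      stats::binom.test(cnt_mut[i], n,
                        p = sum(tot_mut) / (sum(tot_mut) + sum(tot_wt)))$p.value
    }
  }, numeric(1))
  ratio <- (rpm_mut + pseudocount) / (rpm_wt + pseudocount)
  sig <- pv < alpha
  pattern <- rep("unchanged", nrow(catalog))
  pattern[sig & ratio >= ratio_cutoff] <- "up"
  pattern[sig & ratio <= 1 / ratio_cutoff] <- "down"
  out <- data.frame(
    name = catalog$name, family = catalog$family,
    count_mut = cnt_mut, count_wt = cnt_wt,
    rpm_mut = rpm_mut, rpm_wt = rpm_wt, ratio = ratio,
    p_value = pv, pattern = pattern,
    shared_mature = duplicated(catalog$mature_seq) |
      duplicated(catalog$mature_seq, fromLast = TRUE),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "test") <- if (use_ttest) "welch-t" else "count-test"
  out
}

#' Families whose members change in opposite directions
#'
#' @param quants output of \code{\link{quantify_known}}.
#' @return data.frame \code{family}, \code{n_members}, \code{members_up},
#'   \code{members_down} (comma-separated names); one row per family with
#'   at least one up and one down member.
#' @export
family_divergence <- function(quants) {
  out <- lapply(split(quants, quants$family), function(d) {
    if (nrow(d) < 2L) return(NULL)
    up <- d$name[d$pattern == "up"]
    dn <- d$name[d$pattern == "down"]
    if (length(up) == 0L || length(dn) == 0L) return(NULL)
    data.frame(family = d$family[1L], n_members = nrow(d),
               members_up = paste(up, collapse = ","),
               members_down = paste(dn, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(family = character(0), n_members = integer(0),
                      members_up = character(0), members_down = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Discover novel miRNA candidates by stem-loop prediction
#'
#' Candidate seeds are read stacks (reads sharing a 5' genomic position
#' and strand, summed count >= \code{min_reads}, length 20--24 nt) whose
#' hits overlap no annotated feature class other than \code{gene} /
#' unannotated.  Around each stack, \code{n_offsets} precursor windows of
#' \code{window} nt are folded on the stack's strand; a candidate is
#' accepted iff the fold score is at most \code{max_fold_score}, the
#' mature sequence has at most \code{max_unpaired} unpaired bases, and
#' every paired mature base pairs to the opposite arm (so the mature lies
#' entirely on one arm, outside the loop).  The star is the arm region
#' pairing the mature with a 2 nt 3' offset; the guide arm is the arm
#' with the larger read support.  Candidates with identical mature
#' sequences at different loci are grouped into one family.
#'
#' @param placements \code{read_placements} (typically of the pooled
#'   mutant+WT library).
#' @param annotation annotation data.frame.
#' @param genome named character vector of chromosome sequences.
#' @param min_reads minimum summed stack count.
#' @param mature_len closed mature length range.
#' @param window precursor window length (nt).
#' @param n_offsets number of precursor windows tried per stack.
#' @param max_fold_score acceptance threshold on fold_score (model units).
#' @param max_unpaired maximum unpaired mature bases.
#' @param min_stack_gap stacks closer than this (bp, same strand) to a
#'   stronger stack are suppressed before folding.
#' @return data.frame of \code{HairpinCandidate} records.
#' @export
discover_novel <- function(placements, annotation, genome,
                           min_reads = 5L, mature_len = c(20L, 24L),
                           window = 160L, n_offsets = 9L,
                           max_fold_score = -15, max_unpaired = 4L,
                           min_stack_gap = 200L) {
  empty <- data.frame(
    name = character(0), family = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    precursor_seq = character(0), structure = character(0),
    fold_score = numeric(0), mature_arm = character(0),
    mature_seq = character(0), star_seq = character(0),
    reads_5p = numeric(0), reads_3p = numeric(0), guide_arm = character(0),
    stringsAsFactors = FALSE)
  h <- placements$hits
  h <- h[h$length >= mature_len[1] & h$length <= mature_len[2], , drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  pos5 <- ifelse(h$strand == "+", h$start, h$end - 1L)
  key <- paste(h$chrom, pos5, h$strand)
  agg <- rowsum(h$count, group = key)
  # representative (most abundant) read per stack
  ord <- order(key, -h$count)
  first <- !duplicated(key[ord])
  rep_idx <- ord[first]
  stacks <- data.frame(
    chrom = h$chrom[rep_idx], pos5 = pos5[rep_idx],
    strand = h$strand[rep_idx],
    start = h$start[rep_idx], end = h$end[rep_idx],
    seq = placements$reads$seq[h$read_id[rep_idx]],
    total = agg[match(key[rep_idx], rownames(agg)), 1L],
    stringsAsFactors = FALSE)
  stacks <- stacks[stacks$total >= min_reads, , drop = FALSE]
  if (nrow(stacks) == 0L) return(empty)
  # drop stacks overlapping disallowed annotation classes
  disallowed <- annotation[!(annotation$feature_class %in% "gene"), , drop = FALSE]
  if (nrow(disallowed)) {
    sgr <- GenomicRanges::GRanges(stacks$chrom,
                                  IRanges::IRanges(stacks$start + 1L, stacks$end))
    agr <- GenomicRanges::GRanges(disallowed$chrom,
                                  IRanges::IRanges(disallowed$start + 1L,
                                                   disallowed$end))
    bad <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(sgr, agr, ignore.strand = TRUE)))
    if (length(bad)) stacks <- stacks[-bad, , drop = FALSE]
  }
  if (nrow(stacks) == 0L) return(empty)
  # suppress weaker stacks near a stronger one (same strand)
  stacks <- stacks[order(-stacks$total, stacks$chrom, stacks$pos5), , drop = FALSE]
  keep <- rep(TRUE, nrow(stacks))
  for (i in seq_len(nrow(stacks))) {
    if (!keep[i]) next
    near <- which(keep & seq_len(nrow(stacks)) > i &
                    stacks$chrom == stacks$chrom[i] &
                    stacks$strand == stacks$strand[i] &
                    abs(stacks$pos5 - stacks$pos5[i]) < min_stack_gap)
    keep[near] <- FALSE
  }
  stacks <- stacks[keep, , drop = FALSE]
  cands <- list()
  for (i in seq_len(nrow(stacks))) {
    st <- stacks[i, ]
    cand <- fold_stack(st, genome, window, n_offsets, max_fold_score,
                       max_unpaired)
    if (!is.null(cand)) cands[[length(cands) + 1L]] <- cand
  }
  if (!length(cands)) return(empty)
  out <- do.call(rbind, cands)
  # dedupe overlapping precursors on the same strand (keep best-supported)
  out <- out[order(-(out$reads_5p + out$reads_3p), out$fold_score), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    ov <- which(keep & seq_len(nrow(out)) > i &
                  out$chrom == out$chrom[i] & out$strand == out$strand[i] &
                  out$start < out$end[i] & out$end > out$start[i])
    keep[ov] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  fam <- match(out$mature_seq, unique(out$mature_seq))
  out$family <- sprintf("novel_fam%d", fam)
  nsub <- stats::ave(seq_len(nrow(out)), fam, FUN = seq_along)
  multi <- table(fam)[as.character(fam)] > 1L
  out$name <- ifelse(multi, sprintf("novel-m%d.%d", fam, nsub),
                     sprintf("novel-m%d", fam))
  # reads supporting each arm
  h5 <- placements$hits
  h5 <- h5[h5$length >= mature_len[1] & h5$length <= mature_len[2], , drop = FALSE]
  p5 <- ifelse(h5$strand == "+", h5$start, h5$end - 1L)
  for (i in seq_len(nrow(out))) {
    sel <- h5$chrom == out$chrom[i] & h5$strand == out$strand[i] &
      p5 >= out$start[i] & p5 < out$end[i]
    if (!any(sel)) next
    # precursor index (1-based, 5'->3') of each supporting read's 5' end
    idx <- if (out$strand[i] == "+") p5[sel] - out$start[i] + 1L else
      out$end[i] - p5[sel]
    mid <- out$loop_mid[i]
    out$reads_5p[i] <- sum(h5$count[sel][idx <= mid])
    out$reads_3p[i] <- sum(h5$count[sel][idx > mid])
  }
  out$guide_arm <- ifelse(out$reads_5p >= out$reads_3p, "5p", "3p")
  rownames(out) <- NULL
  out[, c("name", "family", "chrom", "start", "end", "strand",
          "precursor_seq", "structure", "fold_score", "mature_arm",
          "mature_seq", "star_seq", "reads_5p", "reads_3p", "guide_arm")]
}

# fold candidate precursor windows around one read stack; return the best
# accepted HairpinCandidate row or NULL
fold_stack <- function(st, genome, window, n_offsets, max_fold_score,
                       max_unpaired) {
  chrlen <- nchar(genome[[st$chrom]])
  L <- st$end - st$start
  fracs <- seq(0.1, 0.9, length.out = n_offsets)
  best <- NULL
  for (f in fracs) {
    if (st$strand == "+") {
      ws <- st$start - as.integer(round((window - L) * f))
    } else {
      ws <- st$start - as.integer(round((window - L) * (1 - f)))
    }
    ws <- max(0L, min(ws, chrlen - window))
    we <- ws + window
    if (st$start < ws || st$end > we) next
    pre <- substr(genome[[st$chrom]], ws + 1L, we)
    m_lo <- st$start - ws + 1L
    m_hi <- st$end - ws
    if (st$strand == "-") {
      pre <- revcomp(pre)
      tmp <- window - m_hi + 1L
      m_hi <- window - m_lo + 1L
      m_lo <- tmp
    }
    fr <- fold_rna(pre)
    if (fr$fold_score > max_fold_score) next
    mpos <- m_lo:m_hi
    partners <- fr$pairs[mpos]
    unpaired <- sum(is.na(partners))
    if (unpaired > max_unpaired) next
    pp <- partners[!is.na(partners)]
    if (!length(pp)) next
    if (all(pp > m_hi)) {
      arm <- "5p"
    } else if (all(pp < m_lo)) {
      arm <- "3p"
    } else next                       # mature spans the loop / both arms
    star_lo <- min(pp)
    star_hi <- min(window, max(pp) + 2L)
    loop_mid <- if (arm == "5p") floor((m_hi + star_lo) / 2) else
      floor((star_hi - 2L + m_lo) / 2)
    cand <- data.frame(
      name = "", family = "", chrom = st$chrom,
      start = ws, end = we, strand = st$strand,
      precursor_seq = pre, structure = fr$structure,
      fold_score = fr$fold_score, mature_arm = arm,
      mature_seq = st$seq,
      star_seq = substr(pre, star_lo, star_hi),
      reads_5p = 0, reads_3p = 0, guide_arm = arm, loop_mid = loop_mid,
      stringsAsFactors = FALSE)
    if (is.null(best) || cand$fold_score < best$fold_score) best <- cand
  }
  best
}

#' Write hairpin candidates in a Vienna-style structure layout
#'
#' For each candidate: a FASTA-like header, the precursor sequence, and
#' its dot-bracket structure with the fold score.
#'
#' @param candidates output of \code{\link{discover_novel}}.
#' @param path output path.
#' @export
write_hairpins <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(candidates))) {
    writeLines(sprintf(">%s %s:%d-%d(%s) guide=%s",
                       candidates$name[i], candidates$chrom[i],
                       candidates$start[i], candidates$end[i],
                       candidates$strand[i], candidates$guide_arm[i]), con)
    writeLines(candidates$precursor_seq[i], con)
    writeLines(sprintf("%s (%.1f)", candidates$structure[i],
                       candidates$fold_score[i]), con)
  }
  invisible(path)
}
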