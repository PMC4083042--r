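# Clone-based bisulfite methylation analysis: bisulfite-aware global
# alignment of clones to their reference locus, per-cytosine context
# classification (CG / CHG / CHH), per-context percent methylation and
# genotype differencing.
#
# Only the top (bisulfite-converted) strand of each amplicon is analyzed;
# reverse-orientation clones are recovered by also trying the reverse
# complement and keeping the orientation with the better identity.

# asymmetric substitution scores: aligning clone base (row) to reference
# base (column); reference C read as clone T is a conversion, cost 0
bisulfite_submat <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 0
  m["T", "C"] <- 0   # bisulfite conversion
  m["N", ] <- -1; m[, "N"] <- -1
  m
}

#' Bisulfite-aware global alignment of a clone to its reference
#'
#' Needleman-Wunsch global alignment under a bisulfite-aware substitution
#' rule: reference C aligned to clone T costs 0 (conversion), identical
#' bases cost 0, any other substitution costs 1, each gap base costs 2
#' (scores are the negated costs).  The clone is also aligned in reverse
#' complement and the orientation with the higher identity is kept.
#' Alignment identity (computed excluding reference-C-to-clone-T
#' positions) below \code{min_identity} rejects the clone.
#'
#' @param clone_seq clone nucleotide string.
#' @param locus_ref reference locus nucleotide string (top strand).
#' @param min_identity identity threshold for acceptance.
#' @return list of class \code{clone_alignment}: \code{score} (negated
#'   cost), \code{identity}, \code{orientation} (\code{"fwd"} /
#'   \code{"rev"}), \code{accepted}, and \code{pairing} -- a character
#'   vector over reference positions giving the aligned clone base
#'   (\code{"-"} where the clone has a gap).
#' @export
align_clone <- function(clone_seq, locus_ref, min_identity = 0.9) {
  clone_seq <- normalize_seq(clone_seq)
  locus_ref <- normalize_seq(locus_ref)
  if (nchar(clone_seq) < 0.5 * nchar(locus_ref) ||
      nchar(clone_seq) > 1.1 * nchar(locus_ref))
    stop("clone length outside 50-110% of the reference length")
  cand <- lapply(c(fwd = clone_seq, rev = revcomp(clone_seq)),
                 align_clone_one, locus_ref = locus_ref)
  best <- if (cand$fwd$identity >= cand$rev$identity) "fwd" else "rev"
  out <- cand[[best]]
  out$orientation <- best
  out$accepted <- out$identity >= min_identity
  class(out) <- "clone_alignment"
  out
}

align_clone_one <- function(clone_seq, locus_ref) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = clone_seq, subject = locus_ref,
    substitutionMatrix = bisulfite_submat(),
    gapOpening = 0, gapExtension = 2, type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  pairing <- rep("-", nchar(locus_ref))
  refpos <- 0L
  n_cmp <- 0L; n_match <- 0L
  for (k in seq_along(as_)) {
    if (as_[k] != "-") {
      refpos <- refpos + 1L
      pairing[refpos] <- ap[k]
      if (!(as_[k] == "C" && ap[k] == "T")) {  # conversions excluded
        n_cmp <- n_cmp + 1L
        if (ap[k] == as_[k]) n_match <- n_match + 1L
      }
    } else {
      n_cmp <- n_cmp + 1L                      # clone insertion counts against
    }
  }
  list(score = Biostrings::score(pa), pairing = pairing,
       identity = if (n_cmp > 0) n_match / n_cmp else 0)
}

#' Classify reference cytosine contexts
#'
#' For a reference C at 0-based position i: CG if ref[i+1] == G, else CHG
#' if ref[i+2] == G, else CHH (H = A/C/T).  Cs whose context is undefined
#' because it runs off the locus end are excluded.
#'
#' @param locus_ref reference sequence.
#' @return data.frame \code{position} (0-based), \code{context}.
#' @export
cytosine_contexts <- function(locus_ref) {
  s <- strsplit(normalize_seq(locus_ref), "")[[1]]
  n <- length(s)
  pos <- which(s == "C")
  ctx <- character(length(pos))
  keep <- logical(length(pos))
  for (k in seq_along(pos)) {
    i <- pos[k]
    if (i + 1L <= n && s[i + 1L] == "G") {
      ctx[k] <- "CG"; keep[k] <- TRUE
    } else if (i + 1L <= n && i + 2L <= n) {
      ctx[k] <- if (s[i + 2L] == "G") "CHG" else "CHH"
      keep[k] <- TRUE
    }                                   # else: undefined near the end
  }
  data.frame(position = pos[keep] - 1L, context = ctx[keep],
             stringsAsFactors = FALSE)
}

#' Call per-clone methylation states at reference cytosines
#'
#' At each in-bounds reference C: clone base C = methylated, T =
#' unmethylated, gap or any other base = uncovered.
#'
#' @param alignments list of accepted \code{clone_alignment} objects.
#' @param locus_ref reference sequence.
#' @param locus_id locus identifier attached to every row.
#' @return data.frame \code{locus_id}, \code{clone}, \code{position},
#'   \code{context}, \code{state}.
#' @export
call_sites <- function(alignments, locus_ref, locus_id = "locus") {
  ctx <- cytosine_contexts(locus_ref)
  out <- lapply(seq_along(alignments), function(ci) {
    al <- alignments[[ci]]
    base <- al$pairing[ctx$position + 1L]
    state <- ifelse(base == "C", "methylated",
                    ifelse(base == "T", "unmethylated", "uncovered"))
    data.frame(locus_id = locus_id, clone = ci, position = ctx$position,
               context = ctx$context, state = state,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

wilson_interval <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, mid - half), min(1, mid + half))
}

#' Summarize per-context methylation for one locus and genotype
#'
#' States are pooled across clones per context; percent = 100 *
#' n_methylated / n_total over covered sites, with a Wilson 95% interval.
#' A context with no covered sites is emitted with missing percent.
#'
#' @param sites data.frame from \code{\link{call_sites}}.
#' @param genotype genotype label attached to the rows.
#' @param control_positions optional 0-based reference-C positions assumed
#'   unmethylated; the fraction read as T there is reported as the
#'   conversion estimate (attribute \code{conversion_estimate}).
#' @return data.frame \code{locus_id}, \code{genotype}, \code{context},
#'   \code{n_methylated}, \code{n_total}, \code{percent}, \code{ci_lo},
#'   \code{ci_hi}.
#' @export
summarize_locus <- function(sites, genotype, control_positions = NULL) {
  out <- lapply(c("CG", "CHG", "CHH"), function(cx) {
    d <- sites[sites$context == cx & sites$state != "uncovered", , drop = FALSE]
    n <- nrow(d)
    x <- sum(d$state == "methylated")
    ci <- wilson_interval(x, n)
    data.frame(locus_id = sites$locus_id[1] %||% "locus", genotype = genotype,
               context = cx, n_methylated = x, n_total = n,
               percent = if (n > 0) 100 * x / n else NA_real_,
               ci_lo = 100 * ci[1], ci_hi = 100 * ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(control_positions)) {
    d <- sites[sites$position %in% control_positions &
                 sites$state != "uncovered", , drop = FALSE]
    attr(out, "conversion_estimate") <-
      if (nrow(d)) sum(d$state == "unmethylated") / nrow(d) else NA_real_
  }
  out
}

#' Per-context genotype difference in percent methylation
#'
#' Point differences in percentage points (mutant minus wild type) with a
#' two-proportion z-test p-value on the pooled site calls (a descriptive
#' stand-in; the underlying comparison is of raw percentages).
#'
#' @param summary_mut,summary_wt outputs of \code{\link{summarize_locus}}
#'   for the same locus.
#' @return data.frame \code{locus_id}, \code{context}, \code{percent_mut},
#'   \code{percent_wt}, \code{delta_points}, \code{p_value}.
#' @export
diff_genotypes <- function(summary_mut, summary_wt) {
  stopifnot(identical(summary_mut$locus_id[1], summary_wt$locus_id[1]))
  out <- lapply(c("CG", "CHG", "CHH"), function(cx) {
    m <- summary_mut[summary_mut$context == cx, ]
    w <- summary_wt[summary_wt$context == cx, ]
    pm <- m$percent; pw <- w$percent
    pv <- NA_real_
    if (!is.na(pm) && !is.na(pw) && m$n_total > 0 && w$n_total > 0) {
      pv <- tryCatch(stats::prop.test(
        c(m$n_methylated, w$n_methylated),
        c(m$n_total, w$n_total), correct = FALSE)$p.value,
        warning = function(wn) suppressWarnings(stats::prop.test(
          c(m$n_methylated, w$n_methylated),
          c(m$n_total, w$n_total), correct = FALSE)$p.value))
    }
    data.frame(locus_id = m$locus_id, context = cx,
               percent_mut = pm, percent_wt = pw,
               delta_points = if (!is.na(pm) && !is.na(pw)) pm - pw else NA_real_,
               p_value = pv, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Text lollipop report of per-clone methylation states
#'
#' One line per clone: \code{*} methylated, \code{o} unmethylated,
#' \code{.} uncovered, ordered by reference position, preceded by a
#' context key line (G = CG, H = CHG, h = CHH).
#'
#' @param sites data.frame from \code{\link{call_sites}}.
#' @param path output path.
#' @export
lollipop_report <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pos <- sort(unique(sites$position))
  ctx <- sites$context[match(pos, sites$position)]
  key <- c(CG = "G", CHG = "H", CHH = "h")[ctx]
  writeLines(sprintf("# locus %s: %d cytosines, %d clones",
                     sites$locus_id[1], length(pos),
                     length(unique(sites$clone))), con)
  writeLines(paste0("ctx    ", paste0(key, collapse = "")), con)
  glyph <- c(methylated = "*", unmethylated = "o", uncovered = ".")
  for (cl in sort(unique(sites$clone))) {
    d <- sites[sites$clone == cl, ]
    line <- glyph[d$state[match(pos, d$position)]]
    writeLines(sprintf("c%-5d %s", cl, paste0(line, collapse = "")), con)
  }
  invisible(path)
}
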