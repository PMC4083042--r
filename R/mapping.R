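# Exact-match placement of collapsed smRNA reads on the genome and the
# size / category profiles derived from the placed library.
#
# Matching is exact (0 mismatches) on both strands; multi-mapped reads are
# kept with all their hits and contribute a full count at every hit
# downstream.  Hits of palindromic reads (seq == its reverse complement)
# are canonicalized to the + strand so a site is never double counted.

#' Build an exact-match genome index
#'
#' @param genome named character vector of chromosome sequences.
#' @return object of class \code{genome_index} used by
#'   \code{\link{map_reads}}.
#' @export
build_index <- function(genome) {
  stopifnot(length(genome) > 0, !is.null(names(genome)),
            !anyDuplicated(names(genome)))
  structure(list(
    chroms = Biostrings::DNAStringSet(genome),
    names = names(genome),
    lengths = nchar(genome)
  ), class = "genome_index")
}

#' Map collapsed reads to the genome by exact matching
#'
#' All exact hits on both strands are reported; reads with no hit are
#' retained with \code{n_hits == 0}.  A read hits the minus strand at a
#' site when its reverse complement matches the plus-strand sequence there.
#'
#' @param lib an \code{smrna_library} data.frame (\code{seq}, \code{count},
#'   \code{length}).
#' @param index a \code{genome_index}.
#' @return object of class \code{read_placements}: list with \code{reads}
#'   (the library plus \code{n_hits}) and \code{hits} (data.frame
#'   \code{read_id}, \code{chrom}, \code{start}, \code{end}, \code{strand},
#'   \code{count}, \code{length}; 0-based half-open).
#' @export
map_reads <- function(lib, index) {
  stopifnot(inherits(index, "genome_index"))
  empty_hits <- data.frame(read_id = integer(0), chrom = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0), count = integer(0),
                           length = integer(0), stringsAsFactors = FALSE)
  if (nrow(lib) == 0L) {
    reads <- lib
    reads$n_hits <- integer(0)
    return(structure(list(reads = reads, hits = empty_hits),
                     class = "read_placements"))
  }
  rc <- revcomp(lib$seq)
  palindromic <- lib$seq == rc
  out <- vector("list", 0L)
  # one variable-width dictionary per strand orientation (trusted band =
  # the shortest read length; matchPDict verifies the remainder exactly)
  tb <- min(lib$length)
  pd_fwd <- Biostrings::PDict(Biostrings::DNAStringSet(lib$seq),
                              tb.start = 1L, tb.width = tb)
  pd_rev <- Biostrings::PDict(Biostrings::DNAStringSet(rc),
                              tb.start = 1L, tb.width = tb)
  for (ci in seq_along(index$chroms)) {
    chr <- index$chroms[[ci]]
    for (str in c("+", "-")) {
      pd <- if (str == "+") pd_fwd else pd_rev
      mi <- Biostrings::matchPDict(pd, chr, max.mismatch = 0)
      st <- Biostrings::startIndex(mi)
      lens <- lengths(st)
      if (sum(lens) == 0L) next
      rid <- rep(seq_len(nrow(lib)), lens)
      starts0 <- unlist(st, use.names = FALSE) - 1L
      keep <- !(palindromic[rid] & str == "-")
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        read_id = rid[keep], chrom = index$names[ci],
        start = starts0[keep], end = starts0[keep] + lib$length[rid[keep]],
        strand = str, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else empty_hits[, 1:5]
  hits <- hits[order(hits$read_id, hits$chrom, hits$start, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits$count <- lib$count[hits$read_id]
  hits$length <- lib$length[hits$read_id]
  reads <- as.data.frame(lib)
  reads$n_hits <- tabulate(hits$read_id, nbins = nrow(lib))
  structure(list(reads = reads, hits = hits), class = "read_placements")
}

#' Size distribution of a collapsed library
#'
#' Counts are weighted by collapsed read counts.  Lengths outside 18--26 nt
#' are tallied in an \code{"other"} bin that is excluded from the
#' fractions.
#'
#' @param lib an \code{smrna_library} data.frame.
#' @param range inclusive length range reported per-length.
#' @return data.frame with columns \code{length} (character; includes
#'   \code{"other"}), \code{count}, \code{fraction} (NA for "other").
#' @export
profile_sizes <- function(lib, range = c(18L, 26L)) {
  lens <- range[1]:range[2]
  counts <- vapply(lens, function(L) sum(lib$count[lib$length == L]),
                   numeric(1))
  other <- sum(lib$count[lib$length < range[1] | lib$length > range[2]])
  tot <- sum(counts)
  data.frame(
    length = c(as.character(lens), "other"),
    count = c(counts, other),
    fraction = c(if (tot > 0) counts / tot else rep(0, length(counts)), NA),
    stringsAsFactors = FALSE)
}

# default assignment priority when a read's hits overlap several classes
CATEGORY_PRIORITY <- c("known_miRNA_locus", "rRNA", "tRNA", "snoRNA",
                       "snRNA", "repeat", "TE", "gene", "unannotated")

#' Category profile of a placed library
#'
#' Each read is assigned exactly one category: the highest-priority feature
#' class overlapped by any of its hits, with unmapped (and
#' nothing-overlapping) reads falling to \code{"unannotated"}.
#'
#' @param placements a \code{read_placements} object.
#' @param annotation annotation data.frame.
#' @param priority category priority order, highest first.
#' @return data.frame \code{category}, \code{count}, \code{fraction}.
#' @export
profile_categories <- function(placements, annotation,
                               priority = CATEGORY_PRIORITY) {
  reads <- placements$reads
  hits <- placements$hits
  cat_per_read <- rep("unannotated", nrow(reads))
  if (nrow(hits) > 0L && nrow(annotation) > 0L) {
    hgr <- GenomicRanges::GRanges(hits$chrom,
                                  IRanges::IRanges(hits$start + 1L, hits$end))
    agr <- GenomicRanges::GRanges(annotation$chrom,
                                  IRanges::IRanges(annotation$start + 1L,
                                                   annotation$end))
    ov <- GenomicRanges::findOverlaps(hgr, agr, ignore.strand = TRUE)
    if (length(ov)) {
      rid <- hits$read_id[S4Vectors::queryHits(ov)]
      cls <- annotation$feature_class[S4Vectors::subjectHits(ov)]
      rank <- match(cls, priority)
      best <- tapply(rank, rid, min)
      cat_per_read[as.integer(names(best))] <- priority[best]
    }
  }
  counts <- vapply(priority, function(p) {
    sum(reads$count[cat_per_read == p])
  }, numeric(1))
  tot <- sum(counts)
  data.frame(category = priority, count = unname(counts),
             fraction = if (tot > 0) unname(counts) / tot else rep(0, length(counts)),
             stringsAsFactors = FALSE)
}

#' Export placements as BED6
#'
#' One line per hit; the score column carries the collapsed read count.
#'
#' @param placements a \code{read_placements} object.
#' @param path output path.
#' @export
placements_to_bed <- function(placements, path) {
  h <- placements$hits
  lines <- sprintf("%s\t%d\t%d\tread%d\t%d\t%s",
                   h$chrom, h$start, h$end, h$read_id, h$count, h$strand)
  writeLines(lines, path)
  invisible(path)
}
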