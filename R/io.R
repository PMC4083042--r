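# Readers/writers for the standard formats the pipeline touches, plus the
# shared coordinate convention: all intervals are 0-based half-open
# internally; GFF3 is emitted/consumed 1-based closed, BED 0-based half-open.

#' Read a FASTA file
#'
#' Sequences are uppercased and U is converted to T so that all downstream
#' matching happens in the DNA alphabet.  Record order is preserved and
#' names must be unique.
#'
#' A small line-oriented reader is used (rather than a DNAStringSet import)
#' so that malformed records can be reported with their line number.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names = record headers up to
#'   the first whitespace).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(structure(character(0), names = character(0)))
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) stop("FASTA parse error at line 1: expected '>' header")
  idx <- which(hdr)
  names_all <- sub("\\s.*$", "", sub("^>", "", lines[idx]))
  if (any(!nzchar(names_all))) {
    stop("FASTA parse error at line ", idx[which(!nzchar(names_all))[1L]],
         ": empty header")
  }
  if (anyDuplicated(names_all)) {
    dup <- names_all[duplicated(names_all)][1L]
    stop("duplicate FASTA record name: ", dup)
  }
  grp <- cumsum(hdr)
  seqs <- vapply(seq_along(idx), function(i) {
    paste0(lines[grp == i & !hdr], collapse = "")
  }, character(1))
  if (any(!nzchar(seqs))) {
    stop("FASTA parse error at line ", idx[which(!nzchar(seqs))[1L]],
         ": record '", names_all[which(!nzchar(seqs))[1L]],
         "' has an empty sequence")
  }
  structure(normalize_seq(seqs), names = names_all)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width in bases.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read and collapse a small-RNA library
#'
#' Identical sequences are collapsed with summed counts.  Reads outside
#' 15--35 nt are dropped (tallied), and reads containing characters other
#' than A/C/G/T after U-to-T conversion (including N) are rejected
#' (tallied): only exactly mappable clean reads enter the analysis.
#'
#' FASTA headers of the form \code{name_x<count>} (the collapsed-library
#' dialect written by \code{\link{write_smrna_library}}) are interpreted as
#' pre-collapsed counts.
#'
#' @param path input file.
#' @param fmt \code{"fasta"} or \code{"fastq"} (phred+33; qualities are
#'   validated for length and otherwise ignored).
#' @return a \code{data.frame} of class \code{smrna_library} with columns
#'   \code{seq}, \code{count}, \code{length}, and attributes
#'   \code{total_input} (input read count), \code{total_clean} (clean reads
#'   kept), \code{n_rejected} and \code{n_out_of_range}.
#' @export
read_smrna_library <- function(path, fmt = c("fasta", "fastq")) {
  fmt <- match.arg(fmt)
  if (fmt == "fasta") {
    recs <- read_fasta_multiset(path)
    seqs <- recs$seq
    counts <- recs$count
  } else {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) %% 4L != 0L) {
      stop("FASTQ parse error: line count ", length(lines),
           " is not a multiple of 4")
    }
    n <- length(lines) %/% 4L
    if (n > 0L) {
      at <- lines[seq(1L, length(lines), by = 4L)]
      plus <- lines[seq(3L, length(lines), by = 4L)]
      bad <- which(!startsWith(at, "@") | !startsWith(plus, "+"))
      if (length(bad)) {
        stop("FASTQ parse error at line ", (bad[1L] - 1L) * 4L + 1L,
             ": malformed record")
      }
      seqs <- normalize_seq(lines[seq(2L, length(lines), by = 4L)])
      quals <- lines[seq(4L, length(lines), by = 4L)]
      if (any(nchar(quals) != nchar(seqs))) {
        stop("FASTQ parse error: quality/sequence length mismatch at record ",
             which(nchar(quals) != nchar(seqs))[1L])
      }
    } else {
      seqs <- character(0)
    }
    counts <- rep(1L, length(seqs))
  }
  collapse_reads(seqs, counts)
}

# FASTA reader that also decodes the name_x<count> collapsed dialect
read_fasta_multiset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(seq = character(0), count = integer(0)))
  }
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) stop("FASTA parse error at line 1: expected '>' header")
  grp <- cumsum(hdr)
  idx <- which(hdr)
  nm <- sub("\\s.*$", "", sub("^>", "", lines[idx]))
  cnt <- suppressWarnings(as.integer(sub("^.*_x(\\d+)$", "\\1", nm)))
  cnt[!grepl("_x\\d+$", nm)] <- 1L
  cnt[is.na(cnt)] <- 1L
  seqs <- vapply(seq_along(idx), function(i) {
    paste0(lines[grp == i & !hdr], collapse = "")
  }, character(1))
  data.frame(seq = normalize_seq(seqs), count = cnt,
             stringsAsFactors = FALSE)
}

#' @rdname read_smrna_library
#' @param seqs character vector of read sequences (already normalized).
#' @param counts integer vector of per-sequence copy counts.
#' @export
collapse_reads <- function(seqs, counts = rep(1L, length(seqs))) {
  stopifnot(length(seqs) == length(counts))
  total_input <- sum(counts)
  ok_alpha <- is_dna(seqs)
  n_rejected <- sum(counts[!ok_alpha])
  seqs <- seqs[ok_alpha]; counts <- counts[ok_alpha]
  len <- nchar(seqs)
  in_range <- len >= 15L & len <= 35L
  n_oor <- sum(counts[!in_range])
  seqs <- seqs[in_range]; counts <- counts[in_range]
  if (length(seqs)) {
    agg <- rowsum(counts, group = seqs)
    lib <- data.frame(seq = rownames(agg), count = as.integer(agg[, 1L]),
                      stringsAsFactors = FALSE)
    lib <- lib[order(lib$seq), , drop = FALSE]
    rownames(lib) <- NULL
  } else {
    lib <- data.frame(seq = character(0), count = integer(0))
  }
  lib$length <- nchar(lib$seq)
  structure(lib,
            total_input = total_input,
            total_clean = sum(lib$count),
            n_rejected = n_rejected,
            n_out_of_range = n_oor,
            class = c("smrna_library", "data.frame"))
}

#' Write a collapsed small-RNA library as FASTA
#'
#' Headers carry the collapsed count in the \code{read<i>_x<count>} dialect.
#'
#' @param lib an \code{smrna_library} data.frame.
#' @param path output path.
#' @export
write_smrna_library <- function(lib, path) {
  seqs <- lib$seq
  names(seqs) <- sprintf("read%d_x%d", seq_along(seqs), lib$count)
  write_fasta(seqs, path)
}

# documented mapping from annotation source types to the closed feature
# class set used throughout the pipeline
FEATURE_CLASS_MAP <- c(
  gene = "gene", mRNA = "gene", protein_coding_gene = "gene",
  transposable_element = "TE", transposable_element_gene = "TE",
  transposon_fragment = "TE", TE = "TE",
  miRNA = "known_miRNA_locus", miRNA_primary_transcript = "known_miRNA_locus",
  known_miRNA_locus = "known_miRNA_locus",
  rRNA = "rRNA", tRNA = "tRNA", snoRNA = "snoRNA", snRNA = "snRNA",
  repeat_region = "repeat", dispersed_repeat = "repeat", `repeat` = "repeat"
)

FEATURE_CLASSES <- c("gene", "TE", "known_miRNA_locus", "rRNA", "tRNA",
                     "snoRNA", "snRNA", "repeat", "other")

map_feature_class <- function(type) {
  cls <- unname(FEATURE_CLASS_MAP[type])
  cls[is.na(cls)] <- "other"
  cls
}

#' Read genome annotation from GFF3 or BED
#'
#' Intervals are normalized to the internal 0-based half-open convention.
#' GFF3 feature types are mapped onto the closed feature-class set
#' \code{gene, TE, known_miRNA_locus, rRNA, tRNA, snoRNA, snRNA, repeat,
#' other}; in BED the class is taken from the name column written as
#' \code{<class>:<feature_id>} (unknown classes fall back to
#' \code{"other"}).  Per-gene GO identifiers are read from the GFF3
#' \code{go} attribute (comma-separated).
#'
#' @param path annotation file.
#' @param dialect \code{"gff3"} (1-based closed) or \code{"bed"} (0-based
#'   half-open).
#' @param genome optional named character vector of chromosome sequences;
#'   when supplied, intervals exceeding a chromosome length raise an error
#'   naming the offending record.
#' @return \code{data.frame} with columns \code{feature_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{feature_class},
#'   \code{go}.
#' @export
read_annotation <- function(path, dialect = c("gff3", "bed"), genome = NULL) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "bed")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # both dialects land 1-based in GRanges
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  md <- S4Vectors::mcols(gr)
  if (dialect == "gff3") {
    df$feature_class <- map_feature_class(as.character(md$type))
    ids <- if ("ID" %in% colnames(md)) as.character(md$ID) else NA_character_
    if (all(is.na(ids)) && "Name" %in% colnames(md)) ids <- as.character(md$Name)
    df$feature_id <- ifelse(is.na(ids) | !nzchar(ids),
                            sprintf("feat%06d", seq_len(nrow(df))), ids)
    go <- if ("go" %in% colnames(md)) as.character(md$go) else NA_character_
    df$go <- ifelse(is.na(go), "", go)
  } else {
    nm <- if ("name" %in% colnames(md)) as.character(md$name) else
      sprintf("feat%06d", seq_len(nrow(df)))
    has_cls <- grepl(":", nm, fixed = TRUE)
    cls <- ifelse(has_cls, sub(":.*$", "", nm), "other")
    df$feature_class <- map_feature_class(cls)
    df$feature_id <- ifelse(has_cls, sub("^[^:]*:", "", nm), nm)
    df$go <- ""
  }
  if (!is.null(genome)) {
    lens <- nchar(genome)[df$chrom]
    bad <- which(is.na(lens) | df$end > lens | df$start < 0L)
    if (length(bad)) {
      stop("annotation record '", df$feature_id[bad[1L]],
           "' exceeds chromosome bounds on ", df$chrom[bad[1L]])
    }
  }
  df[, c("feature_id", "chrom", "start", "end", "strand", "feature_class", "go")]
}

#' Write annotation records
#'
#' @param ann annotation data.frame as returned by
#'   \code{\link{read_annotation}}.
#' @param path output path.
#' @param dialect \code{"gff3"} or \code{"bed"}.
#' @export
write_annotation <- function(ann, path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  ord <- order(ann$chrom, ann$start, ann$feature_id)
  ann <- ann[ord, , drop = FALSE]
  # internal class names back to GFF3 source types
  inv <- c(gene = "gene", TE = "transposable_element",
           known_miRNA_locus = "miRNA", rRNA = "rRNA", tRNA = "tRNA",
           snoRNA = "snoRNA", snRNA = "snRNA", `repeat` = "repeat_region",
           other = "region")
  if (dialect == "gff3") {
    attrs <- sprintf("ID=%s", ann$feature_id)
    has_go <- nzchar(ann$go %||% rep("", nrow(ann)))
    attrs[has_go] <- paste0(attrs[has_go], ";go=", ann$go[has_go])
    lines <- sprintf("%s\tsmrnapipe\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     ann$chrom, inv[ann$feature_class],
                     ann$start + 1L, ann$end,
                     ifelse(ann$strand %in% c("+", "-"), ann$strand, "."),
                     attrs)
    writeLines(c("##gff-version 3", lines), path)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s:%s\t0\t%s",
                     ann$chrom, ann$start, ann$end,
                     ann$feature_class, ann$feature_id,
                     ifelse(ann$strand %in% c("+", "-"), ann$strand, "."))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write a record table as TSV
#'
#' Tab-separated with a header row; doubles rendered with 6 significant
#' digits; rows sorted into genomic order (chrom, start) then by feature id
#' when those columns are present, so output is deterministic.
#'
#' @param records a data.frame.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  df <- as.data.frame(records)
  ord_cols <- intersect(c("chrom", "start", "feature_id", "locus_id",
                          "gene_id", "name"), names(df))
  if (length(ord_cols)) {
    df <- df[do.call(order, df[ord_cols]), , drop = FALSE]
  }
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by \code{write_table}
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
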