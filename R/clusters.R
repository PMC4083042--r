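# Windowed smRNA cluster analysis: per-100 bp-window counting, RPM
# normalization, median-based mutant/WT comparison and log2 fold values
# with a 4-fold differential cut-off.
#
# "Sliding" 100 bp windows are implemented as non-overlapping tiling
# windows (step = width) by default: the fold formula and the chromosome
# tracks treat windows as disjoint clusters, and a 1 bp slide would count
# every read ~100 times.  The step is configurable for sensitivity
# analysis; a read is assigned to every window containing its 5'-most
# genomic base (exactly one under tiling).

#' Count placed reads in genomic windows
#'
#' A hit is assigned to the window containing its 5'-most genomic
#' coordinate (the start for + hits, the last base for - hits); both
#' strands are pooled and multi-mapped reads contribute their full
#' collapsed count at every hit.
#'
#' @param placements a \code{read_placements} object.
#' @param genome named character vector of chromosome sequences (defines
#'   the window tiling).
#' @param size_range closed read-length range counted, default 18--26 nt.
#' @param width window width in bp.
#' @param step window step in bp (default = width: non-overlapping tiling).
#' @return data.frame of class \code{window_profile}: \code{chrom},
#'   \code{start}, \code{end}, \code{raw_count} (windows tile each
#'   chromosome without gaps; the last window may be shorter).
#' @export
count_windows <- function(placements, genome, size_range = c(18L, 26L),
                          width = 100L, step = width) {
  if (size_range[1] < 15L || size_range[2] > 35L || size_range[1] > size_range[2])
    stop("size_range must lie within [15, 35]")
  grid <- window_grid(genome, width, step)
  h <- placements$hits
  h <- h[h$length >= size_range[1] & h$length <= size_range[2], , drop = FALSE]
  raw <- numeric(nrow(grid))
  if (nrow(h)) {
    pos5 <- ifelse(h$strand == "+", h$start, h$end - 1L)
    for (chr in unique(h$chrom)) {
      gsel <- which(grid$chrom == chr)
      if (!length(gsel)) next
      hsel <- h$chrom == chr
      p <- pos5[hsel]; cnt <- h$count[hsel]
      nwin <- length(gsel)
      # windows with start s such that s <= p < s + width, s on the step grid
      jmax <- p %/% step
      jmin <- pmax(0L, (p - width) %/% step + 1L)
      for (off in 0:max(jmax - jmin)) {
        j <- jmax - off
        ok <- j >= jmin & j < nwin
        if (!any(ok)) next
        add <- rowsum(cnt[ok], group = j[ok])
        idx <- gsel[as.integer(rownames(add)) + 1L]
        raw[idx] <- raw[idx] + add[, 1L]
      }
    }
  }
  grid$raw_count <- raw
  class(grid) <- c("window_profile", "data.frame")
  grid
}

window_grid <- function(genome, width = 100L, step = width) {
  out <- lapply(names(genome), function(chr) {
    len <- nchar(genome[[chr]])
    starts <- seq(0L, len - 1L, by = step)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + width, len), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' RPM-normalize a window profile
#'
#' The denominator is the library's total clean-read count (not the mapped
#' subtotal), matching reads-per-million on clean totals.
#'
#' @param profile a \code{window_profile}.
#' @param library_total total clean reads in the library.
#' @return the profile with an \code{rpm} column added.
#' @export
normalize_rpm <- function(profile, library_total) {
  if (!is.numeric(library_total) || library_total <= 0)
    stop("library_total must be a positive clean-read count")
  profile$rpm <- profile$raw_count * 1e6 / library_total
  profile
}

#' Call differential smRNA clusters between genotypes
#'
#' Per window, X and Y are the medians of RPM across the mutant and
#' wild-type libraries respectively (the median of a single library is
#' itself).  The fold value is \code{log2((X + c) / (Y + c))} with
#' pseudocount \code{c} (default 0.5 RPM; the plain \code{log2(X) -
#' log2(Y)} formula is recovered with \code{c = 0} on nonzero windows).
#' A window passes at the cut-off iff \code{|fold_value| >=
#' log2(fold_cutoff)}; all-zero windows (X = Y = 0) never pass.  The
#' threshold is inclusive.
#'
#' @param profiles_mut list of RPM-normalized \code{window_profile}s for
#'   the mutant libraries.
#' @param profiles_wt same for wild type, on the identical window grid.
#' @param fold_cutoff differential cut-off in fold units (default 4).
#' @param pseudocount RPM pseudocount \code{c}.
#' @return data.frame of class \code{differential_clusters}: \code{chrom},
#'   \code{start}, \code{end}, \code{X}, \code{Y}, \code{fold_value},
#'   \code{direction} (up/down/none), \code{passes}.
#' @export
call_differential <- function(profiles_mut, profiles_wt, fold_cutoff = 4,
                              pseudocount = 0.5) {
  if (inherits(profiles_mut, "window_profile")) profiles_mut <- list(profiles_mut)
  if (inherits(profiles_wt, "window_profile")) profiles_wt <- list(profiles_wt)
  stopifnot(length(profiles_mut) >= 1, length(profiles_wt) >= 1)
  g <- profiles_mut[[1]][, c("chrom", "start", "end")]
  for (p in c(profiles_mut, profiles_wt)) {
    if (!identical(p[, c("chrom", "start", "end")], g))
      stop("window grids differ between genotype profiles")
    if (is.null(p$rpm)) stop("profiles must be RPM-normalized first")
  }
  X <- apply(do.call(cbind, lapply(profiles_mut, `[[`, "rpm")), 1L, stats::median)
  Y <- apply(do.call(cbind, lapply(profiles_wt, `[[`, "rpm")), 1L, stats::median)
  fold <- log2((X + pseudocount) / (Y + pseudocount))
  passes <- abs(fold) >= log2(fold_cutoff) & !(X == 0 & Y == 0)
  out <- cbind(g, data.frame(
    X = X, Y = Y, fold_value = fold,
    direction = ifelse(fold > 0, "up", ifelse(fold < 0, "down", "none")),
    passes = passes, stringsAsFactors = FALSE))
  class(out) <- c("differential_clusters", "data.frame")
  out
}

#' Restrict placements to a read-length range
#'
#' Used for the 20--24 nt siRNA-focused subset analysis.
#'
#' @param placements a \code{read_placements} object.
#' @param range closed length range, default \code{c(20, 24)}.
#' @return a \code{read_placements} object containing only reads (and
#'   their hits) whose length lies in the range.
#' @export
subset_by_size <- function(placements, range = c(20L, 24L)) {
  keep_read <- placements$reads$length >= range[1] &
    placements$reads$length <= range[2]
  old_ids <- which(keep_read)
  reads <- placements$reads[keep_read, , drop = FALSE]
  rownames(reads) <- NULL
  hits <- placements$hits[placements$hits$read_id %in% old_ids, , drop = FALSE]
  hits$read_id <- match(hits$read_id, old_ids)
  rownames(hits) <- NULL
  structure(list(reads = reads, hits = hits), class = "read_placements")
}

#' Per-chromosome fold-value tracks
#'
#' One ordered (position, fold_value) series per chromosome, suitable for
#' plotting difference tracks; non-passing windows are included.
#'
#' @param clusters a \code{differential_clusters} data.frame.
#' @return named list of data.frames (\code{position} = window start,
#'   \code{fold_value}, \code{passes}) in genomic order.
#' @export
chromosome_track <- function(clusters) {
  out <- lapply(split(clusters, clusters$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    data.frame(position = d$start, fold_value = d$fold_value,
               passes = d$passes, stringsAsFactors = FALSE)
  })
  out[order(names(out))]
}

#' Export differential clusters as BED6+
#'
#' Columns: chrom, start, end, window id, score = |fold_value| (x100,
#' integer-rounded for BED), strand ".", then X, Y, fold_value, passes.
#'
#' @param clusters a \code{differential_clusters} data.frame.
#' @param path output path.
#' @export
clusters_to_bed <- function(clusters, path) {
  lines <- sprintf("%s\t%d\t%d\twin_%s_%d\t%d\t.\t%g\t%g\t%g\t%d",
                   clusters$chrom, clusters$start, clusters$end,
                   clusters$chrom, clusters$start,
                   as.integer(round(pmin(abs(clusters$fold_value), 10) * 100)),
                   clusters$X, clusters$Y, clusters$fold_value,
                   as.integer(clusters$passes))
  writeLines(lines, path)
  invisible(path)
}
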