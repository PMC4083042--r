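# Orchestration: run every analysis layer on a set of inputs, perform the
# cross-layer associations (smRNA <-> methylation <-> expression,
# miRNA <-> target), and write all tables, the resolved config, a log and
# advisory plots into one run directory.

#' Associate smRNA clusters with methylation and expression changes
#'
#' A differential cluster associates with a locus or gene iff their
#' intervals overlap or lie within \code{max_gap} bp.  The concordance
#' flag records whether the smRNA fold value and the CHH methylation
#' delta share a sign when both are present (the RdDM-style positive
#' correlation).  The distance rule is a stand-in: the association is
#' described only qualitatively in the underlying study design.
#'
#' @param clusters \code{differential_clusters} data.frame (only passing
#'   windows are associated).
#' @param meth_diffs data.frame from \code{\link{diff_genotypes}} rows
#'   (requires \code{locus_id}, \code{context}, \code{delta_points}) plus
#'   locus coordinates (\code{chrom}, \code{start}, \code{end}).
#' @param degs data.frame from \code{\link{call_degs}} plus gene
#'   coordinates via \code{annotation}.
#' @param annotation annotation data.frame (gene coordinates).
#' @param max_gap association distance in bp.
#' @return data.frame of association records: \code{id}, \code{layer}
#'   (\code{locus}/\code{gene}), \code{chrom}, \code{smrna_fold}
#'   (strongest overlapping passing window, NA if none),
#'   \code{meth_delta_chh}, \code{meth_delta_cg}, \code{meth_delta_chg},
#'   \code{expr_direction}, \code{concordance_chh}.
#' @export
associate_layers <- function(clusters, meth_diffs = NULL, degs = NULL,
                             annotation = NULL, max_gap = 1000L) {
  passing <- clusters[clusters$passes, , drop = FALSE]
  assoc_fold <- function(chrom, start, end) {
    sel <- passing$chrom == chrom &
      passing$start <= end + max_gap & passing$end >= start - max_gap
    if (!any(sel)) return(NA_real_)
    f <- passing$fold_value[sel]
    f[which.max(abs(f))]
  }
  out <- list()
  if (!is.null(meth_diffs) && nrow(meth_diffs)) {
    for (lid in unique(meth_diffs$locus_id)) {
      d <- meth_diffs[meth_diffs$locus_id == lid, ]
      fold <- assoc_fold(d$chrom[1], d$start[1], d$end[1])
      chh <- d$delta_points[d$context == "CHH"]
      expr_dir <- NA_character_
      out[[length(out) + 1L]] <- data.frame(
        id = lid, layer = "locus", chrom = d$chrom[1],
        smrna_fold = fold,
        meth_delta_cg = d$delta_points[d$context == "CG"],
        meth_delta_chg = d$delta_points[d$context == "CHG"],
        meth_delta_chh = if (length(chh)) chh else NA_real_,
        expr_direction = expr_dir,
        concordance_chh = if (!is.na(fold) && length(chh) && !is.na(chh) && chh != 0)
          sign(fold) == sign(chh) else NA,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(degs) && !is.null(annotation)) {
    de <- degs[degs$direction != "unchanged", , drop = FALSE]
    for (i in seq_len(nrow(de))) {
      gi <- annotation[annotation$feature_id == de$gene_id[i], ]
      if (nrow(gi) == 0L) next
      fold <- assoc_fold(gi$chrom[1], gi$start[1], gi$end[1])
      out[[length(out) + 1L]] <- data.frame(
        id = de$gene_id[i], layer = "gene", chrom = gi$chrom[1],
        smrna_fold = fold, meth_delta_cg = NA_real_,
        meth_delta_chg = NA_real_, meth_delta_chh = NA_real_,
        expr_direction = de$direction[i], concordance_chh = NA,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(id = character(0), layer = character(0),
                      chrom = character(0), smrna_fold = numeric(0),
                      meth_delta_cg = numeric(0), meth_delta_chg = numeric(0),
                      meth_delta_chh = numeric(0),
                      expr_direction = character(0),
                      concordance_chh = logical(0)))
  }
  do.call(rbind, out)
}

#' Classify miRNA-target expression relationships
#'
#' One record per (miRNA, target) pair in the target table.  Types:
#' I = miRNA down & target up, II = miRNA up & target down, III = both
#' up, IV = both down; \code{"none"} iff either side is unchanged (or
#' missing).
#'
#' @param quants data.frame from \code{\link{quantify_known}}.
#' @param degs data.frame from \code{\link{call_degs}}.
#' @param target_table data.frame \code{mirna_name},
#'   \code{target_gene_id}.
#' @return data.frame with both directions and \code{relation_type}.
#' @export
classify_mirna_targets <- function(quants, degs, target_table) {
  md <- quants$pattern[match(target_table$mirna_name, quants$name)]
  td <- degs$direction[match(target_table$target_gene_id, degs$gene_id)]
  md[is.na(md)] <- "unchanged"
  missing_target <- is.na(td)
  td[missing_target] <- "unchanged"
  rt <- rep("none", nrow(target_table))
  rt[md == "down" & td == "up"] <- "I"
  rt[md == "up" & td == "down"] <- "II"
  rt[md == "up" & td == "up"] <- "III"
  rt[md == "down" & td == "down"] <- "IV"
  data.frame(mirna_name = target_table$mirna_name,
             target_gene_id = target_table$target_gene_id,
             mirna_direction = md, target_direction = td,
             target_missing = missing_target,
             relation_type = rt, stringsAsFactors = FALSE)
}

#' Run the full pipeline on a simulated or user-supplied study
#'
#' Executes map -> size/category profiles -> window clusters (full 18--26
#' and 20--24 nt subset) -> known/novel miRNA -> expression -> methylation
#' -> cross-layer association, and writes every table, the resolved
#' config, a per-stage log and advisory plots into \code{outdir}.
#' Deterministic: identical config + inputs give byte-identical tables.
#'
#' @param study a \code{sim_study} list (see \code{\link{simulate_study}})
#'   or an equivalently shaped list of user inputs.
#' @param outdir run directory (created if needed).
#' @param params list of analysis parameters overriding the defaults
#'   (window_width, size_range, sirna_range, fold_cutoff, pseudocount,
#'   alpha, min_lfc, max_gap, hairpin criteria min_reads /
#'   max_fold_score).
#' @param plots write advisory plots (PDF).
#' @return (invisibly) list of class \code{smrna_run} with every result
#'   table.
#' @export
run_pipeline <- function(study, outdir, params = list(), plots = TRUE) {
  p <- utils::modifyList(list(
    window_width = 100L, size_range = c(18L, 26L), sirna_range = c(20L, 24L),
    fold_cutoff = 4, pseudocount = 0.5, alpha = 0.05, min_lfc = 1,
    max_gap = 1000L, min_reads = 5L, max_fold_score = -15), params)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "run.log")
  logc <- file(logf, "w"); on.exit(close(logc))
  say <- function(...) writeLines(sprintf(...), logc)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  say("smrnapipe run: %d chrom(s), libraries mut=%d wt=%d clean reads",
      length(study$genome),
      attr(study$lib_mut, "total_clean"), attr(study$lib_wt, "total_clean"))
  writeLines(paste(names(p), vapply(p, function(x)
    paste(x, collapse = ","), character(1)), sep = "="),
    file.path(outdir, "config.txt"))

  idx <- stage("index", build_index(study$genome))
  pl_mut <- stage("map", map_reads(study$lib_mut, idx))
  pl_wt <- stage("map", map_reads(study$lib_wt, idx))
  say("mapped: mut %d/%d reads with >=1 hit; wt %d/%d",
      sum(pl_mut$reads$n_hits > 0), nrow(pl_mut$reads),
      sum(pl_wt$reads$n_hits > 0), nrow(pl_wt$reads))

  sizes <- stage("profiles", list(
    mut = profile_sizes(study$lib_mut), wt = profile_sizes(study$lib_wt)))
  cats <- stage("profiles", list(
    mut = profile_categories(pl_mut, study$annotation),
    wt = profile_categories(pl_wt, study$annotation)))
  write_table(cbind(genotype = "mut", sizes$mut), file.path(outdir, "size_profile_mut.tsv"))
  write_table(cbind(genotype = "wt", sizes$wt), file.path(outdir, "size_profile_wt.tsv"))
  write_table(cbind(genotype = "mut", cats$mut), file.path(outdir, "category_profile_mut.tsv"))
  write_table(cbind(genotype = "wt", cats$wt), file.path(outdir, "category_profile_wt.tsv"))

  clusters <- stage("clusters", {
    wm <- normalize_rpm(count_windows(pl_mut, study$genome, p$size_range,
                                      p$window_width),
                        attr(study$lib_mut, "total_clean"))
    ww <- normalize_rpm(count_windows(pl_wt, study$genome, p$size_range,
                                      p$window_width),
                        attr(study$lib_wt, "total_clean"))
    call_differential(wm, ww, p$fold_cutoff, p$pseudocount)
  })
  clusters_sub <- stage("clusters", {
    wm <- normalize_rpm(count_windows(subset_by_size(pl_mut, p$sirna_range),
                                      study$genome, p$sirna_range,
                                      p$window_width),
                        attr(study$lib_mut, "total_clean"))
    ww <- normalize_rpm(count_windows(subset_by_size(pl_wt, p$sirna_range),
                                      study$genome, p$sirna_range,
                                      p$window_width),
                        attr(study$lib_wt, "total_clean"))
    call_differential(wm, ww, p$fold_cutoff, p$pseudocount)
  })
  say("differential clusters: %d passing of %d windows (18-26 nt); %d (20-24 nt)",
      sum(clusters$passes), nrow(clusters), sum(clusters_sub$passes))
  write_table(clusters[clusters$passes, ], file.path(outdir, "clusters_differential.tsv"))
  write_table(clusters_sub[clusters_sub$passes, ],
              file.path(outdir, "clusters_differential_20_24.tsv"))
  clusters_to_bed(clusters[clusters$passes, ], file.path(outdir, "clusters_differential.bed"))

  quants <- stage("mirna", quantify_known(study$lib_mut, study$lib_wt,
                                          study$catalog,
                                          pseudocount = p$pseudocount,
                                          alpha = p$alpha))
  fams <- stage("mirna", family_divergence(quants))
  pooled <- stage("mirna", collapse_reads(
    rep(c(study$lib_mut$seq, study$lib_wt$seq),
        c(study$lib_mut$count, study$lib_wt$count))))
  pl_pooled <- stage("mirna", map_reads(pooled, idx))
  novel <- stage("mirna", discover_novel(pl_pooled, study$annotation,
                                         study$genome,
                                         min_reads = p$min_reads,
                                         max_fold_score = p$max_fold_score))
  novel_q <- stage("mirna", novel_quant(novel, study$lib_mut, study$lib_wt))
  say("miRNA: %d up / %d down / %d unchanged of %d known; %d novel candidates",
      sum(quants$pattern == "up"), sum(quants$pattern == "down"),
      sum(quants$pattern == "unchanged"), nrow(quants), nrow(novel))
  write_table(quants, file.path(outdir, "mirna_known.tsv"))
  write_table(fams, file.path(outdir, "mirna_family_divergence.tsv"))
  write_table(novel, file.path(outdir, "mirna_novel.tsv"))
  write_table(novel_q, file.path(outdir, "mirna_novel_expression.tsv"))
  if (nrow(novel)) write_hairpins(novel, file.path(outdir, "mirna_novel_structures.txt"))

  degs <- stage("expression", call_degs(study$expr$matrix, study$expr$design,
                                        study$annotation, p$alpha, p$min_lfc))
  chromtest <- stage("expression", chrom_distribution_test(degs))
  gop <- stage("expression", go_proportions(degs, study$expr$go_table))
  say("expression: %d up / %d down of %d genes; chrom chi-square p = %.3g",
      sum(degs$direction == "up"), sum(degs$direction == "down"),
      nrow(degs), chromtest$p_value)
  write_table(degs, file.path(outdir, "degs.tsv"))
  write_table(chromtest$table, file.path(outdir, "deg_chrom_distribution.tsv"))
  write_table(data.frame(statistic = chromtest$statistic, df = chromtest$df,
                         p_value = chromtest$p_value),
              file.path(outdir, "deg_chrom_test.tsv"))
  write_table(gop, file.path(outdir, "go_proportions.tsv"))

  meth <- stage("methylation", run_methylation(study$bisulfite))
  write_table(meth$summaries, file.path(outdir, "methylation_summary.tsv"))
  write_table(meth$diffs, file.path(outdir, "methylation_diff.tsv"))

  assoc <- stage("associate", associate_layers(clusters, meth$diffs, degs,
                                               study$annotation, p$max_gap))
  relations <- stage("associate", classify_mirna_targets(
    quants, degs, study$expr$target_table))
  write_table(assoc, file.path(outdir, "associations.tsv"))
  write_table(relations, file.path(outdir, "mirna_target_relations.tsv"))
  say("associations: %d records; target relations: %s",
      nrow(assoc), paste(names(table(relations$relation_type)),
                         table(relations$relation_type),
                         sep = "=", collapse = " "))

  if (plots) plot_run(sizes, clusters, meth$summaries, outdir)

  invisible(structure(list(
    params = p, placements_mut = pl_mut, placements_wt = pl_wt,
    sizes = sizes, categories = cats, clusters = clusters,
    clusters_sub = clusters_sub, quants = quants, families = fams,
    novel = novel, novel_quant = novel_q, degs = degs,
    chrom_test = chromtest, go_proportions = gop,
    methylation = meth, associations = assoc, relations = relations,
    outdir = outdir), class = "smrna_run"))
}

# per-genotype quantification of discovered novel matures (count-test)
novel_quant <- function(novel, lib_mut, lib_wt) {
  if (nrow(novel) == 0L) {
    return(data.frame(name = character(0), count_mut = numeric(0),
                      count_wt = numeric(0), status = character(0)))
  }
  cm <- vapply(novel$mature_seq, isomir_count, numeric(1), lib = lib_mut)
  cw <- vapply(novel$mature_seq, isomir_count, numeric(1), lib = lib_wt)
  data.frame(name = novel$name, count_mut = cm, count_wt = cw,
             status = ifelse(cm > 0 & cw == 0, "mutant_only",
                             ifelse(cw > 0 & cm == 0, "wt_only", "both")),
             stringsAsFactors = FALSE)
}

# run the methylation layer over a bisulfite input block
# (loci manifest with ref_seq + clones[[locus]][[genotype]])
run_methylation <- function(bis) {
  summaries <- list(); diffs <- list()
  for (i in seq_len(nrow(bis$loci))) {
    lid <- bis$loci$locus_id[i]
    ref <- bis$loci$ref_seq[i]
    per_gt <- list()
    for (genotype in c("mut", "wt")) {
      cl <- bis$clones[[lid]][[genotype]]
      al <- lapply(cl, align_clone, locus_ref = ref)
      al <- al[vapply(al, `[[`, logical(1), "accepted")]
      sites <- call_sites(al, ref, lid)
      per_gt[[genotype]] <- summarize_locus(sites, genotype)
    }
    summaries[[lid]] <- rbind(per_gt$mut, per_gt$wt)
    d <- diff_genotypes(per_gt$mut, per_gt$wt)
    d$chrom <- bis$loci$chrom[i]
    d$start <- bis$loci$start[i]
    d$end <- bis$loci$end[i]
    diffs[[lid]] <- d
  }
  list(summaries = do.call(rbind, summaries), diffs = do.call(rbind, diffs))
}

plot_run <- function(sizes, clusters, meth_summaries, outdir) {
  grDevices::pdf(file.path(outdir, "plots.pdf"), width = 9, height = 6)
  on.exit(grDevices::dev.off())
  # size histogram
  sm <- sizes$mut[sizes$mut$length != "other", ]
  sw <- sizes$wt[sizes$wt$length != "other", ]
  bp <- rbind(mut = sm$fraction, wt = sw$fraction)
  graphics::barplot(bp, beside = TRUE, names.arg = sm$length,
                    col = c("firebrick", "steelblue"),
                    xlab = "read length (nt)", ylab = "fraction of reads",
                    main = "smRNA size distribution")
  graphics::legend("topright", c("mutant", "WT"),
                   fill = c("firebrick", "steelblue"))
  # per-chromosome fold tracks
  tracks <- chromosome_track(clusters)
  graphics::par(mfrow = c(length(tracks), 1), mar = c(2, 4, 1, 1))
  for (ch in names(tracks)) {
    t <- tracks[[ch]]
    graphics::plot(t$position, t$fold_value, type = "h",
                   col = ifelse(t$passes, "firebrick", "grey70"),
                   ylab = "log2 fold", main = ch, cex.main = 0.9)
  }
  graphics::par(mfrow = c(1, 1))
  # methylation bars
  if (!is.null(meth_summaries) && nrow(meth_summaries)) {
    loci <- unique(meth_summaries$locus_id)
    graphics::par(mfrow = c(2, ceiling(length(loci) / 2)),
                  mar = c(3, 4, 2, 1))
    for (lid in loci) {
      d <- meth_summaries[meth_summaries$locus_id == lid, ]
      m <- matrix(d$percent[order(d$genotype, d$context)], nrow = 2,
                  byrow = TRUE, dimnames = list(sort(unique(d$genotype)),
                                                c("CG", "CHG", "CHH")))
      graphics::barplot(m, beside = TRUE, ylim = c(0, 100),
                        col = c("firebrick", "steelblue"),
                        main = lid, ylab = "% methylation", cex.main = 0.8)
    }
    graphics::par(mfrow = c(1, 1))
  }
  invisible(NULL)
}

#' @export
print.smrna_run <- function(x, ...) {
  cat("smrnapipe run (", x$outdir, ")\n", sep = "")
  cat(sprintf("  differential clusters : %d passing of %d windows\n",
              sum(x$clusters$passes), nrow(x$clusters)))
  cat(sprintf("  known miRNAs          : %d up / %d down / %d unchanged\n",
              sum(x$quants$pattern == "up"), sum(x$quants$pattern == "down"),
              sum(x$quants$pattern == "unchanged")))
  cat(sprintf("  novel miRNA candidates: %d\n", nrow(x$novel)))
  cat(sprintf("  DEGs                  : %d up / %d down (chi-square p = %.3g)\n",
              sum(x$degs$direction == "up"), sum(x$degs$direction == "down"),
              x$chrom_test$p_value))
  cat(sprintf("  methylation loci      : %d\n",
              length(unique(x$methylation$summaries$locus_id))))
  invisible(x)
}

#' Compare called clusters with the planted differential-window truth
#'
#' Sensitivity = clearly planted differential windows recovered (passing,
#' correct direction) / clearly planted, where "clear" plantings are those
#' whose expected ratio is safely away from the calling cut-off (the
#' truth table's \code{clear} flag); precision = passing windows that are
#' planted (clear or borderline) / passing.
#'
#' @param clusters \code{differential_clusters} data.frame.
#' @param diff_windows truth table (\code{chrom}, \code{window_start},
#'   \code{direction}, optional \code{clear}).
#' @return list \code{sensitivity}, \code{precision}, \code{n_passing},
#'   \code{n_planted}.
#' @export
evaluate_cluster_calls <- function(clusters, diff_windows) {
  if (is.null(diff_windows$clear)) diff_windows$clear <- TRUE
  passing <- clusters[clusters$passes, , drop = FALSE]
  clear <- diff_windows[diff_windows$clear, , drop = FALSE]
  key_pass <- paste(passing$chrom, passing$start, passing$direction)
  key_clear <- paste(clear$chrom, clear$window_start, clear$direction)
  key_truth_any <- paste(diff_windows$chrom, diff_windows$window_start)
  key_pass_any <- paste(passing$chrom, passing$start)
  list(sensitivity = mean(key_clear %in% key_pass),
       precision = if (nrow(passing)) mean(key_pass_any %in% key_truth_any) else NA,
       n_passing = nrow(passing), n_planted = nrow(clear))
}
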