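# Synthetic-study generator: a toy two-genotype (mutant vs sibling WT)
# design with planted, recorded ground truth for every pipeline layer --
# genome + annotation, one smRNA library per genotype, replicate
# expression matrices, a known-miRNA catalogue, planted novel hairpins, a
# miRNA-target table, and per-locus bisulfite clones.  All generators are
# deterministic under the config seed.

#' Simulation configuration
#'
#' Defaults emulate the study design at desk scale: 4 chromosomes of
#' 200 kb (standing in for 12 rice chromosomes), 200,000 reads per
#' genotype library (scaled down from ~10^7 clean reads; all detection
#' thresholds are ratio/RPM-based and hence scale-invariant), three
#' expression replicates per genotype, 10 bisulfite loci with 30 clones
#' each, and planted 8-fold differential clusters / miRNA ratios echoing
#' the magnitudes reported for the organism (9.0:1 top up-ratio, 1:6.1
#' lowest down-ratio, an opposite-direction family pair at 4.2:1 and
#' 1:5.6).
#'
#' @param seed master random seed (integer).
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bases.
#' @param n_library_reads reads emitted per genotype smRNA library.
#' @param n_replicates_expr expression replicates per genotype.
#' @param n_genes_per_chrom annotated genes per chromosome.
#' @param n_known_mirnas known catalogue size (hairpins embedded in the
#'   genome).
#' @param n_clusters planted differential smRNA clusters (including the
#'   methylation-associated ones).
#' @param cluster_read_count expected reads in the unbiased genotype per
#'   planted cluster.
#' @param cluster_bias mutant:WT expected fold of planted clusters.
#' @param n_bisulfite_clones clones per locus per genotype.
#' @param conversion_rate probability an unmethylated C reads as T.
#' @param sigma_expr replicate noise SD on the log2 expression scale (a
#'   configurable stand-in; the arrays' noise model is not estimated from
#'   data).
#' @param n_deg_up,n_deg_down planted up/down regulated genes (3:1 by
#'   default, echoing the study's 896:279 asymmetry).
#' @param null_study when TRUE, nothing differential is planted anywhere
#'   (all miRNA ratios 1, cluster bias 1, no expression effects): the
#'   negative-control condition for calibration.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_chroms = 4L, chrom_length = 200000L,
                       n_library_reads = 200000L, n_replicates_expr = 3L,
                       n_genes_per_chrom = 55L, n_known_mirnas = 40L,
                       n_clusters = 20L, cluster_read_count = 60L,
                       cluster_bias = 8, n_bisulfite_clones = 30L,
                       conversion_rate = 0.995, sigma_expr = 0.25,
                       n_deg_up = 36L, n_deg_down = 12L,
                       null_study = FALSE) {
  stopifnot(conversion_rate >= 0, conversion_rate <= 1, cluster_bias > 0,
            n_replicates_expr >= 2L)
  structure(as.list(environment()), class = "sim_config")
}

# background read-length distribution: bimodal at the canonical 21 nt
# (miRNA/21nt-siRNA) and 24 nt (heterochromatic siRNA) size classes
BG_LENGTH_PROBS <- c(`18` = 0.03, `19` = 0.05, `20` = 0.08, `21` = 0.30,
                     `22` = 0.07, `23` = 0.05, `24` = 0.35, `25` = 0.04,
                     `26` = 0.03)

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mature + loop + star (revcomp of mature with 1-2 mismatches; at least
# one so the mature never exact-maps onto the star arm)
make_hairpin <- function(mature) {
  loop_len <- sample(8:15, 1L)
  star <- strsplit(revcomp(mature), "")[[1]]
  n_mm <- sample(1:2, 1L)
  if (n_mm > 0L) {
    at <- sample(seq_along(star), n_mm)
    for (i in at) star[i] <- sample(setdiff(c("A", "C", "G", "T"), star[i]), 1L)
  }
  list(seq = paste0(mature, random_dna(loop_len), paste0(star, collapse = "")),
       mature_offset = 0L, mature_len = nchar(mature),
       star_seq = paste0(star, collapse = ""))
}

#' Simulate the genome, annotation and miRNA catalogue
#'
#' Uniform i.i.d. ACGT background with planted features per chromosome:
#' genes carrying GO labels, two TE families (Tos17-like LTR
#' retrotransposon and Pong-like DNA transposon copies), known miRNA loci
#' whose genomic sequence embeds a designed hairpin (mature and star arms
#' as reverse complements with at most 2 mismatches, loop 8--15 nt),
#' structural-RNA loci, and unannotated novel-miRNA hairpins recorded only
#' in the ground truth.
#'
#' @param config a \code{sim_config}.
#' @return list: \code{genome} (named character), \code{annotation}
#'   (data.frame), \code{catalog} (known-miRNA data.frame),
#'   \code{mirna_loci} (truth for known + novel hairpin placements),
#'   \code{bisulfite_loci} (locus manifest with planted per-context
#'   methylation probabilities), \code{cluster_spec} (planted cluster
#'   table).
#' @export
simulate_genome <- function(config) {
  set.seed(derive_seed(config$seed, 101L))
  GO_POOL <- c("metabolic process", "stress response", "transcription",
               "signal transduction", "transport", "development",
               "photosynthesis", "protein modification", "cell cycle",
               "lipid metabolism", "RNA processing", "defense response")
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  genome <- vapply(chroms, function(ch) random_dna(config$chrom_length),
                   character(1))
  slot_w <- 2000L
  ann <- list(); mirna_loci <- list(); bis <- list()
  # per-chromosome slot layout: genes, miRNA loci, structural RNAs, TEs
  n_mir_per_chrom <- ceiling(config$n_known_mirnas / config$n_chroms)
  mir_count <- 0L
  catalog <- data.frame(name = character(0), family = character(0),
                        mature_seq = character(0), stringsAsFactors = FALSE)
  te_plan <- data.frame(                       # one TE copy per chromosome
    chrom = chroms[seq_len(min(4L, config$n_chroms))],
    family = c("tos17", "tos17", "pong", "pong")[seq_len(min(4L, config$n_chroms))],
    id = c("tos17a", "tos17b", "pongA", "pongB")[seq_len(min(4L, config$n_chroms))],
    stringsAsFactors = FALSE)
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    n_slots <- (config$chrom_length - 2000L) %/% slot_w
    slots <- 1000L + (seq_len(n_slots) - 1L) * slot_w
    # reserve slots: TE (2 slots wide), structural RNAs, miRNAs, genes
    free <- slots
    take <- function(n) {
      s <- sort(sample(seq_along(free), n))
      out <- free[s]; free <<- free[-s]; out
    }
    if (ci <= nrow(te_plan)) {
      te_start <- free[length(free) %/% 2L]
      free <- setdiff(free, te_start)
      te_len <- 2000L
      ann[[length(ann) + 1L]] <- data.frame(
        feature_id = te_plan$id[ci], chrom = ch, start = te_start,
        end = te_start + te_len, strand = "+", feature_class = "TE",
        go = "", stringsAsFactors = FALSE)
    }
    for (cls in c("rRNA", "tRNA", "snoRNA", "snRNA", "repeat")) {
      st <- take(1L) + sample(0:500, 1L)
      w <- if (cls == "repeat") 400L else sample(80:200, 1L)
      ann[[length(ann) + 1L]] <- data.frame(
        feature_id = sprintf("%s_%s", cls, ch), chrom = ch, start = st,
        end = st + w, strand = sample(c("+", "-"), 1L),
        feature_class = cls, go = "", stringsAsFactors = FALSE)
    }
    n_mir_here <- min(n_mir_per_chrom, config$n_known_mirnas - mir_count)
    if (n_mir_here > 0L) {
      for (st in take(n_mir_here)) {
        mir_count <- mir_count + 1L
        nm <- sprintf("osa-miR%d", 1000L + mir_count)
        mature <- random_dna(21L)
        hp <- make_hairpin(mature)
        pos <- st + sample(100:800, 1L)
        substr(genome[[ch]], pos + 1L, pos + nchar(hp$seq)) <- hp$seq
        ann[[length(ann) + 1L]] <- data.frame(
          feature_id = nm, chrom = ch, start = pos,
          end = pos + nchar(hp$seq), strand = "+",
          feature_class = "known_miRNA_locus", go = "",
          stringsAsFactors = FALSE)
        catalog <- rbind(catalog, data.frame(
          name = nm, family = mirna_family(nm), mature_seq = mature,
          stringsAsFactors = FALSE))
        mirna_loci[[length(mirna_loci) + 1L]] <- data.frame(
          name = nm, type = "known", chrom = ch, start = pos,
          end = pos + nchar(hp$seq), mature_seq = mature,
          star_seq = hp$star_seq, stringsAsFactors = FALSE)
      }
    }
    n_genes <- min(config$n_genes_per_chrom, length(free))
    for (st in take(n_genes)) {
      gid <- sprintf("g%s_%03d", sub("chr", "", ch), st %/% slot_w)
      w <- sample(800:1800, 1L)
      ann[[length(ann) + 1L]] <- data.frame(
        feature_id = gid, chrom = ch, start = st, end = st + w,
        strand = sample(c("+", "-"), 1L), feature_class = "gene",
        go = paste(sample(GO_POOL, sample(1:2, 1L)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, ann)
  # the miR395-like opposite-direction pair: two catalogue members of one
  # family (rename two entries into a shared family stem)
  if (nrow(catalog) >= 4L) {
    catalog$name[1:2] <- c("osa-miR395p", "osa-miR395s")
    catalog$family[1:2] <- "miR395"
    ann$feature_id[match(c("osa-miR1001", "osa-miR1002"), ann$feature_id)] <-
      c("osa-miR395p", "osa-miR395s")
    for (k in 1:2) mirna_loci[[k]]$name <- catalog$name[k]
    for (k in seq_along(mirna_loci)) {
      if (mirna_loci[[k]]$type == "known")
        mirna_loci[[k]]$mature_seq <- catalog$mature_seq[
          match(mirna_loci[[k]]$name, catalog$name)]
    }
  }
  # novel hairpins: a 3-locus family sharing one mature (mutant-only), a
  # 5p-dominant two-arm case, and a WT-only singleton -- unannotated
  novel_mature_fam <- random_dna(21L)
  novel_specs <- list(
    list(name = "novel-N5.1", mature = novel_mature_fam),
    list(name = "novel-N5.2", mature = novel_mature_fam),
    list(name = "novel-N5.3", mature = novel_mature_fam),
    list(name = "novel-N7", mature = random_dna(21L)),
    list(name = "novel-N2", mature = random_dna(21L)))
  occupied <- ann[, c("chrom", "start", "end")]
  for (k in seq_along(novel_specs)) {
    ns <- novel_specs[[k]]
    ch <- chroms[(k - 1L) %% length(chroms) + 1L]
    hp <- make_hairpin(ns$mature)
    repeat {
      pos <- sample(2000:(config$chrom_length - 3000L), 1L)
      occ <- occupied[occupied$chrom == ch, , drop = FALSE]
      if (!any(pos < occ$end + 300L & pos + 400L > occ$start - 300L)) break
    }
    substr(genome[[ch]], pos + 1L, pos + nchar(hp$seq)) <- hp$seq
    occupied <- rbind(occupied,
                      data.frame(chrom = ch, start = pos, end = pos + 400L))
    mirna_loci[[length(mirna_loci) + 1L]] <- data.frame(
      name = ns$name, type = "novel", chrom = ch, start = pos,
      end = pos + nchar(hp$seq), mature_seq = ns$mature,
      star_seq = hp$star_seq, stringsAsFactors = FALSE)
  }
  mirna_loci <- do.call(rbind, mirna_loci)
  # bisulfite loci: 300 bp regions of the TE copies and three gene
  # 5' regions, with planted per-context methylation probabilities
  te <- ann[ann$feature_class == "TE", ]
  genes <- ann[ann$feature_class == "gene", ]
  gene3 <- genes[c(1L, 2L, 3L), ]
  mk_locus <- function(id, chrom, start, p_wt, p_mut) {
    data.frame(locus_id = id, chrom = chrom, start = start, end = start + 300L,
               cg_wt = p_wt[1], chg_wt = p_wt[2], chh_wt = p_wt[3],
               cg_mut = p_mut[1], chg_mut = p_mut[2], chh_mut = p_mut[3],
               stringsAsFactors = FALSE)
  }
  # loci are built only for the TE copies / genes the layout actually
  # holds, so small configurations (fewer chromosomes) stay valid
  te_locus <- function(id, te_id, off, p_wt, p_mut) {
    row <- te[te$feature_id == te_id, ]
    if (nrow(row) == 0L) return(NULL)
    mk_locus(id, row$chrom[1], row$start[1] + off, p_wt, p_mut)
  }
  gene_locus <- function(id, k, p_wt, p_mut) {
    if (nrow(gene3) < k) return(NULL)
    mk_locus(id, gene3$chrom[k], gene3$start[k], p_wt, p_mut)
  }
  bis <- do.call(rbind, Filter(Negate(is.null), list(
    te_locus("tos17a_5", "tos17a", 0L, c(.75, .55, .20), c(.75, .55, .20)),
    te_locus("tos17a_3", "tos17a", 1700L, c(.75, .55, .20), c(.75, .55, .20)),
    te_locus("tos17b_5", "tos17b", 0L,
             c(.75, .60, .25), c(.45, .30, .25)),   # -30 CG, -30 CHG, CHH flat
    te_locus("tos17b_3", "tos17b", 1700L, c(.75, .55, .20), c(.75, .55, .20)),
    te_locus("pongA_5", "pongA", 0L,
             c(.70, .30, .20), c(.50, .60, .70)),   # -20 CG, +30 CHG, +50 CHH
    te_locus("pongB_5", "pongB", 0L,
             c(.70, .35, .35), c(.70, .35, .25)),   # slight CHH decrease
    te_locus("pong_body", "pongB", 800L,
             c(.60, .30, .20), c(.60, .30, .50)),   # +30 CHH
    gene_locus("geneA_up", 1L,
               c(.25, .10, .05), c(.75, .10, .05)), # +50 CG
    gene_locus("geneB_up", 2L, c(.25, .10, .05), c(.25, .10, .05)),
    gene_locus("geneC_up", 3L, c(.30, .12, .06), c(.30, .12, .06)))))
  cluster_spec <- make_cluster_spec(config, genome, ann, mirna_loci, bis)
  list(genome = genome, annotation = ann, catalog = catalog,
       mirna_loci = mirna_loci, bisulfite_loci = bis,
       cluster_spec = cluster_spec)
}

# planted differential clusters: window-aligned 100 bp intervals, three of
# them co-located with the CHH-changing bisulfite loci (sign-matched, the
# RdDM-style association), the rest in unoccupied windows
make_cluster_spec <- function(config, genome, ann, mirna_loci, bis) {
  assoc_ids <- intersect(c("pongA_5", "pong_body", "pongB_5"), bis$locus_id)
  assoc_dir <- c(pongA_5 = "up", pong_body = "up", pongB_5 = "down")
  assoc <- data.frame(
    chrom = bis$chrom[match(assoc_ids, bis$locus_id)],
    start = 100L * (bis$start[match(assoc_ids, bis$locus_id)] %/% 100L + 1L),
    direction = unname(assoc_dir[assoc_ids]),
    length_mode = rep(24L, length(assoc_ids)),
    stringsAsFactors = FALSE)
  n_rest <- config$n_clusters - nrow(assoc)
  chroms <- names(genome)
  rest <- list()
  occupied <- rbind(ann[, c("chrom", "start", "end")],
                    mirna_loci[, c("chrom", "start", "end")])
  tries <- 0L
  while (length(rest) < n_rest && tries < 10000L) {
    tries <- tries + 1L
    ch <- sample(chroms, 1L)
    ws <- 100L * sample(10L:(config$chrom_length %/% 100L - 10L), 1L)
    occ <- occupied[occupied$chrom == ch, , drop = FALSE]
    if (any(ws < occ$end & ws + 100L > occ$start)) next
    if (any(vapply(rest, function(r) r$chrom == ch &&
                     abs(r$start - ws) < 300L, logical(1)))) next
    rest[[length(rest) + 1L]] <- data.frame(
      chrom = ch, start = ws,
      direction = if (length(rest) %% 2L == 0L) "up" else "down",
      length_mode = if (length(rest) %% 3L == 0L) 21L else 24L,
      stringsAsFactors = FALSE)
  }
  spec <- rbind(assoc, do.call(rbind, rest))
  spec <- spec[seq_len(min(nrow(spec), config$n_clusters)), , drop = FALSE]
  spec$end <- spec$start + 100L
  spec$read_count <- config$cluster_read_count
  spec$bias_fold <- if (isTRUE(config$null_study)) 1 else config$cluster_bias
  spec$cluster_id <- sprintf("cl%02d", seq_len(nrow(spec)))
  spec[, c("cluster_id", "chrom", "start", "end", "direction",
           "length_mode", "read_count", "bias_fold")]
}

# planted known-miRNA expression ratios (mut:wt) echoing the reported
# magnitudes; all other catalogue members are unchanged (ratio 1).  Under
# a null study every ratio is 1.
make_mirna_expression_spec <- function(catalog, mirna_loci, null = FALSE) {
  spec <- data.frame(name = catalog$name, ratio = 1, wt_count = 150,
                     stringsAsFactors = FALSE)
  set_one <- function(nm, ratio, wt) {
    spec$ratio[spec$name == nm] <<- ratio
    spec$wt_count[spec$name == nm] <<- wt
  }
  if (!null) {
    set_one("osa-miR395p", 1 / 5.6, 450)    # family pair, opposite directions
    set_one("osa-miR395s", 4.2, 100)
    if (nrow(spec) >= 4L) {
      set_one(spec$name[3L], 9.0, 80)       # top up-regulated
      set_one(spec$name[4L], 1 / 6.1, 490)  # lowest ratio
    }
  }
  novel <- mirna_loci[mirna_loci$type == "novel", ]
  novel_fam <- unique(novel[, c("name", "mature_seq")])
  nv <- data.frame(name = novel_fam$name, ratio = NA_real_, wt_count = NA_real_)
  nv$ratio[grepl("^novel-N5", nv$name)] <- Inf      # mutant-only
  nv$wt_count[grepl("^novel-N5", nv$name)] <- 0
  nv$mut_count <- NA_real_
  nv$mut_count[grepl("^novel-N5", nv$name)] <- 150  # emitted once (shared mature)
  nv$ratio[nv$name == "novel-N7"] <- 2
  nv$wt_count[nv$name == "novel-N7"] <- 100
  nv$mut_count[nv$name == "novel-N7"] <- 200
  nv$ratio[nv$name == "novel-N2"] <- 0              # WT-only
  nv$wt_count[nv$name == "novel-N2"] <- 150
  nv$mut_count[nv$name == "novel-N2"] <- 0
  if (null) {
    nv$ratio <- 1; nv$wt_count <- 150; nv$mut_count <- 150
  }
  spec$mut_count <- spec$wt_count * spec$ratio
  list(known = spec, novel = nv)
}

#' Simulate the two genotype smRNA libraries
#'
#' Background reads are exact genomic substrings drawn uniformly (lengths
#' bimodal at 21/24 nt, random strand); planted clusters receive
#' Poisson(read_count x bias) reads in the biased genotype and
#' Poisson(read_count) in the other, all inside their window; planted
#' mature miRNA sequences are emitted at their mut:wt ratios (85% exact,
#' 15% 1 nt 3'-trimmed isomiRs), plus star-arm reads for the two-arm
#' novel case.  Each library holds exactly \code{n_library_reads} reads:
#' planted reads are drawn from, not added to, the total.
#'
#' @param config a \code{sim_config}.
#' @param gsim output of \code{\link{simulate_genome}}.
#' @return list: \code{lib_mut}, \code{lib_wt} (collapsed
#'   \code{smrna_library}s) and \code{truth} (planted cluster windows,
#'   per-miRNA emitted counts, and the combined expected differential
#'   window table \code{diff_windows}).
#' @export
simulate_smrna_libraries <- function(config, gsim) {
  set.seed(derive_seed(config$seed, 202L))
  genome <- gsim$genome
  mspec <- make_mirna_expression_spec(gsim$catalog, gsim$mirna_loci,
                                      null = isTRUE(config$null_study))
  draw_cluster_reads <- function(spec_row, n) {
    if (n <= 0L) return(character(0))
    lens <- sample(c(spec_row$length_mode - 1L, spec_row$length_mode,
                     spec_row$length_mode + 1L), n, replace = TRUE,
                   prob = c(.2, .6, .2))
    starts <- spec_row$start +
      as.integer(floor(stats::runif(n) * (100L - lens + 1L)))
    seqs <- substring(genome[[spec_row$chrom]], starts + 1L, starts + lens)
    flip <- stats::runif(n) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    seqs
  }
  emit_mirna_reads <- function(mature, star, n_mature, n_star = 0L) {
    out <- character(0)
    if (n_mature > 0L) {
      trimmed <- stats::runif(n_mature) < 0.15
      out <- c(rep(mature, sum(!trimmed)),
               rep(substr(mature, 1L, nchar(mature) - 1L), sum(trimmed)))
    }
    if (n_star > 0L) out <- c(out, rep(star, n_star))
    out
  }
  truth_mirna <- list()
  build_library <- function(genotype) {
    reads <- character(0)
    truth_cl <- gsim$cluster_spec
    truth_cl$expected <- ifelse(
      (genotype == "mut") == (truth_cl$direction == "up"),
      truth_cl$read_count * truth_cl$bias_fold, truth_cl$read_count)
    truth_cl$realized <- stats::rpois(nrow(truth_cl), truth_cl$expected)
    for (i in seq_len(nrow(truth_cl))) {
      reads <- c(reads, draw_cluster_reads(truth_cl[i, ], truth_cl$realized[i]))
    }
    loci <- gsim$mirna_loci
    ksp <- mspec$known
    ksp$expected <- if (genotype == "mut") ksp$mut_count else ksp$wt_count
    ksp$realized <- stats::rpois(nrow(ksp), ksp$expected)
    for (i in seq_len(nrow(ksp))) {
      loc <- loci[loci$name == ksp$name[i], ][1L, ]
      reads <- c(reads, emit_mirna_reads(loc$mature_seq, loc$star_seq,
                                         ksp$realized[i]))
    }
    nsp <- mspec$novel
    nsp <- nsp[!duplicated(nsp$name) & !grepl("N5\\.[23]$", nsp$name), ]
    nsp$expected <- if (genotype == "mut") nsp$mut_count else nsp$wt_count
    nsp$realized <- stats::rpois(nrow(nsp), nsp$expected)
    for (i in seq_len(nrow(nsp))) {
      loc <- loci[loci$name == nsp$name[i] |
                    (nsp$name[i] == "novel-N5.1" & grepl("^novel-N5", loci$name)), ][1L, ]
      n_star <- if (nsp$name[i] == "novel-N7")
        stats::rpois(1L, nsp$expected[i] * 0.2) else 0L
      reads <- c(reads, emit_mirna_reads(loc$mature_seq, loc$star_seq,
                                         nsp$realized[i], n_star))
    }
    n_planted <- length(reads)
    n_bg <- config$n_library_reads - n_planted
    if (n_bg < 0L) stop("planted reads exceed the library size")
    lens <- sample(as.integer(names(BG_LENGTH_PROBS)), n_bg, replace = TRUE,
                   prob = BG_LENGTH_PROBS)
    chs <- sample(names(genome), n_bg, replace = TRUE)
    chrlens <- nchar(genome)
    starts <- as.integer(floor(stats::runif(n_bg) *
                                 (chrlens[chs] - lens + 1L)))
    bg <- substring(genome[chs], starts + 1L, starts + lens)
    flip <- stats::runif(n_bg) < 0.5
    bg[flip] <- revcomp(bg[flip])
    truth_mirna[[genotype]] <<- rbind(
      ksp[, c("name", "ratio", "expected", "realized")],
      nsp[, c("name", "ratio", "expected", "realized")])
    list(lib = collapse_reads(c(reads, bg)), truth_cl = truth_cl)
  }
  mut <- build_library("mut")
  wt <- build_library("wt")
  truth_clusters <- gsim$cluster_spec
  truth_clusters$reads_mut <- mut$truth_cl$realized
  truth_clusters$reads_wt <- wt$truth_cl$realized
  tm <- merge(truth_mirna$mut, truth_mirna$wt, by = c("name", "ratio"),
              suffixes = c("_mut", "_wt"))
  # combined expected-differential-window truth: planted cluster windows
  # plus the windows of miRNA loci planted at >= 4-fold ratios
  loci <- gsim$mirna_loci
  all_ratios <- rbind(mspec$known[, c("name", "ratio")],
                      mspec$novel[, c("name", "ratio")])
  mir_ratio <- all_ratios$ratio[match(loci$name, all_ratios$name)]
  diff_loci <- loci[!is.na(mir_ratio) & (mir_ratio >= 4 | mir_ratio <= 0.25), ]
  dw1 <- data.frame(chrom = truth_clusters$chrom,
                    window_start = truth_clusters$start,
                    direction = truth_clusters$direction,
                    source = "cluster", clear = TRUE,
                    stringsAsFactors = FALSE)
  dw2 <- if (nrow(diff_loci)) {
    r <- all_ratios$ratio[match(diff_loci$name, all_ratios$name)]
    data.frame(chrom = diff_loci$chrom,
               window_start = 100L * (diff_loci$start %/% 100L),
               direction = ifelse(r > 1, "up", "down"),
               source = "mirna",
               # plantings close to the 4-fold cut-off are flagged: noise
               # can legitimately leave them on either side
               clear = r >= 6 | r <= 1 / 6, stringsAsFactors = FALSE)
  } else dw1[0, ]
  diff_windows <- unique(rbind(dw1, dw2))
  list(lib_mut = mut$lib, lib_wt = wt$lib,
       truth = list(clusters = truth_clusters, mirnas = tm,
                    diff_windows = diff_windows))
}

#' Simulate the replicate expression matrix
#'
#' Per-gene baselines ~ Normal(8, 1.5); replicate log2 intensities ~
#' Normal(baseline, sigma_expr); planted DEGs are shifted by their log2
#' effect in the mutant replicates.  Planted DEGs are drawn preferentially
#' from the first two chromosomes so the chromosomal distribution is
#' non-random, and the miRNA-target relationship genes get the directions
#' matching the four relationship types.
#'
#' @param config a \code{sim_config}.
#' @param gsim output of \code{\link{simulate_genome}}.
#' @return list: \code{matrix} (genes x samples, log2), \code{design},
#'   \code{go_table}, \code{target_table} (miRNA -> predicted target
#'   gene), \code{truth} (planted per-gene effects).
#' @export
simulate_expression <- function(config, gsim) {
  set.seed(derive_seed(config$seed, 303L))
  genes <- gsim$annotation[gsim$annotation$feature_class == "gene", ]
  if (nrow(genes) == 0L) stop("annotation contains no genes")
  n <- nrow(genes)
  # miRNA-target table covering the four relationship types + a none case
  ksp <- make_mirna_expression_spec(gsim$catalog, gsim$mirna_loci)$known
  pick <- function(pat) ksp$name[match(pat, round(ksp$ratio, 2))]
  tgt <- data.frame(
    mirna_name = c(pick(round(1 / 6.1, 2)), pick(9.0), "osa-miR395s",
                   "osa-miR395p", ksp$name[5L]),
    target_gene_id = genes$feature_id[4:8],
    target_direction = c("up", "down", "up", "down", "unchanged"),
    stringsAsFactors = FALSE)
  # planted DEG set: relationship targets first, the rest biased to the
  # first two chromosomes
  chrom_w <- c(6, 4, rep(0.5, max(0L, length(unique(genes$chrom)) - 2L)))
  names(chrom_w) <- sort(unique(genes$chrom))
  effects <- rep(0, n); names(effects) <- genes$feature_id
  if (!isTRUE(config$null_study)) {
    forced <- tgt[tgt$target_direction != "unchanged", ]
    effects[forced$target_gene_id] <-
      ifelse(forced$target_direction == "up", 1, -1) *
      stats::runif(nrow(forced), 1.2, 2)
    n_up_left <- max(0L, config$n_deg_up - sum(forced$target_direction == "up"))
    n_dn_left <- max(0L, config$n_deg_down - sum(forced$target_direction == "down"))
    pool <- setdiff(genes$feature_id, forced$target_gene_id)
    # small gene sets: keep at most half the pool differential
    cap <- length(pool) %/% 2L
    if (n_up_left + n_dn_left > cap) {
      sc <- cap / (n_up_left + n_dn_left)
      n_up_left <- as.integer(floor(n_up_left * sc))
      n_dn_left <- as.integer(floor(n_dn_left * sc))
    }
    w <- chrom_w[genes$chrom[match(pool, genes$feature_id)]]
    planted <- sample(pool, n_up_left + n_dn_left, prob = w)
    up_ids <- planted[seq_len(n_up_left)]
    dn_ids <- setdiff(planted, up_ids)
    effects[up_ids] <- stats::runif(n_up_left, 1.2, 2.5)
    effects[dn_ids] <- -stats::runif(n_dn_left, 1.2, 2.5)
  }
  baseline <- stats::rnorm(n, 8, 1.5)
  nrep <- config$n_replicates_expr
  design <- data.frame(
    sample = c(sprintf("mut_r%d", seq_len(nrep)), sprintf("wt_r%d", seq_len(nrep))),
    genotype = rep(c("mut", "wt"), each = nrep),
    replicate = rep(seq_len(nrep), 2L), stringsAsFactors = FALSE)
  mat <- matrix(stats::rnorm(n * 2L * nrep, baseline, config$sigma_expr),
                nrow = n)
  mat[, seq_len(nrep)] <- mat[, seq_len(nrep)] + effects
  dimnames(mat) <- list(genes$feature_id, design$sample)
  go_table <- data.frame(gene_id = genes$feature_id, go = genes$go,
                         stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = genes$feature_id, chrom = genes$chrom,
                      log2_effect = unname(effects),
                      direction = ifelse(effects > 0, "up",
                                         ifelse(effects < 0, "down", "unchanged")),
                      stringsAsFactors = FALSE)
  list(matrix = mat, design = design, go_table = go_table,
       target_table = tgt[, c("mirna_name", "target_gene_id")],
       truth = truth)
}

#' Simulate bisulfite clone sequences
#'
#' For each locus and genotype, \code{n_bisulfite_clones} clones of the
#' locus top strand: each reference C is methylated with the planted
#' context-specific probability (methylated C reads as C; unmethylated C
#' reads as T with probability \code{conversion_rate}, else C); all other
#' bases are copied unchanged.
#'
#' @param config a \code{sim_config}.
#' @param gsim output of \code{\link{simulate_genome}}.
#' @return list: \code{loci} (manifest with reference sequences),
#'   \code{clones} (nested list \code{[[locus_id]][[genotype]]} of
#'   character vectors), \code{truth} (the planted probability table).
#' @export
simulate_bisulfite_clones <- function(config, gsim) {
  set.seed(derive_seed(config$seed, 404L))
  bis <- gsim$bisulfite_loci
  bis$ref_seq <- vapply(seq_len(nrow(bis)), function(i) {
    substr(gsim$genome[[bis$chrom[i]]], bis$start[i] + 1L, bis$end[i])
  }, character(1))
  clones <- list()
  for (i in seq_len(nrow(bis))) {
    ref <- strsplit(bis$ref_seq[i], "")[[1]]
    ctx <- cytosine_contexts(bis$ref_seq[i])
    ctx_all <- rep("CHH", sum(ref == "C"))       # end-Cs default to CHH rate
    cpos <- which(ref == "C")
    ctx_all[match(ctx$position + 1L, cpos)] <- ctx$context
    for (genotype in c("mut", "wt")) {
      p <- unlist(bis[i, paste0(c("cg", "chg", "chh"), "_", genotype)])
      names(p) <- c("CG", "CHG", "CHH")
      cl <- vapply(seq_len(config$n_bisulfite_clones), function(k) {
        s <- ref
        meth <- stats::runif(length(cpos)) < p[ctx_all]
        conv <- stats::runif(length(cpos)) < config$conversion_rate
        s[cpos[!meth & conv]] <- "T"
        paste0(s, collapse = "")
      }, character(1))
      clones[[bis$locus_id[i]]][[genotype]] <- cl
    }
  }
  list(loci = bis, clones = clones,
       truth = bis[, c("locus_id", "chrom", "start", "end",
                       "cg_wt", "chg_wt", "chh_wt",
                       "cg_mut", "chg_mut", "chh_mut")])
}

#' Simulate the complete toy study
#'
#' Runs all four generators under the config seed and returns their
#' outputs plus the combined ground truth.
#'
#' @param config a \code{sim_config}.
#' @return list of class \code{sim_study}: \code{genome},
#'   \code{annotation}, \code{catalog}, \code{lib_mut}, \code{lib_wt},
#'   \code{expr} (matrix/design/go_table/target_table),
#'   \code{bisulfite}, and \code{truth} (clusters, diff_windows, mirnas,
#'   degs, meth, mirna_loci).
#' @export
simulate_study <- function(config = sim_config()) {
  gsim <- simulate_genome(config)
  libs <- simulate_smrna_libraries(config, gsim)
  expr <- simulate_expression(config, gsim)
  bsim <- simulate_bisulfite_clones(config, gsim)
  structure(list(
    genome = gsim$genome, annotation = gsim$annotation,
    catalog = gsim$catalog, lib_mut = libs$lib_mut, lib_wt = libs$lib_wt,
    expr = expr[c("matrix", "design", "go_table", "target_table")],
    bisulfite = bsim[c("loci", "clones")],
    truth = list(clusters = libs$truth$clusters,
                 diff_windows = libs$truth$diff_windows,
                 mirnas = libs$truth$mirnas,
                 mirna_loci = gsim$mirna_loci,
                 degs = expr$truth, meth = bsim$truth)
  ), class = "sim_study")
}
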