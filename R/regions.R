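# Region-level methylation: promoter definition, per-region metrics with
# the study's coverage filters, Fisher-exact DMR detection, and clonal
# bisulfite scoring.

#' Derive promoter intervals from gene TSSs
#'
#' The promoter of a gene is the 2 kb interval immediately upstream of its
#' TSS, strand-aware: for a plus-strand gene with TSS `t` it is
#' `[t - 2000, t - 1]`, for a minus-strand gene `[t + 1, t + 2000]`
#' (1-based closed), clipped at the contig edges.
#'
#' @param genes data.frame with `id`, `strand`, `tss`.
#' @param contig_length Length of the contig, for clipping.
#' @param width Promoter width in bp.
#' @return data.frame: `gene_id`, `start`, `end`, `strand`, `clipped`.
#' @export
define_promoters <- function(genes, contig_length, width = 2000L) {
  if (any(genes$tss < 1L | genes$tss > contig_length)) {
    stop("TSS outside the contig")
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - width, genes$tss + 1L)
  end <- ifelse(plus, genes$tss - 1L, genes$tss + width)
  cs <- pmax(start, 1L); ce <- pmin(end, contig_length)
  data.frame(gene_id = genes$id, start = cs, end = ce,
             strand = genes$strand,
             clipped = cs != start | ce != end)
}

# CpG positions (top-strand C of each CG dinucleotide) of a reference.
cpg_positions <- function(reference) {
  ch <- dna_chars(reference)
  which(ch[-length(ch)] == "C" & ch[-1] == "G")
}

#' Region-level methylation metrics
#'
#' For each region, counts its CpG dinucleotides from the reference
#' sequence; a CpG is *covered* when at least one read informs it and
#' *methylated* when at least `min_meth_reads` reads show C. The percent
#' methylation is methylated CpGs over ALL CpGs of the region; the mean
#' 5mCG level averages the per-CpG methylation level over methylated
#' CpGs only. Two depth summaries are reported for the "at least 5 reads
#' per methylated CpG" filter: the mean coverage over methylated CpGs
#' (used for `passes_depth_filter`) and the per-CpG minimum
#' (`min_coverage_methylated`), so either reading of the filter can be
#' applied downstream.
#'
#' @param calls data.frame from [call_methylation()] (CG rows are merged
#'   per CpG).
#' @param regions data.frame with `id`, `type`, `start`, `end`.
#' @param reference Reference sequence string.
#' @param min_covered_fraction Coverage filter threshold (fraction of
#'   CpGs covered), default 0.8.
#' @param min_mean_coverage Depth filter threshold, default 5 reads.
#' @param min_meth_reads Reads showing C needed to call a CpG methylated.
#' @return data.frame, one row per region, with the fields above plus
#'   `passes_coverage_filter` and `passes_depth_filter`.
#' @export
region_metrics <- function(calls, regions, reference,
                           min_covered_fraction = 0.8,
                           min_mean_coverage = 5,
                           min_meth_reads = 1L) {
  n <- nchar(reference)
  if (any(regions$start < 1L | regions$end > n)) {
    stop("region outside the contig")
  }
  cg <- calls[calls$context == "CG", , drop = FALSE]
  cov_at <- setNames(cg$meth_count + cg$unmeth_count, cg$pos)
  meth_at <- setNames(cg$meth_count, cg$pos)
  lvl_at <- setNames(cg$level, cg$pos)
  all_cpg <- cpg_positions(reference)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    pos <- all_cpg[all_cpg >= regions$start[i] & all_cpg <= regions$end[i]]
    key <- as.character(pos)
    covered <- key[!is.na(cov_at[key]) & cov_at[key] > 0]
    methylated <- covered[meth_at[covered] >= min_meth_reads]
    n_tot <- length(pos); n_cov <- length(covered)
    n_meth <- length(methylated)
    covered_fraction <- if (n_tot > 0) n_cov / n_tot else NA_real_
    data.frame(
      region_id = regions$id[i], region_type = regions$type[i],
      start = regions$start[i], end = regions$end[i],
      n_cpg_total = n_tot, n_cpg_covered = n_cov,
      covered_fraction = covered_fraction,
      n_cpg_methylated = n_meth,
      pct_methylation = if (n_tot > 0) n_meth / n_tot else NA_real_,
      mean_5mCG_level = if (n_meth > 0) mean(lvl_at[methylated])
                        else NA_real_,
      mean_coverage_methylated = if (n_meth > 0) mean(cov_at[methylated])
                                 else NA_real_,
      min_coverage_methylated = if (n_meth > 0) min(cov_at[methylated])
                                else NA_real_,
      passes_coverage_filter = isTRUE(covered_fraction >=
                                        min_covered_fraction),
      passes_depth_filter = n_meth > 0 &&
        mean(cov_at[methylated]) >= min_mean_coverage)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Differentially methylated region scan
#'
#' Per region, pools methylated/unmethylated read counts over the CpGs
#' covered in both conditions into a 2x2 table and tests it with a
#' two-sided Fisher exact test; q-values are Benjamini-Hochberg across
#' tested regions. A region *passes* when the WT/KO ratio of mean per-CpG
#' levels exceeds `min_ratio`, it has more than `min_cg` shared CpGs, the
#' raw p-value is below `max_p` and its midpoint lies within `max_tss_dist`
#' of the nearest TSS.
#'
#' @param metrics_wt,metrics_ko data.frames from [region_metrics()] over
#'   the same region set (used for region identity/coordinates).
#' @param calls_wt,calls_ko Per-condition calls from [call_methylation()].
#' @param tss Integer vector of TSS positions.
#' @param min_ratio,min_cg,max_p,max_tss_dist The filter set (defaults:
#'   ratio > 2, > 10 CpGs, P < 0.01, TSS distance < 5 kb).
#' @return data.frame, one row per region: levels, ratio, `n_cg`,
#'   `p_value`, `q_value`, `tss_distance`, `passes`, and `skipped` with a
#'   reason for regions without testable counts.
#' @export
dmr_scan <- function(metrics_wt, metrics_ko, calls_wt, calls_ko, tss,
                     min_ratio = 2, min_cg = 10L, max_p = 0.01,
                     max_tss_dist = 5000) {
  if (!identical(metrics_wt$region_id, metrics_ko$region_id)) {
    stop("WT and KO metrics must cover the same regions in order")
  }
  cgw <- calls_wt[calls_wt$context == "CG", ]
  cgk <- calls_ko[calls_ko$context == "CG", ]
  rows <- lapply(seq_len(nrow(metrics_wt)), function(i) {
    s <- metrics_wt$start[i]; e <- metrics_wt$end[i]
    w <- cgw[cgw$pos >= s & cgw$pos <= e, ]
    k <- cgk[cgk$pos >= s & cgk$pos <= e, ]
    shared <- intersect(w$pos, k$pos)
    wi <- w[match(shared, w$pos), ]; ki <- k[match(shared, k$pos), ]
    mw <- sum(wi$meth_count); uw <- sum(wi$unmeth_count)
    mk <- sum(ki$meth_count); uk <- sum(ki$unmeth_count)
    mid <- (s + e) / 2
    out <- data.frame(
      region_id = metrics_wt$region_id[i],
      region_type = metrics_wt$region_type[i],
      level_wt = if (length(shared)) mean(wi$level) else NA_real_,
      level_ko = if (length(shared)) mean(ki$level) else NA_real_,
      ratio = NA_real_, n_cg = length(shared),
      p_value = NA_real_, q_value = NA_real_,
      tss_distance = if (length(tss)) min(abs(mid - tss)) else NA_real_,
      passes = FALSE, skipped = NA_character_)
    if (length(shared) == 0L || mw + uw == 0L || mk + uk == 0L) {
      out$skipped <- "no shared covered CpGs or zero read totals"
      return(out)
    }
    out$ratio <- out$level_wt / out$level_ko
    out$p_value <- fisher.test(matrix(c(mw, uw, mk, uk), nrow = 2))$p.value
    out
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tested <- is.na(res$skipped)
  res$q_value[tested] <- bh_adjust(res$p_value[tested])
  res$passes <- tested & !is.na(res$ratio) & res$ratio > min_ratio &
    res$n_cg > min_cg & res$p_value < max_p &
    !is.na(res$tss_distance) & res$tss_distance < max_tss_dist
  res
}

#' Score clonal bisulfite sequencing
#'
#' Scores each CpG of each bisulfite clone as methylated (C) or
#' unmethylated (T). When matched clones from standard (non-bisulfite)
#' sequencing are supplied, a CpG site where standard sequencing shows T
#' is a genomic C-to-T transition, and T observations there are labelled
#' `transition` instead of unmethylated (they reflect mutation, not
#' demethylation) and excluded from the percent methylation.
#'
#' @param bisulfite_clones Character vector of clone sequences, each the
#'   full length of `reference_region` (ungapped); shorter/longer clones
#'   are skipped with a warning.
#' @param standard_clones Optional character vector of standard-sequencing
#'   clones over the same region.
#' @param reference_region Reference sequence of the region.
#' @return List: `matrix` (clones x CpG sites, values
#'   methylated/unmethylated/transition/missing), `site_pct` (per-site %
#'   methylated over informative calls), `pct_5mCG` (region-level %),
#'   `transition_sites` (positions).
#' @export
score_clones <- function(bisulfite_clones, standard_clones = NULL,
                         reference_region) {
  check_dna(reference_region, "reference_region")
  L <- nchar(reference_region)
  ok <- nchar(bisulfite_clones) == L
  if (!all(ok)) {
    warning(sum(!ok), " clone(s) skipped: length differs from the region")
  }
  clones <- bisulfite_clones[ok]
  cpg <- cpg_positions(reference_region)
  if (length(clones) == 0L || length(cpg) == 0L) {
    stop("no usable clones or no CpG in the region")
  }
  trans_sites <- integer(0)
  if (!is.null(standard_clones)) {
    std <- standard_clones[nchar(standard_clones) == L]
    for (p in cpg) {
      if (any(substr(std, p, p) == "T")) trans_sites <- c(trans_sites, p)
    }
  }
  m <- matrix("missing", nrow = length(clones), ncol = length(cpg),
              dimnames = list(paste0("clone_", seq_along(clones)),
                              paste0("CpG_", cpg)))
  for (j in seq_along(cpg)) {
    b <- substr(clones, cpg[j], cpg[j])
    m[, j] <- ifelse(b == "C", "methylated",
                     ifelse(b == "T",
                            if (cpg[j] %in% trans_sites) "transition"
                            else "unmethylated",
                            "missing"))
  }
  nm <- sum(m == "methylated"); nu <- sum(m == "unmethylated")
  site_pct <- apply(m, 2, function(col) {
    i <- sum(col == "methylated"); u <- sum(col == "unmethylated")
    if (i + u > 0) 100 * i / (i + u) else NA_real_
  })
  list(matrix = m, site_pct = site_pct,
       pct_5mCG = if (nm + nu > 0) 100 * nm / (nm + nu) else NA_real_,
       transition_sites = trans_sites)
}
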