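# Built-in validation experiments: planted-truth recovery runs that
# exercise the pipeline end to end and report how faithfully the planted
# signal is recovered. They serve the same role as the example-data
# constructors of differential-expression packages: self-contained,
# seeded, and scored against their own ground truth.

#' DMR recovery experiment on planted per-CpG counts
#'
#' Simulates per-CpG methylation calls for a panel of regions at a fixed
#' read depth (binomial sampling from planted levels), hypomethylates a
#' subset of regions in the KO condition by `fold`, runs [dmr_scan()]
#' with the standard filter set, and scores recall and false positives
#' against the planted truth. With `fold = 1` the run is a null
#' experiment and the score is the empirical pass rate.
#'
#' @param seed RNG seed.
#' @param n_regions Number of regions in the panel.
#' @param n_planted Regions hypomethylated in KO (0 for a null run).
#' @param cpg_per_region CpGs per region.
#' @param coverage Reads per CpG per condition.
#' @param wt_level Planted WT methylation level.
#' @param fold KO level = WT level / fold at planted regions.
#' @return List: `dmr` (the scan table), `planted` (region ids),
#'   `recall`, `n_false_positive`, `pass_rate`.
#' @export
dmr_recovery_experiment <- function(seed = 1L, n_regions = 200L,
                                    n_planted = 20L,
                                    cpg_per_region = 15L, coverage = 20L,
                                    wt_level = 0.4, fold = 4) {
  with_seed(seed, {
    ids <- sprintf("region_%03d", seq_len(n_regions))
    planted <- if (n_planted > 0) sample(ids, n_planted) else character(0)
    region_start <- seq(1000L, by = 1000L, length.out = n_regions)
    mk_calls <- function(levels) {
      pos <- unlist(lapply(region_start, function(s)
        seq(s, by = 30L, length.out = cpg_per_region)))
      lv <- rep(levels, each = cpg_per_region)
      meth <- rbinom(length(pos), coverage, lv)
      data.frame(chrom = "panel", pos = pos, strand = "+",
                 context = "CG", meth_count = meth,
                 unmeth_count = coverage - meth,
                 meth_plus = meth, unmeth_plus = coverage - meth,
                 meth_minus = 0L, unmeth_minus = 0L,
                 level = meth / coverage)
    }
    lv_wt <- rep(wt_level, n_regions)
    lv_ko <- ifelse(ids %in% planted, wt_level / fold, wt_level)
    metrics <- data.frame(region_id = ids, region_type = "promoter",
                          start = region_start,
                          end = region_start +
                            30L * (cpg_per_region - 1L))
    dmr <- dmr_scan(metrics, metrics, mk_calls(lv_wt), mk_calls(lv_ko),
                    tss = region_start)
    hit <- dmr$region_id[dmr$passes]
    list(dmr = dmr, planted = planted,
         recall = if (length(planted)) mean(planted %in% hit) else NA_real_,
         n_false_positive = sum(!(hit %in% planted)),
         pass_rate = length(hit) / n_regions)
  })
}

#' DIP-seq repeat-family fold-change recovery experiment
#'
#' Plants a `fold`-fold 5mC depletion in the KO condition for a set of
#' repeat families, simulates WT and KO IP libraries, runs the full
#' two-pass quantification and [family_stats()] at the DIP thresholds,
#' and scores the recovered log2 ratios against the planted effect.
#' Planted families are chosen from the genome's own truth: the
#' lowest-enrichment retrotransposon families whose expected IP depth at
#' `n_reads` still exceeds `min_expected_reads`, so each planted family
#' is well measured while the planted set stays a modest share of the
#' library (large planted shares shift the library-size normalisation of
#' every family, which is a property of the assay, not an artefact).
#'
#' @param seed RNG seed.
#' @param config A [sim_config()]; `dip_n_reads` is overridden by
#'   `n_reads`.
#' @param n_planted Families to deplete.
#' @param fold Depletion factor in KO.
#' @param n_reads IP reads per condition.
#' @param min_expected_reads A-priori depth floor for eligible families.
#' @return List: `stats` (the [family_stats()] table), `planted`,
#'   `planted_log2` (recovered ratios), `n_flagged_planted`,
#'   `null_flagged_fraction`.
#' @export
dip_recovery_experiment <- function(seed = 1L,
                                    config = sim_config(
                                      seed, dip_fragment_length = 100L),
                                    n_planted = 10L, fold = 2,
                                    n_reads = 200000L,
                                    min_expected_reads = 1200L) {
  genome <- generate_genome(config)
  base <- plant_methylation(genome, config,
                            effects = data.frame(type = character(0),
                                                 id = character(0),
                                                 fold = numeric(0)))
  # expected IP weight share per family, from the planted truth
  glen <- nchar(genome$sequence)
  flen <- config$dip_fragment_length
  cum <- c(0, cumsum(base$wt$level))
  starts <- seq_len(glen - flen + 1L)
  w <- 1 + config$dip_enrichment_alpha * (cum[starts + flen] - cum[starts])
  wsum <- sum(w)
  ri <- genome$repeat_instances
  fam_w <- tapply(seq_len(nrow(ri)), ri$family, function(ii) {
    sum(unlist(lapply(ii, function(i) {
      s0 <- max(1L, ri$start[i] - flen %/% 2L)
      s1 <- min(glen - flen + 1L, ri$end[i] - flen %/% 2L)
      if (s1 >= s0) sum(w[s0:s1]) else 0
    })))
  })
  exp_reads <- n_reads * fam_w / wsum
  eligible <- names(exp_reads)[exp_reads >= min_expected_reads]
  eligible <- eligible[order(exp_reads[eligible])]
  planted <- head(eligible, n_planted)
  eff <- data.frame(type = "family", id = planted, fold = fold)
  ko <- plant_methylation(genome, config, effects = eff)$ko

  run_side <- function(landscape, s) {
    d <- simulate_dip_reads(genome, landscape, "5mC", config,
                            seed = derive_seed(seed, s),
                            n_reads = n_reads)
    a <- align_unique(d$ip, genome$sequence)
    count_repeat_reads(a, d$ip, genome$repeat_instances,
                       genome$consensus_library)
  }
  cw <- run_side(base$wt, 91L)
  ck <- run_side(ko, 92L)
  cm <- cbind(WT = setNames(cw$counts$count_total, cw$counts$family),
              KO = ck$counts$count_total)
  meta <- genome$consensus_library
  meta$cg_per_100bp <- unname(consensus_cg_density(meta))
  stats <- family_stats(cm, factor(c("WT", "KO"), c("WT", "KO")), meta,
                        c(cw$library_size, ck$library_size),
                        assay = "dip")
  pl <- stats[stats$family %in% planted, ]
  nl <- stats[!(stats$family %in% planted), ]
  list(stats = stats, planted = planted,
       expected_reads = exp_reads,
       planted_log2 = setNames(pl$log2_ratio, pl$family),
       n_flagged_planted = sum(pl$significant &
                                 pl$direction == "down"),
       null_flagged_fraction = mean(nl$significant))
}
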