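# End-to-end synthetic demonstration: one seed in, every analysis table
# out. Each stage is a pure function of (inputs, config, seed), so
# re-running with the same seed reproduces every file byte-for-byte.

#' Run the full synthetic pipeline
#'
#' Generates a genome and planted WT/KO methylation landscapes, then runs
#' every analysis stage on simulated reads: RRBS (digest, align, call,
#' QC, region metrics, DMR scan), 5mC and 5hmC DIP-seq (metagene
#' profiles and two-pass repeat-family statistics), and RNA-seq (per-gene
#' differential expression and repeat-family expression). All tables are
#' written to `outdir` as plain text and returned invisibly.
#'
#' @param seed Master seed.
#' @param outdir Output directory (created if needed); NULL skips
#'   writing.
#' @param config A [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param quiet Suppress progress messages.
#' @return (Invisibly) a list with every intermediate: genome,
#'   landscapes, calls, QC, region metrics, DMRs, metagene profiles,
#'   repeat tables, differential expression, and a `summary` of counts
#'   per stage.
#' @export
run_pipeline <- function(seed = 1L, outdir = NULL,
                         config = sim_config(seed = seed),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  say("[simulate] genome")
  genome <- generate_genome(config)
  meth <- plant_methylation(genome, config, mark = "5mC")
  hmc <- plant_methylation(genome, config, mark = "5hmC")
  ref <- genome$sequence
  genomes <- build_converted_genomes(ref)

  ## --- RRBS ---------------------------------------------------------
  say("[rrbs] simulate + align + call")
  rrbs <- lapply(list(WT = list(ls = meth$wt, s = 11L),
                      KO = list(ls = meth$ko, s = 12L)), function(x) {
    sim <- simulate_rrbs_reads(genome, x$ls, config,
                               seed = derive_seed(seed, x$s))
    aln <- align_bisulfite(sim$reads, genomes)
    calls <- call_methylation(aln, ref, genome$chrom_name)
    list(sim = sim, aln = aln, calls = calls, qc = conversion_qc(calls))
  })
  regions <- rbind(
    data.frame(id = genome$cgis$id, type = "CGI",
               start = genome$cgis$start, end = genome$cgis$end),
    data.frame(id = genome$promoters$gene_id, type = "promoter",
               start = genome$promoters$start,
               end = genome$promoters$end))
  met_wt <- region_metrics(rrbs$WT$calls, regions, ref)
  met_ko <- region_metrics(rrbs$KO$calls, regions, ref)
  dmr <- dmr_scan(met_wt, met_ko, rrbs$WT$calls, rrbs$KO$calls,
                  genome$genes$tss)

  ## --- DIP-seq ------------------------------------------------------
  rmsk <- cbind(genome$repeat_instances, chrom = genome$chrom_name)
  meta <- genome$consensus_library
  meta$cg_per_100bp <- unname(consensus_cg_density(meta))
  dip_one <- function(landscape, mark, s) {
    sim <- simulate_dip_reads(genome, landscape, mark, config,
                              seed = derive_seed(seed, s))
    list(sim = sim,
         aln_ip = align_unique(sim$ip, ref),
         aln_input = align_unique(sim$input, ref))
  }
  say("[dip] 5mC / 5hmC libraries")
  dip <- list(
    mC_WT = dip_one(meth$wt, "5mC", 21L),
    mC_KO = dip_one(meth$ko, "5mC", 22L),
    hmC_WT = dip_one(hmc$wt, "5hmC", 23L),
    hmC_KO = dip_one(hmc$ko, "5hmC", 24L))
  say("[dip] metagene profiles")
  profiles <- lapply(dip, function(d) metagene(d$aln_ip, genome$genes))
  profiles$input_WT <- metagene(dip$mC_WT$aln_input, genome$genes)

  say("[repeats] two-pass quantification (DIP)")
  rep_counts <- lapply(dip, function(d)
    count_repeat_reads(d$aln_ip, d$sim$ip, rmsk, meta))
  fam_table <- function(samples, conditions, assay) {
    cm <- do.call(cbind, lapply(samples, function(s)
      setNames(s$counts$count_total, s$counts$family)))
    family_stats(cm, conditions, meta,
                 vapply(samples, `[[`, numeric(1), "library_size"),
                 assay = assay)
  }
  rep_dip_5mC <- fam_table(rep_counts[c("mC_WT", "mC_KO")],
                           factor(c("WT", "KO"), c("WT", "KO")), "dip")
  rep_dip_5hmC <- fam_table(rep_counts[c("hmC_WT", "hmC_KO")],
                            factor(c("WT", "KO"), c("WT", "KO")), "dip")

  ## --- RNA-seq ------------------------------------------------------
  say("[rna] simulate + align + count")
  expr <- default_expression(genome, meth$effects)
  rna <- list()
  for (cond in c("WT", "KO")) {
    for (rep_i in 1:2) {
      nm <- sprintf("%s_rep%d", cond, rep_i)
      ex <- data.frame(feature = expr$feature, type = expr$type,
                       level = expr[[paste0("level_", tolower(cond))]])
      sim <- simulate_rnaseq_reads(genome, ex, config,
                                   seed = derive_seed(seed,
                                                      30L + rep_i +
                                                        4L * (cond == "KO")),
                                   sample_name = nm)
      rna[[nm]] <- list(sim = sim, aln = align_unique(sim$reads, ref))
    }
  }
  conds <- factor(c("WT", "WT", "KO", "KO"), c("WT", "KO"))
  gene_counts <- vapply(rna, function(s)
    count_gene_reads(s$aln, genome$genes), integer(nrow(genome$genes)))
  rownames(gene_counts) <- genome$genes$id
  de <- nb_test(gene_counts, conds)
  de$p_adjusted <- bh_adjust(de$p_value)
  de <- apply_thresholds(de, "genes")

  say("[repeats] two-pass quantification (RNA)")
  rna_rep_counts <- lapply(rna, function(s)
    count_repeat_reads(s$aln, s$sim$reads, rmsk, meta))
  rep_rna <- fam_table(rna_rep_counts, conds, "rna")

  strata <- stratify_age(rep_dip_5mC, direction = "down")
  strata_rna <- stratify_age(rep_rna, direction = "up")

  res <- list(genome = genome, meth = meth, hmc = hmc, rrbs = rrbs,
              region_metrics = list(WT = met_wt, KO = met_ko),
              dmr = dmr, dip = dip, profiles = profiles,
              repeat_dip_5mC = rep_dip_5mC,
              repeat_dip_5hmC = rep_dip_5hmC,
              repeat_rna = rep_rna, strata_dip = strata,
              strata_rna = strata_rna,
              expression = expr, diffexpr = de,
              repeat_partitions = lapply(rep_counts, `[[`, "partition"),
              summary = list(
                seed = seed,
                n_rrbs_reads = vapply(rrbs, function(x) nrow(x$sim$reads),
                                      numeric(1)),
                conversion = vapply(rrbs, function(x)
                  x$qc$non_cpg_conversion_rate, numeric(1)),
                cpg_context_frac = vapply(rrbs, function(x)
                  x$qc$context_fractions[["CG"]], numeric(1)),
                n_dmr_pass = sum(dmr$passes),
                n_genes_sig = sum(de$significant),
                n_families_dip = nrow(rep_dip_5mC),
                n_families_sig_dip = sum(rep_dip_5mC$significant),
                elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))))
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  say(sprintf("[done] %.1f s", res$summary$elapsed_s))
  invisible(res)
}

# Default per-feature expression: genes at level 1 (KO-upregulated 4x when
# their promoter CGI is hypomethylated in the effect table);
# lineage-specific repeat families derepressed 2x in KO.
default_expression <- function(genome, effects) {
  up_genes <- effects$id[effects$type == "promoter"]
  fams <- unique(genome$repeat_instances$family)
  young <- fams %in% genome$consensus_library$family[
    genome$consensus_library$age == "lineage_specific"]
  rbind(
    data.frame(feature = genome$genes$id, type = "gene", level_wt = 1,
               level_ko = ifelse(genome$genes$id %in% up_genes, 4, 1)),
    data.frame(feature = fams, type = "family", level_wt = 0.5,
               level_ko = ifelse(young, 1.0, 0.5)))
}

# Reads (unique alignments) per gene, assigned by start position.
count_gene_reads <- function(alignments, genes) {
  starts <- unique_starts(alignments)
  vapply(seq_len(nrow(genes)), function(i)
    sum(starts >= genes$start[i] & starts <= genes$end[i]), integer(1))
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- res$genome
  p <- function(...) file.path(outdir, ...)
  tsv <- function(df, name) write.table(df, p(name), sep = "\t",
                                        quote = FALSE, row.names = FALSE)
  write_fasta(setNames(g$sequence, g$chrom_name), p("genome.fasta"))
  write_bed6(data.frame(chrom = g$chrom_name, start = g$genes$start,
                        end = g$genes$end, name = g$genes$id, score = 0L,
                        strand = g$genes$strand), p("genes.bed"))
  write_bed6(data.frame(chrom = g$chrom_name, start = g$cgis$start,
                        end = g$cgis$end, name = g$cgis$id, score = 0L,
                        strand = "."), p("cgis.bed"))
  write_rmsk(cbind(g$repeat_instances, chrom = g$chrom_name),
             p("repeats.tsv"))
  write_fasta(setNames(g$consensus_library$sequence,
                       sprintf("%s|%s|%s", g$consensus_library$family,
                               g$consensus_library$repeat_class,
                               g$consensus_library$age)),
              p("consensus.fasta"))
  tsv(res$meth$truth, "methylation_truth.tsv")
  for (cond in names(res$rrbs)) {
    write_cx_report(res$rrbs[[cond]]$calls, g$sequence,
                    p(sprintf("calls_%s.cx.tsv", cond)))
  }
  tsv(res$region_metrics$WT, "region_metrics_WT.tsv")
  tsv(res$region_metrics$KO, "region_metrics_KO.tsv")
  tsv(res$dmr, "dmr.tsv")
  for (nm in names(res$profiles)) {
    tsv(res$profiles[[nm]]$profile, sprintf("metagene_%s.tsv", nm))
  }
  tsv(res$repeat_dip_5mC, "repeat_families_5mC.tsv")
  tsv(res$repeat_dip_5hmC, "repeat_families_5hmC.tsv")
  tsv(res$repeat_rna, "repeat_families_rna.tsv")
  tsv(res$strata_dip, "strata_dip_5mC.tsv")
  tsv(res$strata_rna, "strata_rna.tsv")
  tsv(res$diffexpr, "diffexpr_genes.tsv")
  su <- res$summary
  su$elapsed_s <- NULL  # keep written outputs seed-deterministic
  tsv(data.frame(key = names(unlist(su)), value = unlist(su)),
      "run_summary.tsv")
  invisible(outdir)
}
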