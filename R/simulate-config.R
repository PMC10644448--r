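# Simulation configuration: one object gathering every tunable of the
# synthetic genome, the planted methylation landscapes and the read
# simulators, so that (seed, config) fully determines all outputs.

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic-data generator.
#' Defaults reproduce the sequencing design under study: MspI-digested,
#' 40-220 bp size-selected, 49 bp single-end bisulfite reads with >99%
#' conversion; 50 bp single-end DIP and RNA reads; a small genome carrying
#' CpG islands, promoters, gene bodies, and retroelement copies of two age
#' strata (lineage-specific copies are recent, hence CpG-rich and little
#' diverged; ancestral copies carry heavy CpG-to-TpG decay and point
#' divergence).
#'
#' @param seed Integer master seed; every simulator derives its stream
#'   from it.
#' @param genome_length Contig length in bp (>= 10 kb).
#' @param gc_fraction Background GC content.
#' @param conversion_rate Probability that an unmethylated C reads as T
#'   (methylated cytosines are always protected).
#' @param sequencing_error_rate Uniform substitution rate applied after
#'   conversion; 0 keeps the read oracles exact.
#' @param rrbs_read_length,dip_read_length,rna_read_length Read lengths (bp).
#' @param size_select_min,size_select_max Inclusive fragment-size window.
#' @param directional If FALSE (default) RRBS reads come off either
#'   fragment end with equal probability.
#' @param dip_enrichment_alpha Linear immunoprecipitation enrichment: a
#'   fragment is sampled with weight `1 + alpha * (sum of planted levels
#'   of the mark over its CpGs)`.
#' @param dip_fragment_length Sonicated fragment length for DIP libraries.
#' @param rrbs_n_reads,dip_n_reads,rna_n_reads Library sizes per sample.
#' @param n_genes,gene_length_range Gene complement of the contig.
#' @param cgi_fraction Fraction of genes whose TSS is covered by a CpG
#'   island; `n_cgi_extra` islands are placed away from any TSS.
#' @param n_cgi_extra,cgi_length_range CpG-island geometry.
#' @param repeat_copy_scale Multiplier on the per-family copy numbers of
#'   the built-in library (SINEs are high-copy, LINE/LTR low-copy).
#' @param divergence_young,divergence_old Per-copy point-substitution
#'   rates for lineage-specific and ancestral copies.
#' @param cpg_decay_young,cpg_decay_old Per-copy CpG-to-TpG decay rates.
#' @param cpg_decay_old_consensus CpG decay applied to ancestral consensus
#'   sequences themselves (drives the CG-per-100-bp age stratification).
#' @param meth_baseline Named list of planted WT methylation levels per
#'   compartment: `cgi`, `promoter`, `gene_body`, `repeat_`, `intergenic`.
#' @param hmc_baseline Same for 5hmC (low, gene-body-biased, unaffected by
#'   the knockout by default).
#' @param non_cpg_level Planted methylation of non-CpG cytosines.
#' @param effect_cgi_fraction Fraction of CpG islands (with their
#'   promoters) hypomethylated in the knockout by `effect_region_fold`.
#' @param effect_region_fold,effect_family_fold Division factors applied
#'   to the planted level at targeted regions / lineage-specific repeat
#'   families in the KO landscape.
#' @return List of class `SimulationConfig`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 350000L,
                       gc_fraction = 0.42,
                       conversion_rate = 0.995,
                       sequencing_error_rate = 0,
                       rrbs_read_length = 49L,
                       dip_read_length = 50L,
                       rna_read_length = 50L,
                       size_select_min = 40L,
                       size_select_max = 220L,
                       directional = FALSE,
                       dip_enrichment_alpha = 20,
                       dip_fragment_length = 200L,
                       rrbs_n_reads = 40000L,
                       dip_n_reads = 60000L,
                       rna_n_reads = 40000L,
                       n_genes = 30L,
                       gene_length_range = c(1500L, 6000L),
                       cgi_fraction = 0.6,
                       n_cgi_extra = 8L,
                       cgi_length_range = c(400L, 1000L),
                       repeat_copy_scale = 1,
                       divergence_young = 0.02,
                       divergence_old = 0.10,
                       cpg_decay_young = 0.05,
                       cpg_decay_old = 0.30,
                       cpg_decay_old_consensus = 0.60,
                       meth_baseline = list(cgi = 0.07, promoter = 0.15,
                                            gene_body = 0.80,
                                            repeat_ = 0.85,
                                            intergenic = 0.75),
                       hmc_baseline = list(cgi = 0.02, promoter = 0.02,
                                           gene_body = 0.10,
                                           repeat_ = 0.05,
                                           intergenic = 0.03),
                       non_cpg_level = 0,
                       effect_cgi_fraction = 0.3,
                       effect_region_fold = 4,
                       effect_family_fold = 2) {
  cfg <- as.list(environment())
  rates <- c(gc_fraction, conversion_rate, sequencing_error_rate,
             cgi_fraction, effect_cgi_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates/fractions must lie in [0, 1]")
  if (genome_length < 10000L) stop("'genome_length' must be >= 10 kb")
  if (size_select_min > size_select_max) {
    stop("'size_select_min' must be <= 'size_select_max'")
  }
  if (effect_region_fold <= 0 || effect_family_fold <= 0) {
    stop("effect folds must be > 0")
  }
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig: seed", x$seed, "|", x$genome_length, "bp |",
      x$n_genes, "genes | conversion", x$conversion_rate, "\n")
  invisible(x)
}

# The built-in repeat consensus families. Lengths are kept modest so a
# full complement fits a few-hundred-kb contig; as in real rodent
# genomes, lineage-specific (young) families are a minority of families
# but SINEs are high-copy, and LTR families come as internal/external
# domain pairs, as in RepeatMasker annotation.
default_family_table <- function() {
  data.frame(
    family = c("SINE_A1", "SINE_A2", "SINE_A3",
               "SINE_B1", "SINE_B2", "SINE_B3", "SINE_B4", "SINE_B5",
               "LINE_Y1", "LINE_Y2",
               "LINE_O1", "LINE_O2", "LINE_O3", "LINE_O4",
               "LTR_Y1-int", "LTR_Y1-ext", "LTR_Y2-int", "LTR_Y2-ext",
               "LTR_O1-int", "LTR_O1-ext", "LTR_O2-int", "LTR_O2-ext",
               "LTR_O3-int", "LTR_O3-ext"),
    repeat_class = c(rep("SINE", 8), rep("LINE", 6), rep("LTR", 10)),
    age = c(rep("lineage_specific", 3), rep("ancestral", 5),
            rep("lineage_specific", 2), rep("ancestral", 4),
            rep("lineage_specific", 4), rep("ancestral", 6)),
    ltr_region = c(rep(NA_character_, 14),
                   rep(c("int", "ext"), 5)),
    length = c(180L, 160L, 200L,
               190L, 170L, 150L, 160L, 180L,
               1400L, 1200L,
               1300L, 1100L, 1200L, 1000L,
               800L, 350L, 750L, 320L,
               780L, 340L, 760L, 330L, 700L, 310L),
    n_copies = c(30L, 30L, 30L,
                 12L, 12L, 12L, 12L, 12L,
                 6L, 6L, 4L, 4L, 4L, 4L,
                 6L, 6L, 6L, 6L, 4L, 4L, 4L, 4L, 4L, 4L),
    stringsAsFactors = FALSE)
}
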