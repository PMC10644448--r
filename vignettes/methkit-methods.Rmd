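---
title: "Methods and design of methkit"
author: "methkit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of methkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`methkit` is a self-contained reimplementation of the computational
pipeline used to compare the methylome of a wild-type (WT) cell line
with that of a knockout (KO) lacking a methylation-maintenance factor:
reduced-representation bisulfite sequencing (RRBS) processing with
three-letter alignment and per-cytosine methylation calls; region-level
methylation metrics and differentially methylated region (DMR)
detection at CpG islands and promoters; gene-body metagene profiling of
5mC/5hmC DNA-immunoprecipitation (DIP-seq) tag densities; two-pass
repeat-family quantification of DIP and RNA-seq reads; and
negative-binomial count statistics with Benjamini-Hochberg correction.
Because the original sequencing data are external, every stage is
exercised on a built-in synthetic-data generator that plants a known
methylation landscape and emits reads with full provenance, so each
analysis can be scored against its own ground truth.

# The synthetic genome and landscape

`generate_genome()` assembles a single contig (350 kb by default)
containing:

* 30 genes (1.5–6 kb, random strand) with strand-aware promoters
  defined as the 2 kb interval immediately upstream of the TSS — for a
  plus-strand gene with TSS $t$, positions $[t-2000,\,t-1]$ (1-based
  closed), mirrored on the minus strand and clipped at contig edges;
* CpG islands covering 60% of TSSs plus standalone islands. Island
  sequence is GC-rich with CG dinucleotides planted every ~8 bp and an
  MspI site (`CCGG`) every ~120 bp, so that reduced-representation
  fragments of selectable size tile the islands — the defining coverage
  bias of RRBS;
* repeat copies pasted from a built-in consensus library of 24
  families (SINE/LINE/LTR; LTR families as internal/external domain
  pairs). *Lineage-specific* (young) families are a minority of
  families but high-copy for SINEs, as in rodent genomes; *ancestral*
  families receive CpG-to-TpG decay on the consensus (rate 0.6) and
  per-copy divergence (10% point substitutions, 30% additional CpG
  decay), young copies only 2%/5%. This makes consensus CG density per
  100 bp markedly lower for ancestral families (~6 vs ~14), the
  stratification that downstream age analyses read.

`plant_methylation()` assigns each CpG a WT level by compartment
(defaults: CpG islands 0.07, promoters 0.15, gene bodies 0.80, repeats
0.85, intergenic 0.75; non-CpG cytosines 0) and derives the KO
landscape by dividing the level by a configured fold at targeted
features. The default effect table hypomethylates 30% of TSS islands
(with their promoters) 4-fold and every lineage-specific repeat family
2-fold — hypomethylation concentrated at CpG-rich, low-methylated
targets and young retroelements, the phenotype under study. Symmetric
CpGs share one level keyed by the top-strand C; hemi-methylation is not
modelled. Overlapping effects do not compound: the largest fold wins.

One design point deserves emphasis. Family-level effects are applied to
each element copy *extended by one DIP fragment length*. An
immunoprecipitated fragment whose read overlaps a repeat copy also
carries flanking DNA; if the flank keeps its WT methylation, the
family's recovered IP fold is diluted by an amount that depends on
fragment geometry rather than biology. With the margin, a planted
k-fold family effect is exactly a k-fold effect on the expected IP
weight of every fragment the family can receive, which makes planted
folds interpretable as expected read-count folds. The remaining
deviation seen in recovery experiments (about −0.87 recovered log2 for
a planted −1) is the composition shift of library-size normalisation:
removing reads from depleted families inflates every family's
reads-per-million, a genuine property of the assay's normalisation, not
an artefact of the simulator.

# Read simulators

*RRBS* (`simulate_rrbs_reads()`): in-silico MspI digestion (`C^CGG`),
inclusive 40–220 bp size selection, uniform fragment sampling, 49 bp
reads off a uniformly chosen fragment end (non-directional by default,
since the pipeline aligns against both converted references).
Chemistry: a methylated cytosine (Bernoulli draw per read at the
planted level) always reads C; an unmethylated cytosine converts to T
with probability 0.995 and is otherwise retained — so the non-CpG
retention rate directly estimates conversion failure, making the
">99% conversion" QC meaningful. Sequencing errors default to 0 so
that alignment and counting oracles are exact.

*DIP-seq* (`simulate_dip_reads()`): candidate fragments of fixed length
(200 bp by default) are sampled with weight
$1 + \alpha \sum_{\text{CpG} \in \text{frag}} \text{level}$
($\alpha = 20$); the matched input samples uniformly. The linear weight
is the simplest monotone enrichment model that is analytically
checkable: with $\alpha s \gg 1$ the IP read-count ratio of two regions
approaches the ratio of their planted mark sums.

*RNA-seq* (`simulate_rnaseq_reads()`): unspliced 50 bp reads drawn
multinomially over genes and repeat instances with probability
proportional to level × feature length, in sense orientation.

All simulators are pure functions of (genome, landscape, config, seed)
and emit per-read provenance; a conservation test reconstructs every
read from its recorded origin.

# RRBS processing

Three-letter alignment (`align_bisulfite()`): the reference is copied
into a "T genome" (C→T) and an "A genome" (G→A); reads are C→T
converted and matched forward against the T genome, and
reverse-complemented + G→A converted against the A genome, so that
bisulfite conversion itself is never penalised. Candidate placements
come from a pigeonhole seed scheme — the read is split into
`max_mismatch + 1` disjoint bands and a constant-width seed from each
band is matched exactly (Biostrings `matchPDict`); any placement within
the mismatch budget must leave one band clean, so the candidate list is
complete — followed by exhaustive Hamming verification. A read is
*unique* only if its best placement has strictly fewer mismatches than
every other placement across both references; ties are ambiguous and
never feed methylation calls. The default budget is two mismatches,
counted on the converted alphabet. This is an exact small-genome
aligner: completeness is a provable property, at the price of memory
and speed that would not scale to mammalian genomes (deliberately out
of scope).

Methylation calling (`call_methylation()`): for each reference
cytosine covered by a unique read on the matching strand, C counts as
methylated and T as unmethylated (other bases, i.e. sequencing errors,
are ignored); context (CG/CHG/CHH) comes from the reference. Symmetric
CpG counts are merged onto the top-strand C, with per-strand tallies
retained so the merge is reversible. `conversion_qc()` estimates the
conversion rate from CHG+CHH cytosines and reports the context
distribution of methylated observations; an empty non-CpG denominator
is flagged rather than silently reported as zero.

# Regions and DMRs

`region_metrics()` counts a region's CpGs from the reference; a CpG is
covered with ≥1 informative read and methylated with ≥1 read showing C
(the binary-call threshold is a parameter). Percent methylation divides
methylated CpGs by *all* CpGs of the region. Two filters mirror the
study design: ≥80% of CpGs covered, and an average of ≥5 reads per
methylated CpG; because "at least 5 reads per methylated CpG" can also
be read as a per-CpG minimum, both the mean and the minimum coverage
over methylated CpGs are reported, and the pass flag uses the mean.

`dmr_scan()` pools methylated/unmethylated counts over the CpGs covered
in both conditions into a 2×2 table per region and applies a two-sided
Fisher exact test — the source analysis names no test, and Fisher on
pooled counts is exact and assumption-light; p-values are cross-checked
in the test suite against a hypergeometric enumeration oracle. A region
passes with WT/KO level ratio > 2, more than 10 shared CpGs, raw
P < 0.01 and midpoint within 5 kb of the nearest TSS. Benjamini-Hochberg
q-values are carried alongside; the filter uses the raw p-value because
that is what the thresholds print, with the adjusted column available.

`score_clones()` reproduces clonal bisulfite scoring: per CpG per clone
C = methylated, T = unmethylated, and when standard-sequencing clones
are provided, sites showing T in standard sequencing are genomic C→T
transitions — excluded from percent methylation rather than counted as
demethylation.

# DIP profiles

Tags are counted by the 5′ start of uniquely mapped reads, normalised
to reads per million uniquely mapped. `window_densities()` tiles the
gene ± 2 kb with 100 bp windows (step = width by default, so raw counts
conserve tags exactly; a smaller step gives sliding windows).
`metagene()` maps body positions to 40 relative-length bins
(`floor(40·offset/length)`, strand-aware) and each 2 kb flank to ten
200 bp bins; per-gene densities are rpm per bp (so body and flank bins
are comparable) and the profile averages genes unweighted, preventing
long genes from dominating. Bin mapping is total and exclusive; a
uniform-coverage simulation must produce a flat profile (CV < 5% at
100k reads), which the acceptance suite checks.

# Repeat quantification

Pass 1 annotates uniquely mapped reads overlapping a repeat interval
(≥1 bp) with the interval's family; multiple overlaps resolve to the
largest, and exact ties between *different* families discard the read
(ties between copies of one family still count for it). Reads the
genome could not place uniquely go to pass 2, which aligns them (both
orientations, ≤2 mismatches) against every family consensus and counts
reads whose placements all fall in one family; cross-family hits are
discarded. The partition — pass-1 assigned, tie-discarded, non-repeat
unique, pass-2 assigned, multi-family, unassigned — sums exactly to the
library, an invariant asserted in the tests.

`family_stats()` keeps retrotransposon families (SINE/LINE/LTR) with
more than 100 reads in every sample (read as per-sample, with a switch
for the summed reading), normalises to reads per million of the whole
library, reports log2 KO/WT of normalised means, tests raw counts with
the negative-binomial test below, adjusts with Benjamini-Hochberg and
flags significance at |log2 FC| > 0.5 with P < 0.05 (DIP) or P < 0.01
(repeat RNA). `stratify_age()` tabulates significant families per
(class, age) stratum, splitting LTR families by internal/external
domain.

# Count statistics

`size_factors()` is the median-of-ratios estimator over features with
all-positive counts, rescaled to geometric mean 1 so that normalising a
matrix by its own factors is idempotent. `nb_test()` follows the
classic exact-test idea for negative-binomial counts: per-feature
dispersion (squared CV of concentration) by method of moments, shared
across features, then a conditional two-sided test of the condition-A
count sum given the total, with the two-sided p-value formed by
doubling the smaller tail (capped at 1).

Dispersion sharing is the one genuinely open design choice, and it is
resolved differently for the two designs the pipeline meets:

* with replicates, the raw variance is the pooled *within-condition*
  variance (true effects then do not inflate it) and mean-binned
  sharing is used — the estimator is unbiased, so the test calibrates
  (type-I error within ±0.02 of the nominal 0.05 on a 2,000-feature
  null, asserted in the acceptance suite);
* without replicates (the DIP design), the two conditions are treated
  as replicates of each other ("blind"), which folds true effects into
  every raw estimate; sharing therefore uses the *median* within bins,
  so a minority of genuinely changed features cannot drag the shared
  dispersion up and mask themselves. This is what makes single-sample
  DIP comparisons able to flag 2-fold family effects at all, at the
  price of anticonservatism if most features changed — a documented
  assumption, standard for no-replicate designs.

Gene-level significance uses fold change > 2 (|log2 FC| > 1) with
P < 0.01. The DIP and repeat-RNA presets use |log2 FC| > 0.5 with
P < 0.05 and P < 0.01 respectively. All inequalities are strict, raw
p-values are used in the flags, and flags are recomputable from the
stored columns.

# Validation experiments and problem sizes

Two seeded experiments (`dmr_recovery_experiment()`,
`dip_recovery_experiment()`) plant effects and score recovery:

* DMR: 200 regions × 15 CpGs at 20× coverage, 20 regions hypomethylated
  4-fold (WT 0.4 → KO 0.1); recall ≥ 0.9 with zero false positives, and
  null panels across 20 seeds pass < 1% of regions. The experiment
  simulates binomial per-CpG calls directly — the exact input contract
  of `dmr_scan()` — so that many replicate panels stay cheap.
* DIP: 200k-read IP libraries with 100 bp fragments; ten families,
  chosen from the genome's own truth as the lowest-enrichment
  retrotransposon families still expected to exceed ~1,200 reads, are
  depleted 2-fold. Choosing low-share families keeps the planted set
  ~10% of the library so the composition shift of rpm normalisation
  stays small; the mean recovered log2 is −0.87 with all ten flagged at
  the DIP thresholds and no null family flagged.

The default end-to-end demonstration (`run_pipeline()`) uses a 350 kb
genome, 40k RRBS reads and 4 × 60k-read DIP IP libraries plus 4 × 40k
RNA reads; these sizes give every family past the 100-read filter and
every covered CpG ~15–30× depth while keeping a full run around two
minutes, and they scale linearly for users who want deeper libraries.

# What passing tests do and do not show

The generator emulates coverage bias (MspI + size selection),
conversion chemistry, enrichment sampling, multi-mapping from repeat
copies, and age-dependent CpG decay. It does not model PCR duplicates,
quality-score-dependent errors, adapter read-through, indels, spliced
transcripts, hemi-methylation, or chromatin-driven fragmentation
biases. Recovery results therefore demonstrate correctness of the
*computations* under a faithful but idealised read model, not
robustness to every artefact of real libraries. Likewise the metagene
machinery is validated for flatness and conservation; reproducing the
specific 3′-biased gene-body demethylation shape reported on real data
requires the real data.

# Known limitations

* Single-contig genomes are the supported scale; the exact aligner is
  O(genome × reads) in the worst case and unsuitable beyond a few Mb.
* The NB test implements the 2010-style exact conditional test, not
  shrinkage GLMs; with many replicates a modern GLM framework would be
  preferable.
* Ambiguous bisulfite reads are dropped from calling rather than
  rescued by paired-end or longer-read information.
* `pct_methylation` uses a ≥1-read binary call; at high coverage with
  imperfect conversion this overestimates the fraction of methylated
  CpGs unless the threshold parameter is raised.
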