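# Synthetic genome construction and planted methylation landscapes.

#' Generate a synthetic annotated genome
#'
#' Assembles a single-contig genome carrying genes (with strand-aware
#' TSSs and derived promoters), CpG islands overlapping a configurable
#' fraction of TSSs plus standalone islands, and repeat copies pasted from
#' a built-in consensus library. Ancestral families receive point
#' divergence and CpG-to-TpG decay (on the consensus and per copy) so
#' that their CG density per 100 bp is lower than that of
#' lineage-specific families, as in real retroelement age strata. CpG
#' islands are CpG- and MspI-site-enriched so that reduced-representation
#' fragments cover them densely.
#'
#' @param config A [sim_config()] object.
#' @param with_repeats Set FALSE to generate a repeat-free genome (used
#'   e.g. to study aligner behaviour away from repetitive sequence).
#' @return List of class `SyntheticGenome`: `chrom_name`, `sequence`,
#'   `genes`, `cgis`, `promoters`, `repeat_instances`,
#'   `consensus_library` (with per-family CG density), `config`.
#' @export
generate_genome <- function(config = sim_config(), with_repeats = TRUE) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(derive_seed(config$seed, 1L), {
    fams <- default_family_table()
    fams$sequence <- vapply(seq_len(nrow(fams)), function(i) {
      s <- cpg_rich_dna(fams$length[i], gc = 0.5, cpg_every = 12L)
      if (fams$age[i] == "ancestral") {
        s <- decay_cpg(s, config$cpg_decay_old_consensus)
        s <- mutate_seq(s, 0.08)
      }
      s
    }, character(1))
    fams$cg_per_100bp <- vapply(fams$sequence, cg_density_per_100bp,
                                numeric(1), USE.NAMES = FALSE)

    # Pool of repeat copies to paste, shuffled.
    pool <- if (with_repeats) {
      n_cp <- pmax(1L, ceiling(fams$n_copies * config$repeat_copy_scale))
      p <- fams[rep(seq_len(nrow(fams)), times = n_cp), ]
      p[sample(nrow(p)), ]
    } else fams[0, ]
    pool_i <- 0L

    glen_rng <- config$gene_length_range
    gene_len <- sample(glen_rng[1]:glen_rng[2], config$n_genes,
                       replace = TRUE)
    gene_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    has_cgi <- seq_len(config$n_genes) %in%
      sample(config$n_genes, round(config$cgi_fraction * config$n_genes))
    extra_cgi_at <- sample(config$n_genes, min(config$n_cgi_extra,
                                               config$n_genes))

    segs <- character(0)
    cur <- 0L
    genes <- cgis <- reps <- list()
    add <- function(s) {
      segs[[length(segs) + 1L]] <<- s
      start <- cur + 1L
      cur <<- cur + nchar(s)
      c(start, cur)
    }
    bg <- function(n) random_dna(n, config$gc_fraction)

    for (i in seq_len(config$n_genes)) {
      # intergenic gap, optionally hosting repeat copies / a standalone CGI
      add(bg(sample(400:900, 1L)))
      if (i %in% extra_cgi_at) {
        iv <- add(cpg_rich_dna(sample(config$cgi_length_range[1]:
                                        config$cgi_length_range[2], 1L)))
        cgis[[length(cgis) + 1L]] <- data.frame(
          id = sprintf("CGI_x%02d", match(i, extra_cgi_at)),
          start = iv[1], end = iv[2], at_tss = FALSE)
      }
      per_gene <- ceiling(nrow(pool) / config$n_genes)
      n_here <- if (pool_i < nrow(pool))
        max(0L, per_gene + sample(-2:2, 1L)) else 0L
      if (i == config$n_genes) n_here <- nrow(pool) - pool_i  # flush
      while (n_here > 0L && pool_i < nrow(pool)) {
        pool_i <- pool_i + 1L
        cp <- pool[pool_i, ]
        strand <- sample(c("+", "-"), 1L)
        s <- mutate_seq(cp$sequence,
                        if (cp$age == "ancestral") config$divergence_old
                        else config$divergence_young)
        s <- decay_cpg(s, if (cp$age == "ancestral") config$cpg_decay_old
                          else config$cpg_decay_young)
        if (strand == "-") s <- revcomp(s)
        iv <- add(s)
        reps[[length(reps) + 1L]] <- data.frame(
          id = sprintf("rep_%03d", pool_i), family = cp$family,
          repeat_class = cp$repeat_class, age = cp$age,
          ltr_region = cp$ltr_region, start = iv[1], end = iv[2],
          strand = strand)
        add(bg(sample(80:200, 1L)))
        n_here <- n_here - 1L
      }
      add(bg(sample(2100:2600, 1L)))  # promoter room

      gid <- sprintf("gene_%02d", i)
      glen <- gene_len[i]
      if (has_cgi[i]) {
        lc <- sample(config$cgi_length_range[1]:config$cgi_length_range[2],
                     1L)
        lup <- floor(lc / 2); ldown <- lc - lup
        cgi_s <- cpg_rich_dna(lc)
        if (gene_strand[i] == "+") {
          # island spans the TSS: lup bases upstream, ldown into the body
          iv_cgi <- add(cgi_s)
          gstart <- iv_cgi[1] + lup
          iv_rest <- add(bg(glen - ldown))
          gend <- iv_rest[2]
        } else {
          iv_rest <- add(bg(glen - ldown))
          gstart <- iv_rest[1]
          iv_cgi <- add(cgi_s)
          gend <- iv_cgi[1] + ldown - 1L
        }
        cgis[[length(cgis) + 1L]] <- data.frame(
          id = sprintf("CGI_%s", gid), start = iv_cgi[1], end = iv_cgi[2],
          at_tss = TRUE)
      } else {
        iv <- add(bg(glen)); gstart <- iv[1]; gend <- iv[2]
      }
      tss <- if (gene_strand[i] == "+") gstart else gend
      genes[[length(genes) + 1L]] <- data.frame(
        id = gid, start = gstart, end = gend, strand = gene_strand[i],
        tss = tss)
    }
    add(bg(2200L))  # trailing pad: promoter room for a final minus gene

    if (cur > config$genome_length) {
      stop("cannot place all features: layout needs ", cur,
           " bp but genome_length is ", config$genome_length,
           " (last feature: ", genes[[length(genes)]]$id, ")")
    }
    if (cur < config$genome_length) add(bg(config$genome_length - cur))

    genes <- do.call(rbind, genes)
    cgis <- if (length(cgis)) do.call(rbind, cgis) else
      data.frame(id = character(0), start = integer(0), end = integer(0),
                 at_tss = logical(0))
    reps <- if (length(reps)) do.call(rbind, reps) else
      data.frame(id = character(0), family = character(0),
                 repeat_class = character(0), age = character(0),
                 ltr_region = character(0), start = integer(0),
                 end = integer(0), strand = character(0))
    genome <- structure(list(
      chrom_name = "chrSim",
      sequence = paste(segs, collapse = ""),
      genes = genes,
      cgis = cgis,
      promoters = define_promoters(genes, config$genome_length),
      repeat_instances = reps,
      consensus_library = fams,
      config = config), class = "SyntheticGenome")
    genome
  })
}

#' @export
print.SyntheticGenome <- function(x, ...) {
  cat("SyntheticGenome:", x$chrom_name, "-", nchar(x$sequence), "bp,",
      nrow(x$genes), "genes,", nrow(x$cgis), "CGIs,",
      nrow(x$repeat_instances), "repeat copies from",
      nrow(x$consensus_library), "families\n")
  invisible(x)
}

# CpG-island-like sequence: GC-rich background with CG dinucleotides
# planted every ~`cpg_every` bp and an MspI site (CCGG) every ~120 bp so
# that reduced-representation fragments of selectable size exist.
cpg_rich_dna <- function(n, gc = 0.60, cpg_every = 8L, msp1_every = 120L) {
  ch <- dna_chars(random_dna(n, gc))
  if (n >= cpg_every + 2L) {
    at <- seq(2L, n - 1L, by = cpg_every) +
      sample(0:(cpg_every %/% 2), length(seq(2L, n - 1L, by = cpg_every)),
             replace = TRUE)
    at <- at[at <= n - 1L]
    ch[at] <- "C"; ch[at + 1L] <- "G"
  }
  if (n >= msp1_every + 4L) {
    at <- seq(10L, n - 4L, by = msp1_every)
    for (p in at) ch[p:(p + 3L)] <- c("C", "C", "G", "G")
  }
  paste(ch, collapse = "")
}

#' CG dinucleotide density
#'
#' Counts CG dinucleotides per 100 bp with an overlap-free scan (CGs
#' cannot overlap each other, so this equals the plain occurrence count).
#'
#' @param seq A DNA string.
#' @return Numeric: `100 * n_CG / length`; NA (with a warning) for an
#'   empty sequence.
#' @export
cg_density_per_100bp <- function(seq) {
  if (is.na(seq) || nchar(seq) == 0L) {
    warning("empty sequence: CG density undefined")
    return(NA_real_)
  }
  ch <- dna_chars(seq)
  n_cg <- sum(ch[-length(ch)] == "C" & ch[-1] == "G")
  100 * n_cg / nchar(seq)
}

#' Plant per-CpG methylation landscapes for WT and KO
#'
#' Assigns every CpG a baseline level by genomic compartment (intergenic,
#' gene body, repeat, promoter, CpG island, in increasing precedence),
#' then derives the KO landscape by dividing the level by the configured
#' fold at the targeted features. The default effect table emulates the
#' phenotype under study: a fraction of CpG islands together with their
#' promoters is hypomethylated `effect_region_fold`-fold, and every
#' lineage-specific repeat family `effect_family_fold`-fold. Symmetric
#' CpGs share a single level keyed by the top-strand C
#' (hemi-methylation is not modelled).
#'
#' @param genome A `SyntheticGenome`.
#' @param config Its [sim_config()] (defaults to `genome$config`).
#' @param effects Optional data.frame(`type` in cgi/promoter/family/
#'   gene_body/interval, `id`, `fold`) overriding the default effect
#'   table; an empty data.frame plants no effect (KO == WT).
#' @param mark `"5mC"` (baselines and effects) or `"5hmC"` (low
#'   gene-body-biased baseline, no KO effect by default).
#' @return List with `wt` and `ko` (`MethylationLandscape`: genome-length
#'   `level` vector keyed at top-strand CpG Cs, `is_cpg_c` mask,
#'   `non_cpg_level`, `condition`, `mark`) and `truth`, a per-feature
#'   table of mean planted WT/KO levels.
#' @export
plant_methylation <- function(genome, config = genome$config,
                              effects = NULL, mark = c("5mC", "5hmC")) {
  mark <- match.arg(mark)
  n <- nchar(genome$sequence)
  ch <- dna_chars(genome$sequence)
  is_cpg_c <- c(ch[-n] == "C" & ch[-1] == "G", FALSE)

  base <- if (mark == "5mC") config$meth_baseline else config$hmc_baseline
  lv <- rep(base$intergenic, n)
  assign_iv <- function(lv, df, value) {
    for (k in seq_len(nrow(df))) lv[df$start[k]:df$end[k]] <- value
    lv
  }
  lv <- assign_iv(lv, genome$genes, base$gene_body)
  lv <- assign_iv(lv, genome$repeat_instances, base$repeat_)
  lv <- assign_iv(lv, genome$promoters, base$promoter)
  lv <- assign_iv(lv, genome$cgis, base$cgi)
  lv[!is_cpg_c] <- 0

  if (is.null(effects)) {
    effects <- if (mark == "5mC") default_effects(genome, config)
               else data.frame(type = character(0), id = character(0),
                               fold = numeric(0))
  }
  if (nrow(effects) > 0 && any(effects$fold <= 0)) {
    stop("effect folds must be > 0")
  }
  # Per-position fold: overlapping effects (e.g. a CGI and the promoter
  # containing it) do not compound; the largest fold wins.
  fold_at <- rep(1, n)
  feature_iv <- function(type, id) {
    switch(type,
      cgi = genome$cgis[genome$cgis$id == id, c("start", "end")],
      promoter = genome$promoters[genome$promoters$gene_id == id,
                                  c("start", "end")],
      gene_body = genome$genes[genome$genes$id == id, c("start", "end")],
      family = {
        # element copies plus one DIP-fragment margin: every fragment
        # whose read overlaps a copy is then fully inside the effect
        # region, so the planted family fold carries to the IP signal
        # undiluted by flanking DNA (documented in the methods vignette)
        iv <- genome$repeat_instances[
          genome$repeat_instances$family == id, c("start", "end")]
        iv$start <- pmax(1L, iv$start - config$dip_fragment_length)
        iv$end <- pmin(n, iv$end + config$dip_fragment_length)
        iv
      },
      interval = {
        p <- as.integer(strsplit(id, "-", fixed = TRUE)[[1]])
        data.frame(start = p[1], end = p[2])
      },
      stop("unknown effect type: ", type))
  }
  for (k in seq_len(nrow(effects))) {
    iv <- feature_iv(effects$type[k], effects$id[k])
    if (nrow(iv) == 0L) {
      stop("effect references unknown feature: ", effects$type[k], " ",
           effects$id[k])
    }
    for (r in seq_len(nrow(iv))) {
      idx <- iv$start[r]:iv$end[r]
      fold_at[idx] <- pmax(fold_at[idx], effects$fold[k])
    }
  }
  lv_ko <- lv / fold_at

  truth <- effect_truth(genome, effects, lv, lv_ko, is_cpg_c)
  mk_ls <- function(level, condition) {
    structure(list(condition = condition, mark = mark, level = level,
                   is_cpg_c = is_cpg_c,
                   non_cpg_level = config$non_cpg_level),
              class = "MethylationLandscape")
  }
  list(wt = mk_ls(lv, "WT"), ko = mk_ls(lv_ko, "KO"), truth = truth,
       effects = effects)
}

#' @export
print.MethylationLandscape <- function(x, ...) {
  cat("MethylationLandscape:", x$condition, x$mark, "-",
      sum(x$is_cpg_c), "CpGs, mean planted level",
      round(mean(x$level[x$is_cpg_c]), 3), "\n")
  invisible(x)
}

# Deterministic default effect table: a seed-derived sample of
# TSS-associated CGIs (plus their promoters) and every lineage-specific
# repeat family.
default_effects <- function(genome, config) {
  with_seed(derive_seed(config$seed, 7L), {
    tss_cgis <- genome$cgis$id[genome$cgis$at_tss]
    n_pick <- round(config$effect_cgi_fraction * length(tss_cgis))
    picked <- sort(sample(tss_cgis, n_pick))
    prom_ids <- sub("^CGI_", "", picked)
    fams <- unique(genome$consensus_library$family[
      genome$consensus_library$age == "lineage_specific"])
    fams <- fams[fams %in% genome$repeat_instances$family]
    blocks <- list(
      if (length(picked)) data.frame(type = "cgi", id = picked,
                                     fold = config$effect_region_fold),
      if (length(prom_ids)) data.frame(type = "promoter", id = prom_ids,
                                       fold = config$effect_region_fold),
      if (length(fams)) data.frame(type = "family", id = fams,
                                   fold = config$effect_family_fold))
    blocks <- blocks[!vapply(blocks, is.null, logical(1))]
    if (length(blocks)) do.call(rbind, blocks)
    else data.frame(type = character(0), id = character(0),
                    fold = numeric(0))
  })
}

# Per-feature mean planted level in both conditions, over the feature's
# CpGs (the ground-truth table tests and users read).
effect_truth <- function(genome, effects, lv_wt, lv_ko, is_cpg_c) {
  feats <- rbind(
    data.frame(feature = genome$cgis$id, type = "cgi",
               start = genome$cgis$start, end = genome$cgis$end),
    data.frame(feature = genome$promoters$gene_id, type = "promoter",
               start = genome$promoters$start,
               end = genome$promoters$end),
    if (nrow(genome$repeat_instances) > 0)
      data.frame(feature = genome$repeat_instances$family, type = "family",
                 start = genome$repeat_instances$start,
                 end = genome$repeat_instances$end))
  rows <- lapply(split(feats, list(feats$feature, feats$type), drop = TRUE),
    function(f) {
      idx <- unlist(Map(seq.int, f$start, f$end))
      idx <- idx[is_cpg_c[idx]]
      data.frame(feature = f$feature[1], type = f$type[1],
                 n_cpg = length(idx),
                 wt_level = if (length(idx)) mean(lv_wt[idx]) else NA_real_,
                 ko_level = if (length(idx)) mean(lv_ko[idx]) else NA_real_)
    })
  tr <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  key <- paste(tr$type, tr$feature)
  ekey <- paste(effects$type, effects$id)
  tr$planted_fold <- ifelse(key %in% ekey,
                            effects$fold[match(key, ekey)], 1)
  tr
}

# Planted methylation level of the cytosine read at genome position `pos`
# on `strand` ("+": top-strand C at pos; "-": bottom-strand C paired with
# the G at pos, sharing the level of the top-strand C one base left when
# in CpG context).
level_at <- function(landscape, pos, strand) {
  lv <- numeric(length(pos))
  p <- strand == "+"
  lv[p] <- ifelse(landscape$is_cpg_c[pos[p]], landscape$level[pos[p]],
                  landscape$non_cpg_level)
  m <- !p
  pm <- pos[m]
  prev_is_cpg <- pm > 1L & landscape$is_cpg_c[pmax(pm - 1L, 1L)]
  lv[m] <- ifelse(prev_is_cpg, landscape$level[pmax(pm - 1L, 1L)],
                  landscape$non_cpg_level)
  lv
}
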