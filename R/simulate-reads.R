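# Read simulators: RRBS (bisulfite), DIP (enrichment), RNA-seq.
# Every simulator is a pure function of (genome, landscape/expression,
# config, seed) and emits a per-read provenance truth table.

#' Simulate an RRBS library
#'
#' Digests the genome with MspI in silico, size-selects fragments
#' (inclusive bounds), samples fragments uniformly with replacement, and
#' sequences the first `rrbs_read_length` bases from a uniformly chosen
#' fragment end (both ends, unless `directional`). Bisulfite chemistry:
#' a methylated cytosine (Bernoulli draw at its planted level, per read)
#' always reads C; an unmethylated cytosine reads T with probability
#' `conversion_rate` and C otherwise (failed conversion).
#'
#' @param genome A `SyntheticGenome`.
#' @param landscape A `MethylationLandscape` for the condition sequenced.
#' @param config [sim_config()]; defaults to `genome$config`.
#' @param seed Stream seed for this library (vary it between samples);
#'   defaults to `config$seed`.
#' @param n_reads Library size; defaults to `config$rrbs_n_reads`.
#' @return List: `reads` (data.frame `id`, `seq`), `truth` (per read:
#'   fragment coordinates, strand, read interval `start`/`end` on the
#'   reference), `fragments` (the size-selected digest).
#' @export
simulate_rrbs_reads <- function(genome, landscape, config = genome$config,
                                seed = config$seed,
                                n_reads = config$rrbs_n_reads) {
  frags <- size_select(msp1_digest(genome$sequence),
                       config$size_select_min, config$size_select_max)
  if (nrow(frags) == 0L) {
    warning("no fragments survive size selection: empty library")
    return(list(reads = data.frame(id = character(0), seq = character(0)),
                truth = data.frame(), fragments = frags))
  }
  with_seed(derive_seed(seed, 2L), {
    fi <- sample.int(nrow(frags), n_reads, replace = TRUE)
    strand <- if (config$directional) rep("+", n_reads) else
      sample(c("+", "-"), n_reads, replace = TRUE)
    fs <- frags$start[fi]; fe <- frags$end[fi]
    L <- pmin(config$rrbs_read_length, frags$length[fi])
    rstart <- ifelse(strand == "+", fs, fe - L + 1L)
    rend <- rstart + L - 1L
    tmpl <- substring(genome$sequence, rstart, rend)
    tmpl[strand == "-"] <- revcomp(tmpl[strand == "-"])
    seqs <- bisulfite_convert(tmpl, rstart, rend, strand, landscape,
                              config)
    ids <- sprintf("rrbs_%s_%06d", landscape$condition, seq_len(n_reads))
    list(reads = data.frame(id = ids, seq = seqs),
         truth = data.frame(id = ids, frag_start = fs, frag_end = fe,
                            strand = strand, start = rstart, end = rend,
                            template = tmpl),
         fragments = frags)
  })
}

# Vectorised bisulfite conversion of read templates (already in read
# orientation). Positions map back to the reference to look up planted
# levels; sequencing errors, if configured, are applied afterwards.
bisulfite_convert <- function(tmpl, rstart, rend, strand, landscape,
                              config) {
  lens <- nchar(tmpl)
  flat <- unlist(strsplit(tmpl, "", fixed = TRUE), use.names = FALSE)
  ridx <- rep(seq_along(tmpl), lens)
  offs <- sequence(lens)
  gpos <- ifelse(rep(strand, lens) == "+",
                 rep(rstart, lens) + offs - 1L,
                 rep(rend, lens) - offs + 1L)
  isc <- flat == "C"
  lv <- level_at(landscape, gpos[isc], rep(strand, lens)[isc])
  methylated <- runif(sum(isc)) < lv
  converted <- runif(sum(isc)) < config$conversion_rate
  flat[isc] <- ifelse(methylated, "C", ifelse(converted, "T", "C"))
  if (config$sequencing_error_rate > 0) {
    err <- which(runif(length(flat)) < config$sequencing_error_rate)
    if (length(err)) {
      shift <- sample.int(3L, length(err), replace = TRUE)
      flat[err] <- BASES[(match(flat[err], BASES) - 1L + shift) %% 4L + 1L]
    }
  }
  vapply(split(flat, ridx), paste, character(1), collapse = "")
}

#' Simulate a DIP-seq library (IP + input)
#'
#' Models immunoprecipitation of fragments carrying a cytosine mark: each
#' candidate fragment (every `dip_fragment_length` window) is sampled
#' with weight `1 + dip_enrichment_alpha * (sum of planted levels of the
#' mark over its CpGs)`; the matched input library samples fragments
#' uniformly. Reads are the first `dip_read_length` bases of a uniformly
#' chosen fragment end; DIP libraries are not bisulfite treated, so the
#' sequence is unconverted.
#'
#' @inheritParams simulate_rrbs_reads
#' @param landscape Landscape of the assayed mark (5mC or 5hmC).
#' @param mark Label recorded in read ids and truth.
#' @param n_reads Reads per library (IP and input each).
#' @return List: `ip`, `input` (data.frames `id`, `seq`) and matching
#'   truth tables (`truth_ip`, `truth_input`) with fragment start,
#'   strand and read interval.
#' @export
simulate_dip_reads <- function(genome, landscape, mark = landscape$mark,
                               config = genome$config, seed = config$seed,
                               n_reads = config$dip_n_reads) {
  glen <- nchar(genome$sequence)
  flen <- config$dip_fragment_length
  if (flen > glen) stop("fragment length exceeds the contig")
  cum <- c(0, cumsum(landscape$level))
  starts_all <- seq_len(glen - flen + 1L)
  fragsum <- cum[starts_all + flen] - cum[starts_all]
  w <- 1 + config$dip_enrichment_alpha * fragsum
  with_seed(derive_seed(seed, 3L), {
    draw <- function(prob, n, tag) {
      s <- sample(starts_all, n, replace = TRUE, prob = prob)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      L <- config$dip_read_length
      rstart <- ifelse(strand == "+", s, s + flen - L)
      rend <- rstart + L - 1L
      seqs <- substring(genome$sequence, rstart, rend)
      seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
      ids <- sprintf("dip_%s_%s_%s_%06d", mark, landscape$condition, tag,
                     seq_len(n))
      list(reads = data.frame(id = ids, seq = seqs),
           truth = data.frame(id = ids, frag_start = s,
                              frag_end = s + flen - 1L, strand = strand,
                              start = rstart, end = rend,
                              frag_marksum = fragsum[match(s, starts_all)]))
    }
    ip <- draw(w, n_reads, "IP")
    inp <- draw(NULL, n_reads, "input")
    list(ip = ip$reads, input = inp$reads,
         truth_ip = ip$truth, truth_input = inp$truth)
  })
}

#' Simulate an RNA-seq sample
#'
#' Draws reads from gene bodies and repeat instances with multinomial
#' probabilities proportional to `level * feature_length` (family level
#' is spread over the family's copies by length). Reads are unspliced
#' `rna_read_length`-mers in the sense orientation of the feature.
#'
#' @inheritParams simulate_rrbs_reads
#' @param expression data.frame with columns `feature`, `type`
#'   (`"gene"`/`"family"`) and `level` (>= 0; relative concentration).
#' @param sample_name Used in read ids.
#' @return List: `reads` (data.frame `id`, `seq`) and `truth` (read ->
#'   feature provenance with the read's genomic interval and strand).
#' @export
simulate_rnaseq_reads <- function(genome, expression,
                                  config = genome$config,
                                  seed = config$seed,
                                  n_reads = config$rna_n_reads,
                                  sample_name = "S1") {
  stopifnot(all(c("feature", "type", "level") %in% names(expression)))
  if (all(expression$level <= 0)) stop("all expression levels are zero")
  known <- ifelse(expression$type == "gene",
                  expression$feature %in% genome$genes$id,
                  expression$feature %in% genome$repeat_instances$family)
  if (!all(known)) {
    stop("unknown features in expression table: ",
         paste(expression$feature[!known], collapse = ", "))
  }
  # expand family rows to instances, splitting level by length
  units <- do.call(rbind, lapply(seq_len(nrow(expression)), function(k) {
    e <- expression[k, ]
    if (e$type == "gene") {
      g <- genome$genes[genome$genes$id == e$feature, ]
      data.frame(feature = e$feature, start = g$start, end = g$end,
                 strand = g$strand, weight = e$level * (g$end - g$start + 1L))
    } else {
      ri <- genome$repeat_instances[
        genome$repeat_instances$family == e$feature, ]
      data.frame(feature = e$feature, start = ri$start, end = ri$end,
                 strand = ri$strand,
                 weight = e$level * (ri$end - ri$start + 1L))
    }
  }))
  L <- config$rna_read_length
  units <- units[units$end - units$start + 1L >= L & units$weight > 0, ]
  if (nrow(units) == 0L) stop("no expressible feature is >= one read long")
  with_seed(derive_seed(seed, 4L), {
    cnt <- as.vector(stats::rmultinom(1, n_reads,
                                      units$weight / sum(units$weight)))
    ui <- rep(seq_len(nrow(units)), cnt)
    maxs <- units$end[ui] - L + 1L
    rstart <- units$start[ui] +
      floor(runif(length(ui)) * (maxs - units$start[ui] + 1L))
    rend <- rstart + L - 1L
    seqs <- substring(genome$sequence, rstart, rend)
    minus <- units$strand[ui] == "-"
    seqs[minus] <- revcomp(seqs[minus])
    ord <- sample.int(length(ui))  # shuffle so files are not block-sorted
    ids <- sprintf("rna_%s_%06d", sample_name, seq_along(ui))
    list(reads = data.frame(id = ids, seq = seqs[ord]),
         truth = data.frame(id = ids, feature = units$feature[ui][ord],
                            start = rstart[ord], end = rend[ord],
                            strand = units$strand[ui][ord]))
  })
}
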