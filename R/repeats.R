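# Two-pass repeat-family quantification. Pass 1 annotates uniquely mapped
# reads with the repeat interval they overlap; reads the genome could not
# place uniquely are rescued in pass 2 by alignment to the family
# consensus library. Family counts feed library-size normalisation, log2
# KO/WT ratios and the negative-binomial test, with age stratification.

#' Pass 1: annotate uniquely mapped reads with repeat families
#'
#' A uniquely mapped read overlapping a repeat interval by at least one
#' bp is counted for that interval's family; when several intervals
#' overlap, the largest overlap wins and exact ties between different
#' families discard the read (ties between copies of the same family
#' still count for it). Unique reads with no repeat overlap drop out of
#' repeat counting; ambiguous and unaligned reads are forwarded to
#' pass 2.
#'
#' @param alignments data.frame from [align_unique()].
#' @param rmsk data.frame of repeat instances: `family`, `start`, `end`
#'   (plus any metadata columns), sorted by `start`.
#' @return List: `counts` (named per-family read counts), `assigned`
#'   (read id -> family), `tie_discarded`, `non_repeat` (unique read
#'   ids off repeats), `leftover_ids` (for pass 2).
#' @export
pass1_annotate <- function(alignments, rmsk) {
  if (nrow(rmsk) > 0) {
    if (any(rmsk$end < rmsk$start)) stop("malformed repeat annotation")
    if (is.unsorted(rmsk$start)) stop("repeat annotation must be sorted")
  }
  uni <- alignments[alignments$status == "unique", , drop = FALSE]
  leftover <- alignments$read_id[alignments$status != "unique"]
  if (nrow(uni) == 0L || nrow(rmsk) == 0L) {
    return(list(counts = integer(0), assigned = data.frame(
      read_id = character(0), family = character(0)),
      tie_discarded = character(0),
      non_repeat = uni$read_id, leftover_ids = leftover))
  }
  rir <- IRanges::IRanges(rmsk$start, rmsk$end)
  air <- IRanges::IRanges(uni$pos, width = uni$width)
  ov <- IRanges::findOverlaps(air, rir, minoverlap = 1L)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  ow <- IRanges::width(IRanges::pintersect(air[qh], rir[sh]))
  assigned <- character(0); tie <- character(0)
  if (length(qh)) {
    res <- vapply(split(seq_along(qh), qh), function(ii) {
      best <- ii[ow[ii] == max(ow[ii])]
      fams <- unique(rmsk$family[sh[best]])
      if (length(fams) == 1L) fams else NA_character_
    }, character(1))
    hit_reads <- uni$read_id[as.integer(names(res))]
    assigned <- setNames(res[!is.na(res)], hit_reads[!is.na(res)])
    tie <- hit_reads[is.na(res)]
  }
  non_repeat <- setdiff(uni$read_id, c(names(assigned), tie))
  counts <- table(factor(assigned, levels = sort(unique(rmsk$family))))
  list(counts = setNames(as.integer(counts), names(counts)),
       assigned = data.frame(read_id = names(assigned),
                             family = unname(assigned)),
       tie_discarded = tie, non_repeat = non_repeat,
       leftover_ids = leftover)
}

#' Pass 2: assign leftover reads by consensus alignment
#'
#' Aligns each read (both orientations) against every family consensus
#' with at most `max_mismatch` substitutions. A read all of whose
#' placements fall in one family is counted for it — multiple placements
#' within the family (several positions, or several members) are fine;
#' reads hitting two or more families are discarded.
#'
#' @param reads data.frame with `id`, `seq` for the reads forwarded from
#'   pass 1.
#' @param consensus_library data.frame with `family`, `sequence`.
#' @param max_mismatch Substitution budget per placement.
#' @return List: `counts` (named per-family), `assigned`,
#'   `multi_family_discarded`, `unassigned` (no placement at all).
#' @export
pass2_annotate <- function(reads, consensus_library, max_mismatch = 2L) {
  if (nrow(consensus_library) == 0L) stop("empty consensus library")
  fams <- consensus_library$family
  seqs <- consensus_library$sequence
  spacer <- strrep("N", 60L)
  subject <- paste(seqs, collapse = spacer)
  # map subject position -> family
  starts <- cumsum(c(1L, head(nchar(seqs) + nchar(spacer), -1L)))
  fam_of <- function(pos) fams[findInterval(pos, starts)]
  hit_families <- function(rv) {
    pl <- find_placements(rv, subject, max_mismatch)
    lapply(pl, fam_of)
  }
  if (nrow(reads) == 0L) {
    return(list(counts = setNames(integer(length(unique(fams))),
                                  sort(unique(fams))),
                assigned = data.frame(read_id = character(0),
                                      family = character(0)),
                multi_family_discarded = character(0),
                unassigned = character(0)))
  }
  f_fwd <- hit_families(reads$seq)
  f_rev <- hit_families(revcomp(reads$seq))
  fam_sets <- Map(function(a, b) unique(c(a, b)), f_fwd, f_rev)
  nf <- lengths(fam_sets)
  one <- nf == 1L
  assigned <- data.frame(read_id = reads$id[one],
                         family = unlist(fam_sets[one], use.names = FALSE))
  counts <- table(factor(assigned$family, levels = sort(unique(fams))))
  list(counts = setNames(as.integer(counts), names(counts)),
       assigned = assigned,
       multi_family_discarded = reads$id[nf > 1L],
       unassigned = reads$id[nf == 0L])
}

#' Two-pass repeat counting for one sample
#'
#' Runs [pass1_annotate()] and [pass2_annotate()] and returns per-family
#' counts for both passes together with the read partition (every read
#' lands in exactly one of: pass-1 assigned, pass-1 tie-discarded,
#' non-repeat unique, pass-2 assigned, pass-2 multi-family discarded,
#' pass-2 unassigned).
#'
#' @param alignments data.frame from [align_unique()] for the sample.
#' @param reads The sample's reads (data.frame `id`, `seq`).
#' @param rmsk Repeat instance annotation (see [pass1_annotate()]).
#' @param consensus_library data.frame with `family`, `sequence`.
#' @param max_mismatch Pass-2 substitution budget.
#' @return List: `counts` data.frame (`family`, `count_pass1`,
#'   `count_pass2`, `count_total`), `partition` (named sizes),
#'   `library_size` (total reads in the sample).
#' @export
count_repeat_reads <- function(alignments, reads, rmsk, consensus_library,
                               max_mismatch = 2L) {
  p1 <- pass1_annotate(alignments, rmsk)
  lo <- reads[reads$id %in% p1$leftover_ids, , drop = FALSE]
  p2 <- pass2_annotate(lo, consensus_library, max_mismatch)
  fams <- sort(unique(c(names(p1$counts), names(p2$counts),
                        consensus_library$family)))
  c1 <- setNames(integer(length(fams)), fams)
  c1[names(p1$counts)] <- p1$counts
  c2 <- setNames(integer(length(fams)), fams)
  c2[names(p2$counts)] <- p2$counts
  partition <- c(pass1_assigned = nrow(p1$assigned),
                 pass1_tie_discarded = length(p1$tie_discarded),
                 non_repeat_unique = length(p1$non_repeat),
                 pass2_assigned = nrow(p2$assigned),
                 pass2_multi_family = length(p2$multi_family_discarded),
                 pass2_unassigned = length(p2$unassigned))
  list(counts = data.frame(family = fams, count_pass1 = unname(c1),
                           count_pass2 = unname(c2),
                           count_total = unname(c1 + c2)),
       partition = partition,
       library_size = nrow(reads))
}

#' Per-family differential statistics
#'
#' Restricts to retrotransposon families (SINE/LINE/LTR) with more than
#' `min_reads` total reads in EVERY sample of the assay, normalises
#' counts to reads per million of library size, computes the log2 KO/WT
#' ratio of normalised means, tests counts with [nb_test()] (library-size
#' size factors), adjusts with [bh_adjust()] and flags significance at
#' the assay's thresholds ([apply_thresholds()] preset `"dip"` or
#' `"repeats_rna"`).
#'
#' @param count_matrix Integer matrix, families x samples (`count_total`).
#' @param conditions Condition label per sample (WT/KO; factor levels
#'   order the ratio as KO over WT when WT is the first level).
#' @param meta data.frame with `family`, `repeat_class`, `age`,
#'   `ltr_region`, and optionally `cg_per_100bp`.
#' @param library_sizes Total reads per sample (whole library, not just
#'   repeat-assigned reads).
#' @param min_reads Per-sample raw-count retention threshold (strict
#'   inequality, "more than").
#' @param assay `"dip"` or `"rna"` (chooses the significance preset).
#' @param per_sample_filter Apply the threshold in every sample (default)
#'   or to the summed counts.
#' @return data.frame, one row per retained family: class/age metadata,
#'   raw and normalised counts per sample, `log2_ratio`, `p_value`,
#'   `q_value`, `significant`, `direction`, `consensus_cg_per_100bp`.
#' @export
family_stats <- function(count_matrix, conditions, meta, library_sizes,
                         min_reads = 100L, assay = c("dip", "rna"),
                         per_sample_filter = TRUE) {
  assay <- match.arg(assay)
  count_matrix <- as.matrix(count_matrix)
  if (any(library_sizes <= 0)) stop("zero library size")
  if (length(library_sizes) != ncol(count_matrix)) {
    stop("one library size per sample is required")
  }
  conditions <- as.factor(conditions)
  m <- meta[match(rownames(count_matrix), meta$family), ]
  retro <- m$repeat_class %in% c("SINE", "LINE", "LTR")
  enough <- if (per_sample_filter) {
    rowSums(count_matrix > min_reads) == ncol(count_matrix)
  } else rowSums(count_matrix) > min_reads
  keep <- retro & enough & !is.na(m$repeat_class)
  k <- count_matrix[keep, , drop = FALSE]
  m <- m[keep, , drop = FALSE]
  if (nrow(k) == 0L) {
    warning("no family passes the class and read-count filters")
  }
  rpm <- sweep(k, 2, library_sizes / 1e6, "/")
  lvl <- levels(conditions)
  rpm_wt <- rowMeans(rpm[, conditions == lvl[1], drop = FALSE])
  rpm_ko <- rowMeans(rpm[, conditions == lvl[2], drop = FALSE])
  nb <- if (nrow(k) > 0) {
    nb_test(k, conditions, sf = library_sizes / exp(mean(log(library_sizes))))
  } else data.frame(p_value = numeric(0))
  res <- data.frame(
    family = rownames(k),
    repeat_class = m$repeat_class, age = m$age,
    ltr_region = m$ltr_region,
    log2_ratio = log2(rpm_ko / rpm_wt),
    p_value = nb$p_value,
    q_value = if (nrow(k) > 0) bh_adjust(nb$p_value) else numeric(0),
    consensus_cg_per_100bp =
      if ("cg_per_100bp" %in% names(m)) m$cg_per_100bp else NA_real_,
    row.names = NULL)
  res <- cbind(res,
               setNames(as.data.frame(k), paste0("count_", colnames(k))),
               setNames(as.data.frame(rpm), paste0("rpm_", colnames(k))))
  flagged <- apply_thresholds(
    data.frame(log2_fold_change = res$log2_ratio, p_value = res$p_value),
    preset = if (assay == "dip") "dip" else "repeats_rna")
  res$significant <- flagged$significant
  res$direction <- flagged$direction
  res
}

#' Stratify significant families by class and age
#'
#' Tabulates, per (repeat class, age) stratum — LTR families additionally
#' split by internal/external domain — how many families are significant
#' and in which direction. Families without an age label fall in an
#' `"unlabelled"` stratum.
#'
#' @param table data.frame from [family_stats()].
#' @param direction Count significance in `"any"`, `"up"` or `"down"`
#'   direction (up = higher in KO).
#' @return data.frame: `repeat_class`, `age`, `ltr_region`, `n_families`,
#'   `n_significant`, `pct_significant`.
#' @export
stratify_age <- function(table, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  age <- ifelse(is.na(table$age) | table$age == "", "unlabelled",
                table$age)
  ltr <- ifelse(table$repeat_class == "LTR" & !is.na(table$ltr_region),
                table$ltr_region, NA_character_)
  sig <- table$significant &
    (direction == "any" | (!is.na(table$direction) &
                             table$direction == direction))
  key <- paste(table$repeat_class, age, ltr, sep = "\r")
  rows <- lapply(split(seq_len(nrow(table)), key), function(ii) {
    data.frame(repeat_class = table$repeat_class[ii[1]], age = age[ii[1]],
               ltr_region = ltr[ii[1]], n_families = length(ii),
               n_significant = sum(sig[ii]),
               pct_significant = 100 * sum(sig[ii]) / length(ii))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$repeat_class, out$age), ]
}

#' Consensus CG density per family
#'
#' @param consensus_library data.frame with `family`, `sequence`.
#' @return Named numeric vector: CG dinucleotides per 100 bp of each
#'   family consensus.
#' @export
consensus_cg_density <- function(consensus_library) {
  setNames(vapply(consensus_library$sequence, cg_density_per_100bp,
                  numeric(1), USE.NAMES = FALSE),
           consensus_library$family)
}
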