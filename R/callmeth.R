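# Per-cytosine methylation calling from unique bisulfite alignments.

#' Call per-cytosine methylation
#'
#' For every reference cytosine covered by a uniquely aligned read on the
#' matching strand, a read base of C increments the methylated count and a
#' read base of T the unmethylated count (bottom strand: G/A on the
#' top-strand-oriented read). Any other base, e.g. a sequencing error, is
#' ignored. The context (CG, CHG, CHH) is taken from the reference, never
#' the read. Counts at the two cytosines of a symmetric CpG are merged onto
#' the top-strand C coordinate; the per-strand tallies are retained so the
#' merge is reversible.
#'
#' @param alignments data.frame from [align_bisulfite()]; only rows with
#'   `status == "unique"` are used.
#' @param reference The original (unconverted) reference string.
#' @param chrom Chromosome name recorded in the output.
#' @return data.frame of calls with columns `chrom`, `pos` (1-based
#'   position of the cytosine; for merged CpGs, of the top-strand C),
#'   `strand`, `context`, `meth_count`, `unmeth_count`, `level`, and
#'   per-strand tallies `meth_plus`, `unmeth_plus`, `meth_minus`,
#'   `unmeth_minus`. Only cytosines with at least one informative read are
#'   emitted.
#' @export
call_methylation <- function(alignments, reference, chrom = "chrSim") {
  check_dna(reference, "reference")
  n <- nchar(reference)
  aln <- alignments[alignments$status == "unique", , drop = FALSE]
  if (nrow(aln) > 0 && any(aln$pos + aln$width - 1L > n | aln$pos < 1L)) {
    stop("alignment outside the contig: inconsistent reference")
  }
  refch <- dna_chars(reference)
  mp <- up <- mm <- um <- integer(n)
  if (nrow(aln) > 0) {
    offs <- sequence(aln$width)
    gpos <- rep(aln$pos, aln$width) + offs - 1L
    base <- unlist(strsplit(aln$seq_plus, "", fixed = TRUE), use.names = FALSE)
    strand <- rep(aln$strand, aln$width)
    selp <- strand == "+" & refch[gpos] == "C"
    selm <- strand == "-" & refch[gpos] == "G"
    mp <- tabulate(gpos[selp & base == "C"], nbins = n)
    up <- tabulate(gpos[selp & base == "T"], nbins = n)
    mm <- tabulate(gpos[selm & base == "G"], nbins = n)
    um <- tabulate(gpos[selm & base == "A"], nbins = n)
  }
  is_c <- refch == "C"
  is_g <- refch == "G"
  ctx_plus <- context_of(refch, which(is_c), strand = "+")
  ctx_minus <- context_of(refch, which(is_g), strand = "-")

  rows <- list()
  # CpGs: merge the symmetric pair onto the top-strand C.
  cpg <- which(is_c)[ctx_plus == "CG"]
  meth <- mp[cpg] + mm[cpg + 1L]
  unmeth <- up[cpg] + um[cpg + 1L]
  if (length(cpg) && any(meth + unmeth > 0L)) {
    keep <- meth + unmeth > 0L
    rows$cg <- data.frame(
      pos = cpg[keep], strand = "+", context = "CG",
      meth_count = meth[keep], unmeth_count = unmeth[keep],
      meth_plus = mp[cpg][keep], unmeth_plus = up[cpg][keep],
      meth_minus = mm[cpg + 1L][keep], unmeth_minus = um[cpg + 1L][keep])
  }
  # Non-CpG cytosines: one row per strand.
  ncp <- which(is_c)[ctx_plus != "CG"]
  if (length(ncp) && any(mp[ncp] + up[ncp] > 0L)) {
    keep <- mp[ncp] + up[ncp] > 0L
    rows$chp <- data.frame(
      pos = ncp[keep], strand = "+",
      context = ctx_plus[ctx_plus != "CG"][keep],
      meth_count = mp[ncp][keep], unmeth_count = up[ncp][keep],
      meth_plus = mp[ncp][keep], unmeth_plus = up[ncp][keep],
      meth_minus = 0L, unmeth_minus = 0L)
  }
  ncm <- which(is_g)[ctx_minus != "CG"]
  if (length(ncm) && any(mm[ncm] + um[ncm] > 0L)) {
    keep <- mm[ncm] + um[ncm] > 0L
    rows$chm <- data.frame(
      pos = ncm[keep], strand = "-",
      context = ctx_minus[ctx_minus != "CG"][keep],
      meth_count = mm[ncm][keep], unmeth_count = um[ncm][keep],
      meth_plus = 0L, unmeth_plus = 0L,
      meth_minus = mm[ncm][keep], unmeth_minus = um[ncm][keep])
  }
  calls <- do.call(rbind, rows)
  if (is.null(calls)) {
    calls <- data.frame(pos = integer(0), strand = character(0),
                        context = character(0), meth_count = integer(0),
                        unmeth_count = integer(0), meth_plus = integer(0),
                        unmeth_plus = integer(0), meth_minus = integer(0),
                        unmeth_minus = integer(0))
  }
  calls <- calls[order(calls$pos), , drop = FALSE]
  calls$level <- calls$meth_count / (calls$meth_count + calls$unmeth_count)
  calls <- cbind(chrom = rep_len(chrom, nrow(calls)), calls)
  rownames(calls) <- NULL
  calls
}

# Sequence context of cytosines at `pos` (top strand) or of the cytosines
# complementary to guanines at `pos` (bottom strand). H = A, C or T.
context_of <- function(refch, pos, strand) {
  n <- length(refch)
  if (strand == "+") {
    nxt1 <- ifelse(pos + 1L <= n, refch[pmin(pos + 1L, n)], "N")
    nxt2 <- ifelse(pos + 2L <= n, refch[pmin(pos + 2L, n)], "N")
    ifelse(nxt1 == "G", "CG", ifelse(nxt2 == "G", "CHG", "CHH"))
  } else {
    prv1 <- ifelse(pos - 1L >= 1L, refch[pmax(pos - 1L, 1L)], "N")
    prv2 <- ifelse(pos - 2L >= 1L, refch[pmax(pos - 2L, 1L)], "N")
    ifelse(prv1 == "C", "CG", ifelse(prv2 == "C", "CHG", "CHH"))
  }
}

#' Bisulfite conversion QC
#'
#' Estimates the bisulfite conversion rate from non-CpG cytosines (which
#' are essentially unmethylated in differentiated mammalian cells, so any
#' retained C there reflects failed conversion) and reports where the
#' methylated observations fall by sequence context.
#'
#' @param calls data.frame from [call_methylation()].
#' @return List with `non_cpg_conversion_rate` (NA with `defined = FALSE`
#'   when no non-CpG cytosine is covered), `defined`, `n_non_cpg_obs`, and
#'   `context_fractions`, the share of methylated read observations in each
#'   of CG, CHG, CHH.
#' @export
conversion_qc <- function(calls) {
  if (nrow(calls) == 0L) stop("no methylation calls supplied")
  non <- calls$context %in% c("CHG", "CHH")
  denom <- sum(calls$meth_count[non]) + sum(calls$unmeth_count[non])
  rate <- if (denom > 0) sum(calls$unmeth_count[non]) / denom else NA_real_
  meth_by_ctx <- vapply(c("CG", "CHG", "CHH"), function(cx)
    sum(calls$meth_count[calls$context == cx]), numeric(1))
  total_meth <- sum(meth_by_ctx)
  fr <- if (total_meth > 0) meth_by_ctx / total_meth
        else setNames(rep(NA_real_, 3), c("CG", "CHG", "CHH"))
  list(non_cpg_conversion_rate = rate,
       defined = denom > 0,
       n_non_cpg_obs = denom,
       context_fractions = fr)
}
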