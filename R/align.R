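# Mismatch-bounded short-read placement on small genomes.
#
# Candidate placements are generated with a pigeonhole seed scheme: the read
# is split into (max_mismatch + 1) bands and each band is required in turn to
# match exactly (Biostrings trusted-band PDict matching). Any placement with
# <= max_mismatch substitutions must contain at least one clean band, so the
# union of the per-band hit lists is complete. Exact mismatch counts are then
# recomputed per candidate by direct comparison.

# All placements of `reads` (character vector) on `subject` with at most
# `max_mismatch` substitutions. Each read is split into (max_mismatch + 1)
# disjoint bands and a constant-width seed is taken from the start of each
# band; a placement within the mismatch budget must leave at least one band
# free of mismatches, so matching all seeds exactly (one PDict pass) yields
# a complete candidate list, verified afterwards by direct counting.
# Returns a list (one element per read) of integer start positions;
# attribute "skipped" holds indices of reads longer than the subject.
find_placements <- function(reads, subject, max_mismatch = 2L) {
  stopifnot(is.character(reads))
  slen <- nchar(subject)
  widths <- nchar(reads)
  out <- rep(list(integer(0)), length(reads))
  skipped <- which(widths > slen)
  usable <- setdiff(seq_along(reads), skipped)
  attr(out, "skipped") <- skipped
  if (length(usable) == 0L) return(out)
  nb <- max_mismatch + 1L
  k <- min(16L, floor(min(widths[usable]) / nb))
  if (k < 4L) stop("reads too short to seed with max_mismatch = ",
                   max_mismatch)
  subj <- Biostrings::DNAString(subject)
  # seed offsets: start of each of the nb disjoint bands, per read
  ridx <- rep(usable, each = nb)
  band <- rep.int(seq_len(nb) - 1L, length(usable))
  offs <- floor(band * widths[ridx] / nb) + 1L
  seeds <- substring(reads[ridx], offs, offs + k - 1L)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  mi <- Biostrings::matchPDict(pd, subj)
  si <- Biostrings::startIndex(mi)
  hit <- which(lengths(si) > 0L)
  if (length(hit) == 0L) return(out)
  starts <- as.integer(unlist(si[hit], use.names = FALSE) -
                         rep.int(offs[hit], lengths(si[hit])) + 1L)
  rr <- rep.int(ridx[hit], lengths(si[hit]))
  valid <- starts >= 1L & starts + widths[rr] - 1L <= slen
  starts <- starts[valid]; rr <- rr[valid]
  # de-duplicate (read, start) pairs globally, then split per read
  keep <- !duplicated(rr * (as.double(slen) + 1) + starts)
  cand <- split(starts[keep], rr[keep])
  out[as.integer(names(cand))] <- cand
  out
}

# Hamming distance between `read` and `subject` starting at `pos` (both
# plain character strings, equal alphabet).
count_mismatches <- function(read, subject, pos) {
  w <- nchar(read)
  vapply(pos, function(p) {
    sum(charToRaw(substr(subject, p, p + w - 1L)) != charToRaw(read))
  }, integer(1))
}

# Shared driver: searches each read in a set of (strand, converted read,
# converted subject) rounds, gathers all placements with their exact
# mismatch counts, and classifies each read: "unique" requires the best
# placement to have strictly fewer mismatches than every other placement
# across all rounds; a tied best is "ambiguous".
align_rounds <- function(read_ids, rounds, max_mismatch) {
  n <- length(read_ids)
  ridx <- integer(0); strand <- character(0)
  pos <- integer(0); nedit <- integer(0)
  n_skipped <- 0L
  for (r in rounds) {
    pl <- find_placements(r$reads, r$subject, max_mismatch)
    n_skipped <- max(n_skipped, length(attr(pl, "skipped")))
    li <- lengths(pl)
    if (sum(li) == 0L) next
    ri <- rep.int(seq_len(n), li)
    pp <- unlist(pl, use.names = FALSE)
    ne <- integer(length(pp))
    for (j in seq_along(pp)) {
      ne[j] <- count_mismatches(r$reads[ri[j]], r$subject, pp[j])
    }
    keep <- ne <= max_mismatch
    ridx <- c(ridx, ri[keep]); strand <- c(strand, rep(r$strand, sum(keep)))
    pos <- c(pos, pp[keep]); nedit <- c(nedit, ne[keep])
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " read(s) longer than the contig were skipped")
  }
  out <- data.frame(
    read_id = read_ids,
    status = "unaligned",
    strand = NA_character_, pos = NA_integer_, nedit = NA_integer_,
    stringsAsFactors = FALSE)
  if (length(ridx) == 0L) return(out)
  o <- order(ridx, nedit)
  ridx <- ridx[o]; strand <- strand[o]; pos <- pos[o]; nedit <- nedit[o]
  first <- !duplicated(ridx)
  fi <- which(first)
  # a read is ambiguous when its second-best placement ties the best
  has2 <- fi + 1L <= length(ridx) & c(ridx[-1L], -1L)[fi] == ridx[fi]
  tie <- has2 & nedit[pmin(fi + 1L, length(ridx))] == nedit[fi]
  out$status[ridx[fi]] <- ifelse(tie, "ambiguous", "unique")
  out$strand[ridx[fi]] <- strand[fi]
  out$pos[ridx[fi]] <- pos[fi]
  out$nedit[ridx[fi]] <- nedit[fi]
  out
}

#' Three-letter bisulfite alignment
#'
#' Aligns bisulfite-converted reads against the two converted references of
#' [build_converted_genomes()]: reads are C-to-T converted and matched
#' forward against the T genome (top-strand origin) and, after reverse
#' complementation and G-to-A conversion, against the A genome
#' (bottom-strand origin). Mismatches are counted on the converted alphabet,
#' so bisulfite conversion itself is never penalised. A read is reported
#' `unique` only when its best placement has strictly fewer mismatches than
#' every other placement across both rounds; ties are `ambiguous` and never
#' feed methylation calls.
#'
#' @param reads Named character vector of read sequences (names are read
#'   ids), or a data.frame with columns `id` and `seq`.
#' @param genomes A `ConvertedGenomes` object.
#' @param max_mismatch Maximum substitutions for a valid placement.
#' @return data.frame with one row per read: `read_id`, `status`
#'   (`unique`/`ambiguous`/`unaligned`), `strand` (`+` = top strand),
#'   `pos` (1-based start on the reference), `width`, `nedit`, and
#'   `seq_plus`, the read sequence expressed in top-strand orientation.
#' @export
align_bisulfite <- function(reads, genomes, max_mismatch = 2L) {
  reads <- as_read_vector(reads)
  if (!inherits(genomes, "ConvertedGenomes")) {
    stop("'genomes' must come from build_converted_genomes()")
  }
  fwd <- chartr("C", "T", unname(reads))
  rc <- revcomp(unname(reads))
  rev <- chartr("G", "A", rc)
  res <- align_rounds(
    names(reads),
    list(list(strand = "+", reads = fwd, subject = genomes$t_genome),
         list(strand = "-", reads = rev, subject = genomes$a_genome)),
    max_mismatch)
  res$width <- nchar(unname(reads))
  res$seq_plus <- ifelse(res$strand == "-" & !is.na(res$strand),
                         rc, unname(reads))
  res
}

#' Unique-best alignment of unconverted reads
#'
#' Same placement engine as [align_bisulfite()] but on the plain alphabet:
#' reads are matched forward and reverse-complemented against the
#' reference. Multi-mapped reads are flagged (`ambiguous`), not discarded:
#' repeat-family quantification consumes them in its second pass.
#'
#' @inheritParams align_bisulfite
#' @param reference Single A/C/G/T reference string.
#' @return data.frame as in [align_bisulfite()].
#' @export
align_unique <- function(reads, reference, max_mismatch = 2L) {
  reads <- as_read_vector(reads)
  check_dna(reference, "reference")
  rc <- revcomp(unname(reads))
  res <- align_rounds(
    names(reads),
    list(list(strand = "+", reads = unname(reads), subject = reference),
         list(strand = "-", reads = rc, subject = reference)),
    max_mismatch)
  res$width <- nchar(unname(reads))
  res$seq_plus <- ifelse(res$strand == "-" & !is.na(res$strand),
                         rc, unname(reads))
  res
}

as_read_vector <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("id", "seq") %in% names(reads)))
    reads <- setNames(as.character(reads$seq), as.character(reads$id))
  }
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read_%d", seq_along(reads))
  }
  reads
}
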