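# Readers/writers for the plain-text formats the pipeline consumes and
# emits. Intervals are 1-based closed in memory; BED/bedGraph and the
# RMSK-style table are 0-based half-open on disk, per their conventions;
# the CX report is 1-based.

#' Write/read FASTA (60-character wrapped)
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write/read FASTQ (4-line records, Phred+33, constant quality "I")
#' @param reads data.frame with `id`, `seq`.
#' @param path File path.
#' @return `read_fastq` returns a data.frame with `id`, `seq`.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[seq(1, by = 4, length.out = nrow(reads))] <- paste0("@", reads$id)
  lines[seq(2, by = 4, length.out = nrow(reads))] <- reads$seq
  lines[seq(3, by = 4, length.out = nrow(reads))] <- "+"
  lines[seq(4, by = 4, length.out = nrow(reads))] <-
    strrep("I", nchar(reads$seq))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)")
  }
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  data.frame(id = ids, seq = lines[seq(2, length(lines), by = 4)])
}

#' Write/read BED6 (0-based half-open on disk)
#' @param df data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (1-based closed coordinates in memory).
#' @param path File path.
#' @return `read_bed6` returns the data.frame in 1-based closed
#'   coordinates.
#' @export
write_bed6 <- function(df, path) {
  out <- data.frame(df$chrom, df$start - 1L, df$end, df$name,
                    df$score %||% 0L, df$strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  x <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(x) < 6L) stop("malformed BED6: fewer than 6 columns")
  data.frame(chrom = x[[1]], start = x[[2]] + 1L, end = x[[3]],
             name = x[[4]], score = x[[5]], strand = x[[6]])
}

#' Write/read a RepeatMasker-style repeat instance table
#' @param df data.frame with `chrom`, `start`, `end`, `strand`, `family`,
#'   `repeat_class`, `age`, `ltr_region` (1-based closed in memory).
#' @param path File path.
#' @return `read_rmsk` returns the table in 1-based closed coordinates.
#' @export
write_rmsk <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    strand = df$strand, repName = df$family,
                    repClass = df$repeat_class,
                    age = df$age,
                    ltr_region = ifelse(is.na(df$ltr_region), ".",
                                        df$ltr_region))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rmsk
#' @export
read_rmsk <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE,
                  stringsAsFactors = FALSE)
  data.frame(chrom = x$chrom, start = x$start + 1L, end = x$end,
             strand = x$strand, family = x$repName,
             repeat_class = x$repClass, age = x$age,
             ltr_region = ifelse(x$ltr_region == ".", NA_character_,
                                 x$ltr_region))
}

#' Write/read per-cytosine calls as a CX report
#'
#' Tab-separated with a dialect note: chrom, 1-based position, strand,
#' methylated count, unmethylated count, context, trinucleotide.
#' @param calls data.frame from [call_methylation()].
#' @param reference Reference string (for the trinucleotide column).
#' @param path File path.
#' @return `read_cx_report` returns a calls data.frame (merged per-strand
#'   tallies are not recoverable from the report and are refilled
#'   assuming all counts on the reported strand).
#' @export
write_cx_report <- function(calls, reference, path) {
  n <- nchar(reference)
  tri <- vapply(seq_len(nrow(calls)), function(i) {
    p <- calls$pos[i]
    s <- substr(reference, p, min(p + 2L, n))
    if (calls$strand[i] == "-") revcomp(substr(reference,
                                               max(p - 2L, 1L), p))
    else s
  }, character(1))
  out <- data.frame(chrom = calls$chrom, pos = calls$pos,
                    strand = calls$strand,
                    meth_count = calls$meth_count,
                    unmeth_count = calls$unmeth_count,
                    context = calls$context, trinucleotide = tri)
  con <- file(path, "w")
  writeLines("# CX report dialect: 1-based positions; CG rows merged onto the top-strand C",
             con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_cx_report
#' @export
read_cx_report <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                  stringsAsFactors = FALSE)
  x$level <- x$meth_count / (x$meth_count + x$unmeth_count)
  x
}

#' Write/read a count matrix with condition labels
#' @param counts Integer matrix features x samples.
#' @param conditions Condition label per sample (stored in a header
#'   comment line).
#' @param path File path.
#' @return `read_counts` returns `list(counts, conditions)`.
#' @export
write_counts <- function(counts, conditions, path) {
  con <- file(path, "w")
  writeLines(paste0("# conditions: ", paste(conditions, collapse = ",")),
             con)
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1L)
  conditions <- strsplit(sub("^# conditions: ", "", first), ",")[[1]]
  x <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                  check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  list(counts = m, conditions = conditions)
}

#' Write a bedGraph track (0-based half-open)
#' @param df data.frame with `chrom`, `start`, `end`, `value` (1-based
#'   closed in memory).
#' @param path File path.
#' @param name Track name.
#' @export
write_bedgraph <- function(df, path, name = "track") {
  con <- file(path, "w")
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  write.table(data.frame(df$chrom, df$start - 1L, df$end, df$value),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  invisible(path)
}

#' Write alignments as minimal SAM
#'
#' Header plus the 11 mandatory fields; unaligned reads get flag 4,
#' bottom-strand alignments flag 16 (sequence stored in top-strand
#' orientation, as SAM requires).
#' @param alignments data.frame from [align_bisulfite()] or
#'   [align_unique()].
#' @param chrom,chrom_length Reference name and length for the header.
#' @param path File path.
#' @export
write_sam <- function(alignments, chrom, chrom_length, path) {
  con <- file(path, "w")
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_length)), con)
  a <- alignments
  mapped <- a$status == "unique"
  flag <- ifelse(!mapped, 4L, ifelse(a$strand == "-", 16L, 0L))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                   a$read_id, flag,
                   ifelse(mapped, chrom, "*"),
                   ifelse(mapped, a$pos, 0L),
                   ifelse(mapped, 255L, 0L),
                   ifelse(mapped, paste0(a$width, "M"), "*"),
                   a$seq_plus)
  writeLines(lines, con)
  close(con)
  invisible(path)
}
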