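# In-silico MspI digestion, size selection and converted-genome construction.

#' In-silico MspI digestion
#'
#' Cuts a DNA sequence at every `CCGG` site between the first and second
#' base (`C^CGG`), the recognition/cut pattern of MspI. Fragments tile the
#' input exactly: concatenating them reconstructs the sequence.
#'
#' @param sequence Single uppercase A/C/G/T string.
#' @return A data.frame with columns `start`, `end` (1-based, closed) and
#'   `length`, one row per fragment, ordered left to right.
#' @examples
#' msp1_digest("ACCGGT")   # fragments AC | CGGT
#' @export
msp1_digest <- function(sequence) {
  check_dna(sequence)
  n <- nchar(sequence)
  sites <- Biostrings::start(
    Biostrings::matchPattern("CCGG", Biostrings::DNAString(sequence)))
  # cut after the first C of each site
  cuts <- sites + 1L
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, n)
  keep <- starts <= ends
  data.frame(start = starts[keep], end = ends[keep],
             length = ends[keep] - starts[keep] + 1L)
}

#' Size-select restriction fragments
#'
#' Keeps fragments whose length lies within `[min_bp, max_bp]`, both bounds
#' inclusive (the gel-excision window used for reduced-representation
#' libraries, 40-220 bp by default).
#'
#' @param fragments data.frame from [msp1_digest()].
#' @param min_bp,max_bp Inclusive length bounds.
#' @return The subset of `fragments` passing the window.
#' @export
size_select <- function(fragments, min_bp = 40L, max_bp = 220L) {
  if (min_bp > max_bp) stop("'min_bp' must be <= 'max_bp'")
  fragments[fragments$length >= min_bp & fragments$length <= max_bp, ,
            drop = FALSE]
}

#' Build bisulfite-converted reference genomes
#'
#' Three-letter alignment matches fully converted reads against two reduced
#' alphabets: the "T genome" (every C replaced by T, for reads from the
#' original top strand) and the "A genome" (every G replaced by A, for reads
#' originating from the bottom strand, expressed in top-strand coordinates).
#'
#' @param reference Single A/C/G/T string.
#' @return List of class `ConvertedGenomes` with elements `reference`,
#'   `t_genome`, `a_genome`.
#' @export
build_converted_genomes <- function(reference) {
  check_dna(reference, "reference")
  structure(
    list(reference = reference,
         t_genome = chartr("C", "T", reference),
         a_genome = chartr("G", "A", reference)),
    class = "ConvertedGenomes")
}

#' @export
print.ConvertedGenomes <- function(x, ...) {
  cat("ConvertedGenomes:", nchar(x$reference), "bp reference",
      "(T- and A-converted copies)\n")
  invisible(x)
}
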