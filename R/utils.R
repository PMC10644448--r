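# Internal helpers shared across modules.

#' @importFrom stats runif rbinom rnbinom rpois median quantile setNames
#'   fisher.test p.adjust complete.cases aggregate
#' @importFrom utils read.table write.table head tail
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All simulator entry points route their randomness through this so that
# identical (seed, config) pairs give identical output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# Derive a stream-specific seed so independent simulators draw from
# independent streams even when called with the same top-level seed.
derive_seed <- function(seed, stream) {
  # double arithmetic: exact below 2^53, immune to integer overflow
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 12289) %%
               2147483647)
}

BASES <- c("A", "C", "G", "T")

check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop("'", what, "' must be a single non-empty character string")
  }
  bad <- gregexpr("[^ACGT]", x)[[1]]
  if (bad[1] != -1L) {
    stop("'", what, "' contains non-ACGT characters at positions: ",
         paste(head(bad, 10L), collapse = ", "))
  }
  invisible(x)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Split one string into a character vector of single bases.
dna_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Apply point substitutions to a sequence at a given per-base rate.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- dna_chars(seq)
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1L),
                      character(1))
  }
  paste(ch, collapse = "")
}

# CpG -> TpG decay: each CG dinucleotide loses its C (to T) with prob `rate`,
# mirroring deamination of methylated cytosines over evolutionary time.
decay_cpg <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- dna_chars(seq)
  cg <- which(ch[-length(ch)] == "C" & ch[-1] == "G")
  hit <- cg[runif(length(cg)) < rate]
  if (length(hit)) ch[hit] <- "T"
  paste(ch, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
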