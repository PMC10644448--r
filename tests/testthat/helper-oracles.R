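# Independent oracles used to cross-check the implementation, plus shared
# fixtures memoised across test files (built once per run, in code).

# --- oracles --------------------------------------------------------------

# Regex-scan digestion oracle: find CCGG occurrences, cut after the first C.
digest_oracle <- function(seq) {
  hits <- gregexpr("(?=CCGG)", seq, perl = TRUE)[[1]]
  cuts <- if (hits[1] == -1L) integer(0) else as.integer(hits) + 1L
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, nchar(seq))
  keep <- starts <= ends
  data.frame(start = starts[keep], end = ends[keep],
             length = ends[keep] - starts[keep] + 1L)
}

# Hamming distance between two equal-length strings.
hamming_oracle <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Two-sided Fisher p-value by hypergeometric enumeration: sum the
# probabilities of all tables (fixed margins) no more likely than the
# observed one.
fisher_oracle <- function(m1, u1, m2, u2) {
  n1 <- m1 + u1; n2 <- m2 + u2; m <- m1 + m2
  support <- max(0L, m - n2):min(n1, m)
  pr <- dhyper(support, n1, n2, m)
  p_obs <- dhyper(m1, n1, n2, m)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Brute-force Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, n * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  adj
}

# Planted level of the top-strand CpG C at each position.
level_at_for_tests <- function(landscape, pos) {
  methkit:::level_at(landscape, pos, rep("+", length(pos)))
}

random_seq_for_tests <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- shared fixtures ------------------------------------------------------

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

small_config <- function(seed = 11L, ...) {
  sim_config(seed = seed, genome_length = 90000L, n_genes = 6L,
             repeat_copy_scale = 0.2, n_cgi_extra = 3L,
             rrbs_n_reads = 6000L, dip_n_reads = 8000L,
             rna_n_reads = 8000L, ...)
}

small_genome <- function() fixture("small_genome",
                                   generate_genome(small_config()))

small_meth <- function() fixture("small_meth",
                                 plant_methylation(small_genome()))

# Repeat-free genome at default scale: used for aligner correctness and
# methylation-recovery checks, where repetitive placements are not the
# object under study.
norep_genome <- function() fixture(
  "norep_genome",
  generate_genome(sim_config(seed = 5L), with_repeats = FALSE))

norep_rrbs <- function() fixture("norep_rrbs", {
  g <- norep_genome()
  m <- plant_methylation(g)
  sim <- simulate_rrbs_reads(g, m$wt, g$config, seed = 101L,
                             n_reads = 10000L)
  aln <- align_bisulfite(sim$reads, build_converted_genomes(g$sequence))
  list(genome = g, meth = m, sim = sim, aln = aln,
       calls = call_methylation(aln, g$sequence))
})
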