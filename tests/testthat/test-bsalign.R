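# In-silico digestion, converted genomes, three-letter alignment and
# methylation calling.

test_that("MspI digestion follows the C^CGG rule and tiles the input", {
  expect_equal(msp1_digest("ACCGGT")[, c("start", "end")],
               data.frame(start = c(1L, 3L), end = c(2L, 6L)))
  expect_equal(msp1_digest("CCGGCCGG")$length, c(1L, 4L, 3L))
  expect_equal(msp1_digest("AAAA"),
               data.frame(start = 1L, end = 4L, length = 4L))
  expect_error(msp1_digest("ACGN"), "non-ACGT")
  # fragment sequences reconstruct the input
  s <- random_seq_for_tests(2000, seed = 1)
  fr <- msp1_digest(s)
  expect_identical(paste(substring(s, fr$start, fr$end), collapse = ""), s)
})

test_that("size selection keeps the inclusive 40-220 window", {
  fr <- data.frame(start = 1, end = c(39, 40, 220, 221),
                   length = c(39, 40, 220, 221))
  expect_equal(size_select(fr)$length, c(40, 220))
  expect_equal(nrow(size_select(fr[0, ])), 0L)
  expect_equal(size_select(fr, 0, Inf), fr)
  expect_error(size_select(fr, 100, 50), "min_bp")
})

test_that("converted genomes substitute the expected letters", {
  cg <- build_converted_genomes("ACGT")
  expect_equal(cg$t_genome, "ATGT")
  expect_equal(cg$a_genome, "ACAT")
  cg2 <- build_converted_genomes("CCCC")
  expect_equal(cg2$t_genome, "TTTT")
  expect_equal(cg2$a_genome, "CCCC")
  # number of changed positions equals the C count
  s <- random_seq_for_tests(500, seed = 2)
  cg3 <- build_converted_genomes(s)
  ch <- strsplit(s, "")[[1]]
  cht <- strsplit(cg3$t_genome, "")[[1]]
  expect_equal(sum(ch != cht), sum(ch == "C"))
})

test_that("error-free bisulfite reads map uniquely to their provenance", {
  fx <- norep_rrbs()
  aln <- fx$aln; tr <- fx$sim$truth
  expect_identical(aln$read_id, tr$id)
  expect_true(all(aln$status == "unique"))
  expect_true(all(aln$nedit == 0L))
  expect_identical(aln$pos, tr$start)
  expect_identical(aln$strand, tr$strand)
})

test_that("reported mismatch counts match a Hamming oracle", {
  fx <- norep_rrbs()
  g <- fx$genome
  cg <- build_converted_genomes(g$sequence)
  idx <- seq(1, nrow(fx$aln), by = 37)  # a spread of reads
  for (i in idx) {
    a <- fx$aln[i, ]
    conv_read <- if (a$strand == "+") {
      chartr("C", "T", fx$sim$reads$seq[i])
    } else {
      chartr("G", "A", a$seq_plus)
    }
    subj <- if (a$strand == "+") cg$t_genome else cg$a_genome
    expect_equal(a$nedit,
                 hamming_oracle(conv_read,
                                substr(subj, a$pos,
                                       a$pos + a$width - 1L)))
  }
})

test_that("reads from identical repeat copies are ambiguous", {
  unit <- random_seq_for_tests(400, seed = 3)
  genome <- paste0(random_seq_for_tests(300, seed = 4), unit,
                   random_seq_for_tests(300, seed = 5), unit,
                   random_seq_for_tests(300, seed = 6))
  cg <- build_converted_genomes(genome)
  read <- substr(unit, 100, 148)
  aln <- align_bisulfite(c(r1 = chartr("C", "T", read)), cg)
  expect_equal(aln$status, "ambiguous")
  # and ambiguous reads contribute nothing to calls
  calls <- call_methylation(aln, genome)
  expect_equal(nrow(calls), 0L)
})

test_that("raising max_mismatch never loses alignments", {
  fx <- norep_rrbs()
  g <- fx$genome
  cg <- build_converted_genomes(g$sequence)
  reads <- setNames(fx$sim$reads$seq[1:300], fx$sim$reads$id[1:300])
  # plant one substitution per read so stricter budgets can reject
  reads <- vapply(reads, function(s) {
    p <- 25L
    o <- substr(s, p, p)
    sub <- if (o == "G") "A" else "G"
    paste0(substr(s, 1, p - 1L), sub, substr(s, p + 1L, nchar(s)))
  }, character(1))
  n_aligned <- vapply(0:2, function(mm)
    sum(align_bisulfite(reads, cg, max_mismatch = mm)$status == "unique"),
    numeric(1))
  expect_true(all(diff(n_aligned) >= 0))
  expect_gt(n_aligned[2], n_aligned[1])  # the planted substitution costs 1
})

test_that("methylation calls count C/T per strand and merge CpGs", {
  #      123456789
  ref <- "AACGTTACG"
  # 10 reads over the CpG at 3-4: 7 methylated (C), 3 unmethylated (T)
  reads <- c(rep("AACGTTACG", 7), rep("AATGTTACG", 3))
  aln <- data.frame(read_id = sprintf("r%d", 1:10), status = "unique",
                    strand = "+", pos = 1L, nedit = 0L, width = 9L,
                    seq_plus = reads)
  calls <- call_methylation(aln, ref)
  cg <- calls[calls$pos == 3L, ]
  expect_equal(cg$context, "CG")
  expect_equal(cg$meth_count, 7L)
  expect_equal(cg$unmeth_count, 3L)
  expect_equal(cg$level, 0.7)
  # conservation: counted reads never exceed covering reads
  expect_true(all(calls$meth_count + calls$unmeth_count <= 10L))
})

test_that("context is computed from the reference", {
  # C at 2: CG context; C at 6: CHH (ACAT-like); C at 10: CHG
  ref <- "ACGTTCATTCAGT"
  aln <- data.frame(read_id = "r1", status = "unique", strand = "+",
                    pos = 1L, nedit = 0L, width = nchar(ref),
                    seq_plus = ref)
  calls <- call_methylation(aln, ref)
  expect_equal(calls$context[calls$pos == 2L], "CG")
  expect_equal(calls$context[calls$pos == 6L], "CHH")
  expect_equal(calls$context[calls$pos == 10L], "CHG")
})

test_that("bottom-strand reads inform the complementary cytosine", {
  ref <- "AACGTTAAA"
  # bottom-strand read covering the CpG: G at reference position 4 on the
  # plus-oriented sequence means methylated bottom-strand C
  aln <- data.frame(read_id = c("r1", "r2"), status = "unique",
                    strand = "-", pos = 1L, nedit = 0L, width = 9L,
                    seq_plus = c("AACGTTAAA", "AACATTAAA"))
  calls <- call_methylation(aln, ref)
  cg <- calls[calls$pos == 3L, ]  # merged onto the top-strand C
  expect_equal(cg$meth_count, 1L)
  expect_equal(cg$unmeth_count, 1L)
  expect_equal(cg$meth_minus, 1L)
  expect_equal(cg$meth_plus, 0L)
})

test_that("conversion QC flags an empty non-CpG denominator", {
  calls <- data.frame(chrom = "c", pos = 1L, strand = "+", context = "CG",
                      meth_count = 3L, unmeth_count = 1L,
                      meth_plus = 3L, unmeth_plus = 1L, meth_minus = 0L,
                      unmeth_minus = 0L, level = 0.75)
  qc <- conversion_qc(calls)
  expect_false(qc$defined)
  expect_true(is.na(qc$non_cpg_conversion_rate))
  expect_equal(unname(qc$context_fractions[["CG"]]), 1)
})
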