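# Two-pass repeat-family quantification and family statistics.

test_that("pass 1 resolves overlaps by largest overlap with tie discard", {
  rmsk <- data.frame(family = c("SINE_X", "LINE_Z"),
                     start = c(100L, 181L), end = c(180L, 400L))
  mk_aln <- function(pos, width = 50L) {
    data.frame(read_id = sprintf("r%d", seq_along(pos)),
               status = "unique", strand = "+", pos = pos, nedit = 0L,
               width = width, seq_plus = strrep("A", width))
  }
  # fully inside the LINE
  p1 <- pass1_annotate(mk_aln(200L), rmsk)
  expect_equal(unname(p1$counts["LINE_Z"]), 1L)
  # 30 bp in SINE, 20 bp in LINE: SINE wins
  p2 <- pass1_annotate(mk_aln(151L), rmsk)
  expect_equal(unname(p2$counts["SINE_X"]), 1L)
  expect_equal(unname(p2$counts["LINE_Z"]), 0L)
  # exact 25/25 tie across families: discarded
  p3 <- pass1_annotate(mk_aln(156L), rmsk)
  expect_equal(sum(p3$counts), 0L)
  expect_equal(length(p3$tie_discarded), 1L)
  # tie between two copies of the same family still counts
  rmsk_same <- data.frame(family = c("SINE_X", "SINE_X"),
                          start = c(100L, 181L), end = c(180L, 400L))
  p4 <- pass1_annotate(mk_aln(156L), rmsk_same)
  expect_equal(unname(p4$counts["SINE_X"]), 1L)
  # no overlap: unique read drops out of repeat counting
  p5 <- pass1_annotate(mk_aln(5000L), rmsk)
  expect_equal(length(p5$non_repeat), 1L)
  expect_error(pass1_annotate(mk_aln(200L),
                              data.frame(family = "x", start = 5L,
                                         end = 2L)),
               "malformed")
})

test_that("pass 2 assigns single-family hits and discards cross-family", {
  set.seed(41)
  lib <- data.frame(
    family = c("famA", "famB"),
    sequence = c(random_seq_for_tests(300, 42),
                 random_seq_for_tests(300, 43)))
  readA <- substr(lib$sequence[1], 50, 99)
  readB_rc <- methkit:::revcomp(substr(lib$sequence[2], 100, 149))
  shared <- random_seq_for_tests(60, 44)
  lib2 <- data.frame(family = c("famA", "famB"),
                     sequence = paste0(shared, c(lib$sequence[1],
                                                 lib$sequence[2])))
  reads <- data.frame(id = c("a", "b", "x", "none"),
                      seq = c(readA, readB_rc, substr(shared, 1, 50),
                              random_seq_for_tests(50, 45)))
  p2 <- pass2_annotate(reads, lib2)
  expect_equal(unname(p2$counts["famA"]), 1L)
  expect_equal(unname(p2$counts["famB"]), 1L)
  expect_equal(p2$multi_family_discarded, "x")
  expect_equal(p2$unassigned, "none")
  expect_error(pass2_annotate(reads, lib[0, ]), "empty")
})

test_that("two-pass counts match provenance exactly on clean simulations", {
  # (a) single-copy families: every repeat read is uniquely placeable and
  # must be recovered in pass 1
  cfg_a <- sim_config(seed = 61, genome_length = 60000L, n_genes = 3L,
                      repeat_copy_scale = 0.01)
  ga <- generate_genome(cfg_a)
  expect_true(all(table(ga$repeat_instances$family) == 1L))
  fams <- unique(ga$repeat_instances$family)
  ex <- data.frame(feature = fams, type = "family", level = 1)
  sim <- simulate_rnaseq_reads(ga, ex, cfg_a, seed = 62L, n_reads = 4000L)
  aln <- align_unique(sim$reads, ga$sequence)
  cr <- count_repeat_reads(aln, sim$reads, ga$repeat_instances,
                           ga$consensus_library)
  truth <- table(sim$truth$feature)
  got <- setNames(cr$counts$count_total, cr$counts$family)
  expect_equal(got[names(truth)], unclass(truth)[names(truth)],
               ignore_attr = TRUE)
  expect_equal(sum(cr$partition), nrow(sim$reads))
  # (b) zero-divergence multi-copy families: identical copies make reads
  # multi-mapped, and pass 2 must recover every one from the consensus
  cfg_b <- sim_config(seed = 63, genome_length = 120000L, n_genes = 4L,
                      repeat_copy_scale = 0.1, divergence_young = 0,
                      divergence_old = 0, cpg_decay_young = 0,
                      cpg_decay_old = 0)
  gb <- generate_genome(cfg_b)
  fams_b <- unique(gb$repeat_instances$family)
  multi <- names(which(table(gb$repeat_instances$family) >= 2L))
  ex_b <- data.frame(feature = fams_b, type = "family", level = 1)
  sim_b <- simulate_rnaseq_reads(gb, ex_b, cfg_b, seed = 64L,
                                 n_reads = 4000L)
  aln_b <- align_unique(sim_b$reads, gb$sequence)
  cr_b <- count_repeat_reads(aln_b, sim_b$reads, gb$repeat_instances,
                             gb$consensus_library)
  truth_b <- table(sim_b$truth$feature)
  got_b <- setNames(cr_b$counts$count_total, cr_b$counts$family)
  expect_equal(got_b[names(truth_b)], unclass(truth_b)[names(truth_b)],
               ignore_attr = TRUE)
  expect_gt(sum(cr_b$counts$count_pass2[cr_b$counts$family %in% multi]),
            0L)
  expect_equal(sum(cr_b$partition), nrow(sim_b$reads))
})

test_that("family_stats filters, normalises and flags correctly", {
  meta <- data.frame(family = c("f1", "f2", "f3", "f4"),
                     repeat_class = c("SINE", "LINE", "DNA", "LTR"),
                     age = c("lineage_specific", "ancestral",
                             "lineage_specific", "ancestral"),
                     ltr_region = c(NA, NA, NA, "int"),
                     cg_per_100bp = c(10, 5, 7, 6))
  k <- rbind(f1 = c(1000L, 2000L), f2 = c(99L, 5000L),
             f3 = c(4000L, 4000L), f4 = c(500L, 500L))
  colnames(k) <- c("WT", "KO")
  fs <- family_stats(k, factor(c("WT", "KO"), c("WT", "KO")), meta,
                     library_sizes = c(1e6, 1e6), assay = "dip")
  # f2 fails the >100-per-sample filter; f3 is not a retrotransposon
  expect_setequal(fs$family, c("f1", "f4"))
  # normalised 2x change: log2 ratio 1
  expect_equal(fs$log2_ratio[fs$family == "f1"], 1)
  expect_equal(fs$log2_ratio[fs$family == "f4"], 0)
  # normalisation invariance: scaling all libraries leaves ratios alone
  fs2 <- family_stats(k, factor(c("WT", "KO"), c("WT", "KO")), meta,
                      library_sizes = c(2e6, 2e6), assay = "dip")
  expect_equal(fs$log2_ratio, fs2$log2_ratio)
  expect_error(family_stats(k, c("WT", "KO"), meta, c(0, 1e6)), "zero")
})

test_that("null family counts stay below the significance floor across seeds", {
  # count-level null: equal expected rpm in both conditions, Poisson noise
  meta <- data.frame(family = sprintf("f%02d", 1:20),
                     repeat_class = rep(c("SINE", "LINE", "LTR", "LTR"), 5),
                     age = rep(c("lineage_specific", "ancestral"), 10),
                     ltr_region = NA, cg_per_100bp = 8)
  n_sig <- 0L; n_tot <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    mu <- runif(20, 300, 5000)
    k <- cbind(WT = rpois(20, mu), KO = rpois(20, mu))
    rownames(k) <- meta$family
    fs <- family_stats(k, factor(c("WT", "KO"), c("WT", "KO")), meta,
                       library_sizes = c(1e6, 1e6), assay = "dip")
    n_sig <- n_sig + sum(fs$significant)
    n_tot <- n_tot + nrow(fs)
  }
  margin <- 2 * sqrt(0.05 * 0.95 / n_tot)
  expect_lte(n_sig / n_tot, 0.05 + margin)
})

test_that("age stratification tabulates significance per stratum", {
  tab <- data.frame(
    family = sprintf("f%d", 1:8),
    repeat_class = c("SINE", "SINE", "LINE", "LINE", "LTR", "LTR", "LTR",
                     "LTR"),
    age = c("lineage_specific", "ancestral", "lineage_specific",
            "ancestral", "lineage_specific", "lineage_specific",
            "ancestral", NA),
    ltr_region = c(NA, NA, NA, NA, "int", "ext", "int", "ext"),
    significant = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
    direction = c("down", NA, "down", NA, "down", NA, NA, "down"))
  st <- stratify_age(tab, direction = "down")
  young_sine <- st[st$repeat_class == "SINE" &
                     st$age == "lineage_specific", ]
  expect_equal(young_sine$pct_significant, 100)
  old_sine <- st[st$repeat_class == "SINE" & st$age == "ancestral", ]
  expect_equal(old_sine$pct_significant, 0)
  expect_true("unlabelled" %in% st$age)
  # LTR strata are split by internal/external domain
  expect_setequal(st$ltr_region[st$repeat_class == "LTR" &
                                  st$age == "lineage_specific"],
                  c("int", "ext"))
  # percentages re-derivable by direct tabulation
  expect_equal(sum(st$n_significant), sum(tab$significant &
                                            tab$direction == "down",
                                          na.rm = TRUE))
})

test_that("CG density counts CG dinucleotides per 100 bp", {
  expect_equal(cg_density_per_100bp("CGCG"), 50)
  expect_equal(cg_density_per_100bp("CCGG"), 25)
  expect_warning(d <- cg_density_per_100bp(""), "undefined")
  expect_true(is.na(d))
  # uniform random sequence approaches p(C)p(G) per bp
  s <- random_seq_for_tests(20000, seed = 51)
  expect_equal(cg_density_per_100bp(s), 6.25, tolerance = 0.15)
})
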