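# Region metrics, coverage filters, DMR detection and clone scoring.

# A reference with exactly 10 CpGs at known positions, and calls covering
# 8 of them, 2 methylated (levels 0.5 and 0.8, coverage 10 each).
toy_region <- function() {
  unit <- "CGAAATTTAA"  # one CpG per 10 bp
  ref <- paste(rep(unit, 10), collapse = "")
  pos <- seq(1L, 91L, by = 10L)
  covered <- pos[1:8]
  meth <- c(5L, 8L, rep(0L, 6))
  calls <- data.frame(
    chrom = "c", pos = covered, strand = "+", context = "CG",
    meth_count = meth, unmeth_count = 10L - meth,
    meth_plus = meth, unmeth_plus = 10L - meth,
    meth_minus = 0L, unmeth_minus = 0L,
    level = meth / 10)
  list(ref = ref, calls = calls,
       regions = data.frame(id = "R1", type = "CGI", start = 1L,
                            end = 100L))
}

test_that("region metrics reproduce the hand-computed example", {
  toy <- toy_region()
  rm <- region_metrics(toy$calls, toy$regions, toy$ref)
  expect_equal(rm$n_cpg_total, 10L)
  expect_equal(rm$n_cpg_covered, 8L)
  expect_equal(rm$covered_fraction, 0.8)
  expect_true(rm$passes_coverage_filter)
  expect_equal(rm$n_cpg_methylated, 2L)
  expect_equal(rm$pct_methylation, 0.2)
  expect_equal(rm$mean_5mCG_level, 0.65)
  expect_equal(rm$mean_coverage_methylated, 10)
  expect_true(rm$passes_depth_filter)
})

test_that("regions with no covered CpGs are flagged, not dropped", {
  toy <- toy_region()
  rm <- region_metrics(toy$calls[0, ], toy$regions, toy$ref)
  expect_equal(nrow(rm), 1L)
  expect_equal(rm$covered_fraction, 0)
  expect_false(rm$passes_coverage_filter)
  expect_true(is.na(rm$mean_5mCG_level))
  expect_error(region_metrics(toy$calls,
                              data.frame(id = "R", type = "CGI",
                                         start = 1L, end = 9999L),
                              toy$ref),
               "outside")
})

test_that("metrics are invariant under call-row permutation and filters are monotone", {
  toy <- toy_region()
  shuffled <- toy$calls[sample(nrow(toy$calls)), ]
  expect_equal(region_metrics(shuffled, toy$regions, toy$ref),
               region_metrics(toy$calls, toy$regions, toy$ref))
  n_pass <- vapply(c(0.5, 0.8, 0.9), function(th)
    sum(region_metrics(toy$calls, toy$regions, toy$ref,
                       min_covered_fraction = th)$passes_coverage_filter),
    numeric(1))
  expect_true(all(diff(n_pass) <= 0))
})

test_that("Fisher p-values match the hypergeometric enumeration oracle", {
  set.seed(7)
  for (i in 1:40) {
    m1 <- sample(0:100, 1); u1 <- sample(0:100, 1)
    m2 <- sample(0:100, 1); u2 <- sample(0:100, 1)
    if (m1 + u1 == 0 || m2 + u2 == 0) next
    p_impl <- fisher.test(matrix(c(m1, u1, m2, u2), 2))$p.value
    expect_equal(p_impl, fisher_oracle(m1, u1, m2, u2), tolerance = 1e-10)
  }
})

test_that("dmr_scan applies the full filter set", {
  # one clear DMR (WT 40/60 vs KO 10/90 pooled over 12 CpGs), one null
  mk_calls <- function(pos, meth, unmeth) {
    data.frame(chrom = "c", pos = pos, strand = "+", context = "CG",
               meth_count = meth, unmeth_count = unmeth,
               meth_plus = meth, unmeth_plus = unmeth,
               meth_minus = 0L, unmeth_minus = 0L,
               level = meth / (meth + unmeth))
  }
  pos1 <- seq(100L, 650L, by = 50L)           # 12 CpGs
  pos2 <- seq(10100L, 10650L, by = 50L)
  calls_wt <- rbind(mk_calls(pos1, 4L, 6L), mk_calls(pos2, 4L, 6L))
  calls_ko <- rbind(mk_calls(pos1, 1L, 9L), mk_calls(pos2, 4L, 6L))
  metrics <- data.frame(region_id = c("dmr", "null"),
                        region_type = "promoter",
                        start = c(50L, 10050L), end = c(700L, 10700L))
  res <- dmr_scan(metrics, metrics, calls_wt, calls_ko,
                  tss = c(1000L, 11000L))
  expect_equal(res$n_cg, c(12L, 12L))
  expect_equal(res$ratio[1], 4)
  expect_lt(res$p_value[1], 0.01)
  expect_true(res$passes[1])
  # identical counts: ratio 1, fails
  expect_equal(res$ratio[2], 1)
  expect_false(res$passes[2])
  # pooled table matches a direct Fisher computation
  expect_equal(res$p_value[1],
               fisher_oracle(12L * 4L, 12L * 6L, 12L * 1L, 12L * 9L),
               tolerance = 1e-10)
})

test_that("dmr_scan skips regions without testable counts", {
  calls <- data.frame(chrom = "c", pos = 5L, strand = "+", context = "CG",
                      meth_count = 3L, unmeth_count = 2L, meth_plus = 3L,
                      unmeth_plus = 2L, meth_minus = 0L,
                      unmeth_minus = 0L, level = 0.6)
  metrics <- data.frame(region_id = "r", region_type = "CGI",
                        start = 100L, end = 200L)
  res <- dmr_scan(metrics, metrics, calls, calls, tss = 150L)
  expect_false(res$passes)
  expect_match(res$skipped, "no shared")
})

test_that("clone scoring separates methylation from C-to-T transitions", {
  ref <- "AACGAACGAACGAACGAACGAA"  # 5 CpGs
  # 10 clones, all C at every CpG: 100% methylated
  all_c <- rep(ref, 10)
  sc <- score_clones(all_c, reference_region = ref)
  expect_equal(sc$pct_5mCG, 100)
  # 6 C / 4 T at the first site: site-level 60%
  t_at_1 <- sub("AACG", "AATG", ref)
  mix <- c(rep(ref, 6), rep(t_at_1, 4))
  sc2 <- score_clones(mix, reference_region = ref)
  expect_equal(unname(sc2$site_pct[1]), 60)
  # standard clones showing T at that site reclassify T as transition
  sc3 <- score_clones(mix, standard_clones = t_at_1,
                      reference_region = ref)
  expect_equal(sc3$transition_sites, 3L)
  expect_true(all(sc3$matrix[7:10, 1] == "transition"))
  expect_true(is.na(sc3$site_pct[1]) || sc3$site_pct[1] == 100)
  # length-mismatched clones are skipped with a warning
  expect_warning(score_clones(c(ref, "ACGT"), reference_region = ref),
                 "skipped")
})
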