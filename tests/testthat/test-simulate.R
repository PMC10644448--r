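# The synthetic-data generator: determinism, planted landscapes, read
# provenance and the conversion chemistry.

test_that("genome generation is deterministic and structurally valid", {
  g1 <- small_genome()
  g2 <- generate_genome(small_config())
  expect_identical(g1, g2)
  n <- nchar(g1$sequence)
  ivs <- rbind(g1$genes[, c("start", "end")],
               g1$cgis[, c("start", "end")],
               g1$repeat_instances[, c("start", "end")],
               g1$promoters[, c("start", "end")])
  expect_true(all(ivs$start >= 1 & ivs$end <= n & ivs$start <= ivs$end))
  expect_true(all(g1$promoters$end - g1$promoters$start + 1L == 2000L))
  expect_true(all(g1$repeat_instances$family %in%
                    g1$consensus_library$family))
})

test_that("promoters are strand-aware 2 kb upstream intervals", {
  genes <- data.frame(id = c("gp", "gm", "gc"),
                      strand = c("+", "-", "+"),
                      tss = c(10000L, 10000L, 500L))
  pr <- define_promoters(genes, 50000L)
  expect_equal(unlist(pr[1, c("start", "end")], use.names = FALSE),
               c(8000L, 9999L))
  expect_equal(unlist(pr[2, c("start", "end")], use.names = FALSE),
               c(10001L, 12000L))
  # clipped at the contig edge
  expect_equal(unlist(pr[3, c("start", "end")], use.names = FALSE),
               c(1L, 499L))
  expect_true(pr$clipped[3] && !any(pr$clipped[1:2]))
  expect_error(define_promoters(data.frame(id = "g", strand = "+",
                                           tss = 0L), 100L),
               "TSS outside")
})

test_that("ancestral consensus CG density is below lineage-specific", {
  lib <- small_genome()$consensus_library
  dens <- consensus_cg_density(lib)
  expect_lt(mean(dens[lib$age == "ancestral"]),
            mean(dens[lib$age == "lineage_specific"]))
})

test_that("planted landscapes honour baselines and fold effects", {
  g <- small_genome()
  m <- small_meth()
  cfg <- g$config
  # null effect table: identical landscapes
  m0 <- plant_methylation(g, effects = data.frame(type = character(0),
                                                  id = character(0),
                                                  fold = numeric(0)))
  expect_identical(m0$wt$level, m0$ko$level)
  # planted arithmetic: KO = WT / fold at targeted features
  tr <- m$truth
  hit <- tr[tr$planted_fold > 1 & tr$n_cpg > 0, ]
  expect_gt(nrow(hit), 0)
  expect_equal(hit$ko_level, hit$wt_level / hit$planted_fold)
  # CGI baseline ~0.07 on average over CGI CpGs
  cgi <- tr[tr$type == "cgi" & tr$n_cpg > 0, ]
  expect_equal(mean(cgi$wt_level), cfg$meth_baseline$cgi, tolerance = 0.01)
  expect_error(plant_methylation(g, effects = data.frame(
    type = "cgi", id = g$cgis$id[1], fold = -1)), "fold")
})

test_that("rrbs conversion chemistry obeys its limits", {
  g <- small_genome()
  cfg_full <- small_config()
  cfg_full$conversion_rate <- 1
  m <- small_meth()
  # all levels 0 with full conversion: every read C becomes T
  zero <- m$wt; zero$level[] <- 0
  sim0 <- simulate_rrbs_reads(g, zero, cfg_full, seed = 3L, n_reads = 500)
  expect_false(any(grepl("C", sim0$reads$seq)))
  # all CpG levels 1, full conversion: CpG-context Cs survive, others not
  one <- m$wt; one$level[one$is_cpg_c] <- 1
  sim1 <- simulate_rrbs_reads(g, one, cfg_full, seed = 3L, n_reads = 300)
  ch <- strsplit(g$sequence, "")[[1]]
  for (i in seq_len(50)) {
    tr <- sim1$truth[i, ]
    rd <- strsplit(sim1$reads$seq[i], "")[[1]]
    gpos <- if (tr$strand == "+") tr$start:tr$end else tr$end:tr$start
    ref <- ch[gpos]
    if (tr$strand == "-") ref <- chartr("ACGT", "TGCA", ref)
    is_c <- ref == "C"
    in_cpg <- if (tr$strand == "+") {
      one$is_cpg_c[gpos]
    } else {
      gpos > 1 & one$is_cpg_c[pmax(gpos - 1L, 1L)]
    }
    expect_true(all(rd[is_c & in_cpg] == "C"))
    expect_true(all(rd[is_c & !in_cpg] == "T"))
    expect_true(all(rd[!is_c] == ref[!is_c]))
  }
})

test_that("read provenance reconstructs every read (conservation)", {
  fx <- norep_rrbs()
  tr <- fx$sim$truth
  # with conversion active, reads differ from the template only at C
  # positions (read space); check on a sample
  for (i in seq(1, nrow(tr), by = 101)) {
    rd <- strsplit(fx$sim$reads$seq[i], "")[[1]]
    tm <- strsplit(tr$template[i], "")[[1]]
    diffs <- which(rd != tm)
    expect_true(all(tm[diffs] == "C" & rd[diffs] == "T"))
  }
})

test_that("simulators are byte-deterministic under a fixed seed", {
  g <- small_genome()
  m <- small_meth()
  s1 <- simulate_rrbs_reads(g, m$wt, seed = 9L, n_reads = 400)
  s2 <- simulate_rrbs_reads(g, m$wt, seed = 9L, n_reads = 400)
  expect_identical(s1, s2)
  d1 <- simulate_dip_reads(g, m$wt, seed = 9L, n_reads = 400)
  d2 <- simulate_dip_reads(g, m$wt, seed = 9L, n_reads = 400)
  expect_identical(d1, d2)
  ex <- data.frame(feature = g$genes$id[1], type = "gene", level = 1)
  r1 <- simulate_rnaseq_reads(g, ex, seed = 9L, n_reads = 400)
  r2 <- simulate_rnaseq_reads(g, ex, seed = 9L, n_reads = 400)
  expect_identical(r1, r2)
})

test_that("DIP enrichment weights fragments by planted mark content", {
  g <- small_genome()
  m <- small_meth()
  cfg <- small_config()
  # alpha = 0: IP starts uniform over the contig (chi-square GOF)
  cfg0 <- cfg; cfg0$dip_enrichment_alpha <- 0
  d0 <- simulate_dip_reads(g, m$wt, config = cfg0, seed = 13L,
                           n_reads = 50000)
  glen <- nchar(g$sequence)
  bins <- cut(d0$truth_ip$frag_start, breaks = 50)
  expect_gt(chisq.test(table(bins))$p.value, 0.01)
  # two regions with 2:1 planted mark sums: coverage ratio follows the
  # fragment-weight ratio within 10% at large alpha
  lv <- numeric(glen)
  cp <- which(m$wt$is_cpg_c)
  r1 <- cp[cp >= 10000 & cp < 12000]; r2 <- cp[cp >= 30000 & cp < 32000]
  lv[r1] <- 0.8; lv[r2] <- 0.4
  ls <- m$wt; ls$level <- lv
  cfg2 <- cfg; cfg2$dip_enrichment_alpha <- 50
  d2 <- simulate_dip_reads(g, ls, config = cfg2, seed = 14L,
                           n_reads = 200000)
  fs <- d2$truth_ip$frag_start
  flen <- cfg2$dip_fragment_length
  n1 <- sum(fs >= 10000 & fs <= 12000 - flen)
  n2 <- sum(fs >= 30000 & fs <= 32000 - flen)
  # expected weight ratio from the truth table itself
  w <- 1 + cfg2$dip_enrichment_alpha *
    (cumsum(lv)[seq_len(glen - flen) + flen] -
       cumsum(lv)[seq_len(glen - flen)])
  ew1 <- sum(w[10000:(12000 - flen)]); ew2 <- sum(w[30000:(32000 - flen)])
  expect_equal(n1 / n2, ew1 / ew2, tolerance = 0.1)
  # null mark: IP indistinguishable from input (KS on start positions)
  null_ls <- m$wt; null_ls$level[] <- 0
  d3 <- simulate_dip_reads(g, null_ls, config = cfg, seed = 15L,
                           n_reads = 20000)
  ks <- suppressWarnings(ks.test(d3$truth_ip$frag_start,
                                 d3$truth_input$frag_start))
  expect_gt(ks$p.value, 0.01)
})

test_that("RNA reads stay inside their features", {
  g <- small_genome()
  ex <- data.frame(feature = g$genes$id[2], type = "gene", level = 1)
  sim <- simulate_rnaseq_reads(g, ex, seed = 21L, n_reads = 500)
  gene <- g$genes[2, ]
  expect_true(all(sim$truth$start >= gene$start &
                    sim$truth$end <= gene$end))
  expect_error(simulate_rnaseq_reads(
    g, data.frame(feature = g$genes$id[1], type = "gene", level = 0)),
    "zero")
  expect_error(simulate_rnaseq_reads(
    g, data.frame(feature = "nope", type = "gene", level = 1)),
    "unknown")
})
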