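test_that("promoter intervals are strand-aware and clipped", {
  plus <- toy_tx("p", c(1000, 2000))
  expect_equal(unclass(promoter_interval(plus))[c("start", "end")],
               list(start = 500, end = 1000))
  minus <- toy_tx("m", c(400, 1000), strand = "-")
  expect_equal(unclass(promoter_interval(minus))[c("start", "end")],
               list(start = 1000, end = 1500))
  near <- toy_tx("n", c(200, 700))
  iv <- promoter_interval(near)
  expect_equal(iv$start, 0)
  expect_equal(iv_width(iv), 200)
  minus_edge <- toy_tx("e", c(500, 900), strand = "-")
  iv2 <- promoter_interval(minus_edge, contig_length = 1100)
  expect_equal(iv2$end, 1100)
})

test_that("promoter annotation reports GC, CpG and repeat content", {
  g <- c(chr1 = paste0(strrep("A", 600), paste(rep("GC", 50), collapse = ""),
                       strrep("T", 600)))
  # promoter [600, 700): all G/C, length 100 via clipping? use flank 100
  tx <- toy_tx("t", c(700, 1000))
  rep_bed <- data.frame(chrom = "chr1", start = 600, end = 700, name = "ERVK")
  cpg_bed <- data.frame(chrom = "chr1", start = 650, end = 660, name = "cpg")
  pr <- annotate_promoters(list(tx), g, cpg_bed, rep_bed, flank = 100)
  expect_equal(pr$gc_fraction, 1.0)
  expect_true(pr$has_cpg)
  expect_equal(pr$repeat_fraction, 1.0)
  expect_equal(pr$repeat_families, "ERVK")
  # no overlapping CpG interval
  pr2 <- annotate_promoters(list(toy_tx("u", c(300, 500))), g,
                            cpg_bed, rep_bed, flank = 100)
  expect_false(pr2$has_cpg)
  expect_equal(pr2$repeat_bp, 0)
  expect_equal(pr2$gc_fraction, 0)     # all A
})

test_that("matched background matches length and GC and avoids annotations", {
  set.seed(81)
  genome <- c(chr1 = random_dna_str(300000))
  txs <- lapply(1:10, function(i) {
    toy_tx(paste0("t", i), c(20000 * i, 20000 * i + 500))
  })
  prom <- annotate_promoters(txs, genome, flank = 500)
  bg <- sample_matched_background(prom, genome, txs, gc_tol = 0.02,
                                  rng_seed = 4)
  expect_equal(nrow(bg), nrow(prom))
  expect_true(all(bg$end - bg$start == prom$length))
  for (i in seq_len(nrow(bg))) {
    s <- substr(genome[[bg$chrom[i]]], bg$start[i] + 1, bg$end[i])
    gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
    expect_lte(abs(gc - prom$gc_fraction[i]), 0.02 + 1e-12)
    for (tx in txs) {
      expect_true(bg$end[i] <= tx$start || bg$start[i] >= tx$end)
    }
  }
  bg2 <- sample_matched_background(prom, genome, txs, gc_tol = 0.02,
                                   rng_seed = 4)
  expect_identical(bg, bg2)
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  set.seed(82)
  for (i in 1:30) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- sample(0:15, 1)
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    p <- fisher.test(matrix(c(a, b, c, d), nrow = 2))$p.value
    expect_equal(p, fisher_oracle_p(a, b, c, d), tolerance = 1e-12)
  }
  # the specific worked table
  expect_equal(fisher.test(matrix(c(8, 2, 1, 9), nrow = 2))$p.value,
               fisher_oracle_p(8, 2, 1, 9), tolerance = 1e-12)
})

test_that("identical proportions give p = 1 and no significance", {
  prom <- data.frame(chrom = "chr1", start = seq(0, 900, 100),
                     end = seq(50, 950, 100))
  rep_bed <- data.frame(chrom = "chr1",
                        start = c(0, 100, 2000, 2100),
                        end = c(40, 140, 2040, 2140), name = "fam")
  bg <- data.frame(chrom = "chr1", start = seq(2000, 2900, 100),
                   end = seq(2050, 2950, 100))
  res <- repeat_enrichment(prom, bg, rep_bed, alpha = 0.005)
  expect_equal(res$p, 1)
  expect_false(res$significant)
})

test_that("a family absent from both sets is skipped", {
  prom <- data.frame(chrom = "chr1", start = 0, end = 100)
  bg <- data.frame(chrom = "chr1", start = 1000, end = 1100)
  rep_bed <- data.frame(chrom = "chr1", start = 5000, end = 5100,
                        name = "ghost")
  res <- repeat_enrichment(prom, bg, rep_bed)
  expect_equal(nrow(res), 0)
})

test_that("the planted promoter fixture family is detected", {
  pf <- plant_promoter_fixture(n_promoters = 60, frac_planted = 0.35,
                               rng_seed = 5)
  prom <- annotate_promoters(pf$txs, pf$genome, NULL, pf$repeat_bed)
  bg <- sample_matched_background(prom, pf$genome, pf$txs, rng_seed = 6)
  res <- repeat_enrichment(prom, bg, pf$repeat_bed, alpha = 0.005)
  expect_true(res$significant[res$family == pf$planted_family])
  expect_false(any(res$significant[res$family != pf$planted_family]))
})

test_that("de novo CpG calling flags designed islands", {
  set.seed(83)
  # AT-rich background with a planted CpG-dense GC-rich island
  bgseq <- paste(sample(c("A", "T"), 3000, replace = TRUE), collapse = "")
  island <- paste(rep("CG", 150), collapse = "")
  g <- c(chr1 = paste0(substr(bgseq, 1, 1500), island,
                       substr(bgseq, 1501, 3000)))
  isl <- call_cpg_islands(g)
  expect_gte(nrow(isl), 1)
  expect_true(any(isl$start <= 1600 & isl$end >= 1700))
  # pure AT genome: nothing called
  expect_equal(nrow(call_cpg_islands(c(chr1 = bgseq))), 0)
})
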