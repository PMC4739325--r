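# Hand-constructed evolution-metric cases with exactly computable values.

test_that("self-alignment gives the metric identities", {
  set.seed(61)
  g <- c(chr1 = random_dna_str(4000))
  tx <- toy_tx("t", c(1000, 1300, 1600, 1800, 2100, 2500))
  m <- evo_metrics(tx, tx, g, g)
  expect_equal(m$tgi, 1)
  expect_equal(m$tti, 1)
  expect_equal(m$ssc, 1)
  expect_equal(m$idr, 0)
  expect_equal(m$conserved_junctions, 2)
})

test_that("an untranscribed target exon reduces TTI but not TGI", {
  set.seed(62)
  g <- c(chr1 = random_dna_str(4000))
  q <- toy_tx("q", c(1000, 1300, 1600, 2000))         # 300 + 400 exonic
  t <- toy_tx("t", c(1000, 1300, 1950, 2000))         # exon 2 mostly lost
  m <- evo_metrics(q, t, g, g)
  expect_equal(m$tgi, 1, tolerance = 1e-9)
  # identical bases exonic in both: 300 (exon 1) + 50 (tail of exon 2)
  expect_equal(m$tti, 350 / 700, tolerance = 1e-9)
  # donor matches but acceptor is 350 bp off: junction not conserved
  expect_equal(m$ssc, 0)
  expect_equal(m$idr, 0, tolerance = 1e-9)
})

test_that("junction conservation is scored per junction with tolerance", {
  set.seed(63)
  g <- c(chr1 = random_dna_str(5000))
  q <- toy_tx("q", c(1000, 1200, 1400, 1700, 1900, 2200))
  t <- toy_tx("t", c(1000, 1200, 1400, 1700, 1910, 2200))
  m <- evo_metrics(q, t, g, g)
  # junction 1 exact; junction 2 donor exact but acceptor off by 10 > 2 bp
  expect_equal(m$ssc, 0.5, tolerance = 1e-9)
  expect_equal(m$tgi, 1, tolerance = 1e-9)
  expect_equal(m$tti, (200 + 300 + 290) / 800, tolerance = 1e-9)
  expect_equal(m$idr, 0, tolerance = 1e-9)
})

test_that("substitutions and an intronic deletion give exact hand values", {
  set.seed(64)
  g1s <- random_dna_str(3000)
  # query: exons [1000,1300) and [1600,2000)
  q <- toy_tx("q", c(1000, 1300, 1600, 2000))
  # target contig: copy of the query span with 20 substituted bases in
  # exon 1 and a 10 bp deletion mid-intron
  span <- substr(g1s, 1001, 2000)
  v <- strsplit(span, "")[[1]]
  cyc <- c(A = "C", C = "G", G = "T", T = "A")
  sub_pos <- 51:70                      # offsets 50..69 inside exon 1
  v[sub_pos] <- cyc[v[sub_pos]]
  v <- v[-(451:460)]                    # delete span offsets 450..459 (intron)
  tseq <- paste(v, collapse = "")
  g2 <- c(chrT = paste0(random_dna_str(100), tseq, random_dna_str(100)))
  t <- transcript("t", "chrT", 100, 100 + nchar(tseq), "+",
                  rbind(c(100, 400), c(690, 1090)))
  g1 <- c(chr1 = g1s)
  m <- evo_metrics(q, t, g1, g2)
  expect_equal(m$tgi, 680 / 700, tolerance = 1e-9)
  expect_equal(m$tti, 680 / 700, tolerance = 1e-9)
  expect_equal(m$ssc, 1, tolerance = 1e-9)
  expect_equal(m$exonic_indel_events, 0)
  expect_equal(m$intronic_indel_events, 1)
  expect_equal(m$idr, log2(1e-3 / (1 / 290 + 1e-3)), tolerance = 1e-9)
})

test_that("TGI and TTI are invariant under swapping query and target", {
  set.seed(65)
  g1s <- random_dna_str(4000)
  v <- strsplit(g1s, "")[[1]]
  cyc <- c(A = "C", C = "G", G = "T", T = "A")
  idx <- sample(1500:2200, 60)
  v[idx] <- cyc[v[idx]]
  g2 <- c(chr1 = paste(v, collapse = ""))
  g1 <- c(chr1 = g1s)
  tx <- toy_tx("x", c(1400, 1700, 2000, 2400))
  m_ab <- evo_metrics(tx, tx, g1, g2)
  m_ba <- evo_metrics(tx, tx, g2, g1)
  expect_equal(m_ab$tgi, m_ba$tgi, tolerance = 1e-9)
  expect_equal(m_ab$tti, m_ba$tti, tolerance = 1e-9)
})

test_that("per-exon profiles aggregate medians in transcription order", {
  set.seed(66)
  g <- c(chr1 = random_dna_str(4000))
  q <- toy_tx("q", c(1000, 1300, 1600, 2000))
  t_part <- toy_tx("t", c(1000, 1300, 1950, 2000))
  m1 <- evo_metrics(q, q, g, g)
  m2 <- evo_metrics(q, t_part, g, g)
  prof <- exon_identity_profile(list(m1, m2), first_n = 3)
  expect_equal(nrow(prof), 2)          # queries have two exons
  expect_equal(prof$median_tti[1], 1)
  expect_equal(prof$median_tti[2], mean(c(1, 50 / 400)))
  expect_equal(prof$n_pairs, c(2, 2))
  # single pair: profile equals its own values
  solo <- exon_identity_profile(list(m2), first_n = 3)
  expect_equal(solo$median_tti[2], 50 / 400)
})

test_that("lncRNA classes follow the host / divergent / intergenic rules", {
  tx <- toy_tx("l", c(1000, 1500, 2000, 2600))
  mir <- data.frame(chrom = "chr1", start = 1600, end = 1680, name = "mir")
  sno <- data.frame(chrom = "chr1", start = 1600, end = 1680, name = "sno")
  expect_equal(classify_lncrna(tx, mirna_bed = mir)$class, "MIRNA_HOST")
  expect_false(classify_lncrna(tx, mirna_bed = mir)$exonic_host)
  mir_ex <- data.frame(chrom = "chr1", start = 1100, end = 1180, name = "m")
  expect_true(classify_lncrna(tx, mirna_bed = mir_ex)$exonic_host)
  expect_equal(classify_lncrna(tx, snorna_bed = sno)$class, "SNORNA_HOST")
  # miRNA host takes precedence
  expect_equal(classify_lncrna(tx, mirna_bed = mir, snorna_bed = sno)$class,
               "MIRNA_HOST")
  # divergent: opposite-strand coding TSS within 500 bp of the lncRNA TSS
  div_gene <- toy_tx("g", c(700, 1400), strand = "-")   # TSS at 1400? no: "-" TSS = end
  lnc <- toy_tx("l2", c(1700, 2500))                     # TSS at 1700
  expect_equal(classify_lncrna(lnc, coding_txs = list(div_gene))$class,
               "DIVERGENT")
  far_gene <- toy_tx("g2", c(700, 1100), strand = "-")
  expect_equal(classify_lncrna(lnc, coding_txs = list(far_gene))$class,
               "INTERGENIC")
  same_strand <- toy_tx("g3", c(700, 1400), strand = "+")
  expect_equal(classify_lncrna(lnc, coding_txs = list(same_strand))$class,
               "INTERGENIC")
})

test_that("a pair is classed only when both species agree", {
  tx <- toy_tx("l", c(1000, 1500, 2000, 2600))
  mir <- data.frame(chrom = "chr1", start = 1600, end = 1680, name = "mir")
  ann_host <- list(mirna = mir, snorna = NULL, coding = list())
  ann_plain <- list(mirna = NULL, snorna = NULL, coding = list())
  expect_equal(classify_pair(tx, tx, ann_host, ann_host), "MIRNA_HOST")
  expect_equal(classify_pair(tx, tx, ann_host, ann_plain), "INTERGENIC")
})

test_that("reciprocal confirmation keeps exactly the two-way pairs", {
  mk <- function(q, t) {
    list(query = list(id = q), target = if (is.na(t)) NULL else list(id = t),
         syntolog = FALSE)
  }
  ab <- list(mk("a1", "b1"), mk("a2", "b2"), mk("a3", NA))
  ba <- list(mk("b1", "a1"), mk("b3", "a2"))
  rec <- reciprocal_orthologs(ab, ba)
  expect_length(rec, 1)
  expect_equal(rec[[1]]$query$id, "a1")
  expect_true(rec[[1]]$reciprocal)
  # symmetry of the confirmed set under swapping the input order
  rec2 <- reciprocal_orthologs(ba, ab)
  expect_equal(vapply(rec2, function(p) p$target$id, ""), "a1")
})

test_that("canonical pair choice ranks by conserved junctions then TTI", {
  mk <- function(q, g, ssc_n, tti) {
    list(query = list(id = q, gene_id = g), target = list(gene_id = "tg"),
         metrics = list(conserved_junctions = ssc_n, tti = tti))
  }
  pairs <- list(mk("i1", "g", 2L, 0.5), mk("i2", "g", 1L, 0.9),
                mk("i3", "g", 2L, 0.7), mk("solo", "h", 0L, 0.1))
  res <- canonical_pair_per_gene(pairs)
  ids <- vapply(res, function(p) p$query$id, "")
  expect_setequal(ids, c("i3", "solo"))
})

test_that("shuffled transcripts keep structure and avoid annotations", {
  fx <- get_fixture()
  txs <- fx$candidates_a[c(13, 14, 15)]
  ann <- c(fx$coding_a, fx$candidates_a)
  shuf <- shuffled_transcript_control(txs, fx$genome_a, ann, rng_seed = 9)
  ann_gr <- lncevo:::txs_span_granges(ann)
  for (i in seq_along(shuf)) {
    expect_equal(sort(shuf[[i]]$exons[, 2] - shuf[[i]]$exons[, 1]),
                 sort(txs[[i]]$exons[, 2] - txs[[i]]$exons[, 1]))
    gr <- lncevo:::txs_span_granges(shuf[i])
    expect_equal(length(GenomicRanges::findOverlaps(gr, ann_gr,
                                                    ignore.strand = TRUE)), 0)
  }
  again <- shuffled_transcript_control(txs, fx$genome_a, ann, rng_seed = 9)
  expect_equal(vapply(again, `[[`, 0, "start"),
               vapply(shuf, `[[`, 0, "start"))
})

test_that("pinned splice-site shuffling recovers the observed count", {
  set.seed(67)
  g <- c(chr1 = random_dna_str(4000))
  q <- toy_tx("q", c(1000, 1300, 1600, 2000))
  jm <- tx_junctions(q)
  res <- splice_shuffle_expectation(
    q, q, g, g, n_shuffles = 5, rng_seed = 1,
    donors = jm[, "donor"] - q$start,
    acceptors = jm[, "acceptor"] - q$start, min_intron = 100)
  expect_equal(res$expected, res$observed)
  expect_equal(res$observed, 1)
})

test_that("random splice-site placement rarely lands on a junction", {
  set.seed(68)
  g <- c(chr1 = random_dna_str(6000))
  q <- toy_tx("q", c(1000, 1400, 2600, 3200))
  res <- splice_shuffle_expectation(q, q, g, g, n_shuffles = 100,
                                    rng_seed = 2)
  expect_equal(res$observed, 1)
  expect_lt(res$expected, 0.5)          # chance placement is rare
  res2 <- splice_shuffle_expectation(q, q, g, g, n_shuffles = 100,
                                     rng_seed = 3)
  expect_lt(abs(res$expected - res2$expected), 0.2)
})

test_that("the EM mixture recovers planted components", {
  set.seed(11)
  x <- c(rnorm(250, 0.66, 0.07), rnorm(250, 0.16, 0.12))
  truth <- rep(c(2L, 1L), each = 250)
  fit <- fit_tti_mixture(x, rng_seed = 11)
  expect_lt(abs(fit$means[2] - 0.66), 0.03)
  expect_lt(abs(fit$means[1] - 0.16), 0.03)
  acc <- mean(fit$assignment == truth)
  expect_gte(max(acc, 1 - acc), 0.9)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_equal(sum(fit$weights), 1)
})

test_that("degenerate and single-component inputs are handled", {
  expect_error(fit_tti_mixture(rep(0.5, 50)), "degenerat")
  expect_error(fit_tti_mixture(c(0.1, 0.2)), "at least 10")
  set.seed(12)
  x <- rnorm(300, 0.5, 0.05)
  fit <- fit_tti_mixture(x, rng_seed = 3)
  expect_true(max(fit$weights) >= 0.9 ||
                abs(diff(fit$means)) < 0.02)
})
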