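identity_chain <- function(len = 10000, contig = "c1") {
  structure(list(chains = list(list(
    score = len, t_name = contig, t_size = len, t_strand = "+",
    t_start = 0, t_end = len, q_name = contig, q_size = len,
    q_strand = "+", q_start = 0, q_end = len, id = "1",
    blocks = cbind(size = len, dt = 0, dq = 0)))), class = "chain_set")
}

# one 10 bp target gap in the middle: [0,500) -> [0,500), [510,1000) -> [500,990)
gapped_chain <- function() {
  structure(list(chains = list(list(
    score = 990, t_name = "c1", t_size = 1000, t_strand = "+",
    t_start = 0, t_end = 1000, q_name = "c1", q_size = 990,
    q_strand = "+", q_start = 0, q_end = 990, id = "g",
    blocks = cbind(size = c(500, 490), dt = c(10, 0), dq = c(0, 0))))),
    class = "chain_set")
}

test_that("lifting through an identity chain is the identity", {
  cs <- identity_chain()
  lr <- lift_interval(cs, genomic_interval("c1", 100, 200, "+"))
  expect_equal(lr$mapped_fraction, 1.0)
  expect_equal(lr$mapped$start, 100)
  expect_equal(lr$mapped$end, 200)
})

test_that("mappings below min_match are suppressed", {
  # chain covering only the first 5% of the interval
  cs <- structure(list(chains = list(list(
    score = 50, t_name = "c1", t_size = 10000, t_strand = "+",
    t_start = 0, t_end = 50, q_name = "c1", q_size = 50, q_strand = "+",
    q_start = 0, q_end = 50, id = "s",
    blocks = cbind(size = 50, dt = 0, dq = 0)))), class = "chain_set")
  lr <- lift_interval(cs, genomic_interval("c1", 0, 1000), min_match = 0.1)
  expect_equal(nrow(lr$mapped), 0)
  lr2 <- lift_interval(cs, genomic_interval("c1", 0, 1000), min_match = 0.01)
  expect_equal(nrow(lr2$mapped), 1)
})

test_that("an interval spanning a target gap shortens by the gap", {
  cs <- gapped_chain()
  lr <- lift_interval(cs, genomic_interval("c1", 400, 600))
  # hand-walk: [400,500) -> [400,500); [510,600) -> [500,590); bases
  # [500,510) fall in the gap
  expect_equal(lr$mapped_fraction, 190 / 200)
  expect_equal(sum(lr$mapped$end - lr$mapped$start), 190)
  expect_equal(min(lr$mapped$start), 400)
  expect_equal(max(lr$mapped$end), 590)
})

test_that("lift is monotone: sub-interval mappings are contained", {
  fx <- get_fixture()
  set.seed(11)
  for (i in 1:40) {
    chrom <- sample(names(fx$genome_a), 1)
    len <- nchar(fx$genome_a[[chrom]])
    s <- sample.int(len - 5000, 1)
    big <- lift_interval(fx$chains, genomic_interval(chrom, s, s + 4000),
                         min_match = 0)
    small <- lift_interval(fx$chains,
                           genomic_interval(chrom, s + 1000, s + 3000),
                           min_match = 0)
    if (nrow(small$mapped) == 0 || nrow(big$mapped) == 0) next
    if (small$chain_id != big$chain_id) next
    expect_gte(min(small$mapped$start), min(big$mapped$start))
    expect_lte(max(small$mapped$end), max(big$mapped$end))
  }
})

test_that("transcript lifting unions exon images and fractions add up", {
  cs <- gapped_chain()
  tx <- toy_tx("t", c(100, 300, 700, 900), chrom = "c1")
  lr <- lift_transcript(cs, tx)
  expect_equal(lr$mapped_fraction, 1.0)
  expect_equal(nrow(lr$mapped), 2)
  # exon 2 shifts left by the 10 bp gap
  expect_equal(lr$mapped$start, c(100, 690))
  # one exon fully unmappable
  cs2 <- structure(list(chains = list(list(
    score = 300, t_name = "c1", t_size = 1000, t_strand = "+",
    t_start = 0, t_end = 300, q_name = "c1", q_size = 300, q_strand = "+",
    q_start = 0, q_end = 300, id = "h",
    blocks = cbind(size = 300, dt = 0, dq = 0)))), class = "chain_set")
  lr2 <- lift_transcript(cs2, tx, min_match = 0.1)
  expect_equal(lr2$mapped_fraction, 200 / 400)
  # fully unmappable
  tx2 <- toy_tx("t2", c(400, 600, 700, 900), chrom = "c1")
  lr3 <- lift_transcript(cs2, tx2)
  expect_equal(nrow(lr3$mapped), 0)
})

test_that("syntenic windows pad and clip correctly", {
  cs <- identity_chain(2000000)
  tx <- toy_tx("t", c(1000000, 1005000, 1008000, 1010000), chrom = "c1")
  win <- syntenic_window(cs, tx, pad = 150000)
  expect_equal(win$start, 850000)
  expect_equal(win$end, 1160000)
  win0 <- syntenic_window(cs, tx, pad = 0)
  expect_equal(win0$start, 1000000)
  expect_equal(win0$end, 1010000)
  tx2 <- toy_tx("t2", c(1000, 5000), chrom = "c1")
  win2 <- syntenic_window(cs, tx2, pad = 150000)
  expect_equal(win2$start, 0)
})

test_that("minus-strand chains map onto the reverse strand consistently", {
  # target [0,100) maps to query [900,1000) reversed
  cs <- structure(list(chains = list(list(
    score = 100, t_name = "t", t_size = 100, t_strand = "+",
    t_start = 0, t_end = 100, q_name = "q", q_size = 1000, q_strand = "-",
    q_start = 0, q_end = 100, id = "m",
    blocks = cbind(size = 100, dt = 0, dq = 0)))), class = "chain_set")
  lr <- lift_interval(cs, genomic_interval("t", 10, 30, "+"))
  expect_equal(lr$mapped$strand, "-")
  # chain query coords count from the reversed strand: forward [900, 1000)
  expect_equal(lr$mapped$start, 970)
  expect_equal(lr$mapped$end, 990)
  # inverting the chain set and lifting back recovers the source
  inv <- invert_chain_set(cs)
  back <- lift_interval(inv, genomic_interval("q", 970, 990, "-"))
  expect_equal(back$mapped$start, 10)
  expect_equal(back$mapped$end, 30)
  expect_equal(back$mapped$strand, "+")
})

test_that("fixture chains invert consistently", {
  fx <- get_fixture()
  inv <- invert_chain_set(fx$chains)
  truth <- fx$truth
  lincs <- truth[grepl("conserved_linc", truth$element), ]
  for (i in seq_len(nrow(lincs))) {
    txb <- Filter(function(t) t$id == lincs$ortholog[i], fx$lncrnas_b)[[1]]
    lr <- lift_transcript(inv, txb)
    expect_gt(lr$mapped_fraction, 0.9)
    txa <- Filter(function(t) t$id == lincs$id_a[i], fx$candidates_a)[[1]]
    expect_equal(lr$mapped$chrom[1], txa$chrom)
    expect_lte(abs(min(lr$mapped$start) - txa$start), 50)
  }
})
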