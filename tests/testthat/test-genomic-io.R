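test_that("FASTA reading normalises case, RNA and ambiguous bases", {
  f <- withr::local_tempfile()
  writeLines(c(">c1", "acgt"), f)
  expect_equal(read_fasta(f), c(c1 = "ACGT"))
  writeLines(c(">c1", "ACGU"), f)
  expect_equal(read_fasta(f), c(c1 = "ACGT"))
  writeLines(c(">c1", "ACRYWSKX"), f)
  expect_equal(unname(read_fasta(f)["c1"]), "ACNNNNNN")
})

test_that("FASTA errors name the offending header", {
  f <- withr::local_tempfile()
  writeLines(c(">c1", "AC", ">c1", "GG"), f)
  expect_error(read_fasta(f), "duplicate.*c1")
  writeLines(character(0), f)
  expect_error(read_fasta(f))
})

test_that("FASTA writing round-trips a genome", {
  g <- c(chrA = random_dna_str(157), chrB = random_dna_str(500))
  f <- withr::local_tempfile()
  write_fasta(g, f, width = 60)
  expect_equal(read_fasta(f), g)
})

test_that("BED12 blocks reconstruct exons exactly", {
  f <- withr::local_tempfile()
  writeLines("c1\t100\t1100\ttx1\t0\t+\t100\t1100\t0\t2\t200,300,\t0,700,", f)
  txs <- read_bed12(f)
  expect_length(txs, 1)
  expect_equal(unname(txs[[1]]$exons[, 1]), c(100, 800))
  expect_equal(unname(txs[[1]]$exons[, 2]), c(300, 1100))
})

test_that("BED12 read/write is the identity on canonical records", {
  txs <- list(
    toy_tx("a", c(100, 300, 800, 1100)),
    toy_tx("b", c(50, 600), strand = "-"),
    toy_tx("c", c(10, 40, 60, 90, 120, 200), chrom = "chr2"))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_bed12(txs, f1)
  back <- read_bed12(f1)
  write_bed12(back, f2)
  expect_equal(readLines(f1), readLines(f2))
  expect_equal(vapply(back, `[[`, "", "id"), c("b", "a", "c"))  # sorted
  minus <- back[vapply(back, `[[`, "", "id") == "b"][[1]]
  expect_equal(minus$strand, "-")
  expect_equal(unname(minus$exons), matrix(c(50, 600), ncol = 2))
})

test_that("BED12 parse errors carry line numbers", {
  f <- withr::local_tempfile()
  writeLines("c1\t100\t1100\ttx1\t0\t+\t100\t1100\t0\t2\t200,\t0,700,", f)
  expect_error(read_bed12(f), "line 1.*blockCount")
  writeLines(c("c1\t0\t100\tok\t0\t+\t0\t100\t0\t1\t100,\t0,",
               "c1\t100\t200\tbad\t0\t+\t100\t200\t0\t1\t200,\t0,"), f)
  expect_error(read_bed12(f), "line 2")
  writeLines(character(0), f)
  expect_equal(read_bed12(f), list())
})

test_that("GTF exons convert to the 0-based model and round-trip", {
  f <- withr::local_tempfile()
  writeLines(c(
    'c1\tx\texon\t101\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'c1\tx\texon\t801\t1100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'), f)
  txs <- read_gtf(f)
  expect_length(txs, 1)
  tx <- txs[[1]]
  expect_equal(unname(tx$exons), matrix(c(100, 800, 300, 1100), ncol = 2))
  b <- withr::local_tempfile()
  write_bed12(list(tx), b)
  expect_equal(unname(read_bed12(b)[[1]]$exons), unname(tx$exons))
})

test_that("chain parsing validates block arithmetic", {
  f <- withr::local_tempfile()
  writeLines(c("chain 1000 c1 1000 + 0 1000 c1 1000 + 0 1000 1",
               "1000", ""), f)
  cs <- read_chain(f)
  expect_length(cs$chains, 1)
  expect_equal(unname(cs$chains[[1]]$blocks[, "size"]), 1000)

  writeLines(c("chain 990 c1 1010 + 0 1000 c1 990 + 0 990 2",
               "500 10 0", "490", ""), f)
  cs <- read_chain(f)
  b <- cs$chains[[1]]$blocks
  expect_equal(unname(b[, "size"]), c(500, 490))
  expect_equal(unname(b[, "dt"]), c(10, 0))

  writeLines(c("chain 990 c1 1010 + 0 1000 c1 990 + 0 990 3",
               "500 10 0", "400", ""), f)
  expect_error(read_chain(f), "chain 3.*sum")
})

test_that("chain write/read round-trips the fixture chains", {
  fx <- get_fixture()
  f <- withr::local_tempfile()
  write_chain(fx$chains, f)
  back <- read_chain(f)
  expect_equal(length(back$chains), length(fx$chains$chains))
  for (i in seq_along(back$chains)) {
    expect_equal(unname(back$chains[[i]]$blocks),
                 unname(fx$chains$chains[[i]]$blocks))
    expect_equal(back$chains[[i]]$t_start, fx$chains$chains[[i]]$t_start)
  }
})

test_that("transcript invariants are enforced", {
  expect_error(toy_tx("bad", c(100, 50)), "empty exon")
  expect_error(transcript("bad", "c1", 0, 100, "+",
                          rbind(c(0, 60), c(50, 100))), "overlapping")
  expect_error(transcript("bad", "c1", 0, 100, "+", rbind(c(10, 100))),
               "footprint")
  tx <- toy_tx("ok", c(0, 50, 80, 130))
  expect_equal(exonic_length(tx), 100)
  expect_equal(unname(tx_junctions(tx)), matrix(c(50, 80), ncol = 2))
})

test_that("spliced sequence extraction respects strand", {
  g <- c(chr1 = "AAACCCGGGTTT")
  tx <- toy_tx("t", c(0, 3, 9, 12))
  expect_equal(tx_spliced_seq(g, tx), "AAATTT")
  txm <- toy_tx("t", c(0, 3, 9, 12), strand = "-")
  expect_equal(tx_spliced_seq(g, txm), "AAATTT")  # revcomp of AAATTT
  tx2 <- toy_tx("t", c(3, 9))
  expect_equal(tx_spliced_seq(g, tx2), "CCCGGG")
  tx2m <- toy_tx("t", c(3, 9), strand = "-")
  expect_equal(tx_spliced_seq(g, tx2m), "CCCGGG")
})
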