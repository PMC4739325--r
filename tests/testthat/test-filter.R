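test_that("coding overlap removal follows the any-amount same-strand rule", {
  cand <- list(
    toy_tx("one_bp", c(999, 1500)),                 # 1 bp exonic overlap
    toy_tx("opp", c(500, 900), strand = "-"),       # opposite strand
    toy_tx("intronic", c(1600, 1900)),              # inside coding intron
    toy_tx("clear", c(5000, 5400)))
  coding <- list(toy_tx("g", c(500, 1000, 2000, 2500)))
  res <- remove_coding_overlap(cand, coding, mode = "exon")
  expect_equal(vapply(res$removed, `[[`, "", "id"), "one_bp")
  expect_setequal(vapply(res$kept, `[[`, "", "id"),
                  c("opp", "intronic", "clear"))
  # gene-span mode also removes the intronic candidate
  res2 <- remove_coding_overlap(cand, coding, mode = "span")
  expect_setequal(vapply(res2$removed, `[[`, "", "id"),
                  c("one_bp", "intronic"))
})

test_that("canonical isoform selection keeps the longest per exonic cluster", {
  txs <- list(
    toy_tx("short", c(100, 300, 600, 900), gene_id = "g"),   # 500 exonic bp
    toy_tx("long", c(100, 300, 600, 1200), gene_id = "g"),   # 800 exonic bp
    toy_tx("solo", c(5000, 5500)))
  res <- select_canonical_isoforms(txs)
  expect_setequal(vapply(res$canonical, `[[`, "", "id"), c("long", "solo"))
  cm <- res$cluster_map
  expect_equal(cm$canonical_id[cm$id == "short"], "long")
})

test_that("isoform clustering is transitive", {
  txs <- list(
    toy_tx("A", c(0, 500)),
    toy_tx("B", c(400, 1000)),        # overlaps A
    toy_tx("C", c(900, 1600)),        # overlaps B only
    toy_tx("D", c(5000, 5100)))
  res <- select_canonical_isoforms(txs)
  cm <- res$cluster_map
  expect_equal(length(unique(cm$cluster[cm$id %in% c("A", "B", "C")])), 1)
  expect_length(res$canonical, 2)    # one per cluster: {A,B,C} and {D}
})

test_that("duplication clusters respect min_cluster_size", {
  set.seed(21)
  genome <- c(chr1 = random_dna_str(120000))
  base <- random_dna_str(800)
  mut <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), round(rate * length(v)))
    v[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
    paste(v, collapse = "")
  }
  copies <- lapply(1:3, function(i) mut(base, 0.1))
  g <- paste0(substr(genome, 1, 10000), copies[[1]],
              substr(genome, 10001, 40000), copies[[2]],
              substr(genome, 40001, 80000), copies[[3]],
              substr(genome, 80001, 120000))
  genome <- c(chr1 = g)
  cands <- list(toy_tx("c1", c(10000, 10800)),
                toy_tx("c2", c(40800, 41600)),
                toy_tx("c3", c(81600, 82400)),
                toy_tx("solo", c(100000, 100700)))
  res <- find_duplication_clusters(cands, genome, cands, rng_seed = 3)
  expect_length(res$clusters, 1)
  expect_setequal(res$clusters[[1]], c("c1", "c2", "c3"))
  expect_setequal(vapply(res$kept, `[[`, "", "id"), "solo")
  # raising min_cluster_size keeps the family
  res4 <- find_duplication_clusters(cands, genome, cands,
                                    min_cluster_size = 4, rng_seed = 3)
  expect_length(res4$clusters, 0)
  expect_length(res4$kept, 4)
})

test_that("the learned threshold is the empirical 5th percentile", {
  m <- coding_filter_model(rep(1.0, 50))
  expect_equal(m$threshold, 1.0)
  scores <- seq(0.01, 1, by = 0.01)     # uniform grid of 100 positives
  m2 <- coding_filter_model(scores)
  expect_equal(m2$threshold, unname(quantile(scores, 0.05, type = 1)))
  expect_equal(m2$threshold, 0.05)
})

test_that("too few positives is an instructive error", {
  fx <- get_fixture()
  few <- fx$candidates_a[1:3]
  expect_error(
    learn_coding_identity_threshold(few, fx$coding_b, fx$chains,
                                    fx$genome_a, fx$genome_b),
    "supply a threshold")
})

test_that("the pipeline handles empty input and disabled stages", {
  fx <- get_fixture()
  res <- run_filter_pipeline(list(), list())
  expect_length(res$lncrnas, 0)
  expect_equal(nrow(res$report), 0)
  cfg <- list(coding = fx$coding_a, other_coding = fx$coding_b,
              chains = fx$chains, genome = fx$genome_a,
              other_genome = fx$genome_b, skip_syntenic = TRUE,
              n_null = 50L, seed = 5L)
  res2 <- run_filter_pipeline(fx$candidates_a[1:20], cfg)
  expect_equal(unname(res2$stage_counts["removed_syntenic_coding"]), 0L)
  # fates partition the input
  expect_equal(nrow(res2$report), 20)
  expect_false(anyNA(res2$report$fate))
})

test_that("the pipeline is idempotent on its own output", {
  fx <- get_fixture()
  run <- get_golden_run()
  model <- run$filter$coding_model
  kept <- run$filter$lncrnas
  cfg <- list(coding = fx$coding_a, other_coding = fx$coding_b,
              chains = fx$chains, genome = fx$genome_a,
              other_genome = fx$genome_b, coding_model = model,
              known_panels = fx$known_panels, seed = 7L)
  res2 <- run_filter_pipeline(kept, cfg)
  expect_equal(sort(vapply(res2$lncrnas, `[[`, "", "id")),
               sort(vapply(kept, `[[`, "", "id")))
})
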