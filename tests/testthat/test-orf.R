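# Hand-worked Nei-Gojobori values (pathway counting, equal weights, stop
# pathways excluded, stop-creating changes counted as nonsynonymous sites).
ng_cases <- list(
  list(a = "AAA", b = "AAA", N = 8 / 3, S = 1 / 3, Nd = 0, Sd = 0, ratio = 0),
  list(a = "AAA", b = "AAG", N = 8 / 3, S = 1 / 3, Nd = 0, Sd = 1, ratio = 0),
  list(a = "TTT", b = "TTA", N = 5 / 2, S = 1 / 2, Nd = 1, Sd = 0,
       ratio = Inf),
  # two-position difference, both pathways valid: averaged counts
  list(a = "TTT", b = "GTA", N = 7 / 3, S = 2 / 3, Nd = 1.5, Sd = 0.5,
       ratio = NA),
  # one pathway passes through TGA and is excluded
  list(a = "TGG", b = "CGA", N = 7 / 3, S = 2 / 3, Nd = 1, Sd = 1,
       ratio = NA))

test_that("Nei-Gojobori counts equal hand-worked values", {
  for (cs in ng_cases) {
    d <- nei_gojobori_dnds(cs$a, cs$b)
    expect_equal(d$N, cs$N, tolerance = 1e-12, info = cs$a)
    expect_equal(d$S, cs$S, tolerance = 1e-12, info = cs$a)
    expect_equal(d$Nd, cs$Nd, tolerance = 1e-12, info = cs$a)
    expect_equal(d$Sd, cs$Sd, tolerance = 1e-12, info = cs$a)
    if (!is.na(cs$ratio)) expect_equal(d$ratio, cs$ratio, info = cs$a)
  }
})

test_that("site counts always sum to three per codon", {
  set.seed(31)
  for (i in 1:50) {
    cp <- neutral_codon_pair(20, sub_rate = 0.2, omega = 1, rng_seed = i)
    d <- nei_gojobori_dnds(cp$a, cp$b)
    expect_equal(d$N + d$S, 3 * 20, tolerance = 1e-9)
  }
})

test_that("sentinel rules: identical, synonymous-only, dS = 0", {
  same <- nei_gojobori_dnds("ATGAAACCC", "ATGAAACCC")
  expect_equal(same$ratio, 0)
  syn <- nei_gojobori_dnds("ATGAAACCC", "ATGAAGCCC")   # AAA->AAG synonymous
  expect_equal(syn$Nd, 0)
  expect_equal(syn$ratio, 0)
  nonsyn <- nei_gojobori_dnds("TTTTTT", "TTATTT")
  expect_equal(nonsyn$ratio, Inf)
  expect_error(nei_gojobori_dnds("ATGTAAAAA", "ATGTAAAAA"), "stop")
  expect_error(nei_gojobori_dnds("ATG-AA", "ATGAAA"), "gap-free")
})

test_that("uncorrected mode returns raw p-distances", {
  cp <- neutral_codon_pair(50, sub_rate = 0.2, omega = 1, rng_seed = 9)
  jc <- nei_gojobori_dnds(cp$a, cp$b, correction = "jc")
  raw <- nei_gojobori_dnds(cp$a, cp$b, correction = "none")
  expect_equal(raw$dN, raw$pN)
  expect_gte(jc$dN, raw$dN)   # JC stretches distances
})

test_that("aligned ORFs are found only when frame-intact in both species", {
  orf <- paste0("ATG", strrep("AAA", 10), "TAA")       # 36 nt
  a <- paste0("CCCCCCCCCCCCCCC", orf, "CCCCCCCCCCCCCCC")
  al <- best_alignment(a, a, scoring_scheme(seed_length = 8))
  hits <- enumerate_aligned_orfs(al, a, a, min_len = 33)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$length_nt, 36)
  expect_equal(hits[[1]]$ratio, 0)
  # 1 bp insertion mid-ORF in species B: frameshift, nothing reported
  b <- paste0(substr(a, 1, 25), "G", substr(a, 26, nchar(a)))
  al2 <- best_alignment(a, b, scoring_scheme(seed_length = 8, gap_open = 5,
                                             gap_extend = 2))
  expect_length(enumerate_aligned_orfs(al2, a, b, min_len = 33), 0)
  # too-short ORF is not reported
  short <- paste0("CCCCCCCCCCCCCCC", "ATGAAATAA", "CCCCCCCCCCCCCCC")
  al3 <- best_alignment(short, short, scoring_scheme(seed_length = 8))
  expect_length(enumerate_aligned_orfs(al3, short, short, min_len = 33), 0)
  expect_length(enumerate_aligned_orfs(al3, short, short, min_len = 9), 1)
})

test_that("ORFs must stop at the same aligned position in both species", {
  # species B gains an early stop: no aligned ORF reported at that start
  a <- paste0("GGGGGGGGGGGGGGG", "ATG", strrep("AAA", 12), "TAA",
              "GGGGGGGGGGGGGGG")
  b_chars <- strsplit(a, "")[[1]]
  b_chars[19:21] <- c("T", "A", "A")   # first codon after ATG becomes TAA
  b <- paste(b_chars, collapse = "")
  al <- best_alignment(a, b, scoring_scheme(seed_length = 8))
  expect_length(enumerate_aligned_orfs(al, a, b, min_len = 33), 0)
})

test_that("empirical ORF significance uses the one-sided low-ratio estimator", {
  null <- lncevo:::dnds_null_from_ratios(
    ratios = rep(seq(0.5, 2, length.out = 100)),
    lengths = rep(35L, 100))
  hit0 <- list(length_nt = 36L, ratio = 0)
  sig <- orf_significance(list(hit0), null, alpha = 0.05)
  expect_equal(sig$p_empirical, 1 / 101)
  expect_true(sig$flagged_coding)
  # long ORF with no usable bin: dN/dS < 1 fallback
  long_low <- list(length_nt = 900L, ratio = 0.4)
  long_high <- list(length_nt = 900L, ratio = 1.3)
  sig2 <- orf_significance(list(long_low, long_high), null, alpha = 0.05)
  expect_false(any(sig2$bin_usable))
  expect_equal(sig2$flagged_coding, c(TRUE, FALSE))
})

test_that("the dN/dS null table bins ratios by length and is seeded", {
  fx <- get_fixture()
  nt1 <- build_dnds_null(fx$genome_a, fx$genome_b, fx$chains,
                         c(fx$candidates_a, fx$coding_a),
                         n_regions = 150L, rng_seed = 5L)
  nt2 <- build_dnds_null(fx$genome_a, fx$genome_b, fx$chains,
                         c(fx$candidates_a, fx$coding_a),
                         n_regions = 150L, rng_seed = 5L)
  expect_identical(nt1$bins, nt2$bins)
  for (nm in names(nt1$bins)) {
    lo <- as.numeric(nm)
    expect_true(all(is.finite(lo)))
  }
})

test_that("neutral simulation is calibrated and purifying is detected", {
  ratios <- vapply(1:200, function(i) {
    cp <- neutral_codon_pair(100, sub_rate = 0.15, omega = 1, rng_seed = i)
    nei_gojobori_dnds(cp$a, cp$b)$ratio
  }, 0)
  expect_lt(abs(median(ratios) - 1), 0.15)
  pur <- vapply(1:50, function(i) {
    cp <- neutral_codon_pair(100, sub_rate = 0.15, omega = 0.1,
                             rng_seed = 5000 + i)
    nei_gojobori_dnds(cp$a, cp$b)$ratio
  }, 0)
  expect_lt(median(pur), 0.3)
  # omega = 0 permits no nonsynonymous changes at all
  cp0 <- neutral_codon_pair(100, sub_rate = 0.3, omega = 0, rng_seed = 1)
  expect_equal(nei_gojobori_dnds(cp0$a, cp0$b)$Nd, 0)
})
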