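# Shared, memoized test fixtures: the planted genome pair is expensive to
# build and the full pipeline run is reused by several tests.

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    .fixture_cache$fx <- plant_genome_pair(fixture_config(rng_seed = 7L))
  }
  .fixture_cache$fx
}

golden_config <- function(seed = 7L) {
  # fixture-scale ORF null (the genomes are small; the bin occupancy rule
  # makes larger nulls pointless here)
  pipeline_defaults(seed = seed, orf_null_regions = 400L)
}

get_golden_run <- function() {
  if (is.null(.fixture_cache$run)) {
    dir <- file.path(tempdir(), "lncevo-golden-run")
    .fixture_cache$run <- run_all(get_fixture(), dir, golden_config())
  }
  .fixture_cache$run
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# simple single-contig genome + transcript builders for unit tests
toy_tx <- function(id, exons, chrom = "chr1", strand = "+", gene_id = id) {
  exons <- matrix(exons, ncol = 2, byrow = TRUE)
  transcript(id, chrom, exons[1, 1], exons[nrow(exons), 2], strand, exons,
             gene_id = gene_id)
}

# Full affine-gap Smith-Waterman oracle via Biostrings (independent of the
# package's own DP): same scoring convention (gap of length L costs
# open + L * extend).
sw_oracle_score <- function(a, b, scoring) {
  m <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = -scoring$mismatch, baseOnly = TRUE)
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = m,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)))
}

# Brute-force minimum-change LCA oracle: enumerates every internal labeling.
brute_force_lca <- function(tree, profile) {
  tips <- tree$tip.label
  pres <- as.logical(profile[tips])
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  parent <- rep(NA_integer_, n_node)
  for (r in seq_len(nrow(tree$edge))) parent[tree$edge[r, 2]] <- tree$edge[r, 1]
  anc_of <- function(v) {
    p <- v
    while (!is.na(parent[v])) { v <- parent[v]; p <- c(v, p) }
    p
  }
  depth <- vapply(seq_len(n_node), function(v) length(anc_of(v)) - 1L, 0L)
  best <- Inf
  optimal_present <- list()
  for (mask in 0:(2^tree$Nnode - 1)) {
    lab <- c(pres, as.logical(bitwAnd(bitwShiftR(mask, 0:(tree$Nnode - 1)), 1)))
    ch <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    if (ch < best) {
      best <- ch
      optimal_present <- list(which(lab))
    } else if (ch == best) {
      optimal_present[[length(optimal_present) + 1L]] <- which(lab)
    }
  }
  pl <- which(pres)
  mrca <- if (length(pl) == 1L) pl else ape::getMRCA(tree, tips[pl])
  path <- anc_of(mrca)
  in_some <- vapply(path, function(v) {
    any(vapply(optimal_present, function(s) v %in% s, TRUE))
  }, TRUE)
  cand <- path[in_some]
  if (length(cand) == 0L) cand <- mrca   # parsimony prefers independent
                                         # gains; most-recent rule -> set-MRCA
  list(node_id = cand[which.max(depth[cand])], min_changes = best,
       n_candidates = length(cand))
}

# Two-sided Fisher exact P oracle: sum of hypergeometric point masses no
# larger than the observed one.
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}
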