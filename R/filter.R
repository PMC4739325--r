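# The stringent three-step filter that turns candidate transcripts into a
# high-confidence lncRNA set: (1) same-strand coding overlap, (2) canonical
# isoforms and duplication-cluster removal against empirical intergenic
# nulls, (3) a learned exonic-identity threshold against syntenic coding
# genes of another species.

#' Remove candidates overlapping coding genes on the same strand
#'
#' Any amount of exonic overlap on the same strand removes a candidate; the
#' stricter gene-span mode additionally removes candidates whose exons fall
#' inside a coding gene's introns.
#'
#' @param candidates,coding Lists of transcripts on the same genome.
#' @param mode `"exon"` (default; exon-exon overlap) or `"span"` (candidate
#'   exon vs whole coding span).
#' @return List with `kept` and `removed` transcript lists.
#' @export
remove_coding_overlap <- function(candidates, coding,
                                  mode = c("exon", "span")) {
  mode <- match.arg(mode)
  if (length(candidates) == 0L) return(list(kept = list(), removed = list()))
  cand_gr <- txs_exon_granges(candidates)
  cod_gr <- if (mode == "exon") txs_exon_granges(coding) else
    txs_span_granges(coding)
  hits <- GenomicRanges::findOverlaps(cand_gr, cod_gr, ignore.strand = FALSE)
  removed_idx <- sort(unique(cand_gr$tx_index[S4Vectors::queryHits(hits)]))
  list(kept = candidates[setdiff(seq_along(candidates), removed_idx)],
       removed = candidates[removed_idx])
}

#' Collapse overlapping isoforms to one canonical transcript
#'
#' Transcripts with any amount of same-strand exonic overlap are clustered
#' transitively; the canonical isoform of each cluster is the one with the
#' greatest exonic length (ties broken by genomic span, then id).
#'
#' @param txs List of transcripts.
#' @return List with `canonical` (transcript list) and `cluster_map`
#'   (data.frame `id`, `cluster`, `canonical_id`).
#' @export
select_canonical_isoforms <- function(txs) {
  if (length(txs) == 0L) {
    return(list(canonical = list(),
                cluster_map = data.frame(id = character(0),
                                         cluster = integer(0),
                                         canonical_id = character(0))))
  }
  gr <- txs_exon_granges(txs)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = FALSE)
  from <- gr$tx_index[S4Vectors::queryHits(hits)]
  to <- gr$tx_index[S4Vectors::subjectHits(hits)]
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = FALSE,
    vertices = data.frame(name = seq_along(txs)))
  comp <- igraph::components(g)$membership
  comp <- comp[as.character(seq_along(txs))]
  ids <- vapply(txs, `[[`, "", "id")
  ex_len <- vapply(txs, exonic_length, 0)
  span <- vapply(txs, function(tx) tx$end - tx$start, 0)
  canon_of <- vapply(unique(comp), function(cl) {
    members <- which(comp == cl)
    o <- order(-ex_len[members], -span[members], ids[members])
    members[o[1L]]
  }, 0L)
  names(canon_of) <- unique(comp)
  cluster_map <- data.frame(id = ids, cluster = as.integer(comp),
                            canonical_id = ids[canon_of[as.character(comp)]],
                            stringsAsFactors = FALSE)
  list(canonical = txs[sort(unname(canon_of))], cluster_map = cluster_map)
}

#' Detect and remove duplication clusters
#'
#' Every candidate's spliced sequence is aligned to every other candidate's;
#' a pair is linked when its alignment score is significant at `alpha`
#' against the shuffled-intergenic nulls of *both* transcripts.  Linked
#' candidates are merged transitively into duplication clusters; clusters
#' with at least `min_cluster_size` members are removed (lineage-specific
#' gene-family expansions such as zinc-finger or olfactory genes masquerade
#' as lncRNAs this way).  Removed members are additionally aligned to the
#' optional known-gene panels and hits reported -- an annotation, not a
#' removal criterion.
#'
#' @param candidates Canonical candidate transcripts.
#' @param genome Their genome.
#' @param annotations Transcripts excluded from null sampling.
#' @param scoring A [scoring_scheme()] (default gap-strict scheme:
#'   duplications are recent and gap-poor).
#' @param n_null,alpha Null size and significance level.
#' @param min_cluster_size Smallest removable cluster.
#' @param known_panels Optional named character vector of known gene
#'   sequences (e.g. zinc-finger, olfactory panels).
#' @param rng_seed Integer seed.
#' @return List with `kept`, `removed` (transcript lists), `clusters`
#'   (list of member-id vectors) and `panel_hits` (data.frame `id`,
#'   `panel_gene`, `score`).
#' @export
find_duplication_clusters <- function(candidates, genome, annotations,
                                      scoring = scoring_default(),
                                      n_null = 200L, alpha = 0.05,
                                      min_cluster_size = 2L,
                                      known_panels = NULL, rng_seed = 1L) {
  n <- length(candidates)
  if (n == 0L) {
    return(list(kept = list(), removed = list(), clusters = list(),
                panel_hits = data.frame(id = character(0),
                                        panel_gene = character(0),
                                        score = numeric(0))))
  }
  seqs <- vapply(candidates, function(tx) tx_spliced_seq(genome, tx), "")
  ids <- vapply(candidates, `[[`, "", "id")
  # per-candidate null: the candidate against length-matched intergenic draws
  null_q95 <- vapply(seq_len(n), function(i) {
    draws <- sample_intergenic(genome, annotations, nchar(seqs[i]),
                               n = n_null,
                               rng_seed = derive_seed(rng_seed, ids[i]))
    ns <- sort(top_scores(seqs[i], draws, scoring))
    # score must exceed this to reach p <= alpha with the add-one estimator
    k <- floor(alpha * (n_null + 1)) - 1
    ns[n_null - k]
  }, 0)
  edges <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- top_scores(seqs[i], list(seqs[j]), scoring)
      if (s > 0 && s > null_q95[i] && s > null_q95[j]) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  clusters <- list()
  removed_idx <- integer(0)
  if (!is.null(edges)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1], to = edges[, 2]), directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    comp <- igraph::components(g)$membership
    for (cl in unique(comp)) {
      members <- which(comp[as.character(seq_len(n))] == cl)
      if (length(members) >= min_cluster_size && length(members) >= 2L) {
        clusters[[length(clusters) + 1L]] <- ids[members]
        removed_idx <- c(removed_idx, members)
      }
    }
  }
  removed_idx <- sort(removed_idx)
  panel_hits <- data.frame(id = character(0), panel_gene = character(0),
                           score = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(known_panels) && length(removed_idx)) {
    for (i in removed_idx) {
      sc <- top_scores(seqs[i], as.list(known_panels), scoring)
      hit <- sc > null_q95[i]
      if (any(hit)) {
        panel_hits <- rbind(panel_hits, data.frame(
          id = ids[i], panel_gene = names(known_panels)[hit],
          score = sc[hit], stringsAsFactors = FALSE))
      }
    }
  }
  list(kept = candidates[setdiff(seq_len(n), removed_idx)],
       removed = candidates[removed_idx],
       clusters = clusters, panel_hits = panel_hits)
}

# Exonic identity of a candidate against a syntenic coding gene: the number
# of distinct candidate bases aligned identically (over all kept local
# alignments of the spliced candidate vs the gene's unspliced pre-mRNA span)
# divided by the candidate's exonic length.  Counting per base rather than
# per alignment column makes the score robust to alignments that share a few
# boundary bases.
coding_alignment_identity <- function(cand_seq, gene_span_seq, scoring) {
  alns <- local_align(cand_seq, gene_span_seq, scoring)
  if (length(alns) == 0L) return(0)
  matched <- rep(FALSE, nchar(cand_seq))
  for (al in alns) {
    ex <- expand_alignment(al)
    sel <- ex$op == 0
    matched[ex$q[sel] + 1] <- TRUE
  }
  sum(matched) / nchar(cand_seq)
}

# Syntenic coding transcripts whose span overlaps the candidate's lifted
# footprint.
syntenic_coding_partners <- function(tx, chain_set, other_species_coding,
                                     min_match = 0.1) {
  lr <- lift_transcript(chain_set, tx, min_match = min_match)
  if (nrow(lr$mapped) == 0L) return(list())
  partners <- list()
  for (ct in other_species_coding) {
    ov <- sum(vapply(seq_len(nrow(lr$mapped)), function(r) {
      if (lr$mapped$chrom[r] != ct$chrom) return(0)
      overlap_bp(lr$mapped$start[r], lr$mapped$end[r], ct$start, ct$end)
    }, 0))
    if (ov > 0) partners[[length(partners) + 1L]] <- ct
  }
  partners
}

#' Learn the syntenic-coding identity threshold
#'
#' The positive distribution is built from transcripts already removed for
#' coding-gene overlap: each is aligned to its syntenic coding gene in the
#' other species, and the threshold is set at the empirical 5th percentile of
#' the resulting exonic-identity scores (an empirical P of 0.05 for a true
#' coding alignment).  At most `cap` positives are used.
#'
#' @param removed_coding_overlaps Transcripts removed in filter step 1.
#' @param other_species_coding Coding transcripts of the comparison species.
#' @param chain_set Chains to the comparison species.
#' @param genome_a,genome_b The two genomes.
#' @param scoring A [scoring_scheme()].
#' @param cap Maximum number of positives used.
#' @param min_positives Minimum scored positives for a usable model.
#' @param min_match Lift threshold.
#' @param rng_seed Integer seed (positive subsampling).
#' @return A `coding_filter_model`: `positive_scores`, `threshold`,
#'   `n_positive`.
#' @export
learn_coding_identity_threshold <- function(removed_coding_overlaps,
                                            other_species_coding, chain_set,
                                            genome_a, genome_b,
                                            scoring = scoring_default(),
                                            cap = 250L, min_positives = 10L,
                                            min_match = 0.1, rng_seed = 1L) {
  pos <- removed_coding_overlaps
  if (length(pos) > cap) {
    pos <- with_seed(derive_seed(rng_seed, "threshold-cap"),
                     pos[sort(sample.int(length(pos), cap))])
  }
  scores <- numeric(0)
  for (tx in pos) {
    partners <- syntenic_coding_partners(tx, chain_set, other_species_coding,
                                         min_match)
    if (length(partners) == 0L) next
    cand_seq <- tx_spliced_seq(genome_a, tx)
    best <- max(vapply(partners, function(ct) {
      coding_alignment_identity(cand_seq, tx_span_seq(genome_b, ct), scoring)
    }, 0))
    scores <- c(scores, best)
  }
  if (length(scores) < min_positives) {
    stop("only ", length(scores), " liftable coding-overlap positives (< ",
         min_positives, "): supply a threshold explicitly via ",
         "coding_filter_model()")
  }
  coding_filter_model(scores)
}

#' @rdname learn_coding_identity_threshold
#' @param positive_scores Exonic-identity scores of known coding alignments
#'   (or a single user-chosen threshold).
#' @export
coding_filter_model <- function(positive_scores) {
  threshold <- unname(quantile(positive_scores, 0.05, type = 1))
  structure(list(positive_scores = positive_scores, threshold = threshold,
                 n_positive = length(positive_scores)),
            class = "coding_filter_model")
}

#' Remove candidates aligning to syntenic coding genes
#'
#' A candidate is removed when its best exonic identity against any syntenic
#' coding transcript -- aligned over the gene's whole pre-mRNA span, so UTR
#' and intronic homology counts -- exceeds the learned threshold.  This
#' removes unannotated coding genes, processed pseudogenes, and UTR or
#' intronic fragments of incomplete assemblies.
#'
#' @param candidates Candidate transcripts.
#' @param model A `coding_filter_model`.
#' @param other_species_coding Coding transcripts of the comparison species.
#' @param chain_set Chains to the comparison species.
#' @param genome_a,genome_b The two genomes.
#' @param scoring A [scoring_scheme()].
#' @param min_match Lift threshold.
#' @return List with `kept`, `removed`, and `scores` (named numeric of best
#'   identities).
#' @export
filter_syntenic_coding <- function(candidates, model, other_species_coding,
                                   chain_set, genome_a, genome_b,
                                   scoring = scoring_default(),
                                   min_match = 0.1) {
  n <- length(candidates)
  scores <- setNames(numeric(n), vapply(candidates, `[[`, "", "id"))
  removed <- logical(n)
  for (i in seq_len(n)) {
    tx <- candidates[[i]]
    partners <- syntenic_coding_partners(tx, chain_set, other_species_coding,
                                         min_match)
    if (length(partners) == 0L) next
    cand_seq <- tx_spliced_seq(genome_a, tx)
    scores[i] <- max(vapply(partners, function(ct) {
      coding_alignment_identity(cand_seq, tx_span_seq(genome_b, ct), scoring)
    }, 0))
    removed[i] <- scores[i] > model$threshold
  }
  list(kept = candidates[!removed], removed = candidates[removed],
       scores = scores)
}

#' Run the full lncRNA filtering pipeline
#'
#' Stage order: same-strand coding overlap; canonical isoform selection;
#' single-exon quarantine (single-exon reconstructions are overwhelmingly
#' artifacts, so they are set aside and only rescued later if conserved);
#' duplication clusters; syntenic-coding threshold.  Every input candidate
#' receives exactly one fate.
#'
#' @param candidates Candidate transcripts.
#' @param config List with the annotation inputs and parameters:
#'   `coding` (same-species coding transcripts), `other_coding`
#'   (comparison-species coding transcripts), `chains`, `genome`,
#'   `other_genome`, and optionally `overlap_mode`, `n_null`, `alpha`,
#'   `min_cluster_size`, `known_panels`, `threshold_cap`, `min_match`,
#'   `scoring`, `coding_model` (supply to skip learning), `skip_syntenic`
#'   (logical), `seed`.
#' @return List with `lncrnas` (kept multi-exon transcripts),
#'   `single_exon` (quarantined), `report` (data.frame `id`, `fate`),
#'   `stage_counts`, `coding_model`, `clusters`, `panel_hits`.
#' @export
run_filter_pipeline <- function(candidates, config) {
  fates <- setNames(rep(NA_character_, length(candidates)),
                    vapply(candidates, `[[`, "", "id"))
  cfg <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  scoring <- cfg("scoring", scoring_default())
  seed <- cfg("seed", 1L)
  if (length(candidates) == 0L) {
    return(list(lncrnas = list(), single_exon = list(),
                report = data.frame(id = character(0), fate = character(0)),
                stage_counts = c(kept = 0L, removed_coding_overlap = 0L,
                                 collapsed_isoform = 0L,
                                 removed_single_exon = 0L,
                                 removed_duplication = 0L,
                                 removed_syntenic_coding = 0L),
                coding_model = NULL, clusters = list(), panel_hits = NULL))
  }

  # stage 1: coding overlap
  st1 <- remove_coding_overlap(candidates, config$coding,
                               mode = cfg("overlap_mode", "exon"))
  for (tx in st1$removed) fates[tx$id] <- "removed_coding_overlap"

  # stage 2a: canonical isoforms
  st2 <- select_canonical_isoforms(st1$kept)
  collapsed <- setdiff(st2$cluster_map$id, st2$cluster_map$canonical_id)
  for (id in collapsed) fates[id] <- "collapsed_isoform"

  # stage 2b: single-exon quarantine
  n_ex <- vapply(st2$canonical, function(tx) nrow(tx$exons), 0L)
  single_exon <- st2$canonical[n_ex == 1L]
  multi <- st2$canonical[n_ex > 1L]
  for (tx in single_exon) fates[tx$id] <- "removed_single_exon"

  # stage 2c: duplication clusters
  ann <- c(candidates, config$coding)
  dup <- find_duplication_clusters(
    multi, config$genome, ann, scoring = scoring,
    n_null = cfg("n_null", 200L), alpha = cfg("alpha", 0.05),
    min_cluster_size = cfg("min_cluster_size", 2L),
    known_panels = config$known_panels,
    rng_seed = derive_seed(seed, "duplication"))
  for (tx in dup$removed) fates[tx$id] <- "removed_duplication"

  # stage 3: syntenic coding threshold
  model <- config$coding_model
  kept3 <- dup$kept
  if (!isTRUE(config$skip_syntenic)) {
    if (is.null(model)) {
      model <- learn_coding_identity_threshold(
        st1$removed, config$other_coding, config$chains, config$genome,
        config$other_genome, scoring = scoring,
        cap = cfg("threshold_cap", 250L),
        min_match = cfg("min_match", 0.1),
        rng_seed = derive_seed(seed, "threshold"))
    }
    st3 <- filter_syntenic_coding(dup$kept, model, config$other_coding,
                                  config$chains, config$genome,
                                  config$other_genome, scoring = scoring,
                                  min_match = cfg("min_match", 0.1))
    for (tx in st3$removed) fates[tx$id] <- "removed_syntenic_coding"
    kept3 <- st3$kept
  }
  for (tx in kept3) fates[tx$id] <- "kept"
  stopifnot(!anyNA(fates))
  report <- data.frame(id = names(fates), fate = unname(fates),
                       stringsAsFactors = FALSE)
  counts <- table(factor(fates, levels = c(
    "kept", "removed_coding_overlap", "collapsed_isoform",
    "removed_single_exon", "removed_duplication",
    "removed_syntenic_coding")))
  list(lncrnas = kept3, single_exon = single_exon, report = report,
       stage_counts = counts, coding_model = model, clusters = dup$clusters,
       panel_hits = dup$panel_hits)
}
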