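# End-to-end orchestration: filter -> orf -> ortho -> phylo -> promoter, with
# deterministic outputs and a JSON run manifest.

#' Default pipeline configuration
#'
#' All stage parameters with their standard defaults: 200-draw nulls at
#' alpha 0.05, duplication clusters of 2+, a 250-transcript cap on the
#' learned-threshold positives, 33 nt minimum ORFs, 150 kb syntenic padding,
#' reduced gap-open lncRNA alignment scoring (open 25, extend 40), a 0.1
#' liftover match fraction, 2 bp junction tolerance, 500 bp promoters and a
#' 0.005 enrichment threshold.
#'
#' @param ... Overrides.
#' @return Named list of parameters.
#' @export
pipeline_defaults <- function(...) {
  cfg <- list(
    n_null = 200L, alpha = 0.05, min_cluster_size = 2L,
    threshold_cap = 250L, min_orf = 33L, pad = 150000,
    min_match = 0.1, ssc_tol = 2, flank = 500L,
    enrich_alpha = 0.005, orf_null_regions = 50000L,
    orf_region_length = 1000L, seed = 1L,
    scoring_lnc = scoring_lncrna(), scoring_default = scoring_default(),
    species = c(a = "spA", b = "spB"), skip = character(0))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full pipeline on a fixture or file-based inputs
#'
#' Stages run in order: `filter` (three-step lncRNA filter with single-exon
#' quarantine), `ortho` (reciprocal syntenic ortholog search, evolution
#' metrics, classes, conserved single-exon rescue, TTI mixture), `orf`
#' (aligned-ORF dN/dS flags on ortholog pairs), `phylo` (ortholog-group
#' linking and parsimony ancestors) and `promoter` (promoter annotation and
#' repeat enrichment against GC-matched background).  Identical inputs, the
#' same configuration and the same seed produce byte-identical outputs.
#'
#' @param fx A `fixture` (or an equivalently shaped list of in-memory
#'   inputs: genomes, chains, transcript lists and tracks).
#' @param out_dir Output directory; created if needed.
#' @param config From [pipeline_defaults()].
#' @return List with per-stage results and `out_dir`; output tables and a
#'   JSON manifest are written under `out_dir`.
#' @export
run_all <- function(fx, out_dir, config = pipeline_defaults()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  seed <- config$seed
  skip <- config$skip
  tsv <- function(df, f) {
    write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res <- list(out_dir = out_dir)

  # ---- filter ---------------------------------------------------------------
  filt <- run_filter_pipeline(fx$candidates_a, list(
    coding = fx$coding_a, other_coding = fx$coding_b, chains = fx$chains,
    genome = fx$genome_a, other_genome = fx$genome_b,
    n_null = config$n_null, alpha = config$alpha,
    min_cluster_size = config$min_cluster_size,
    known_panels = fx$known_panels, threshold_cap = config$threshold_cap,
    min_match = config$min_match, seed = derive_seed(seed, "filter")))
  res$filter <- filt
  fates <- setNames(filt$report$fate, filt$report$id)

  ann_b <- c(fx$coding_b, fx$lncrnas_b)
  ann_a <- c(fx$coding_a, fx$candidates_a)

  # ---- ortho ----------------------------------------------------------------
  pairs <- list(); syntologs <- list(); mixture <- NULL
  if (!"ortho" %in% skip) {
    queries_a <- c(filt$lncrnas, filt$single_exon)
    cands_ab <- list()
    for (tx in queries_a) {
      oc <- find_candidate_ortholog(
        tx, fx$genome_a, fx$genome_b, fx$lncrnas_b, fx$chains,
        annotations_b = ann_b, scoring = config$scoring_lnc,
        pad = config$pad, min_match = config$min_match,
        n_null = config$n_null, alpha = config$alpha,
        rng_seed = derive_seed(seed, "ortho-ab"))
      if (!is.null(oc)) cands_ab[[length(cands_ab) + 1L]] <- oc
    }
    inv <- invert_chain_set(fx$chains)
    targets_a <- queries_a
    cands_ba <- list()
    for (tx in fx$lncrnas_b) {
      oc <- find_candidate_ortholog(
        tx, fx$genome_b, fx$genome_a, targets_a, inv,
        annotations_b = ann_a, scoring = config$scoring_lnc,
        pad = config$pad, min_match = config$min_match,
        n_null = config$n_null, alpha = config$alpha,
        rng_seed = derive_seed(seed, "ortho-ba"))
      if (!is.null(oc)) cands_ba[[length(cands_ba) + 1L]] <- oc
    }
    pairs <- reciprocal_orthologs(cands_ab, cands_ba)
    syntologs <- Filter(function(x) isTRUE(x$syntolog), cands_ab)

    # conserved single-exon rescue: quarantined transcripts with a
    # reciprocally confirmed ortholog enter the lncRNA set
    single_ids <- vapply(filt$single_exon, `[[`, "", "id")
    rescued <- vapply(pairs, function(pp) pp$query$id, "")
    rescued <- intersect(single_ids, rescued)
    fates[rescued] <- "kept"
    res$rescued_single_exon <- rescued

    classes_a <- list(mirna = fx$mirna_a, snorna = fx$snorna_a,
                      coding = fx$coding_a)
    classes_b <- list(mirna = fx$mirna_b, snorna = fx$snorna_b,
                      coding = fx$coding_b)
    for (i in seq_along(pairs)) {
      pairs[[i]]$metrics <- evo_metrics(
        pairs[[i]]$query, pairs[[i]]$target, fx$genome_a, fx$genome_b,
        scoring = config$scoring_lnc, ssc_tol = config$ssc_tol)
      pairs[[i]]$class <- classify_pair(pairs[[i]]$query, pairs[[i]]$target,
                                        classes_a, classes_b)
    }
    pairs <- canonical_pair_per_gene(pairs)
    ttis <- vapply(pairs, function(pp) pp$metrics$tti, 0)
    if (length(ttis) >= 10L) {
      mixture <- tryCatch(
        fit_tti_mixture(ttis, rng_seed = derive_seed(seed, "mixture")),
        error = function(e) NULL)
    }
  }
  res$pairs <- pairs
  res$syntologs <- syntologs
  res$mixture <- mixture

  # ---- orf ------------------------------------------------------------------
  orf_table <- NULL
  if (!"orf" %in% skip && length(pairs) > 0L) {
    null_tab <- build_dnds_null(
      fx$genome_a, fx$genome_b, fx$chains, ann_a, ann_b,
      scoring = config$scoring_lnc, n_regions = config$orf_null_regions,
      region_length = config$orf_region_length, min_len = config$min_orf,
      rng_seed = derive_seed(seed, "orfnull"))
    hits <- list(); hit_tx <- character(0)
    for (pp in pairs) {
      qs <- tx_spliced_seq(fx$genome_a, pp$query)
      ts <- tx_spliced_seq(fx$genome_b, pp$target)
      for (al in local_align(qs, ts, config$scoring_lnc)) {
        hh <- enumerate_aligned_orfs(al, qs, ts, min_len = config$min_orf)
        hits <- c(hits, hh)
        hit_tx <- c(hit_tx, rep(pp$query$id, length(hh)))
      }
    }
    sig <- orf_significance(hits, null_tab, alpha = config$alpha)
    if (nrow(sig) > 0L) sig <- cbind(id = hit_tx, sig)
    orf_table <- sig
    res$orf_null <- null_tab
  }
  res$orfs <- orf_table

  # ---- phylo ----------------------------------------------------------------
  groups_df <- NULL
  if (!"phylo" %in% skip) {
    sp <- config$species
    pair_df <- if (length(pairs)) data.frame(
      species_a = sp[["a"]],
      id_a = vapply(pairs, function(pp) pp$query$id, ""),
      species_b = sp[["b"]],
      id_b = vapply(pairs, function(pp) pp$target$id, ""),
      stringsAsFactors = FALSE) else
        data.frame(species_a = character(0), id_a = character(0),
                   species_b = character(0), id_b = character(0))
    groups <- link_ortholog_groups(pair_df)
    kept_ids <- names(fates)[fates == "kept"]
    paired_a <- if (length(pairs)) vapply(pairs, function(pp) pp$query$id, "")
    else character(0)
    for (id in setdiff(kept_ids, paired_a)) {
      groups[[length(groups) + 1L]] <- paste0(sp[["a"]], ":", id)
    }
    groups_df <- assign_group_lca(groups, fx$tree)
  }
  res$groups <- groups_df

  # ---- promoter -------------------------------------------------------------
  promoters <- NULL; enrichment <- NULL
  if (!"promoter" %in% skip) {
    kept_ids <- names(fates)[fates == "kept"]
    kept_txs <- Filter(function(tx) tx$id %in% kept_ids, fx$candidates_a)
    promoters <- annotate_promoters(kept_txs, fx$genome_a, fx$cpg_a,
                                    fx$repeats_a, flank = config$flank)
    if (!is.null(fx$repeats_a) && nrow(promoters) > 0L) {
      bg <- sample_matched_background(
        promoters, fx$genome_a, ann_a,
        rng_seed = derive_seed(seed, "background"))
      enrichment <- repeat_enrichment(promoters, bg, fx$repeats_a,
                                      alpha = config$enrich_alpha)
    }
  }
  res$promoters <- promoters
  res$enrichment <- enrichment

  # ---- outputs and manifest -------------------------------------------------
  filt$report$fate <- unname(fates[filt$report$id])
  res$report <- filt$report
  kept_txs <- Filter(function(tx) fates[tx$id] == "kept", fx$candidates_a)
  removed_txs <- Filter(function(tx) fates[tx$id] != "kept", fx$candidates_a)
  write_bed12(kept_txs, p("lncrnas.bed"))
  write_bed12(removed_txs, p("removed.bed"),
              name_suffix = vapply(removed_txs, function(tx)
                unname(fates[tx$id]), ""))
  tsv(filt$report[order(filt$report$id), ], "filter_report.tsv")
  if (length(pairs)) {
    pair_tab <- do.call(rbind, lapply(pairs, function(pp) {
      m <- pp$metrics
      data.frame(query = pp$query$id, target = pp$target$id,
                 class = pp$class, tgi = m$tgi, tti = m$tti,
                 ssc = ifelse(is.na(m$ssc), NA, m$ssc), idr = m$idr,
                 conserved_junctions = m$conserved_junctions,
                 n_junctions = m$n_junctions,
                 score = pp$significance$score,
                 p = pp$significance$empirical_p,
                 stringsAsFactors = FALSE)
    }))
    tsv(pair_tab[order(pair_tab$query), ], "pairs.tsv")
    res$pair_table <- pair_tab
  } else {
    tsv(data.frame(query = character(0)), "pairs.tsv")
  }
  if (length(syntologs)) {
    tsv(data.frame(
      query = sort(vapply(syntologs, function(x) x$query$id, ""))),
      "syntologs.tsv")
  }
  if (!is.null(mixture)) {
    tsv(data.frame(component = 1:2, weight = mixture$weights,
                   mean = mixture$means, sd = mixture$sds,
                   loglik = mixture$loglik), "tti_mixture.tsv")
  }
  if (!is.null(orf_table)) tsv(orf_table, "orfs.tsv")
  if (!is.null(groups_df)) tsv(groups_df[order(groups_df$members), ],
                               "ortholog_groups.tsv")
  if (!is.null(promoters)) tsv(promoters[order(promoters$id), ],
                               "promoters.tsv")
  if (!is.null(enrichment)) tsv(enrichment, "repeat_enrichment.tsv")
  manifest <- list(
    parameters = config[c("n_null", "alpha", "min_cluster_size",
                          "threshold_cap", "min_orf", "pad", "min_match",
                          "ssc_tol", "flank", "enrich_alpha",
                          "orf_null_regions", "orf_region_length")],
    scoring_lnc = unclass(config$scoring_lnc),
    scoring_default = unclass(config$scoring_default),
    seed = seed, skipped = as.list(skip),
    n_candidates = length(fx$candidates_a),
    stage_counts = as.list(table(fates)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  res
}
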