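# Orthologous lncRNA discovery across two genomes and metrics of sequence and
# transcript evolution: transcript-genome identity (TGI), transcript-
# transcript identity (TTI), splice-site conservation (SSC) and the
# exon/intron indel rate (IDR); plus classing, shuffle controls and the
# two-Gaussian mixture fit of TTI.

#' Search the syntenic locus of a lncRNA for an ortholog
#'
#' The transcript's exonic footprint is lifted through the chains; if the
#' locus maps, the transcript locus is aligned (reduced gap-open scoring by
#' default) to the syntenic target region and kept only when it outscores 95%
#' of length-matched shuffled-intergenic draws.  A significant alignment with
#' no transcript annotated at the target is reported as a syntolog-style
#' record (the orthologous position is occupied, but nothing is annotated
#' there); when the transcript itself does not align, the flanking regions
#' are probed so that loci conserved only in synteny are still reported as
#' syntologs.
#'
#' @param tx Query `transcript`.
#' @param genome_a,genome_b Query and target genomes.
#' @param target_txs List of non-coding transcripts annotated on the target
#'   genome.
#' @param chain_set Chains mapping genome A to genome B.
#' @param annotations_b Transcripts excluded from null sampling on B.
#' @param scoring A [scoring_scheme()]; defaults to the lncRNA preset.
#' @param pad Syntenic window padding in bp.
#' @param min_match Minimum lifted fraction.
#' @param n_null,alpha Null size and significance level.
#' @param rng_seed Integer seed.
#' @param flank_probe Flank length (bp) probed for syntolog detection when
#'   the transcript itself does not align.
#' @param flank_min_score Minimum flank alignment score for a syntolog call.
#' @return An `ortho_candidate` (list with `query`, `target` transcript or
#'   `NULL`, `syntolog`, `significance`, `mapped`, `target_region`) or `NULL`
#'   when the locus is unmappable and its flanks do not align.
#' @export
find_candidate_ortholog <- function(tx, genome_a, genome_b, target_txs,
                                    chain_set, annotations_b = list(),
                                    scoring = scoring_lncrna(), pad = 150000,
                                    min_match = 0.1, n_null = 200L,
                                    alpha = 0.05, rng_seed = 1L,
                                    flank_probe = 20000L,
                                    flank_min_score = 500L) {
  lr <- lift_transcript(chain_set, tx, min_match = min_match)
  if (nrow(lr$mapped) == 0L) return(NULL)
  chroms <- unique(lr$mapped$chrom)
  if (length(chroms) > 1L) {
    bp <- vapply(chroms, function(cc) {
      sel <- lr$mapped$chrom == cc
      sum(lr$mapped$end[sel] - lr$mapped$start[sel])
    }, 0)
    chroms <- chroms[which.max(bp)]
  }
  sel <- lr$mapped$chrom == chroms
  m_lo <- min(lr$mapped$start[sel]); m_hi <- max(lr$mapped$end[sel])
  # best-overlapping annotated transcript at the target locus
  slack <- 500
  target <- NULL; best_ov <- 0
  for (tt in target_txs) {
    if (tt$chrom != chroms) next
    ov <- overlap_bp(tt$start, tt$end, m_lo - slack, m_hi + slack)
    if (ov > best_ov) { best_ov <- ov; target <- tt }
  }
  t_lo <- if (is.null(target)) m_lo else min(m_lo, target$start)
  t_hi <- if (is.null(target)) m_hi else max(m_hi, target$end)
  query_seq <- tx_span_seq(genome_a, tx)
  target_seq <- seq_slice(genome_b[[chroms]], t_lo, t_hi)
  es <- empirical_significance(query_seq, target_seq, genome_b, annotations_b,
                               scoring, n_null = n_null, alpha = alpha,
                               rng_seed = derive_seed(rng_seed, tx$id))
  target_region <- genomic_interval(chroms, t_lo, t_hi,
                                    lr$mapped$strand[sel][1])
  if (es$kept) {
    return(structure(list(query = tx, target = target,
                          syntolog = is.null(target),
                          significance = es$significance,
                          mapped = lr$mapped, target_region = target_region),
                     class = "ortho_candidate"))
  }
  # transcript does not align: probe the flanks for synteny-only conservation
  win <- syntenic_window(chain_set, tx, pad = pad, genome = genome_b,
                         min_match = min_match)
  if (!is.null(win)) {
    win_seq <- seq_slice(genome_b[[win$chrom]], win$start, win$end)
    up <- seq_slice(genome_a[[tx$chrom]], max(0, tx$start - flank_probe),
                    tx$start)
    dn <- seq_slice(genome_a[[tx$chrom]], tx$end,
                    min(nchar(genome_a[[tx$chrom]]), tx$end + flank_probe))
    fsc <- 0
    if (nchar(up) >= scoring$seed_length) {
      fsc <- max(fsc, top_scores(up, list(win_seq), scoring))
    }
    if (nchar(dn) >= scoring$seed_length) {
      fsc <- max(fsc, top_scores(dn, list(win_seq), scoring))
    }
    if (fsc >= flank_min_score) {
      return(structure(list(query = tx, target = NULL, syntolog = TRUE,
                            significance = es$significance,
                            mapped = lr$mapped, target_region = target_region),
                       class = "ortho_candidate"))
    }
  }
  NULL
}

#' Keep ortholog pairs confirmed in both reciprocal searches
#'
#' @param pairs_ab `ortho_candidate` list from the A-to-B search.
#' @param pairs_ba `ortho_candidate` list from the B-to-A search.
#' @return The A-to-B pairs (with non-`NULL` targets) whose reversed pair is
#'   present in the B-to-A result, each with `reciprocal = TRUE`.
#' @export
reciprocal_orthologs <- function(pairs_ab, pairs_ba) {
  key <- function(p) {
    if (is.null(p) || is.null(p$target)) return(NA_character_)
    paste(p$query$id, p$target$id, sep = "\r")
  }
  keys_ba <- vapply(pairs_ba, function(p) {
    if (is.null(p) || is.null(p$target)) return(NA_character_)
    paste(p$target$id, p$query$id, sep = "\r")
  }, "")
  out <- list()
  for (p in pairs_ab) {
    k <- key(p)
    if (!is.na(k) && k %in% keys_ba) {
      p$reciprocal <- TRUE
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

# Alignment walker shared by the metric computations: aligns the two
# transcript loci and returns per-base query->target offset maps plus the
# per-column bookkeeping needed for TGI/TTI/SSC/IDR.
locus_alignment_walk <- function(qtx, ttx, genome_a, genome_b,
                                 scoring = scoring_lncrna()) {
  qseq <- tx_span_seq(genome_a, qtx)
  tseq <- tx_span_seq(genome_b, ttx)
  qlen <- nchar(qseq); tlen <- nchar(tseq)
  qex <- rep(FALSE, qlen)
  for (r in seq_len(nrow(qtx$exons))) {
    qex[(qtx$exons[r, 1] - qtx$start + 1):(qtx$exons[r, 2] - qtx$start)] <- TRUE
  }
  qexon_idx <- rep(NA_integer_, qlen)
  ord <- if (qtx$strand == "-") rev(seq_len(nrow(qtx$exons))) else
    seq_len(nrow(qtx$exons))
  for (k in seq_along(ord)) {
    r <- ord[k]
    qexon_idx[(qtx$exons[r, 1] - qtx$start + 1):(qtx$exons[r, 2] - qtx$start)] <- k
  }
  tex <- rep(FALSE, tlen)
  for (r in seq_len(nrow(ttx$exons))) {
    tex[(ttx$exons[r, 1] - ttx$start + 1):(ttx$exons[r, 2] - ttx$start)] <- TRUE
  }
  alns <- local_align(qseq, tseq, scoring)
  qmap <- rep(NA_real_, qlen)
  match_q <- rep(FALSE, qlen)        # query base aligned and identical
  aligned_q <- rep(FALSE, qlen)      # query base in an aligned column
  tti_q <- rep(FALSE, qlen)          # identical and exonic in target too
  e_ex <- 0; e_in <- 0               # indel events by query compartment
  for (al in alns) {
    ops <- al$ops
    q <- al$q_start; t <- al$t_start
    for (r in seq_len(nrow(ops))) {
      op <- ops[r, "op"]; len <- ops[r, "len"]
      if (op == 0 || op == 1) {
        idx <- (q + 1):(q + len)
        qmap[idx] <- t:(t + len - 1)
        aligned_q[idx] <- TRUE
        if (op == 0) {
          match_q[idx] <- TRUE
          tti_q[idx] <- tex[(t + 1):(t + len)]
        }
        q <- q + len; t <- t + len
      } else if (op == 2) {           # extra query sequence
        at <- min(q + 1, qlen)
        if (qex[at]) e_ex <- e_ex + 1 else e_in <- e_in + 1
        q <- q + len
      } else {                        # extra target sequence
        at <- min(q + 1, qlen)
        if (qex[at]) e_ex <- e_ex + 1 else e_in <- e_in + 1
        t <- t + len
      }
    }
  }
  list(qtx = qtx, ttx = ttx, qlen = qlen, qex = qex, qexon_idx = qexon_idx,
       tex = tex, qmap = qmap, match_q = match_q, aligned_q = aligned_q,
       tti_q = tti_q, e_ex = e_ex, e_in = e_in, alns = alns)
}

# conserved-junction count given a walk and a tolerance; `qj` overrides the
# query's junction matrix (used by the splice-site reshuffling control)
count_conserved_junctions <- function(walk, ssc_tol = 2, per_site = FALSE,
                                      qj = NULL) {
  qtx <- walk$qtx; ttx <- walk$ttx
  if (is.null(qj)) qj <- tx_junctions(qtx)
  tj <- tx_junctions(ttx)
  if (nrow(qj) == 0L) {
    return(list(conserved = 0L, total = 0L))
  }
  map_boundary <- function(gpos) {
    # image of the boundary between gpos-1 and gpos (genomic, query)
    off <- gpos - qtx$start
    left <- if (off >= 1 && !is.na(walk$qmap[off])) walk$qmap[off] + 1 else NA
    right <- if (off < walk$qlen && !is.na(walk$qmap[off + 1]))
      walk$qmap[off + 1] else NA
    img <- if (!is.na(left)) left else right
    if (is.na(img)) NA else img + ttx$start
  }
  conserved <- 0L
  total <- if (per_site) 2L * nrow(qj) else nrow(qj)
  for (r in seq_len(nrow(qj))) {
    d_img <- map_boundary(qj[r, "donor"])
    a_img <- map_boundary(qj[r, "acceptor"])
    if (per_site) {
      if (!is.na(d_img) && any(abs(tj[, "donor"] - d_img) <= ssc_tol)) {
        conserved <- conserved + 1L
      }
      if (!is.na(a_img) && any(abs(tj[, "acceptor"] - a_img) <= ssc_tol)) {
        conserved <- conserved + 1L
      }
    } else {
      hit <- FALSE
      if (!is.na(d_img) && !is.na(a_img) && nrow(tj) > 0L) {
        hit <- any(abs(tj[, "donor"] - d_img) <= ssc_tol &
                     abs(tj[, "acceptor"] - a_img) <= ssc_tol)
      }
      if (hit) conserved <- conserved + 1L
    }
  }
  list(conserved = conserved, total = total)
}

#' Evolution metrics of an ortholog pair
#'
#' The transcript loci (unspliced spans) are aligned with the lncRNA scoring
#' preset and walked to compute:
#' \describe{
#'   \item{TGI}{identical aligned bp within the query's exons, over the
#'     query's exonic length: conservation of the transcript sequence
#'     regardless of transcription at the target.}
#'   \item{TTI}{identical aligned bp that are exonic in *both* transcripts,
#'     over the query's exonic length: conservation of the transcribed
#'     product.}
#'   \item{SSC}{fraction of the query's internal splice junctions whose
#'     aligned image coincides (within `ssc_tol` bp) with a junction of the
#'     target transcript; undefined for single-exon queries.}
#'   \item{IDR}{log2 ratio of indel-event rates (maximal gap runs per aligned
#'     bp, stabilised by a small pseudorate so identical loci score exactly 0)
#'     in the query's exons versus introns; undefined when either compartment
#'     has fewer than 100 aligned bp.}
#' }
#'
#' @param qtx,ttx Query and target transcripts (same forward orientation).
#' @param genome_a,genome_b Their genomes.
#' @param scoring A [scoring_scheme()].
#' @param ssc_tol Junction tolerance in bp.
#' @param idr_pseudorate Rate added to both indel rates (events/bp).
#' @param min_compartment_bp Minimum aligned bp per compartment for IDR.
#' @return An `evo_metrics` list: `tgi`, `tti`, `ssc`, `idr`,
#'   `conserved_junctions`, `n_junctions`, `exonic_aligned_bp`,
#'   `intronic_aligned_bp`, `exonic_indel_events`, `intronic_indel_events`,
#'   `per_exon` (data.frame of per-exon TGI/TTI in 5'-to-3' order).
#' @export
evo_metrics <- function(qtx, ttx, genome_a, genome_b,
                        scoring = scoring_lncrna(), ssc_tol = 2,
                        idr_pseudorate = 1e-3, min_compartment_bp = 100) {
  walk <- locus_alignment_walk(qtx, ttx, genome_a, genome_b, scoring)
  ex_len <- exonic_length(qtx)
  tgi <- sum(walk$match_q & walk$qex) / ex_len
  tti <- sum(walk$tti_q & walk$qex) / ex_len
  jc <- count_conserved_junctions(walk, ssc_tol)
  ssc <- if (jc$total > 0) jc$conserved / jc$total else NA_real_
  bp_ex <- sum(walk$aligned_q & walk$qex)
  bp_in <- sum(walk$aligned_q & !walk$qex)
  idr <- if (bp_ex >= min_compartment_bp && bp_in >= min_compartment_bp) {
    log2((walk$e_ex / bp_ex + idr_pseudorate) /
           (walk$e_in / bp_in + idr_pseudorate))
  } else NA_real_
  n_exons <- nrow(qtx$exons)
  per_exon <- data.frame(
    exon_index = seq_len(n_exons),
    tgi = vapply(seq_len(n_exons), function(k) {
      sel <- !is.na(walk$qexon_idx) & walk$qexon_idx == k
      sum(walk$match_q[sel]) / sum(sel)
    }, 0),
    tti = vapply(seq_len(n_exons), function(k) {
      sel <- !is.na(walk$qexon_idx) & walk$qexon_idx == k
      sum(walk$tti_q[sel]) / sum(sel)
    }, 0))
  structure(list(tgi = tgi, tti = tti, ssc = ssc, idr = idr,
                 conserved_junctions = jc$conserved,
                 n_junctions = jc$total,
                 exonic_aligned_bp = bp_ex, intronic_aligned_bp = bp_in,
                 exonic_indel_events = walk$e_ex,
                 intronic_indel_events = walk$e_in,
                 per_exon = per_exon),
            class = "evo_metrics")
}

#' Choose one canonical ortholog pair per gene pair
#'
#' Among isoform pairs of the same (query gene, target gene), keeps the pair
#' with the highest number of conserved splice sites, then the highest TTI,
#' then the lexicographically smallest query id.
#'
#' @param pairs List of `ortho_candidate`s, each carrying a `metrics` field
#'   (an `evo_metrics`).
#' @return Filtered list, one pair per gene pair.
#' @export
canonical_pair_per_gene <- function(pairs) {
  if (length(pairs) == 0L) return(pairs)
  keys <- vapply(pairs, function(p) {
    paste(p$query$gene_id, p$target$gene_id, sep = "\r")
  }, "")
  out <- list()
  for (k in unique(keys)) {
    grp <- pairs[keys == k]
    scores <- vapply(grp, function(p) p$metrics$conserved_junctions, 0L)
    ttis <- vapply(grp, function(p) p$metrics$tti, 0)
    ids <- vapply(grp, function(p) p$query$id, "")
    o <- order(-scores, -ttis, ids)
    out[[length(out) + 1L]] <- grp[[o[1L]]]
  }
  out
}

#' Median per-exon identity profile across ortholog pairs
#'
#' @param metrics_list List of `evo_metrics`.
#' @param first_n Number of leading (5'-most) exons to report.
#' @return data.frame `exon_index`, `median_tgi`, `median_tti`, `n_pairs`.
#' @export
exon_identity_profile <- function(metrics_list, first_n = 3L) {
  rows <- lapply(seq_len(first_n), function(k) {
    tg <- unlist(lapply(metrics_list, function(m) {
      if (k <= nrow(m$per_exon)) m$per_exon$tgi[k] else NULL
    }))
    tt <- unlist(lapply(metrics_list, function(m) {
      if (k <= nrow(m$per_exon)) m$per_exon$tti[k] else NULL
    }))
    if (length(tg) == 0L) return(NULL)
    data.frame(exon_index = k, median_tgi = median(tg),
               median_tti = median(tt), n_pairs = length(tg))
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Classify a lncRNA by its genomic context
#'
#' Host classes require the small RNA to lie fully inside the transcript
#' span; a divergent lncRNA has a coding transcription start site on the
#' opposite strand within `window` bp of its own TSS.
#'
#' @param tx A `transcript`.
#' @param mirna_bed,snorna_bed Small-RNA tracks ([read_bed6()] data.frames).
#' @param coding_txs List of coding transcripts.
#' @param window Divergent-promoter distance in bp.
#' @return List with `class` (one of `"MIRNA_HOST"`, `"SNORNA_HOST"`,
#'   `"DIVERGENT"`, `"INTERGENIC"`) and `exonic_host` (small RNA inside an
#'   exon).
#' @export
classify_lncrna <- function(tx, mirna_bed = NULL, snorna_bed = NULL,
                            coding_txs = list(), window = 500L) {
  contains <- function(bed) {
    if (is.null(bed) || nrow(bed) == 0L) return(integer(0))
    which(bed$chrom == tx$chrom & bed$start >= tx$start & bed$end <= tx$end)
  }
  in_exon <- function(bed, idx) {
    any(vapply(idx, function(i) {
      any(tx$exons[, 1] <= bed$start[i] & tx$exons[, 2] >= bed$end[i])
    }, TRUE))
  }
  mi <- contains(mirna_bed)
  if (length(mi)) {
    return(list(class = "MIRNA_HOST", exonic_host = in_exon(mirna_bed, mi)))
  }
  sn <- contains(snorna_bed)
  if (length(sn)) {
    return(list(class = "SNORNA_HOST", exonic_host = in_exon(snorna_bed, sn)))
  }
  tss <- if (tx$strand == "-") tx$end else tx$start
  for (ct in coding_txs) {
    if (ct$chrom != tx$chrom) next
    if (ct$strand == tx$strand || ct$strand == "." || tx$strand == ".") next
    ctss <- if (ct$strand == "-") ct$end else ct$start
    if (abs(ctss - tss) <= window) {
      return(list(class = "DIVERGENT", exonic_host = FALSE))
    }
  }
  list(class = "INTERGENIC", exonic_host = FALSE)
}

#' Class of an ortholog pair
#'
#' A pair is a miRNA host / snoRNA host / divergent lncRNA only when both
#' species' transcripts are annotated as such; everything else is intergenic.
#'
#' @param qtx,ttx The two transcripts.
#' @param ann_a,ann_b Lists with `mirna`, `snorna` (BED data.frames) and
#'   `coding` (transcript lists) for each species.
#' @param window Divergent-promoter distance.
#' @return Class string.
#' @export
classify_pair <- function(qtx, ttx, ann_a, ann_b, window = 500L) {
  ca <- classify_lncrna(qtx, ann_a$mirna, ann_a$snorna, ann_a$coding, window)
  cb <- classify_lncrna(ttx, ann_b$mirna, ann_b$snorna, ann_b$coding, window)
  if (ca$class == cb$class && ca$class != "INTERGENIC") return(ca$class)
  "INTERGENIC"
}

#' Relocate transcripts to random intergenic positions
#'
#' The negative control for the ortholog search: each transcript keeps its
#' exon/intron structure but is moved to a uniform intergenic start on a
#' random strand (so shuffled "orthologs" arise only by chance synteny).
#'
#' @param txs Transcripts to shuffle.
#' @param genome Genome to place them in.
#' @param annotations Transcripts whose spans must not be overlapped.
#' @param rng_seed Integer seed.
#' @param max_tries Attempts per transcript.
#' @return List of relocated transcripts (ids suffixed `"_shuf"`).
#' @export
shuffled_transcript_control <- function(txs, genome, annotations,
                                        rng_seed = 1L, max_tries = 1000L) {
  out <- vector("list", length(txs))
  for (i in seq_along(txs)) {
    tx <- txs[[i]]
    span <- tx$end - tx$start
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      seed_it <- derive_seed(rng_seed, paste("shuf", i, try))
      draw <- tryCatch(
        sample_intergenic(genome, annotations, span, n = 1L,
                          rng_seed = seed_it),
        error = function(e) NULL)
      if (is.null(draw)) break
      iv <- attr(draw, "intervals")
      strand <- with_seed(derive_seed(seed_it, "strand"),
                          sample(c("+", "-"), 1L))
      offs <- tx$exons - tx$start
      out[[i]] <- transcript(id = paste0(tx$id, "_shuf"), chrom = iv$chrom,
                             start = iv$start, end = iv$start + span,
                             strand = strand, exons = offs + iv$start,
                             gene_id = paste0(tx$gene_id, "_shuf"))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place shuffled copy of ", tx$id, " after ", max_tries,
           " tries")
    }
  }
  out
}

#' Expected conserved-junction count under splice-site reshuffling
#'
#' Re-places the query transcript's junctions uniformly on candidate
#' donor/acceptor motif positions (GT ... AG) within its locus and recounts
#' conserved junctions against the target using the true locus alignment;
#' the mean over shuffles estimates how many "conserved" junctions arise by
#' chance placement alone.
#'
#' @param qtx,ttx The ortholog pair.
#' @param genome_a,genome_b Their genomes.
#' @param scoring A [scoring_scheme()].
#' @param n_shuffles Number of reshuffles.
#' @param rng_seed Integer seed.
#' @param ssc_tol Junction tolerance in bp.
#' @param min_intron Minimum shuffled intron length.
#' @param donors,acceptors Optional explicit candidate positions (locus
#'   offsets of intron start / intron end), overriding the motif scan.
#' @return List with `expected` (mean conserved count), `observed`, and
#'   `n_candidates` (donor/acceptor motif counts).
#' @export
splice_shuffle_expectation <- function(qtx, ttx, genome_a, genome_b,
                                       scoring = scoring_lncrna(),
                                       n_shuffles = 200L, rng_seed = 1L,
                                       ssc_tol = 2, min_intron = 50L,
                                       donors = NULL, acceptors = NULL) {
  qj <- tx_junctions(qtx)
  if (nrow(qj) == 0L) stop("query transcript has no internal junction")
  walk <- locus_alignment_walk(qtx, ttx, genome_a, genome_b, scoring)
  qseq <- tx_span_seq(genome_a, qtx)
  chars <- strsplit(qseq, "")[[1]]
  n <- length(chars)
  if (is.null(donors)) {
    donors <- which(chars[-n] == "G" & chars[-1] == "T")  # intron start offset
    donors <- donors - 1L                                  # 0-based
  }
  if (is.null(acceptors)) {
    acceptors <- which(chars[-n] == "A" & chars[-1] == "G") + 1L  # intron end
  }
  if (length(donors) == 0L || length(acceptors) == 0L) {
    stop("locus lacks GT/AG motifs to reshuffle splice sites onto")
  }
  count_at <- function(jmat) {
    jm <- cbind(donor = jmat[, 1] + qtx$start,
                acceptor = jmat[, 2] + qtx$start)
    count_conserved_junctions(walk, ssc_tol, qj = jm)$conserved
  }
  observed <- count_conserved_junctions(walk, ssc_tol)$conserved
  n_j <- nrow(qj)
  counts <- with_seed(rng_seed, {
    vapply(seq_len(n_shuffles), function(s) {
      picks <- matrix(NA_real_, nrow = n_j, ncol = 2)
      for (r in seq_len(n_j)) {
        ok <- FALSE
        for (try in 1:50) {
          d <- donors[sample.int(length(donors), 1L)]
          a_ok <- acceptors[acceptors >= d + min_intron]
          if (length(a_ok) == 0L) next
          a <- a_ok[sample.int(length(a_ok), 1L)]
          picks[r, ] <- c(d, a)
          ok <- TRUE
          break
        }
        if (!ok) stop("could not place a shuffled junction (motifs too sparse)")
      }
      picks <- picks[order(picks[, 1]), , drop = FALSE]
      count_at(picks)
    }, 0)
  })
  list(expected = mean(counts), observed = observed,
       n_candidates = c(donors = length(donors),
                        acceptors = length(acceptors)))
}

#' Two-component Gaussian mixture of transcript-transcript identity
#'
#' Expectation-maximisation for a univariate two-Gaussian mixture, run from
#' `n_starts` random initialisations, keeping the best log-likelihood.
#' The log-likelihood is non-decreasing at every EM iteration; starts that
#' collapse onto a degenerate (near-zero variance) component are discarded
#' and an error is raised only when every start degenerates.  Observations
#' are assigned to the component with posterior probability above 0.5.
#'
#' @param ttis Numeric vector of observations (at least 10).
#' @param k Number of components (fixed at 2).
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations per start.
#' @param n_starts Random restarts.
#' @param rng_seed Integer seed.
#' @return A `mixture_fit`: `weights`, `means`, `sds` (components sorted by
#'   mean), `loglik`, `loglik_trace`, `iterations`, `assignment` (component
#'   index per observation), `posterior` (matrix).
#' @export
fit_tti_mixture <- function(ttis, k = 2L, tol = 1e-6, max_iter = 500L,
                            n_starts = 10L, rng_seed = 1L) {
  x <- as.numeric(ttis)
  n <- length(x)
  stopifnot(k == 2L)
  if (n < 10L) stop("need at least 10 observations for the mixture fit")
  run_em <- function(mu, sig, w) {
    trace <- numeric(0)
    prev <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * dnorm(x, mu[1], sig[1])
      d2 <- w[2] * dnorm(x, mu[2], sig[2])
      tot <- d1 + d2
      if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      g1 <- d1 / tot
      n1 <- sum(g1); n2 <- n - n1
      if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
      mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
      v1 <- sum(g1 * (x - mu[1])^2) / n1
      v2 <- sum((1 - g1) * (x - mu[2])^2) / n2
      if (v1 < 1e-8 || v2 < 1e-8) return(NULL)   # degenerate variance
      sig <- sqrt(c(v1, v2))
      w <- c(n1, n2) / n
      if (is.finite(prev) && ll - prev < tol && it > 1L) {
        return(list(mu = mu, sig = sig, w = w, ll = ll, trace = trace,
                    iter = it))
      }
      prev <- ll
    }
    list(mu = mu, sig = sig, w = w, ll = prev, trace = trace, iter = max_iter)
  }
  best <- NULL
  with_seed(rng_seed, {
    for (s in seq_len(n_starts)) {
      mu0 <- sort(sample(x, 2L))
      if (diff(mu0) < 1e-6) mu0 <- mu0 + c(-0.05, 0.05)
      sig0 <- rep(max(sd(x), 1e-3), 2L)
      fit <- run_em(mu0, sig0, c(0.5, 0.5))
      if (!is.null(fit) && (is.null(best) || fit$ll > best$ll)) best <- fit
    }
  })
  if (is.null(best)) {
    stop("all EM starts degenerated (observations may be constant)")
  }
  o <- order(best$mu)
  mu <- best$mu[o]; sig <- best$sig[o]; w <- best$w[o]
  d1 <- w[1] * dnorm(x, mu[1], sig[1])
  d2 <- w[2] * dnorm(x, mu[2], sig[2])
  post <- cbind(d1, d2) / (d1 + d2)
  assignment <- ifelse(post[, 2] > 0.5, 2L, 1L)
  structure(list(weights = w, means = mu, sds = sig, loglik = best$ll,
                 loglik_trace = best$trace, iterations = best$iter,
                 assignment = assignment, posterior = post),
            class = "mixture_fit")
}
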