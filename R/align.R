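# Seed-and-extend local pairwise alignment with affine gaps, and empirical
# significance of alignment scores against shuffled-intergenic nulls.

#' Alignment scoring scheme
#'
#' A gap of length L costs `gap_open + L * gap_extend`.  The lncRNA preset
#' ([scoring_lncrna()]) uses a drastically reduced gap-open penalty because
#' small insertions are well tolerated by lncRNA transcripts; the default
#' preset ([scoring_default()]) is gap-strict and is used for duplication
#' detection and coding-gene alignment, where homology is recent.
#'
#' @param match Positive match reward.
#' @param mismatch Positive mismatch penalty.
#' @param gap_open Positive gap-open penalty.
#' @param gap_extend Positive per-base gap-extension penalty.
#' @param seed_length Exact-match seed length k (>= 8).
#' @return A `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5L, mismatch = 4L, gap_open = 400L,
                           gap_extend = 30L, seed_length = 12L) {
  stopifnot(match > 0, mismatch > 0, gap_open >= 0, gap_extend > 0,
            seed_length >= 8, seed_length <= 15)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 seed_length = as.integer(seed_length)),
            class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
scoring_default <- function() scoring_scheme()

#' @rdname scoring_scheme
#' @export
scoring_lncrna <- function() scoring_scheme(gap_open = 25L, gap_extend = 40L)

#' Local pairwise alignment
#'
#' Exact-match k-mer seeds are chained by diagonal; each chained group is
#' refined by banded affine-gap dynamic programming.  Inputs small enough
#' (both sequences at most `full_dp_limit` bp) are refined over the full DP
#' rectangle, so the top score there equals the unrestricted affine-gap
#' Smith-Waterman optimum.  Sequences sharing no exact k-mer produce an empty
#' result, as do sequences shorter than k.
#'
#' @param seq_a Query DNA string.
#' @param seq_b Target DNA string.
#' @param scoring A [scoring_scheme()].
#' @param band Half-width (columns) of the DP corridor around each chained
#'   seed group.
#' @param full_dp_limit Below this length (both sequences), alignment is done
#'   by full exact DP.
#' @param max_occ Seeds occurring more than this many times in the target are
#'   skipped (repeat guard).
#' @return List of `local_alignment` objects, sorted by decreasing score,
#'   mutually non-overlapping in both sequences.  Each holds 0-based half-open
#'   `q_start`/`q_end`/`t_start`/`t_end`, `score`, `matches`, `mismatches`,
#'   `gapcols`, and a run-length `ops` matrix over codes 0=match, 1=mismatch,
#'   2=insertion-in-query, 3=deletion-from-query.
#' @export
local_align <- function(seq_a, seq_b, scoring = scoring_default(),
                        band = 64L, full_dp_limit = 1000L, max_occ = 64L) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  raw <- .cpp_local_align(seq_a, seq_b, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend,
                          scoring$seed_length, as.integer(band),
                          as.integer(full_dp_limit), as.integer(max_occ),
                          200L, 4e7)
  lapply(raw, function(al) structure(al, class = "local_alignment"))
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("<local_alignment q[%d,%d) t[%d,%d) score=%d identity=%.3f>\n",
              x$q_start, x$q_end, x$t_start, x$t_end, x$score,
              alignment_identity(x)))
  invisible(x)
}

#' Identity of a local alignment
#'
#' Matches over all aligned columns, counting gap columns; `N` never matches.
#'
#' @param aln A `local_alignment`.
#' @return Fraction in `[0, 1]` (0 for an alignment with no columns).
#' @export
alignment_identity <- function(aln) {
  cols <- aln$matches + aln$mismatches + aln$gapcols
  if (cols == 0) return(0)
  aln$matches / cols
}

#' Best (top-scoring) local alignment, or NULL
#' @param seq_a,seq_b DNA strings.
#' @param scoring A [scoring_scheme()].
#' @param ... Passed to [local_align()].
#' @return A `local_alignment` or `NULL`.
#' @export
best_alignment <- function(seq_a, seq_b, scoring = scoring_default(), ...) {
  alns <- local_align(seq_a, seq_b, scoring, ...)
  if (length(alns) == 0L) NULL else alns[[1L]]
}

# Batched top scores of one query against many targets (null machinery).
top_scores <- function(query, targets, scoring, band = 64L,
                       full_dp_limit = 1000L, max_occ = 64L) {
  if (length(targets) == 0L) return(numeric(0))
  .cpp_top_scores(query, as.list(targets), scoring$match, scoring$mismatch,
                  scoring$gap_open, scoring$gap_extend, scoring$seed_length,
                  as.integer(band), as.integer(full_dp_limit),
                  as.integer(max_occ), 200L, 4e7)
}

# ---- intergenic sampling ----------------------------------------------------

# Complement of annotated spans per contig: data.frame chrom/start/end.
intergenic_space <- function(genome, annotations) {
  spans <- list()
  for (tx in annotations) {
    spans[[length(spans) + 1L]] <- c(tx$chrom, tx$start, tx$end)
  }
  out <- NULL
  for (chrom in names(genome)) {
    len <- nchar(genome[[chrom]])
    if (length(spans)) {
      m <- do.call(rbind, spans)
      sel <- m[, 1] == chrom
      if (any(sel)) {
        runs <- merge_runs(as.numeric(m[sel, 2]), as.numeric(m[sel, 3]))
        gaps_s <- c(0, runs[, "end"])
        gaps_e <- c(runs[, "start"], len)
      } else {
        gaps_s <- 0; gaps_e <- len
      }
    } else {
      gaps_s <- 0; gaps_e <- len
    }
    keep <- gaps_e > gaps_s
    if (any(keep)) {
      out <- rbind(out, data.frame(chrom = chrom, start = gaps_s[keep],
                                   end = gaps_e[keep]))
    }
  }
  if (is.null(out)) data.frame(chrom = character(0), start = numeric(0),
                               end = numeric(0)) else out
}

#' Sample random intergenic sequence
#'
#' Draws windows uniformly among all positions not overlapping any annotated
#' transcript span, reproducibly under a seed.
#'
#' @param genome Named character vector of contig sequences.
#' @param annotations List of transcripts to exclude (their genomic spans).
#' @param length Window length in bp.
#' @param n Number of draws.
#' @param rng_seed Integer seed.
#' @return Character vector of `n` sequences with an `"intervals"` attribute
#'   (data.frame `chrom`, `start`, `end`).
#' @export
sample_intergenic <- function(genome, annotations, length, n = 1L,
                              rng_seed = 1L) {
  space <- intergenic_space(genome, annotations)
  space$navail <- pmax(0, (space$end - space$start) - length + 1)
  total <- sum(space$navail)
  if (total <= 0) {
    stop("no intergenic window of length ", length, " available")
  }
  with_seed(rng_seed, {
    pos <- floor(runif(n) * total)
    cum <- c(0, cumsum(space$navail))
    idx <- pmin(findInterval(pos, cum), nrow(space))
    offs <- pos - cum[idx]
    starts <- space$start[idx] + offs
    ivs <- data.frame(chrom = space$chrom[idx], start = starts,
                      end = starts + length)
    seqs <- vapply(seq_len(n), function(i) {
      seq_slice(genome[[ivs$chrom[i]]], ivs$start[i], ivs$end[i])
    }, "")
    attr(seqs, "intervals") <- ivs
    seqs
  })
}

#' Empirical alignment significance against shuffled-intergenic nulls
#'
#' Aligns the query to the target, then re-aligns the query against `n_null`
#' length-matched random intergenic draws.  The empirical P-value uses the
#' add-one estimator `(1 + #\{null >= score\}) / (n_null + 1)` so it is never
#' zero; with the defaults (`n_null = 200`, `alpha = 0.05`) an alignment is
#' kept exactly when it outscores more than 95% of the null draws.
#'
#' @param query Query DNA string.
#' @param target Target DNA string.
#' @param genome_for_null Genome the null windows are drawn from.
#' @param annotations Transcripts excluded from null sampling.
#' @param scoring A [scoring_scheme()].
#' @param n_null Number of null draws.
#' @param alpha Significance level.
#' @param rng_seed Integer seed.
#' @param null_length Length of each null draw; defaults to the target length
#'   (clipped to the largest available intergenic window).
#' @return List with `alignment` (best `local_alignment` or `NULL`), `kept`
#'   (logical), and `significance` (`score`, `null_scores`, `empirical_p`,
#'   `n_null`).
#' @export
empirical_significance <- function(query, target, genome_for_null, annotations,
                                   scoring = scoring_default(), n_null = 200L,
                                   alpha = 0.05, rng_seed = 1L,
                                   null_length = NULL) {
  aln <- best_alignment(query, target, scoring)
  score <- if (is.null(aln)) 0 else aln$score
  if (is.null(null_length)) null_length <- nchar(target)
  space <- intergenic_space(genome_for_null, annotations)
  max_win <- max(space$end - space$start, 0)
  null_length <- min(null_length, max_win)
  if (null_length < scoring$seed_length) {
    stop("no intergenic window of usable length for the null")
  }
  draws <- sample_intergenic(genome_for_null, annotations, null_length,
                             n = n_null, rng_seed = rng_seed)
  null_scores <- top_scores(query, draws, scoring)
  p <- (1 + sum(null_scores >= score)) / (n_null + 1)
  kept <- !is.null(aln) && score > 0 && p <= alpha
  list(alignment = aln,
       kept = kept,
       significance = list(score = score, null_scores = null_scores,
                           empirical_p = p, n_null = n_null))
}
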