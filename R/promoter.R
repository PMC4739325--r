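# Promoter extraction and conservation-correlate statistics: CpG islands,
# repeat content, and repeat-family enrichment against GC-matched intergenic
# background.

#' Promoter interval of a transcript
#'
#' The 500 bp (by default) immediately upstream of the transcription start
#' site, strand-aware and clipped to the contig.
#'
#' @param tx A `transcript`.
#' @param flank Upstream window size in bp.
#' @param contig_length Optional contig length for clipping on the plus side.
#' @return A [genomic_interval()], possibly shorter than `flank` after
#'   clipping; `NULL` if clipping leaves nothing.
#' @export
promoter_interval <- function(tx, flank = 500L, contig_length = NULL) {
  if (tx$strand == "-") {
    lo <- tx$end
    hi <- tx$end + flank
    if (!is.null(contig_length)) hi <- min(hi, contig_length)
  } else {
    lo <- max(0, tx$start - flank)
    hi <- tx$start
  }
  if (lo >= hi) return(NULL)
  genomic_interval(tx$chrom, lo, hi, tx$strand)
}

# union overlap bp of iv with rows of a BED-like data.frame
bed_overlap_bp <- function(iv, bed) {
  sel <- bed$chrom == iv$chrom & bed$end > iv$start & bed$start < iv$end
  if (!any(sel)) return(0)
  runs <- merge_runs(pmax(bed$start[sel], iv$start), pmin(bed$end[sel], iv$end))
  sum(runs[, "end"] - runs[, "start"])
}

#' Annotate promoters with GC, CpG-island and repeat content
#'
#' @param txs List of transcripts whose promoters to annotate.
#' @param genome Named character vector of contig sequences.
#' @param cpg_bed CpG-island track (data.frame from [read_bed6()]).
#' @param repeat_bed Repeat track (family name in the `name` column).
#' @param flank Promoter size in bp.
#' @return data.frame: `id`, `chrom`, `start`, `end`, `length`,
#'   `gc_fraction`, `has_cpg`, `repeat_bp`, `repeat_fraction`,
#'   `repeat_families` (comma-separated).
#' @export
annotate_promoters <- function(txs, genome, cpg_bed = NULL, repeat_bed = NULL,
                               flank = 500L) {
  rows <- lapply(txs, function(tx) {
    iv <- promoter_interval(tx, flank,
                            contig_length = nchar(genome[[tx$chrom]]))
    if (is.null(iv)) return(NULL)
    s <- seq_slice(genome[[iv$chrom]], iv$start, iv$end)
    has_cpg <- !is.null(cpg_bed) && bed_overlap_bp(iv, cpg_bed) > 0
    rep_bp <- if (is.null(repeat_bed)) 0 else bed_overlap_bp(iv, repeat_bed)
    fams <- ""
    if (!is.null(repeat_bed)) {
      sel <- repeat_bed$chrom == iv$chrom & repeat_bed$end > iv$start &
        repeat_bed$start < iv$end
      fams <- paste(sort(unique(repeat_bed$name[sel])), collapse = ",")
    }
    data.frame(id = tx$id, chrom = iv$chrom, start = iv$start, end = iv$end,
               length = iv_width(iv), gc_fraction = gc_fraction(s),
               has_cpg = has_cpg, repeat_bp = rep_bp,
               repeat_fraction = rep_bp / iv_width(iv),
               repeat_families = fams, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), length = numeric(0),
                      gc_fraction = numeric(0), has_cpg = logical(0),
                      repeat_bp = numeric(0), repeat_fraction = numeric(0),
                      repeat_families = character(0)))
  }
  do.call(rbind, rows)
}

#' Sample size- and GC-matched intergenic background intervals
#'
#' For each promoter, draws an intergenic interval of equal length whose GC
#' fraction is within `gc_tol` of the promoter's.
#'
#' @param promoters data.frame from [annotate_promoters()].
#' @param genome Named character vector of contig sequences.
#' @param annotations Transcripts whose spans are excluded.
#' @param gc_tol Maximum absolute GC difference.
#' @param n_per Background intervals per promoter.
#' @param max_tries Sampling attempts per interval before failing.
#' @param rng_seed Integer seed.
#' @return data.frame with `promoter_id`, `chrom`, `start`, `end`,
#'   `gc_fraction`.
#' @export
sample_matched_background <- function(promoters, genome, annotations,
                                      gc_tol = 0.02, n_per = 1L,
                                      max_tries = 1000L, rng_seed = 1L) {
  out <- list()
  for (i in seq_len(nrow(promoters))) {
    len <- promoters$length[i]
    target_gc <- promoters$gc_fraction[i]
    for (j in seq_len(n_per)) {
      found <- FALSE
      for (try in seq_len(max_tries)) {
        seed_ij <- derive_seed(rng_seed, paste("bg", i, j, try))
        draw <- sample_intergenic(genome, annotations, len, n = 1L,
                                  rng_seed = seed_ij)
        gc <- gc_fraction(draw[1])
        if (abs(gc - target_gc) <= gc_tol) {
          iv <- attr(draw, "intervals")
          out[[length(out) + 1L]] <- data.frame(
            promoter_id = promoters$id[i], chrom = iv$chrom, start = iv$start,
            end = iv$end, gc_fraction = gc, stringsAsFactors = FALSE)
          found <- TRUE
          break
        }
      }
      if (!found) {
        stop("no GC-matched intergenic interval found for promoter ",
             promoters$id[i], " (GC ", round(target_gc, 3), ") within ",
             max_tries, " tries")
      }
    }
  }
  do.call(rbind, out)
}

#' Repeat-family enrichment of promoters versus matched background
#'
#' Per repeat family, a two-sided Fisher's exact test on the 2x2 table of
#' interval sets (promoters vs background) containing at least one element of
#' the family, corrected across the families tested (Bonferroni by default,
#' Benjamini-Hochberg available).
#'
#' @param promoters data.frame of intervals (`chrom`, `start`, `end`).
#' @param background data.frame of intervals (`chrom`, `start`, `end`).
#' @param repeat_bed Repeat track with family names in `name`.
#' @param alpha Significance threshold on the corrected P-value.
#' @param correction `"bonferroni"` or `"BH"`.
#' @return data.frame with `family`, `promoters_with`, `promoters_without`,
#'   `background_with`, `background_without`, `odds_ratio`, `p`,
#'   `p_corrected`, `significant`.
#' @export
repeat_enrichment <- function(promoters, background, repeat_bed,
                              alpha = 0.005,
                              correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  families <- sort(unique(repeat_bed$name))
  has_family <- function(set, fam) {
    fam_bed <- repeat_bed[repeat_bed$name == fam, , drop = FALSE]
    vapply(seq_len(nrow(set)), function(i) {
      iv <- genomic_interval(set$chrom[i], set$start[i], set$end[i])
      bed_overlap_bp(iv, fam_bed) > 0
    }, TRUE)
  }
  rows <- list()
  for (fam in families) {
    pw <- sum(has_family(promoters, fam))
    bw <- sum(has_family(background, fam))
    if (pw == 0 && bw == 0) next   # family absent from both sets
    tab <- matrix(c(pw, nrow(promoters) - pw, bw, nrow(background) - bw),
                  nrow = 2)
    ft <- fisher.test(tab, alternative = "two.sided")
    rows[[length(rows) + 1L]] <- data.frame(
      family = fam, promoters_with = pw,
      promoters_without = nrow(promoters) - pw,
      background_with = bw, background_without = nrow(background) - bw,
      odds_ratio = unname(ft$estimate), p = ft$p.value,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(family = character(0), promoters_with = integer(0),
                      promoters_without = integer(0),
                      background_with = integer(0),
                      background_without = integer(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      p_corrected = numeric(0), significant = logical(0)))
  }
  df <- do.call(rbind, rows)
  df$p_corrected <- p.adjust(df$p, method = correction)
  df$significant <- df$p_corrected < alpha
  df[order(df$p_corrected, df$family), ]
}

#' Call CpG islands de novo (Gardiner-Garden criteria)
#'
#' Sliding-window helper for annotating synthetic genomes that lack a
#' curated CpG track: reports maximal regions of length at least `min_len`
#' with GC at least `min_gc` and observed/expected CpG at least `min_oe`.
#'
#' @param genome Named character vector of contig sequences.
#' @param min_len Minimum island length.
#' @param min_gc Minimum GC fraction.
#' @param min_oe Minimum observed/expected CpG ratio.
#' @param window Scan window size.
#' @return data.frame `chrom`, `start`, `end` of candidate islands.
#' @export
call_cpg_islands <- function(genome, min_len = 200L, min_gc = 0.5,
                             min_oe = 0.6, window = 200L) {
  out <- list()
  for (chrom in names(genome)) {
    s <- strsplit(genome[[chrom]], "")[[1]]
    n <- length(s)
    if (n < window) next
    isC <- s == "C"; isG <- s == "G"
    cpg <- c(isC[-n] & isG[-1], FALSE)
    cum_c <- cumsum(isC); cum_g <- cumsum(isG); cum_cpg <- cumsum(cpg)
    starts <- seq(1L, n - window + 1L, by = window %/% 2L)
    win_ok <- vapply(starts, function(st) {
      en <- st + window - 1L
      nc <- cum_c[en] - if (st > 1) cum_c[st - 1] else 0
      ng <- cum_g[en] - if (st > 1) cum_g[st - 1] else 0
      ncpg <- cum_cpg[en] - if (st > 1) cum_cpg[st - 1] else 0
      gc <- (nc + ng) / window
      exp_cpg <- nc * ng / window
      gc >= min_gc && exp_cpg > 0 && (ncpg / exp_cpg) >= min_oe
    }, TRUE)
    if (!any(win_ok)) next
    runs <- rle(win_ok)
    ends_idx <- cumsum(runs$lengths)
    starts_idx <- ends_idx - runs$lengths + 1
    for (r in which(runs$values)) {
      lo <- starts[starts_idx[r]] - 1L
      hi <- min(starts[ends_idx[r]] + window - 1L, n)
      if (hi - lo >= min_len) {
        out[[length(out) + 1L]] <- data.frame(chrom = chrom, start = lo,
                                              end = hi)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  do.call(rbind, out)
}
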