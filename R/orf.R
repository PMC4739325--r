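# Detection of conserved open reading frames hidden in putative lncRNAs:
# ORF enumeration over a pairwise alignment, Nei-Gojobori dN/dS, and
# length-binned empirical significance against intergenic nulls.

GENCODE_STOPS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")

translate_codon <- local({
  tab <- NULL
  function(codon) {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    aa <- tab[codon]
    if (is.na(aa)) NA_character_ else unname(aa)
  }
})

# Synonymous site count of one codon: at each position, the fraction of the
# three possible changes that preserve the amino acid.  Changes to stop codons
# count as nonsynonymous, so sites always sum to 3 per codon.
codon_syn_sites <- local({
  cache <- new.env(parent = emptyenv())
  function(codon) {
    if (!is.null(cache[[codon]])) return(cache[[codon]])
    aa <- translate_codon(codon)
    s <- 0
    cs <- strsplit(codon, "")[[1]]
    for (pos in 1:3) {
      for (b in BASES[BASES != cs[pos]]) {
        alt <- cs; alt[pos] <- b
        alt_codon <- paste(alt, collapse = "")
        alt_aa <- translate_codon(alt_codon)
        if (!is.na(alt_aa) && alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
      }
    }
    cache[[codon]] <- s
    s
  }
})

# Pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair.  All mutational orderings are weighted equally; orderings passing
# through a stop codon are excluded (unless all do, in which case every
# ordering is used so the pair still contributes).
codon_pair_diffs <- function(c1, c2) {
  p1 <- strsplit(c1, "")[[1]]
  p2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(p1 != p2)
  nd_total <- 0; sd_total <- 0
  if (length(diff_pos) == 0L) return(c(nd = 0, sd = 0))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  paths <- perms(diff_pos)
  evaluate <- function(path) {
    cur <- p1
    nd <- 0; sd <- 0
    for (pos in path) {
      nxt <- cur; nxt[pos] <- p2[pos]
      aa1 <- translate_codon(paste(cur, collapse = ""))
      aa2 <- translate_codon(paste(nxt, collapse = ""))
      if (aa2 == "*" || aa1 == "*") return(NULL)   # passes through a stop
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd = nd, sd = sd)
  }
  res <- lapply(paths, evaluate)
  ok <- !vapply(res, is.null, TRUE)
  if (!any(ok)) {
    # all orderings pass through a stop; fall back to counting them anyway
    res <- lapply(paths, function(path) {
      cur <- p1; nd <- 0; sd <- 0
      for (pos in path) {
        nxt <- cur; nxt[pos] <- p2[pos]
        a1 <- translate_codon(paste(cur, collapse = ""))
        a2 <- translate_codon(paste(nxt, collapse = ""))
        if (!is.na(a1) && !is.na(a2) && a1 == a2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(nd = nd, sd = sd)
    })
    ok <- rep(TRUE, length(res))
  }
  m <- do.call(rbind, res[ok])
  c(nd = mean(m[, "nd"]), sd = mean(m[, "sd"]))
}

#' Nei-Gojobori dN/dS for a gap-free codon alignment
#'
#' Pathway counting with equal weighting of mutational orderings
#' (orderings through stop codons excluded), Jukes-Cantor multiple-hit
#' correction of the proportions, and the sentinel rules: no substitutions at
#' all gives ratio 0 (maximally conserved; the identically-processed empirical
#' null absorbs this degeneracy), and dS = 0 with dN > 0 gives ratio `Inf`
#' (never coding-flagged).
#'
#' @param seq_a,seq_b Aligned coding sequences (equal length, multiple of 3,
#'   no gaps, no internal stop codons; the terminal stop should be excluded).
#' @param correction `"jc"` (Jukes-Cantor) or `"none"` (raw p-distances).
#' @return List with `N`, `S` (expected site counts), `Nd`, `Sd` (observed
#'   differences), `pN`, `pS`, `dN`, `dS` and `ratio`.
#' @export
nei_gojobori_dnds <- function(seq_a, seq_b, correction = c("jc", "none")) {
  correction <- match.arg(correction)
  stopifnot(nchar(seq_a) == nchar(seq_b), nchar(seq_a) %% 3 == 0,
            nchar(seq_a) >= 3)
  n_codons <- nchar(seq_a) / 3
  codons_a <- substring(seq_a, 3 * (0:(n_codons - 1)) + 1, 3 * (1:n_codons))
  codons_b <- substring(seq_b, 3 * (0:(n_codons - 1)) + 1, 3 * (1:n_codons))
  if (any(codons_a %in% GENCODE_STOPS) || any(codons_b %in% GENCODE_STOPS)) {
    stop("internal stop codon in codon alignment")
  }
  if (any(grepl("[^ACGT]", c(codons_a, codons_b)))) {
    stop("codon alignment must be gap-free ACGT sequence")
  }
  s_a <- sum(vapply(codons_a, codon_syn_sites, 0))
  s_b <- sum(vapply(codons_b, codon_syn_sites, 0))
  S <- (s_a + s_b) / 2
  N <- 3 * n_codons - S
  Nd <- 0; Sd <- 0
  for (i in seq_len(n_codons)) {
    d <- codon_pair_diffs(codons_a[i], codons_b[i])
    Nd <- Nd + d[["nd"]]; Sd <- Sd + d[["sd"]]
  }
  pN <- if (N > 0) Nd / N else 0
  pS <- if (S > 0) Sd / S else 0
  jc <- function(p) {
    if (p >= 0.75) return(Inf)
    -0.75 * log(1 - 4 * p / 3)
  }
  if (correction == "jc") {
    dN <- jc(pN); dS <- jc(pS)
  } else {
    dN <- pN; dS <- pS
  }
  ratio <- if (Nd == 0 && Sd == 0) 0 else if (dS == 0) Inf else dN / dS
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
       dN = dN, dS = dS, ratio = ratio)
}

# Expand a run-length ops matrix to per-column vectors of (op, q_offset,
# t_offset); offsets are 0-based positions of the consumed base, NA when the
# sequence is not consumed in that column.
expand_alignment <- function(aln) {
  ops <- rep(aln$ops[, "op"], aln$ops[, "len"])
  qoff <- toff <- rep(NA_real_, length(ops))
  q <- aln$q_start; t <- aln$t_start
  qc <- ops %in% c(0, 1, 2)
  tc <- ops %in% c(0, 1, 3)
  qoff[qc] <- q + cumsum(qc)[qc] - 1
  toff[tc] <- t + cumsum(tc)[tc] - 1
  list(op = ops, q = qoff, t = toff)
}

#' Enumerate ORFs aligned in both species
#'
#' Crawls a significant pairwise alignment of two transcript sequences and
#' reports every open reading frame (`ATG` ... `TAA`/`TAG`/`TGA`) that is
#' present, in frame, and stop-aligned in both species.  By default any gap
#' within the ORF disqualifies it (the strict frame-shift rule);
#' `allow_inframe_gaps = TRUE` additionally permits gaps whose length is a
#' multiple of 3 and that fall on codon boundaries, comparing only the aligned
#' codons.
#'
#' @param aln A `local_alignment` between `seq_a` (query) and `seq_b`
#'   (target).
#' @param seq_a,seq_b The aligned transcript sequences.
#' @param min_len Minimum ORF span in nt, stop codon included (default 33:
#'   a start plus at least 9 further amino acids plus the stop).
#' @param allow_inframe_gaps Permit 3n gaps at codon boundaries?
#' @return List of `orf_hit` entries: `a_start`/`a_end` and `b_start`/`b_end`
#'   (0-based half-open, in transcript coordinates), `length_nt` (stop
#'   included), `codons_a`, `codons_b` (stop excluded) and the dN/dS fields
#'   of [nei_gojobori_dnds()].
#' @export
enumerate_aligned_orfs <- function(aln, seq_a, seq_b, min_len = 33L,
                                   allow_inframe_gaps = FALSE) {
  ex <- expand_alignment(aln)
  ncol_aln <- length(ex$op)
  achr <- strsplit(seq_a, "")[[1]]
  bchr <- strsplit(seq_b, "")[[1]]
  acol <- ifelse(is.na(ex$q), "-", achr[ex$q + 1])
  bcol <- ifelse(is.na(ex$t), "-", bchr[ex$t + 1])
  # maximal gap-free runs
  gapfree <- ex$op %in% c(0, 1)
  r <- rle(gapfree)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  hits <- list()
  segs <- which(r$values)
  if (allow_inframe_gaps) {
    # merge consecutive gap-free runs separated by 3n-length gap runs
    merged <- list()
    i <- 1
    while (i <= length(r$values)) {
      if (!r$values[i]) { i <- i + 1; next }
      cols <- run_start[i]:run_end[i]
      j <- i + 1
      while (j + 1 <= length(r$values) && !r$values[j] &&
             r$lengths[j] %% 3 == 0 && r$values[j + 1]) {
        cols <- c(cols, run_start[j + 1]:run_end[j + 1])
        j <- j + 2
      }
      merged[[length(merged) + 1L]] <- cols
      i <- j
    }
    seg_cols <- merged
  } else {
    seg_cols <- lapply(segs, function(s) run_start[s]:run_end[s])
  }
  for (cols in seg_cols) {
    a_sub <- acol[cols]; b_sub <- bcol[cols]
    n <- length(cols)
    if (n < 6L) next
    codon_at <- function(v, i) paste(v[i:(i + 2)], collapse = "")
    starts <- which(vapply(seq_len(n - 5L), function(i) {
      codon_at(a_sub, i) == "ATG" && codon_at(b_sub, i) == "ATG"
    }, TRUE))
    for (s in starts) {
      i <- s + 3L
      repeat {
        if (i + 2L > n) break
        ca <- codon_at(a_sub, i); cb <- codon_at(b_sub, i)
        a_stop <- ca %in% GENCODE_STOPS
        b_stop <- cb %in% GENCODE_STOPS
        if (a_stop != b_stop) break          # stops not aligned: no ORF
        if (a_stop && b_stop) {
          span <- (i + 3L) - s                # nt, stop included
          if (span >= min_len) {
            body <- s:(i - 1L)
            keep <- a_sub[body] != "-"        # aligned codons only
            cod_a <- paste(a_sub[body][keep], collapse = "")
            cod_b <- paste(b_sub[body][keep], collapse = "")
            dn <- nei_gojobori_dnds(cod_a, cod_b)
            qcols <- ex$q[cols[s:(i + 2L)]]
            tcols <- ex$t[cols[s:(i + 2L)]]
            hits[[length(hits) + 1L]] <- c(
              list(a_start = min(qcols, na.rm = TRUE),
                   a_end = max(qcols, na.rm = TRUE) + 1,
                   b_start = min(tcols, na.rm = TRUE),
                   b_end = max(tcols, na.rm = TRUE) + 1,
                   length_nt = span, codons_a = cod_a, codons_b = cod_b),
              dn)
          }
          break
        }
        i <- i + 3L
      }
    }
  }
  hits
}

#' Build a length-binned null distribution of dN/dS ratios
#'
#' Random intergenic regions are lifted to their syntenic counterparts,
#' aligned, and the ORF-finding procedure repeated; the resulting ratios are
#' binned by ORF length.  Bins are usable only when they hold at least
#' `min_per_bin` ratios.
#'
#' @param genome_a,genome_b The two genomes.
#' @param chain_set Chains from genome A to genome B.
#' @param annotations_a,annotations_b Transcripts excluded from sampling.
#' @param scoring A [scoring_scheme()] (lncRNA preset recommended).
#' @param n_regions Number of random regions.
#' @param region_length Length of each sampled region.
#' @param bin_width ORF-length bin width in nt.
#' @param min_per_bin Minimum ratios per usable bin.
#' @param min_len Minimum ORF span passed to [enumerate_aligned_orfs()].
#' @param rng_seed Integer seed.
#' @return A `dnds_null_table`: list with `bin_width`, `bins` (named list of
#'   sorted ratio vectors, name = bin lower bound), `min_per_bin`,
#'   `n_regions`.
#' @export
build_dnds_null <- function(genome_a, genome_b, chain_set, annotations_a,
                            annotations_b = list(),
                            scoring = scoring_lncrna(), n_regions = 50000L,
                            region_length = 1000L, bin_width = 5L,
                            min_per_bin = 100L, min_len = 33L, rng_seed = 1L) {
  draws <- sample_intergenic(genome_a, annotations_a, region_length,
                             n = n_regions, rng_seed = rng_seed)
  ivs <- attr(draws, "intervals")
  ratios <- numeric(0); lengths <- integer(0)
  for (i in seq_len(n_regions)) {
    iv <- genomic_interval(ivs$chrom[i], ivs$start[i], ivs$end[i], "+")
    lr <- lift_interval(chain_set, iv, min_match = 0.1)
    if (nrow(lr$mapped) == 0L) next
    t_lo <- min(lr$mapped$start); t_hi <- max(lr$mapped$end)
    t_seq <- seq_slice(genome_b[[lr$mapped$chrom[1]]], t_lo, t_hi)
    alns <- local_align(draws[i], t_seq, scoring)
    for (al in alns) {
      for (h in enumerate_aligned_orfs(al, draws[i], t_seq, min_len = min_len)) {
        ratios <- c(ratios, h$ratio)
        lengths <- c(lengths, h$length_nt)
      }
    }
  }
  bin_lo <- (lengths %/% bin_width) * bin_width
  bins <- lapply(split(ratios, bin_lo), sort)
  structure(list(bin_width = as.integer(bin_width), bins = bins,
                 min_per_bin = as.integer(min_per_bin),
                 n_regions = as.integer(n_regions)),
            class = "dnds_null_table")
}

# Insert observed ratios directly (used for simulation-driven nulls).
dnds_null_from_ratios <- function(ratios, lengths, bin_width = 5L,
                                  min_per_bin = 100L) {
  bin_lo <- (lengths %/% bin_width) * bin_width
  structure(list(bin_width = as.integer(bin_width),
                 bins = lapply(split(ratios, bin_lo), sort),
                 min_per_bin = as.integer(min_per_bin),
                 n_regions = NA_integer_),
            class = "dnds_null_table")
}

#' Assign empirical significance to ORF hits
#'
#' The empirical P-value is one-sided low-ratio (lower dN/dS = more
#' coding-like): `p = (1 + #\{null ratios in bin <= observed\}) / (n_bin + 1)`.
#' P-values are Benjamini-Hochberg corrected across hits; a hit is flagged as
#' coding when its q-value is at most `alpha`.  Hits whose length bin is
#' unusable (fewer than `min_per_bin` null ratios, typically long ORFs) are
#' flagged when their ratio is below 1.
#'
#' @param hits List of ORF hits from [enumerate_aligned_orfs()].
#' @param null A `dnds_null_table`.
#' @param alpha Significance level.
#' @return data.frame with one row per hit: `length_nt`, `ratio`,
#'   `p_empirical`, `q_value`, `bin_usable`, `flagged_coding`.
#' @export
orf_significance <- function(hits, null, alpha = 0.05) {
  if (length(hits) == 0L) {
    return(data.frame(length_nt = integer(0), ratio = numeric(0),
                      p_empirical = numeric(0), q_value = numeric(0),
                      bin_usable = logical(0), flagged_coding = logical(0)))
  }
  lens <- vapply(hits, `[[`, 0, "length_nt")
  ratios <- vapply(hits, `[[`, 0, "ratio")
  bin_lo <- (lens %/% null$bin_width) * null$bin_width
  p <- rep(NA_real_, length(hits))
  usable <- logical(length(hits))
  for (i in seq_along(hits)) {
    b <- null$bins[[as.character(bin_lo[i])]]
    if (!is.null(b) && length(b) >= null$min_per_bin) {
      usable[i] <- TRUE
      p[i] <- (1 + sum(b <= ratios[i])) / (length(b) + 1)
    }
  }
  q <- rep(NA_real_, length(hits))
  if (any(usable)) q[usable] <- p.adjust(p[usable], method = "BH")
  flagged <- ifelse(usable, !is.na(q) & q <= alpha, ratios < 1)
  data.frame(length_nt = lens, ratio = ratios, p_empirical = p, q_value = q,
             bin_usable = usable, flagged_coding = flagged)
}
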