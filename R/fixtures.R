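# Synthetic genome-pair fixtures: two toy genomes related by a known event
# log, with planted coding genes, pseudogenes, duplicated families, conserved
# and species-specific lncRNAs, a matching chain file, annotation tracks, and
# a machine-readable truth table.  Because genome B is derived from genome A
# segment by segment, the chain blocks are exact, and because every planted
# element is generated k-mer-disjoint from every other element, the homology
# structure of the fixture is exactly the planted one: unrelated transcripts
# cannot share an alignment seed, so filter and ortholog fates are
# deterministic consequences of the construction.

#' Random DNA sequence
#' @param n Length in bp.
#' @param gc GC fraction.
#' @return DNA string (caller is responsible for seeding).
#' @export
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Mutate a sequence with substitutions and indels, logging events
#'
#' Per-base independent substitutions; indel events occur independently per
#' position with geometric lengths (insertions add new sequence to the copy,
#' deletions drop it).  The event log is an exact run-length alignment
#' between input and output, from which chain blocks and expected identities
#' can be computed.
#'
#' @param seq Input DNA string.
#' @param sub_rate Per-base substitution probability.
#' @param indel_rate Per-base indel event probability.
#' @param indel_len_mean Mean indel length (geometric).
#' @param rng_seed Optional seed; when `NULL` the caller's RNG state is used.
#' @return List with `seq` (mutated), `ops` (matrix `op`, `len`; op 1 =
#'   aligned, 2 = insertion in the copy, 3 = deletion from the copy) and
#'   `n_sub` (realized substitutions in aligned columns).
#' @export
mutate_sequence <- function(seq, sub_rate, indel_rate, indel_len_mean = 2,
                            rng_seed = NULL) {
  go <- function() {
    chars <- strsplit(seq, "")[[1]]
    L <- length(chars)
    sub_mask <- runif(L) < sub_rate
    if (any(sub_mask)) {
      alt <- function(b) {
        others <- BASES[BASES != b]
        others[sample.int(3L, 1L)]
      }
      chars[sub_mask] <- vapply(chars[sub_mask], alt, "")
    }
    ev_pos <- which(runif(L) < indel_rate)
    ev_ins <- runif(length(ev_pos)) < 0.5
    ev_len <- rgeom(length(ev_pos), prob = 1 / indel_len_mean) + 1L
    out <- character(0)
    ops <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("op", "len")))
    push <- function(op, len) {
      if (len <= 0) return()
      n <- nrow(ops)
      if (n > 0 && ops[n, "op"] == op) {
        ops[n, "len"] <<- ops[n, "len"] + len
      } else {
        ops <<- rbind(ops, c(op, len))
      }
    }
    pos <- 1L
    n_sub <- 0L
    for (k in seq_along(ev_pos)) {
      p <- ev_pos[k]
      if (p < pos) next                 # swallowed by a previous deletion
      if (p > pos) {
        seg <- pos:(p - 1L)
        out <- c(out, chars[seg])
        n_sub <- n_sub + sum(sub_mask[seg])
        push(1, length(seg))
      }
      if (ev_ins[k]) {
        out <- c(out, sample(BASES, ev_len[k], replace = TRUE))
        push(2, ev_len[k])
        pos <- p
      } else {
        dl <- min(ev_len[k], L - p + 1L)
        push(3, dl)
        pos <- p + dl
      }
    }
    if (pos <= L) {
      seg <- pos:L
      out <- c(out, chars[seg])
      n_sub <- n_sub + sum(sub_mask[seg])
      push(1, length(seg))
    }
    list(seq = paste(out, collapse = ""), ops = ops, n_sub = n_sub)
  }
  if (is.null(rng_seed)) go() else with_seed(rng_seed, go())
}

#' Simulate an aligned codon pair under a selection regime
#'
#' Starting from a random stop-free coding sequence, each site attempts a
#' substitution with probability `sub_rate`; synonymous changes are always
#' accepted, nonsynonymous changes with probability `omega`, and changes
#' creating a stop codon are rejected.  `omega = 1` simulates neutral
#' evolution, small `omega` purifying selection on the protein.
#'
#' @param n_codons Number of codons.
#' @param sub_rate Per-site attempted substitution probability.
#' @param omega Acceptance probability for nonsynonymous changes.
#' @param rng_seed Integer seed.
#' @return List with `a` and `b` (aligned codon sequences, no stops).
#' @export
neutral_codon_pair <- function(n_codons, sub_rate = 0.15, omega = 1,
                               rng_seed = 1L) {
  stopifnot(omega >= 0)
  with_seed(rng_seed, {
    codons <- character(n_codons)
    for (i in seq_len(n_codons)) {
      repeat {
        cd <- paste(sample(BASES, 3L, replace = TRUE), collapse = "")
        if (!cd %in% GENCODE_STOPS) break
      }
      codons[i] <- cd
    }
    a <- paste(codons, collapse = "")
    b_chars <- strsplit(a, "")[[1]]
    for (site in seq_along(b_chars)) {
      if (runif(1) >= sub_rate) next
      ci <- (site - 1L) %/% 3L
      codon <- paste(b_chars[(3 * ci + 1):(3 * ci + 3)], collapse = "")
      newb <- sample(BASES[BASES != b_chars[site]], 1L)
      alt <- strsplit(codon, "")[[1]]
      alt[(site - 1L) %% 3L + 1L] <- newb
      alt_codon <- paste(alt, collapse = "")
      if (alt_codon %in% GENCODE_STOPS) next
      syn <- translate_codon(alt_codon) == translate_codon(codon)
      if (syn || runif(1) < omega) b_chars[site] <- newb
    }
    list(a = a, b = paste(b_chars, collapse = ""))
  })
}

#' Default fixture configuration
#'
#' The defaults define the study conditions every golden-fixture test runs
#' under: 12 coding orthologs (with matching reconstructed candidates that
#' trigger the coding-overlap filter and feed the learned threshold), 5
#' conserved intergenic lncRNAs, 2 divergent pairs, one miRNA and one snoRNA
#' host, one 3-copy duplicated family, one processed pseudogene, one UTR
#' fragment, species-specific lncRNAs with and without a conserved locus, an
#' isoform cluster, and two single-exon candidates (one conserved).
#'
#' @param rng_seed Integer seed (default 7).
#' @param ... Overrides for individual fields.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(rng_seed = 7L, ...) {
  cfg <- list(
    rng_seed = as.integer(rng_seed),
    n_coding = 12L, n_lincs = 5L, n_divergent = 2L,
    n_mirna_host = 1L, n_snorna_host = 1L,
    dup_copies = 3L, n_ss_locus = 3L, n_ss_nolocus = 1L,
    filler_len = 18000L,
    filler_sub = 0.25, filler_indel = 0.012,
    coding_exon_sub = c(0.02, 0.10), coding_intron_sub = 0.12,
    coding_intron_indel = 0.004,
    linc_exon_sub = 0.10, linc_exon_indel = 0.001,
    linc_intron_sub = 0.18, linc_intron_indel = 0.012,
    dup_copy_sub = 0.10, pseudo_sub = 0.03, utr_sub = 0.03,
    ss_sub = 0.12, ss_indel = 0.008,
    indel_len_mean = 2,
    species = c("spA", "spB"),
    tree = "(spA:1,spB:1)anc;")
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "fixture_config")
}

# --- internal builder machinery ---------------------------------------------

# k-mer disjointness registry: rewrites clashing positions until an element
# sequence shares no 12-mer with previously registered element sequence.
kmer_set_new <- function() new.env(parent = emptyenv(), hash = TRUE)

kmers_of <- function(seq, k = 12L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

kmer_register <- function(reg, seq, k = 12L) {
  for (km in kmers_of(seq, k)) assign(km, TRUE, envir = reg)
  invisible(NULL)
}

fresh_element_seq <- function(reg, n, k = 12L, max_rounds = 80L) {
  s <- strsplit(random_dna(n), "")[[1]]
  for (round in seq_len(max_rounds)) {
    str <- paste(s, collapse = "")
    kms <- kmers_of(str, k)
    clash <- which(vapply(kms, function(km) {
      !is.null(reg[[km]])
    }, TRUE))
    if (length(clash) == 0L) return(str)
    # rewrite the center base of each clashing k-mer
    fix_pos <- unique(pmin(clash + (k %/% 2L), n))
    for (p in fix_pos) s[p] <- sample(BASES[BASES != s[p]], 1L)
  }
  stop("could not generate a k-mer-disjoint element sequence of length ", n)
}

builder_new <- function(contigs) {
  env <- new.env(parent = emptyenv())
  env$contigs <- contigs
  env$a <- setNames(vector("list", length(contigs)), contigs)
  env$b <- setNames(vector("list", length(contigs)), contigs)
  env$ops <- setNames(vector("list", length(contigs)), contigs)
  env$a_pos <- setNames(rep(0, length(contigs)), contigs)
  env$b_pos <- setNames(rep(0, length(contigs)), contigs)
  env
}

# Append a segment: a_seq (possibly ""), b_seq, ops runs relating them.
builder_add <- function(bld, contig, a_seq, b_seq, ops) {
  a0 <- bld$a_pos[[contig]]
  b0 <- bld$b_pos[[contig]]
  bld$a[[contig]] <- c(bld$a[[contig]], a_seq)
  bld$b[[contig]] <- c(bld$b[[contig]], b_seq)
  bld$ops[[contig]] <- c(bld$ops[[contig]], list(ops))
  bld$a_pos[[contig]] <- a0 + nchar(a_seq)
  bld$b_pos[[contig]] <- b0 + nchar(b_seq)
  list(a_start = a0, a_end = a0 + nchar(a_seq),
       b_start = b0, b_end = b0 + nchar(b_seq))
}

seg_conserved <- function(bld, contig, a_seq, sub, indel, indel_len_mean = 2) {
  m <- mutate_sequence(a_seq, sub, indel, indel_len_mean)
  builder_add(bld, contig, a_seq, m$seq, m$ops)
}

seg_a_only <- function(bld, contig, a_seq) {
  builder_add(bld, contig, a_seq, "",
              matrix(c(3, nchar(a_seq)), ncol = 2,
                     dimnames = list(NULL, c("op", "len"))))
}

seg_replaced <- function(bld, contig, a_seq, b_seq) {
  builder_add(bld, contig, a_seq, b_seq,
              matrix(c(3, nchar(a_seq), 2, nchar(b_seq)), ncol = 2,
                     byrow = TRUE, dimnames = list(NULL, c("op", "len"))))
}

# collapse a contig's op-run list into a chain (target = A, query = B)
ops_to_chain <- function(ops_list, contig, a_len, b_len, id) {
  ops <- do.call(rbind, ops_list)
  # merge consecutive runs of the same op
  keep <- ops[, "len"] > 0
  ops <- ops[keep, , drop = FALSE]
  blocks <- NULL
  t_pos <- 0; q_pos <- 0
  t_start <- NA; q_start <- NA
  cur_size <- 0; cur_dt <- 0; cur_dq <- 0
  flush_block <- function() {
    if (cur_size > 0) {
      blocks <<- rbind(blocks, c(cur_size, cur_dt, cur_dq))
    }
    cur_size <<- 0; cur_dt <<- 0; cur_dq <<- 0
  }
  for (r in seq_len(nrow(ops))) {
    op <- ops[r, "op"]; len <- ops[r, "len"]
    if (op == 1) {
      if (is.na(t_start)) { t_start <- t_pos; q_start <- q_pos }
      if (cur_dt > 0 || cur_dq > 0) flush_block()
      cur_size <- cur_size + len
      t_pos <- t_pos + len; q_pos <- q_pos + len
    } else if (op == 3) {             # A-only
      if (!is.na(t_start)) cur_dt <- cur_dt + len
      t_pos <- t_pos + len
    } else {                          # B-only
      if (!is.na(t_start)) cur_dq <- cur_dq + len
      q_pos <- q_pos + len
    }
  }
  flush_block()
  if (is.null(blocks)) return(NULL)
  colnames(blocks) <- c("size", "dt", "dq")
  # trailing gaps after the last block are not part of the chain span
  n <- nrow(blocks)
  t_end <- t_start + sum(blocks[, "size"]) + sum(blocks[-n, "dt"])
  q_end <- q_start + sum(blocks[, "size"]) + sum(blocks[-n, "dq"])
  blocks[n, c("dt", "dq")] <- 0
  list(score = sum(blocks[, "size"]),
       t_name = contig, t_size = a_len, t_strand = "+",
       t_start = t_start, t_end = t_end,
       q_name = contig, q_size = b_len, q_strand = "+",
       q_start = q_start, q_end = q_end,
       id = id, blocks = blocks)
}

# truth-row helper
truth_row <- function(element, id_a, id_b = NA, fate, ortholog = NA,
                      class = NA, lca = NA) {
  data.frame(element = element, id_a = id_a, id_b = id_b, fate = fate,
             ortholog = ortholog, class = class, lca = lca,
             stringsAsFactors = FALSE)
}

#' Generate the planted genome pair
#'
#' Builds genome A segment by segment, derives genome B with per-element
#' divergence, and emits exact chain blocks from the generative event log
#' together with all annotation tracks and the truth table.  See
#' [fixture_config()] for what is planted.
#'
#' @param config A [fixture_config()].
#' @return A `fixture` list: `genome_a`, `genome_b`, `chains` (a
#'   `chain_set`), `candidates_a`, `lncrnas_b`, `coding_a`, `coding_b`,
#'   `mirna_a`, `mirna_b`, `snorna_a`, `snorna_b`, `repeats_a`, `cpg_a`,
#'   `known_panels`, `tree`, `species`, `truth`.
#' @export
plant_genome_pair <- function(config = fixture_config()) {
  with_seed(config$rng_seed, plant_genome_pair_impl(config))
}

plant_genome_pair_impl <- function(cfg) {
  reg <- kmer_set_new()
  contigs <- c("chr1", "chr2")
  bld <- builder_new(contigs)
  ilm <- cfg$indel_len_mean

  candidates_a <- list(); lncrnas_b <- list()
  coding_a <- list(); coding_b <- list()
  mirna_a <- NULL; mirna_b <- NULL
  snorna_a <- NULL; snorna_b <- NULL
  repeats_a <- NULL; cpg_a <- NULL
  truth <- NULL
  panels <- character(0)
  extra_chains <- list()

  next_contig <- local({
    i <- 0L
    function() {
      i <<- i + 1L
      contigs[(i %% length(contigs)) + 1L]
    }
  })
  filler <- function(contig, len = cfg$filler_len) {
    seg_conserved(bld, contig, random_dna(len), cfg$filler_sub,
                  cfg$filler_indel, ilm)
  }

  # multi-piece conserved element; returns per-piece A/B coordinates
  plant_pieces <- function(contig, piece_lens, subs, indels,
                           b_mode = rep("cons", length(piece_lens))) {
    a_seqs <- lapply(piece_lens, function(n) fresh_element_seq(reg, n))
    coords <- vector("list", length(piece_lens))
    for (i in seq_along(piece_lens)) {
      coords[[i]] <- switch(
        b_mode[i],
        cons = seg_conserved(bld, contig, a_seqs[[i]], subs[i], indels[i], ilm),
        a_only = seg_a_only(bld, contig, a_seqs[[i]]),
        replaced = seg_replaced(bld, contig, a_seqs[[i]],
                                fresh_element_seq(reg, piece_lens[i])))
      kmer_register(reg, a_seqs[[i]])
      b_piece <- bld$b[[contig]][[length(bld$b[[contig]])]]
      if (nzchar(b_piece)) kmer_register(reg, b_piece)
    }
    coords
  }

  # -- coding genes (with reconstructed candidates overlapping them) ----------
  exon_subs <- seq(cfg$coding_exon_sub[1], cfg$coding_exon_sub[2],
                   length.out = cfg$n_coding)
  gene1_b_exons <- NULL   # pseudogene parent bookkeeping
  gene1_contig <- NULL
  for (g in seq_len(cfg$n_coding)) {
    contig <- next_contig()
    filler(contig)
    lens <- c(300, 350, 300, 350, 300, 350, 300)
    subs <- rep(c(exon_subs[g], cfg$coding_intron_sub), length.out = 7)
    indels <- rep(c(0, cfg$coding_intron_indel), length.out = 7)
    coords <- plant_pieces(contig, lens, subs, indels)
    ex_idx <- c(1, 3, 5, 7)
    a_ex <- cbind(vapply(coords[ex_idx], `[[`, 0, "a_start"),
                  vapply(coords[ex_idx], `[[`, 0, "a_end"))
    b_ex <- cbind(vapply(coords[ex_idx], `[[`, 0, "b_start"),
                  vapply(coords[ex_idx], `[[`, 0, "b_end"))
    ga <- transcript(paste0("gA_cod", g), contig, a_ex[1, 1], a_ex[4, 2], "+",
                     a_ex, gene_id = paste0("cod", g), biotype = "coding")
    gb <- transcript(paste0("gB_cod", g), contig, b_ex[1, 1], b_ex[4, 2], "+",
                     b_ex, gene_id = paste0("cod", g), biotype = "coding")
    coding_a[[length(coding_a) + 1L]] <- ga
    coding_b[[length(coding_b) + 1L]] <- gb
    cand <- ga; cand$id <- paste0("cand_cod", g); cand$biotype <- "candidate"
    candidates_a[[length(candidates_a) + 1L]] <- cand
    truth <- rbind(truth, truth_row(paste0("coding_overlap_", g),
                                    cand$id, NA, "removed_coding_overlap"))
    if (g == 1L) {
      gene1_b_exons <- b_ex
      gene1_contig <- contig
    }
  }

  # -- conserved intergenic lncRNAs ------------------------------------------
  for (i in seq_len(cfg$n_lincs)) {
    contig <- next_contig()
    filler(contig)
    if (i <= 2L) {
      # CpG-island promoter piece directly upstream
      cpg_seq <- random_dna(300, gc = 0.54)
      cc <- seg_conserved(bld, contig, cpg_seq, 0.10, 0, ilm)
      cpg_a <- rbind(cpg_a, data.frame(chrom = contig, start = cc$a_start,
                                       end = cc$a_end, name = "CpG"))
      filler(contig, 100L)
    }
    lens <- c(300, 350, 400, 450, 300)
    subs <- rep(c(cfg$linc_exon_sub, cfg$linc_intron_sub), length.out = 5)
    indels <- rep(c(cfg$linc_exon_indel, cfg$linc_intron_indel),
                  length.out = 5)
    coords <- plant_pieces(contig, lens, subs, indels)
    ex_idx <- c(1, 3, 5)
    a_ex <- cbind(vapply(coords[ex_idx], `[[`, 0, "a_start"),
                  vapply(coords[ex_idx], `[[`, 0, "a_end"))
    b_ex <- cbind(vapply(coords[ex_idx], `[[`, 0, "b_start"),
                  vapply(coords[ex_idx], `[[`, 0, "b_end"))
    ida <- paste0("lincA", i); idb <- paste0("lincB", i)
    candidates_a[[length(candidates_a) + 1L]] <-
      transcript(ida, contig, a_ex[1, 1], a_ex[3, 2], "+", a_ex,
                 gene_id = ida, biotype = "candidate")
    lncrnas_b[[length(lncrnas_b) + 1L]] <-
      transcript(idb, contig, b_ex[1, 1], b_ex[3, 2], "+", b_ex,
                 gene_id = idb)
    truth <- rbind(truth, truth_row(paste0("conserved_linc_", i), ida, idb,
                                    "kept", idb, "INTERGENIC", "anc"))
  }

  # -- divergent lncRNA / coding gene pairs ----------------------------------
  for (i in seq_len(cfg$n_divergent)) {
    contig <- next_contig()
    filler(contig)
    # left-to-right: lnc exon2 (replaced), lnc intron (replaced),
    # lnc exon1 (conserved), 200 bp shared promoter gap, partner gene
    lnc_lens <- c(400, 300, 300)
    lnc_modes <- c("replaced", "replaced", "cons")
    coords <- plant_pieces(contig, lnc_lens,
                           subs = c(0, 0, 0.08), indels = c(0, 0, 0),
                           b_mode = lnc_modes)
    a_ex <- rbind(c(coords[[1]]$a_start, coords[[1]]$a_end),
                  c(coords[[3]]$a_start, coords[[3]]$a_end))
    b_ex <- rbind(c(coords[[1]]$b_start, coords[[1]]$b_end),
                  c(coords[[3]]$b_start, coords[[3]]$b_end))
    gap <- seg_conserved(bld, contig, random_dna(200), 0.15, 0, ilm)
    glens <- c(300, 350, 300)
    gcoords <- plant_pieces(contig, glens,
                            subs = c(0.05, cfg$coding_intron_sub, 0.05),
                            indels = c(0, cfg$coding_intron_indel, 0))
    g_ex_a <- rbind(c(gcoords[[1]]$a_start, gcoords[[1]]$a_end),
                    c(gcoords[[3]]$a_start, gcoords[[3]]$a_end))
    g_ex_b <- rbind(c(gcoords[[1]]$b_start, gcoords[[1]]$b_end),
                    c(gcoords[[3]]$b_start, gcoords[[3]]$b_end))
    ida <- paste0("divA", i); idb <- paste0("divB", i)
    candidates_a[[length(candidates_a) + 1L]] <-
      transcript(ida, contig, a_ex[1, 1], a_ex[2, 2], "-", a_ex,
                 gene_id = ida, biotype = "candidate")
    lncrnas_b[[length(lncrnas_b) + 1L]] <-
      transcript(idb, contig, b_ex[1, 1], b_ex[2, 2], "-", b_ex,
                 gene_id = idb)
    coding_a[[length(coding_a) + 1L]] <-
      transcript(paste0("gA_divp", i), contig, g_ex_a[1, 1], g_ex_a[2, 2],
                 "+", g_ex_a, gene_id = paste0("divp", i), biotype = "coding")
    coding_b[[length(coding_b) + 1L]] <-
      transcript(paste0("gB_divp", i), contig, g_ex_b[1, 1], g_ex_b[2, 2],
                 "+", g_ex_b, gene_id = paste0("divp", i), biotype = "coding")
    truth <- rbind(truth, truth_row(paste0("divergent_", i), ida, idb,
                                    "kept", idb, "DIVERGENT", "anc"))
  }

  # -- miRNA / snoRNA hosts --------------------------------------------------
  plant_host <- function(kind, i) {
    contig <- next_contig()
    filler(contig)
    lens <- c(300, 200, 90, 200, 300, 350, 300)   # exon,intr,smallRNA,intr,...
    subs <- c(0.10, 0.18, 0.01, 0.18, 0.10, 0.18, 0.10)
    indels <- c(0.001, 0.012, 0, 0.012, 0.001, 0.012, 0.001)
    coords <- plant_pieces(contig, lens, subs, indels)
    ex_idx <- c(1, 5, 7)
    a_ex <- cbind(vapply(coords[ex_idx], `[[`, 0, "a_start"),
                  vapply(coords[ex_idx], `[[`, 0, "a_end"))
    b_ex <- cbind(vapply(coords[ex_idx], `[[`, 0, "b_start"),
                  vapply(coords[ex_idx], `[[`, 0, "b_end"))
    ida <- paste0(kind, "hostA", i); idb <- paste0(kind, "hostB", i)
    candidates_a[[length(candidates_a) + 1L]] <<-
      transcript(ida, contig, a_ex[1, 1], a_ex[3, 2], "+", a_ex,
                 gene_id = ida, biotype = "candidate")
    lncrnas_b[[length(lncrnas_b) + 1L]] <<-
      transcript(idb, contig, b_ex[1, 1], b_ex[3, 2], "+", b_ex,
                 gene_id = idb)
    small_a <- data.frame(chrom = contig, start = coords[[3]]$a_start,
                          end = coords[[3]]$a_end,
                          name = paste0(kind, "-", i))
    small_b <- data.frame(chrom = contig, start = coords[[3]]$b_start,
                          end = coords[[3]]$b_end,
                          name = paste0(kind, "-", i))
    if (kind == "mir") {
      mirna_a <<- rbind(mirna_a, small_a); mirna_b <<- rbind(mirna_b, small_b)
      cls <- "MIRNA_HOST"
    } else {
      snorna_a <<- rbind(snorna_a, small_a)
      snorna_b <<- rbind(snorna_b, small_b)
      cls <- "SNORNA_HOST"
    }
    truth <<- rbind(truth, truth_row(paste0(kind, "_host_", i), ida, idb,
                                     "kept", idb, cls, "anc"))
  }
  for (i in seq_len(cfg$n_mirna_host)) plant_host("mir", i)
  for (i in seq_len(cfg$n_snorna_host)) plant_host("sno", i)

  # -- duplicated lncRNA family ----------------------------------------------
  dup_base <- list(ex1 = fresh_element_seq(reg, 600),
                   intr = fresh_element_seq(reg, 250),
                   ex2 = fresh_element_seq(reg, 600))
  kmer_register(reg, dup_base$ex1); kmer_register(reg, dup_base$intr)
  kmer_register(reg, dup_base$ex2)
  for (c_i in seq_len(cfg$dup_copies)) {
    contig <- next_contig()
    filler(contig)
    pieces <- lapply(dup_base, function(s) {
      mutate_sequence(s, cfg$dup_copy_sub, 0.002, ilm)$seq
    })
    c1 <- seg_a_only(bld, contig, pieces$ex1)
    c2 <- seg_a_only(bld, contig, pieces$intr)
    c3 <- seg_a_only(bld, contig, pieces$ex2)
    for (p in pieces) kmer_register(reg, p)
    a_ex <- rbind(c(c1$a_start, c1$a_end), c(c3$a_start, c3$a_end))
    ida <- paste0("dupA", c_i)
    candidates_a[[length(candidates_a) + 1L]] <-
      transcript(ida, contig, a_ex[1, 1], a_ex[2, 2], "+", a_ex,
                 gene_id = ida, biotype = "candidate")
    truth <- rbind(truth, truth_row(paste0("duplication_", c_i), ida, NA,
                                    "removed_duplication"))
  }
  panels <- c(ZFP_panel_1 = mutate_sequence(
    paste0(dup_base$ex1, dup_base$ex2), cfg$dup_copy_sub, 0.002, ilm)$seq)

  # -- processed pseudogene of coding gene 1 ---------------------------------
  {
    contig <- next_contig()
    filler(contig)
    b_gene_exons <- gene1_b_exons
    b_exon_lens <- b_gene_exons[, 2] - b_gene_exons[, 1]
    mrna_b <- paste(vapply(seq_len(nrow(b_gene_exons)), function(r) {
      # reconstruct gene1's B exon sequence from the builder output later;
      # here we store coordinates and defer sequence extraction
      ""
    }, ""), collapse = "")
    # mark position; actual sequence filled in after assembly
    L1 <- floor(sum(b_exon_lens) / 2)
    ph1 <- seg_a_only(bld, contig, strrep("A", L1))
    pint <- seg_a_only(bld, contig, strrep("A", 150L))
    ph2 <- seg_a_only(bld, contig, strrep("A", sum(b_exon_lens) - L1))
    pseudo_info <- list(contig = contig, L1 = L1,
                        a1 = c(ph1$a_start, ph1$a_end),
                        aint = c(pint$a_start, pint$a_end),
                        a2 = c(ph2$a_start, ph2$a_end),
                        piece1_idx = length(bld$a[[contig]]) - 2L,
                        piece2_idx = length(bld$a[[contig]]),
                        b_gene_exons = b_gene_exons,
                        b_gene_contig = gene1_contig)
    a_ex <- rbind(pseudo_info$a1, pseudo_info$a2)
    candidates_a[[length(candidates_a) + 1L]] <-
      transcript("pseudoA1", contig, a_ex[1, 1], a_ex[2, 2], "+", a_ex,
                 gene_id = "pseudoA1", biotype = "candidate")
    truth <- rbind(truth, truth_row("processed_pseudogene", "pseudoA1", NA,
                                    "removed_syntenic_coding"))
  }

  # -- UTR fragment of a coding gene with longer annotation in B -------------
  {
    contig <- next_contig()
    filler(contig)
    glens <- c(300, 350, 300)
    gcoords <- plant_pieces(contig, glens, subs = c(0.04, 0.12, 0.04),
                            indels = c(0, 0.004, 0))
    utr_lens <- c(250, 100, 250)
    ucoords <- plant_pieces(contig, utr_lens,
                            subs = rep(cfg$utr_sub, 3), indels = rep(0, 3))
    g_ex_a <- rbind(c(gcoords[[1]]$a_start, gcoords[[1]]$a_end),
                    c(gcoords[[3]]$a_start, gcoords[[3]]$a_end))
    # B annotation includes the UTR: last exon extended through it
    g_ex_b <- rbind(c(gcoords[[1]]$b_start, gcoords[[1]]$b_end),
                    c(gcoords[[3]]$b_start, ucoords[[3]]$b_end))
    coding_a[[length(coding_a) + 1L]] <-
      transcript("gA_utr", contig, g_ex_a[1, 1], g_ex_a[2, 2], "+", g_ex_a,
                 gene_id = "utrgene", biotype = "coding")
    coding_b[[length(coding_b) + 1L]] <-
      transcript("gB_utr", contig, g_ex_b[1, 1], g_ex_b[2, 2], "+", g_ex_b,
                 gene_id = "utrgene", biotype = "coding")
    u_ex <- rbind(c(ucoords[[1]]$a_start, ucoords[[1]]$a_end),
                  c(ucoords[[3]]$a_start, ucoords[[3]]$a_end))
    candidates_a[[length(candidates_a) + 1L]] <-
      transcript("utrfragA1", contig, u_ex[1, 1], u_ex[2, 2], "+", u_ex,
                 gene_id = "utrfragA1", biotype = "candidate")
    truth <- rbind(truth, truth_row("utr_fragment", "utrfragA1", NA,
                                    "removed_syntenic_coding"))
  }

  # -- species-specific lncRNAs with a conserved locus -----------------------
  for (i in seq_len(cfg$n_ss_locus)) {
    contig <- next_contig()
    filler(contig)
    if (i <= 2L) {
      # species-specific ERVK-like repeat in the promoter (A only)
      ervk <- random_dna(300)
      rc <- seg_a_only(bld, contig, ervk)
      repeats_a <- rbind(repeats_a,
                         data.frame(chrom = contig, start = rc$a_start,
                                    end = rc$a_end, name = "ERVK"))
      filler(contig, 100L)
    }
    lens <- c(400, 300, 400)
    coords <- plant_pieces(contig, lens,
                           subs = rep(cfg$ss_sub, 3),
                           indels = c(0.002, cfg$ss_indel, 0.002))
    a_ex <- rbind(c(coords[[1]]$a_start, coords[[1]]$a_end),
                  c(coords[[3]]$a_start, coords[[3]]$a_end))
    ida <- paste0("sslocA", i)
    candidates_a[[length(candidates_a) + 1L]] <-
      transcript(ida, contig, a_ex[1, 1], a_ex[2, 2], "+", a_ex,
                 gene_id = ida, biotype = "candidate")
    truth <- rbind(truth, truth_row(paste0("species_specific_locus_", i),
                                    ida, NA, "kept", NA, "INTERGENIC", "spA"))
  }

  # -- species-specific lncRNA with no syntenic locus ------------------------
  for (i in seq_len(cfg$n_ss_nolocus)) {
    contig <- next_contig()
    filler(contig)
    lens <- c(500, 250, 500)
    coords <- plant_pieces(contig, lens, subs = rep(0, 3),
                           indels = rep(0, 3),
                           b_mode = rep("replaced", 3))
    a_ex <- rbind(c(coords[[1]]$a_start, coords[[1]]$a_end),
                  c(coords[[3]]$a_start, coords[[3]]$a_end))
    ida <- paste0("ssnoA", i)
    candidates_a[[length(candidates_a) + 1L]] <-
      transcript(ida, contig, a_ex[1, 1], a_ex[2, 2], "+", a_ex,
                 gene_id = ida, biotype = "candidate")
    truth <- rbind(truth, truth_row("species_specific_nolocus", ida, NA,
                                    "kept", NA, "INTERGENIC", "spA"))
  }

  # -- isoform cluster -------------------------------------------------------
  {
    contig <- next_contig()
    filler(contig)
    lens <- c(300, 300, 300, 300, 300)
    coords <- plant_pieces(contig, lens,
                           subs = rep(c(cfg$linc_exon_sub,
                                        cfg$linc_intron_sub), length.out = 5),
                           indels = rep(c(0.001, 0.012), length.out = 5))
    ex_idx <- c(1, 3, 5)
    a_ex <- cbind(vapply(coords[ex_idx], `[[`, 0, "a_start"),
                  vapply(coords[ex_idx], `[[`, 0, "a_end"))
    b_ex <- cbind(vapply(coords[ex_idx], `[[`, 0, "b_start"),
                  vapply(coords[ex_idx], `[[`, 0, "b_end"))
    candidates_a[[length(candidates_a) + 1L]] <-
      transcript("isoA_long", contig, a_ex[1, 1], a_ex[3, 2], "+", a_ex,
                 gene_id = "isoA", biotype = "candidate")
    candidates_a[[length(candidates_a) + 1L]] <-
      transcript("isoA_short", contig, a_ex[1, 1], a_ex[2, 2], "+",
                 a_ex[1:2, , drop = FALSE], gene_id = "isoA",
                 biotype = "candidate")
    lncrnas_b[[length(lncrnas_b) + 1L]] <-
      transcript("isoB1", contig, b_ex[1, 1], b_ex[3, 2], "+", b_ex,
                 gene_id = "isoB")
    truth <- rbind(truth,
                   truth_row("isoform_long", "isoA_long", "isoB1", "kept",
                             "isoB1", "INTERGENIC", "anc"),
                   truth_row("isoform_short", "isoA_short", NA,
                             "collapsed_isoform"))
  }

  # -- single-exon candidates ------------------------------------------------
  {
    contig <- next_contig()
    filler(contig)
    cc <- plant_pieces(contig, 800L, subs = 0.08, indels = 0.001)
    candidates_a[[length(candidates_a) + 1L]] <-
      transcript("se_consA1", contig, cc[[1]]$a_start, cc[[1]]$a_end, "+",
                 rbind(c(cc[[1]]$a_start, cc[[1]]$a_end)),
                 gene_id = "se_consA1", biotype = "candidate")
    lncrnas_b[[length(lncrnas_b) + 1L]] <-
      transcript("se_consB1", contig, cc[[1]]$b_start, cc[[1]]$b_end, "+",
                 rbind(c(cc[[1]]$b_start, cc[[1]]$b_end)),
                 gene_id = "se_consB1")
    truth <- rbind(truth, truth_row("single_exon_conserved", "se_consA1",
                                    "se_consB1", "kept", "se_consB1",
                                    "INTERGENIC", "anc"))
    contig <- next_contig()
    filler(contig)
    cc <- plant_pieces(contig, 800L, subs = 0, indels = 0,
                       b_mode = "replaced")
    candidates_a[[length(candidates_a) + 1L]] <-
      transcript("se_specA1", contig, cc[[1]]$a_start, cc[[1]]$a_end, "+",
                 rbind(c(cc[[1]]$a_start, cc[[1]]$a_end)),
                 gene_id = "se_specA1", biotype = "candidate")
    truth <- rbind(truth, truth_row("single_exon_specific", "se_specA1", NA,
                                    "removed_single_exon"))
  }

  # scattered neutral repeats (present in both sets at background rates)
  for (contig in contigs) {
    for (j in 1:4) {
      rc <- filler(contig, 2000L)
      repeats_a <- rbind(repeats_a,
                         data.frame(chrom = contig,
                                    start = rc$a_start + 500,
                                    end = rc$a_start + 800,
                                    name = if (j %% 2 == 0) "SINE" else "LINE"))
    }
  }
  for (contig in contigs) filler(contig, 30000L)

  # -- assemble genomes ------------------------------------------------------
  genome_a <- vapply(contigs, function(cc) paste(bld$a[[cc]], collapse = ""),
                     "")
  genome_b <- vapply(contigs, function(cc) paste(bld$b[[cc]], collapse = ""),
                     "")

  # fill in the pseudogene sequence now that gene1's B exons are assembled
  pin <- pseudo_info
  b_seq_parent <- genome_b[[pin$b_gene_contig]]
  mrna <- paste(vapply(seq_len(nrow(pin$b_gene_exons)), function(r) {
    seq_slice(b_seq_parent, pin$b_gene_exons[r, 1], pin$b_gene_exons[r, 2])
  }, ""), collapse = "")
  mrna_mut <- mutate_sequence(mrna, cfg$pseudo_sub, 0, ilm)$seq
  p_seq1 <- substr(mrna_mut, 1, pin$L1)
  p_seq2 <- substr(mrna_mut, pin$L1 + 1, nchar(mrna_mut))
  p_intron <- fresh_element_seq(reg, 150L)
  a_str <- genome_a[[pin$contig]]
  genome_a[[pin$contig]] <- paste0(
    substr(a_str, 1, pin$a1[1]), p_seq1, p_intron, p_seq2,
    substr(a_str, pin$a2[2] + 1, nchar(a_str)))
  stopifnot(nchar(genome_a[[pin$contig]]) == nchar(a_str))

  # -- cross-talk repair ------------------------------------------------------
  # The seeded aligner keys on exact 12-mers, and spliced junctions or
  # mutated-copy elements can still share a stray 12-mer across unrelated
  # transcripts.  Rewrite such positions (a handful of extra substitutions in
  # genome A) so that the only transcript pairs sharing any seed are the ones
  # planted to share homology; filter and ortholog outcomes on the fixture
  # are then exact consequences of the construction.
  allowed <- list(paste0("dupA", seq_len(cfg$dup_copies)),
                  c("isoA_long", "isoA_short"))
  genome_a <- repair_crosstalk(genome_a, candidates_a, allowed,
                               exclude_pattern = "^cand_cod")

  # -- chains ----------------------------------------------------------------
  chains <- list()
  for (cc in contigs) {
    ch <- ops_to_chain(bld$ops[[cc]], cc, nchar(genome_a[[cc]]),
                       nchar(genome_b[[cc]]), paste0("chain_", cc))
    if (!is.null(ch)) chains[[length(chains) + 1L]] <- ch
  }
  # paralog chain: A pseudogene locus -> B parent gene locus
  {
    b_ex <- pin$b_gene_exons
    b_lens <- b_ex[, 2] - b_ex[, 1]
    # mRNA breakpoints: B exon boundaries and the A intron insertion at L1
    brk <- sort(unique(c(0, cumsum(b_lens), pin$L1)))
    blocks <- NULL
    for (s in seq_len(length(brk) - 1L)) {
      m0 <- brk[s]; m1 <- brk[s + 1L]
      dt <- 0; dq <- 0
      if (m1 < sum(b_lens)) {
        # gap after this block: A intron if the break is at L1,
        # B intron if the break is at an exon boundary
        if (m1 == pin$L1) dt <- dt + (pin$aint[2] - pin$aint[1])
        cum <- cumsum(b_lens)
        k <- which(cum == m1)
        if (length(k) && k < length(b_lens)) {
          dq <- dq + (b_ex[k + 1L, 1] - b_ex[k, 2])
        }
      }
      blocks <- rbind(blocks, c(m1 - m0, dt, dq))
    }
    colnames(blocks) <- c("size", "dt", "dq")
    chains[[length(chains) + 1L]] <- list(
      score = sum(blocks[, "size"]),
      t_name = pin$contig, t_size = nchar(genome_a[[pin$contig]]),
      t_strand = "+", t_start = pin$a1[1],
      t_end = pin$a2[2],
      q_name = pin$b_gene_contig, q_size = nchar(genome_b[[pin$b_gene_contig]]),
      q_strand = "+", q_start = b_ex[1, 1], q_end = b_ex[nrow(b_ex), 2],
      id = "chain_pseudo_paralog", blocks = blocks)
  }
  chain_set <- structure(list(chains = chains), class = "chain_set")

  structure(list(
    genome_a = genome_a, genome_b = genome_b, chains = chain_set,
    candidates_a = candidates_a, lncrnas_b = lncrnas_b,
    coding_a = coding_a, coding_b = coding_b,
    mirna_a = mirna_a, mirna_b = mirna_b,
    snorna_a = snorna_a, snorna_b = snorna_b,
    repeats_a = repeats_a, cpg_a = cpg_a,
    known_panels = panels, tree = cfg$tree, species = cfg$species,
    truth = truth, config = cfg), class = "fixture")
}

# Map a spliced-sequence offset (0-based) of a transcript to its genomic
# position on the forward strand.
spliced_offset_to_genomic <- function(tx, off) {
  lens <- tx$exons[, 2] - tx$exons[, 1]
  total <- sum(lens)
  concat_off <- if (tx$strand == "-") total - 1 - off else off
  cum <- cumsum(c(0, lens))
  r <- findInterval(concat_off, cum, rightmost.closed = FALSE,
                    left.open = FALSE)
  tx$exons[r, 1] + (concat_off - cum[r])
}

# Remove unintended exact 12-mer sharing between candidate transcripts by
# rewriting single bases in genome A; `allowed_groups` lists id sets that are
# planted to share homology, and ids matching `exclude_pattern` are ignored
# (they never reach the all-vs-all duplication alignment).
repair_crosstalk <- function(genome_a, candidates, allowed_groups,
                             exclude_pattern = NULL, k = 12L,
                             max_rounds = 40L) {
  txs <- candidates
  if (!is.null(exclude_pattern)) {
    txs <- Filter(function(tx) !grepl(exclude_pattern, tx$id), txs)
  }
  if (length(txs) < 2L) return(genome_a)
  group_of <- setNames(vapply(txs, `[[`, "", "id"),
                       vapply(txs, `[[`, "", "id"))
  for (g in seq_along(allowed_groups)) {
    ids <- allowed_groups[[g]]
    group_of[ids[ids %in% names(group_of)]] <- paste0("grp", g)
  }
  cycle <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  for (round in seq_len(max_rounds)) {
    seqs <- vapply(txs, function(tx) tx_spliced_seq(genome_a, tx), "")
    index <- new.env(parent = emptyenv(), hash = TRUE)
    clashes <- list()
    for (i in seq_along(txs)) {
      kms <- kmers_of(seqs[i], k)
      for (o in seq_along(kms)) {
        km <- kms[o]
        prev <- index[[km]]
        if (is.null(prev)) {
          assign(km, c(i, o - 1L), envir = index)
        } else if (group_of[[txs[[prev[1]]]$id]] != group_of[[txs[[i]]$id]]) {
          clashes[[length(clashes) + 1L]] <- c(i, o - 1L)
        }
      }
    }
    if (length(clashes) == 0L) return(genome_a)
    flip_at <- unique(vapply(clashes, function(cl) {
      tx <- txs[[cl[1]]]
      pos <- spliced_offset_to_genomic(tx, cl[2] + (k %/% 2L))
      paste(tx$chrom, pos)
    }, ""))
    for (key in flip_at) {
      parts <- strsplit(key, " ")[[1]]
      chrom <- parts[1]; pos <- as.numeric(parts[2])
      base <- substr(genome_a[[chrom]], pos + 1, pos + 1)
      substr(genome_a[[chrom]], pos + 1, pos + 1) <- cycle[[base]]
    }
  }
  warning("cross-talk repair did not converge in ", max_rounds, " rounds")
  genome_a
}

#' Write a fixture to a directory of plain-text files
#'
#' @param fx A `fixture` from [plant_genome_pair()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(fx$genome_a, p("genome_a.fa"))
  write_fasta(fx$genome_b, p("genome_b.fa"))
  write_chain(fx$chains, p("a_to_b.chain"))
  write_bed12(fx$candidates_a, p("candidates_a.bed"))
  write_bed12(fx$lncrnas_b, p("lncrnas_b.bed"))
  write_bed12(fx$coding_a, p("coding_a.bed"))
  write_bed12(fx$coding_b, p("coding_b.bed"))
  for (nm in c("mirna_a", "mirna_b", "snorna_a", "snorna_b", "repeats_a",
               "cpg_a")) {
    df <- fx[[nm]]
    if (is.null(df)) df <- data.frame(chrom = character(0),
                                      start = numeric(0), end = numeric(0))
    write_bed6(df, p(paste0(nm, ".bed")))
  }
  write_fasta(fx$known_panels, p("known_panels.fa"))
  writeLines(fx$tree, p("tree.nwk"))
  write.table(fx$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(fx$truth, p("truth.json"), dataframe = "rows",
                       na = "null")
  invisible(dir)
}

#' Synthetic promoter fixture for repeat-enrichment testing
#'
#' One random genome with `n_promoters` anchor transcripts; an ERVK-like
#' family is planted in `frac_planted` of the promoter windows and nowhere
#' else, while neutral families (SINE/LINE) are scattered uniformly so they
#' appear in promoters and intergenic background at comparable rates.
#'
#' @param n_promoters Number of anchor transcripts.
#' @param frac_planted Fraction of promoters containing the planted family.
#' @param rng_seed Integer seed.
#' @return List with `genome`, `txs`, `repeat_bed`, `planted_family`.
#' @export
plant_promoter_fixture <- function(n_promoters = 60L, frac_planted = 0.35,
                                   rng_seed = 1L) {
  with_seed(rng_seed, {
    glen <- 1200000L
    genome <- c(chr1 = random_dna(glen))
    spacing <- floor(glen / (n_promoters + 2L))
    txs <- lapply(seq_len(n_promoters), function(i) {
      st <- i * spacing
      transcript(paste0("p", i), "chr1", st, st + 200, "+",
                 rbind(c(st, st + 200)))
    })
    planted <- sort(sample.int(n_promoters, round(frac_planted * n_promoters)))
    rep_bed <- NULL
    for (i in planted) {
      st <- txs[[i]]$start - 400
      rep_bed <- rbind(rep_bed, data.frame(chrom = "chr1", start = st,
                                           end = st + 300, name = "ERVK"))
    }
    # neutral families scattered uniformly (promoters and background alike)
    for (fam in c("SINE", "LINE")) {
      pos <- sort(floor(runif(60L) * (glen - 400)))
      rep_bed <- rbind(rep_bed, data.frame(chrom = "chr1", start = pos,
                                           end = pos + 300, name = fam))
    }
    list(genome = genome, txs = txs, repeat_bed = rep_bed,
         planted_family = "ERVK")
  })
}
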