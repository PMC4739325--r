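# Genome, transcript and chain I/O: the formats the pipeline touches and the
# coordinate model every other module builds on.

#' Construct a transcript model
#'
#' A stranded, multi-exon gene model on a named contig with BED12 semantics.
#' Exons are stored as a two-column matrix of 0-based half-open `[start, end)`
#' rows, sorted, non-overlapping, with the first exon starting at the
#' transcript start and the last exon ending at the transcript end.
#'
#' @param id Transcript identifier (unique within a set).
#' @param chrom Contig name.
#' @param start,end Genomic span (0-based half-open).
#' @param strand `"+"` or `"-"` (`"."` allowed for unstranded features).
#' @param exons Two-column numeric matrix of exon `[start, end)` rows.
#' @param gene_id Optional gene identifier; defaults to `id`.
#' @param biotype Optional tag such as `"coding"`, `"candidate"`.
#' @return A `transcript` object.
#' @export
transcript <- function(id, chrom, start, end, strand, exons,
                       gene_id = id, biotype = NA_character_) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  tx <- structure(list(id = id, gene_id = gene_id, chrom = chrom,
                       start = as.numeric(start), end = as.numeric(end),
                       strand = strand, exons = exons, biotype = biotype),
                  class = "transcript")
  validate_transcript(tx)
  tx
}

validate_transcript <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 1L) stop("transcript ", tx$id, ": needs >= 1 exon")
  if (any(ex[, 1] >= ex[, 2])) stop("transcript ", tx$id, ": empty exon")
  if (is.unsorted(ex[, 1], strictly = TRUE) && nrow(ex) > 1L) {
    stop("transcript ", tx$id, ": exons not sorted by start")
  }
  if (nrow(ex) > 1L && any(ex[-nrow(ex), 2] > ex[-1L, 1])) {
    stop("transcript ", tx$id, ": overlapping exons")
  }
  if (ex[1L, 1] != tx$start || ex[nrow(ex), 2] != tx$end) {
    stop("transcript ", tx$id, ": exon footprint does not match span")
  }
  if (!tx$strand %in% c("+", "-", ".")) stop("transcript ", tx$id, ": bad strand")
  invisible(tx)
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s %s:%d-%d(%s) %d exon(s), %d exonic bp>\n",
              x$id, x$chrom, x$start, x$end, x$strand, nrow(x$exons),
              exonic_length(x)))
  invisible(x)
}

#' Exonic length of a transcript (sum of exon sizes)
#' @param tx A `transcript`.
#' @return Total exonic base pairs.
#' @export
exonic_length <- function(tx) sum(tx$exons[, 2] - tx$exons[, 1])

#' Internal splice junctions of a transcript
#'
#' Each intron contributes one junction, reported as its donor/acceptor
#' genomic positions `(intron start, intron end)` in 0-based half-open
#' coordinates.
#'
#' @param tx A `transcript`.
#' @return Matrix with columns `donor`, `acceptor` (genomic coordinates; for
#'   minus-strand transcripts the biological donor is the `acceptor` column).
#' @export
tx_junctions <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2L) {
    return(cbind(donor = numeric(0), acceptor = numeric(0)))
  }
  cbind(donor = ex[-nrow(ex), 2], acceptor = ex[-1L, 1])
}

#' Read a FASTA file into a genome
#'
#' Sequences are uppercased, `U` is mapped to `T`, and every character outside
#' `{A,C,G,T,N}` becomes `N` (which never counts as a match in any identity
#' computation downstream).
#'
#' @param path FASTA file.
#' @return Named character vector of contig sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1])
  }
  if (any(nm == "")) stop("empty FASTA header in ", path)
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  seqs <- gsub("[^ACGTN]", "N", seqs)
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for contig ", nm[nchar(seqs) == 0L][1])
  }
  names(seqs) <- nm
  seqs
}

#' Write a genome to FASTA
#' @param genome Named character vector of sequences.
#' @param path Output file.
#' @param width Line width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read transcripts from a BED12 file
#'
#' @param path BED12 file (12 whitespace-separated columns).
#' @return List of [transcript()] objects.
#' @export
read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  txs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) < 12L) {
      stop("BED12 parse error at line ", i, ": expected 12 columns, got ",
           length(f))
    }
    chrom <- f[1]; start <- as.numeric(f[2]); end <- as.numeric(f[3])
    id <- f[4]; strand <- f[6]
    n_blocks <- as.integer(f[10])
    sizes <- as.numeric(strsplit(f[11], ",")[[1]])
    offs <- as.numeric(strsplit(f[12], ",")[[1]])
    if (length(sizes) != n_blocks || length(offs) != n_blocks) {
      stop("BED12 parse error at line ", i, ": blockCount=", n_blocks,
           " but ", length(sizes), " sizes / ", length(offs), " starts listed")
    }
    ex_start <- start + offs
    ex_end <- ex_start + sizes
    if (any(ex_start < start) || any(ex_end > end)) {
      stop("BED12 parse error at line ", i, ": block outside [chromStart, chromEnd)")
    }
    txs[[i]] <- transcript(id = id, chrom = chrom, start = start, end = end,
                           strand = strand, exons = cbind(ex_start, ex_end))
  }
  txs
}

#' Write transcripts to BED12
#'
#' Inverse of [read_bed12()] on canonical records.  Output is deterministically
#' ordered by (chrom, start, id).
#'
#' @param txs List of transcripts.
#' @param path Output file.
#' @param name_suffix Optional character vector (same length as `txs`) appended
#'   to each name with `"|"`, e.g. to carry a filter fate.
#' @export
write_bed12 <- function(txs, path, name_suffix = NULL) {
  if (length(txs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  o <- order(vapply(txs, `[[`, "", "chrom"),
             vapply(txs, `[[`, 0, "start"),
             vapply(txs, `[[`, "", "id"))
  txs <- txs[o]
  if (!is.null(name_suffix)) name_suffix <- name_suffix[o]
  lines <- vapply(seq_along(txs), function(i) {
    tx <- txs[[i]]
    nm <- if (is.null(name_suffix)) tx$id else paste0(tx$id, "|", name_suffix[i])
    sizes <- paste0(paste(format(tx$exons[, 2] - tx$exons[, 1],
                                 scientific = FALSE, trim = TRUE),
                          collapse = ","), ",")
    offs <- paste0(paste(format(tx$exons[, 1] - tx$start,
                                scientific = FALSE, trim = TRUE),
                         collapse = ","), ",")
    paste(tx$chrom, format(tx$start, scientific = FALSE),
          format(tx$end, scientific = FALSE), nm, 0, tx$strand,
          format(tx$start, scientific = FALSE),
          format(tx$end, scientific = FALSE), 0, nrow(tx$exons), sizes, offs,
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 annotation track
#' @param path BED file with at least 3 columns (name/score/strand optional).
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  }
  f <- do.call(rbind, strsplit(lines, "[ \t]+"))
  data.frame(
    chrom = f[, 1], start = as.numeric(f[, 2]), end = as.numeric(f[, 3]),
    name = if (ncol(f) >= 4) f[, 4] else ".",
    score = if (ncol(f) >= 5) suppressWarnings(as.numeric(f[, 5])) else 0,
    strand = if (ncol(f) >= 6) f[, 6] else ".",
    stringsAsFactors = FALSE)
}

#' Write a BED6 track
#' @param df data.frame with chrom/start/end and optionally name/score/strand.
#' @param path Output file.
#' @export
write_bed6 <- function(df, path) {
  if (nrow(df) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  nm <- if ("name" %in% names(df)) df$name else "."
  sc <- if ("score" %in% names(df)) df$score else 0
  st <- if ("strand" %in% names(df)) df$strand else "."
  o <- order(df$chrom, df$start)
  lines <- paste(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                 format(df$end, scientific = FALSE, trim = TRUE),
                 nm, sc, st, sep = "\t")[o]
  writeLines(lines, path)
  invisible(path)
}

#' Read transcripts from a GTF file
#'
#' Only `exon` features are used; 1-based closed coordinates are converted to
#' the package's 0-based half-open convention at parse time, so a GTF record
#' round-trips losslessly through BED12.
#'
#' @param path GTF file.
#' @return List of [transcript()] objects.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t")
  keep <- vapply(f, function(x) length(x) >= 9 && x[3] == "exon", TRUE)
  f <- f[keep]
  if (length(f) == 0L) return(list())
  get_attr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, ' "([^"]+)"'), attrs))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  recs <- lapply(f, function(x) {
    list(chrom = x[1], start = as.numeric(x[4]) - 1, end = as.numeric(x[5]),
         strand = x[7], tx_id = get_attr(x[9], "transcript_id"),
         gene_id = get_attr(x[9], "gene_id"))
  })
  ids <- vapply(recs, `[[`, "", "tx_id")
  lapply(split(recs, ids), function(rr) {
    ex <- cbind(vapply(rr, `[[`, 0, "start"), vapply(rr, `[[`, 0, "end"))
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    transcript(id = rr[[1]]$tx_id, chrom = rr[[1]]$chrom,
               start = min(ex[, 1]), end = max(ex[, 2]),
               strand = rr[[1]]$strand, exons = ex,
               gene_id = rr[[1]]$gene_id)
  })
}

# ---- UCSC chain format ------------------------------------------------------

#' Read a UCSC chain file
#'
#' Each chain maps blocks of the *target* genome onto the *query* genome.
#' Block arithmetic (sizes plus gaps summing to the declared spans) is
#' validated; a mismatch is an error naming the chain id.
#'
#' @param path Chain file.
#' @return A `chain_set`: list of chains, each with header fields and a
#'   `blocks` matrix (`size`, `dt`, `dq`).
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (!startsWith(ln, "chain")) stop("chain parse error at line ", i)
    h <- strsplit(ln, "[ \t]+")[[1]]
    if (length(h) < 13L) stop("chain header with too few fields at line ", i)
    ch <- list(score = as.numeric(h[2]),
               t_name = h[3], t_size = as.numeric(h[4]), t_strand = h[5],
               t_start = as.numeric(h[6]), t_end = as.numeric(h[7]),
               q_name = h[8], q_size = as.numeric(h[9]), q_strand = h[10],
               q_start = as.numeric(h[11]), q_end = as.numeric(h[12]),
               id = h[13])
    if (ch$t_strand != "+") stop("chain ", ch$id, ": target strand must be +")
    blocks <- NULL
    i <- i + 1L
    repeat {
      if (i > length(lines)) stop("chain ", ch$id, ": truncated block list")
      bl <- trimws(lines[i])
      i <- i + 1L
      if (!nzchar(bl)) next
      bf <- as.numeric(strsplit(bl, "[ \t]+")[[1]])
      if (length(bf) == 3L) {
        blocks <- rbind(blocks, bf)
      } else if (length(bf) == 1L) {
        blocks <- rbind(blocks, c(bf, 0, 0))
        break
      } else stop("chain ", ch$id, ": malformed block line")
    }
    colnames(blocks) <- c("size", "dt", "dq")
    rownames(blocks) <- NULL
    if (any(blocks[, "size"] < 1)) stop("chain ", ch$id, ": aligned block size < 1")
    t_span <- sum(blocks[, "size"]) + sum(blocks[, "dt"])
    q_span <- sum(blocks[, "size"]) + sum(blocks[, "dq"])
    if (t_span != ch$t_end - ch$t_start || q_span != ch$q_end - ch$q_start) {
      stop("chain ", ch$id, ": block sizes do not sum to declared spans")
    }
    ch$blocks <- blocks
    chains[[length(chains) + 1L]] <- ch
  }
  structure(list(chains = chains), class = "chain_set")
}

#' Write a chain set to a UCSC chain file
#' @param chain_set A `chain_set`.
#' @param path Output file.
#' @export
write_chain <- function(chain_set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chain_set$chains) {
    writeLines(paste("chain", format(ch$score, scientific = FALSE),
                     ch$t_name, format(ch$t_size, scientific = FALSE),
                     ch$t_strand,
                     format(ch$t_start, scientific = FALSE),
                     format(ch$t_end, scientific = FALSE),
                     ch$q_name, format(ch$q_size, scientific = FALSE),
                     ch$q_strand,
                     format(ch$q_start, scientific = FALSE),
                     format(ch$q_end, scientific = FALSE), ch$id), con)
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1L) {
      writeLines(paste(format(b[-n, "size"], scientific = FALSE, trim = TRUE),
                       format(b[-n, "dt"], scientific = FALSE, trim = TRUE),
                       format(b[-n, "dq"], scientific = FALSE, trim = TRUE)),
                 con)
    }
    writeLines(format(b[n, "size"], scientific = FALSE, trim = TRUE), con)
    writeLines("", con)
  }
  invisible(path)
}

# Per-chain normalized block table on forward coordinates of both genomes.
# Returns matrix columns: t_start, t_end, q_fwd_start, q_fwd_end.
chain_block_table <- function(ch) {
  b <- ch$blocks
  sizes <- b[, "size"]
  t_starts <- ch$t_start + cumsum(c(0, head(sizes + b[, "dt"], -1)))
  q_pos <- ch$q_start + cumsum(c(0, head(sizes + b[, "dq"], -1)))
  t_ends <- t_starts + sizes
  q_ends <- q_pos + sizes
  if (ch$q_strand == "-") {
    # chain query coords are on the reversed strand; convert to forward
    q_fwd_start <- ch$q_size - q_ends
    q_fwd_end <- ch$q_size - q_pos
  } else {
    q_fwd_start <- q_pos
    q_fwd_end <- q_ends
  }
  cbind(t_start = t_starts, t_end = t_ends,
        q_fwd_start = q_fwd_start, q_fwd_end = q_fwd_end)
}

#' Invert a chain set (swap target and query genomes)
#'
#' Lifting from genome B to genome A uses the inversion of an A-to-B chain
#' set.
#'
#' @param chain_set A `chain_set`.
#' @return A `chain_set` with target and query roles swapped.
#' @export
invert_chain_set <- function(chain_set) {
  inv <- lapply(chain_set$chains, function(ch) {
    b <- ch$blocks
    if (ch$q_strand == "-") {
      # After swapping, the old query becomes the new (forward-strand)
      # target; the old target is then carried on the minus strand.
      tab <- chain_block_table(ch)
      o <- order(tab[, "q_fwd_start"])
      tab <- tab[o, , drop = FALSE]
      sizes <- tab[, "q_fwd_end"] - tab[, "q_fwd_start"]
      dts <- c(tab[-1, "q_fwd_start"] - tab[-nrow(tab), "q_fwd_end"], 0)
      # old target coords walk backwards on the new minus strand:
      # express them on the reversed strand of the new query
      nt_start <- ch$t_size - tab[, "t_end"]
      dqs <- c(nt_start[-1] - (nt_start[-nrow(tab)] + sizes[-nrow(tab)]), 0)
      blocks <- cbind(size = sizes, dt = dts, dq = dqs)
      list(score = ch$score,
           t_name = ch$q_name, t_size = ch$q_size, t_strand = "+",
           t_start = tab[1, "q_fwd_start"], t_end = tab[nrow(tab), "q_fwd_end"],
           q_name = ch$t_name, q_size = ch$t_size, q_strand = "-",
           q_start = nt_start[1], q_end = nt_start[nrow(tab)] + sizes[nrow(tab)],
           id = ch$id, blocks = blocks)
    } else {
      blocks <- cbind(size = b[, "size"], dt = b[, "dq"], dq = b[, "dt"])
      list(score = ch$score,
           t_name = ch$q_name, t_size = ch$q_size, t_strand = "+",
           t_start = ch$q_start, t_end = ch$q_end,
           q_name = ch$t_name, q_size = ch$t_size, q_strand = "+",
           q_start = ch$t_start, q_end = ch$t_end,
           id = ch$id, blocks = blocks)
    }
  })
  structure(list(chains = inv), class = "chain_set")
}

# ---- sequence extraction ----------------------------------------------------

#' Spliced (exonic) sequence of a transcript
#'
#' Concatenates exon sequences 5' to 3' (reverse-complemented for minus-strand
#' transcripts).
#'
#' @param genome Named character vector from [read_fasta()].
#' @param tx A `transcript`.
#' @return DNA string.
#' @export
tx_spliced_seq <- function(genome, tx) {
  s <- genome[[tx$chrom]]
  if (is.null(s) || is.na(s)) stop("contig ", tx$chrom, " not in genome")
  parts <- apply(tx$exons, 1L, function(e) seq_slice(s, e[1], e[2]))
  joined <- paste(parts, collapse = "")
  if (tx$strand == "-") revcomp(joined) else joined
}

#' Unspliced genomic span sequence of a transcript (forward strand)
#' @param genome Named character vector.
#' @param tx A `transcript`.
#' @return DNA string covering `[start, end)` on the forward strand.
#' @export
tx_span_seq <- function(genome, tx) {
  s <- genome[[tx$chrom]]
  if (is.null(s) || is.na(s)) stop("contig ", tx$chrom, " not in genome")
  seq_slice(s, tx$start, tx$end)
}

# GRanges of transcript exons (for overlap queries)
txs_exon_granges <- function(txs) {
  if (length(txs) == 0L) {
    return(GenomicRanges::GRanges())
  }
  n_ex <- vapply(txs, function(tx) nrow(tx$exons), 0L)
  chrom <- rep(vapply(txs, `[[`, "", "chrom"), n_ex)
  strand <- rep(vapply(txs, `[[`, "", "strand"), n_ex)
  strand[strand == "."] <- "*"
  starts <- unlist(lapply(txs, function(tx) tx$exons[, 1]))
  ends <- unlist(lapply(txs, function(tx) tx$exons[, 2]))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts + 1, end = ends),
    strand = strand)
  gr$tx_index <- rep(seq_along(txs), n_ex)
  gr
}

# GRanges of transcript spans
txs_span_granges <- function(txs) {
  if (length(txs) == 0L) return(GenomicRanges::GRanges())
  strand <- vapply(txs, `[[`, "", "strand")
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(txs, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(start = vapply(txs, `[[`, 0, "start") + 1,
                              end = vapply(txs, `[[`, 0, "end")),
    strand = strand)
  gr$tx_index <- seq_along(txs)
  gr
}
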