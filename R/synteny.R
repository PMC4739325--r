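# Mapping intervals and transcripts between genomes through alignment chains,
# and padded syntenic windows for the ortholog search.

#' Lift an interval through a chain set
#'
#' Source base pairs inside aligned chain blocks are mapped block by block
#' onto the other genome.  A mapping is emitted only when the mapped fraction
#' of the source interval reaches `min_match`; with `multiple = FALSE` only
#' the best-covering chain is used (ties broken by chain score, then id).
#' Strand flips when the chain's query strand is minus.
#'
#' @param chain_set A `chain_set` from [read_chain()].
#' @param iv A [genomic_interval()] on the chain target genome.
#' @param min_match Minimum fraction of source bp that must map.
#' @param multiple Report mappings from all qualifying chains?
#' @return A `lift_result`: list with `source`, `mapped` (data.frame `chrom`,
#'   `start`, `end`, `strand`), `mapped_fraction`, `chain_id`.  Unmappable
#'   input yields an empty `mapped` and fraction 0.
#' @export
lift_interval <- function(chain_set, iv, min_match = 0.1, multiple = FALSE) {
  width <- iv_width(iv)
  per_chain <- list()
  for (ch in chain_set$chains) {
    if (ch$t_name != iv$chrom) next
    if (ch$t_end <= iv$start || ch$t_start >= iv$end) next
    tab <- chain_block_table(ch)
    hits <- NULL
    covered <- 0
    for (r in seq_len(nrow(tab))) {
      ov_s <- max(tab[r, "t_start"], iv$start)
      ov_e <- min(tab[r, "t_end"], iv$end)
      if (ov_s >= ov_e) next
      covered <- covered + (ov_e - ov_s)
      if (ch$q_strand == "-") {
        q_s <- tab[r, "q_fwd_start"] + (tab[r, "t_end"] - ov_e)
        q_e <- tab[r, "q_fwd_end"] - (ov_s - tab[r, "t_start"])
      } else {
        q_s <- tab[r, "q_fwd_start"] + (ov_s - tab[r, "t_start"])
        q_e <- q_s + (ov_e - ov_s)
      }
      hits <- rbind(hits, data.frame(chrom = ch$q_name, start = q_s, end = q_e))
    }
    frac <- covered / width
    if (!is.null(hits) && frac >= min_match) {
      runs <- merge_runs(hits$start, hits$end)
      strand <- if (iv$strand == ".") "." else {
        if (ch$q_strand == "-") chartr("+-", "-+", iv$strand) else iv$strand
      }
      mapped <- data.frame(chrom = ch$q_name, start = runs[, "start"],
                           end = runs[, "end"], strand = strand)
      per_chain[[length(per_chain) + 1L]] <- list(
        mapped = mapped, fraction = frac, score = ch$score, id = ch$id)
    }
  }
  empty <- list(source = iv,
                mapped = data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0), strand = character(0)),
                mapped_fraction = 0, chain_id = NA_character_)
  class(empty) <- "lift_result"
  if (length(per_chain) == 0L) return(empty)
  o <- order(-vapply(per_chain, `[[`, 0, "fraction"),
             -vapply(per_chain, `[[`, 0, "score"),
             vapply(per_chain, `[[`, "", "id"))
  per_chain <- per_chain[o]
  if (!multiple) per_chain <- per_chain[1L]
  res <- list(source = iv,
              mapped = do.call(rbind, lapply(per_chain, `[[`, "mapped")),
              mapped_fraction = per_chain[[1L]]$fraction,
              chain_id = per_chain[[1L]]$id)
  class(res) <- "lift_result"
  res
}

#' Lift a transcript's exonic footprint through a chain set
#'
#' Exons are lifted independently and their images unioned on the target
#' genome; the mapped fraction is computed over exonic bp (the conservative
#' reading of lifting a gene model).
#'
#' @param chain_set A `chain_set`.
#' @param tx A `transcript`.
#' @param min_match Minimum mapped fraction of exonic bp.
#' @return A `lift_result` over the exonic footprint.
#' @export
lift_transcript <- function(chain_set, tx, min_match = 0.1) {
  total <- exonic_length(tx)
  mapped_bp <- 0
  pieces <- NULL
  chain_id <- NA_character_
  for (r in seq_len(nrow(tx$exons))) {
    iv <- genomic_interval(tx$chrom, tx$exons[r, 1], tx$exons[r, 2], tx$strand)
    lr <- lift_interval(chain_set, iv, min_match = 0, multiple = FALSE)
    if (nrow(lr$mapped) > 0L) {
      mapped_bp <- mapped_bp + lr$mapped_fraction * iv_width(iv)
      pieces <- rbind(pieces, lr$mapped)
      if (is.na(chain_id)) chain_id <- lr$chain_id
    }
  }
  frac <- mapped_bp / total
  res <- list(source = genomic_interval(tx$chrom, tx$start, tx$end, tx$strand),
              mapped = data.frame(chrom = character(0), start = numeric(0),
                                  end = numeric(0), strand = character(0)),
              mapped_fraction = frac, chain_id = chain_id)
  if (!is.null(pieces) && frac >= min_match) {
    # union per chrom/strand
    out <- NULL
    for (key in unique(paste(pieces$chrom, pieces$strand))) {
      sel <- paste(pieces$chrom, pieces$strand) == key
      runs <- merge_runs(pieces$start[sel], pieces$end[sel])
      out <- rbind(out, data.frame(chrom = pieces$chrom[sel][1],
                                   start = runs[, "start"],
                                   end = runs[, "end"],
                                   strand = pieces$strand[sel][1]))
    }
    res$mapped <- out
  } else {
    res$mapped_fraction <- if (frac >= min_match) frac else frac
  }
  class(res) <- "lift_result"
  res
}

#' Padded syntenic window for a transcript
#'
#' The target-genome span of the lifted exonic footprint, extended by `pad`
#' bp on both sides and clipped to contig bounds.  The pad is chosen so the
#' window typically captures easily-alignable flanking genes that anchor the
#' locus alignment.
#'
#' @param chain_set A `chain_set`.
#' @param tx A `transcript`.
#' @param pad Padding in bp (default 150000; a relaxed distant-species preset
#'   would use 500000 with `min_match = 0.01`).
#' @param genome Optional target genome used to clip to contig bounds.
#' @param min_match Passed to [lift_transcript()].
#' @return A [genomic_interval()] or `NULL` when the transcript is
#'   unmappable.
#' @export
syntenic_window <- function(chain_set, tx, pad = 150000, genome = NULL,
                            min_match = 0.1) {
  lr <- lift_transcript(chain_set, tx, min_match = min_match)
  if (nrow(lr$mapped) == 0L) return(NULL)
  chroms <- unique(lr$mapped$chrom)
  # windows live on one contig; with multi-contig mappings take the one
  # holding the most mapped bp
  if (length(chroms) > 1L) {
    bp <- vapply(chroms, function(cc) {
      sel <- lr$mapped$chrom == cc
      sum(lr$mapped$end[sel] - lr$mapped$start[sel])
    }, 0)
    chroms <- chroms[which.max(bp)]
  }
  sel <- lr$mapped$chrom == chroms
  lo <- max(0, min(lr$mapped$start[sel]) - pad)
  hi <- max(lr$mapped$end[sel]) + pad
  if (!is.null(genome) && chroms %in% names(genome)) {
    hi <- min(hi, nchar(genome[[chroms]]))
  }
  genomic_interval(chroms, lo, hi, lr$mapped$strand[sel][1])
}
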