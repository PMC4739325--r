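# Internal helpers: seeded RNG scoping, interval arithmetic, sequence utilities.

# Derive a reproducible child seed from a parent seed and a stage label.
# Keeps every derived seed strictly below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629 + 1)
}

# Evaluate expr with a locally-set RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483629))
  expr
}

#' Create a genomic interval
#'
#' Intervals are 0-based half-open, the package-wide convention.
#'
#' @param chrom Contig name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @return A `genomic_interval` list.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), nchar(chrom) > 0L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start >= 0 && start < end)) {
    stop("invalid interval [", start, ", ", end, ") on ", chrom)
  }
  if (!strand %in% c("+", "-", ".")) stop("strand must be one of +, -, .")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

iv_width <- function(iv) iv$end - iv$start

# bp overlap of two [start,end) pairs
overlap_bp <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

# Merge a data.frame/matrix-like set of (start, end) rows into disjoint runs.
merge_runs <- function(starts, ends) {
  if (length(starts) == 0L) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

# reverse complement of an ACGTN string
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

gc_fraction <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(NA_real_)
  gc <- sum(strsplit(s, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  gc / n
}

# 0-based substring: sequence of [start, end)
seq_slice <- function(seq, start, end) substr(seq, start + 1, end)
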