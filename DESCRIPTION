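Package: lncevo
Title: Filtering and Comparative Evolutionary Analysis of Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A toolkit for deriving high-confidence long non-coding RNA
    (lncRNA) catalogs from transcript annotations and for scoring their
    evolution across a pair of genomes. Implements a stringent three-step
    filter (coding-gene overlap, duplication-cluster detection against
    empirical intergenic nulls, and a learned syntenic-coding identity
    threshold), detection of conserved open reading frames by Nei-Gojobori
    dN/dS with length-binned empirical significance, sensitive seed-and-extend
    local alignment of syntenic lncRNA loci with shuffled-intergenic null
    calibration, transcript-evolution metrics (transcript-genome identity,
    transcript-transcript identity, splice-site conservation, exon/intron
    indel rate), Fitch-parsimony ancestral presence assignment on a species
    tree, two-component Gaussian mixture classification of ortholog identity,
    and promoter repeat/CpG enrichment statistics against GC-matched
    intergenic backgrounds. Ships a synthetic genome-pair generator with a
    planted, machine-readable ground truth so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
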