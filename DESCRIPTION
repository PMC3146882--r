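Package: uORFindels
Title: Selective Constraint on Indel Sizes in 5'UTRs with Upstream ORFs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies upstream open reading frames (uORFs) in mammalian
    5'UTRs, catalogues insertions and deletions from pairwise genomic
    alignments, and tests whether frame-shifting (non-3n) indels are
    selectively depleted downstream of upstream AUGs. The central statistic
    is the Indel Selection Index (ISI), the proportion of positionally
    shuffled indel configurations whose log ratio-of-ratios R falls below
    the observed value; uORF-bearing transcript groups are compared with a
    matched neutral reference built from uAUG-free transcripts via
    Mann-Whitney U tests, a tertile analysis of uAUG position, and a
    size-equalising bootstrap. A synthetic-evolution generator emits
    complete FASTA/GTF/MAF inputs with known ground truth so that every
    pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
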