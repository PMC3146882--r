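# Transcript loading, isoform selection and ortholog pairing.

test_that("a plus-strand toy transcript round-trips through GTF+FASTA", {
  dir <- withr::local_tempdir()
  utr <- "CCATGAAATAACC"                       # 13 nt
  gene <- paste0(utr, TOY_CDS)
  seqstr <- paste0("AAACCCGGGT", gene, "ACGTACGT") # gene at 0-based 10
  files <- writeToyAnnotation(dir, seqstr, list(list(
    gene = "g1", tx = "t1", strand = "+",
    exons = data.frame(start1 = 11L, end1 = 10L + nchar(gene)),
    cds = data.frame(start1 = 11L + 13L, end1 = 10L + nchar(gene)))))
  txs <- loadTranscripts(files$gtf, files$fasta, "sp", verbose = FALSE)
  expect_length(txs, 1L)
  expect_identical(tisOffset(txs[[1]]), 13L)
  expect_identical(as.character(utr5Seq(txs[[1]])), utr)
  expect_identical(as.character(cdsSeq(txs[[1]])), TOY_CDS)
})

test_that("a CDS that does not start at an ATG is excluded as misannotated", {
  dir <- withr::local_tempdir()
  utr <- "CCATGAAATAACC"
  gene <- paste0(utr, TOY_CDS)
  seqstr <- paste0("AAACCCGGGT", gene)
  files <- writeToyAnnotation(dir, seqstr, list(list(
    gene = "g1", tx = "t1", strand = "+",
    exons = data.frame(start1 = 11L, end1 = 10L + nchar(gene)),
    # CDS shifted one base: starts at "TGG...", not ATG
    cds = data.frame(start1 = 11L + 14L, end1 = 10L + nchar(gene)))))
  expect_message(
    txs <- loadTranscripts(files$gtf, files$fasta, "sp"),
    "misannotated")
  expect_length(txs, 0L)
})

test_that("a minus-strand embedding yields the same transcript sequences", {
  dir <- withr::local_tempdir()
  utr <- "CCATGAAATAACC"
  gene <- paste0(utr, TOY_CDS)
  flankL <- "AAACCCGGGT"; flankR <- "ACGTACGT"
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  seqstr <- paste0(rc(flankR), rc(gene), rc(flankL))
  gStart1 <- nchar(flankR) + 1L                 # 1-based start of rc(gene)
  gEnd1 <- nchar(flankR) + nchar(gene)
  # CDS occupies the transcript 3' end = genomic left end on minus strand
  files <- writeToyAnnotation(dir, seqstr, list(list(
    gene = "g1", tx = "t1", strand = "-",
    exons = data.frame(start1 = gStart1, end1 = gEnd1),
    cds = data.frame(start1 = gStart1, end1 = gEnd1 - 13L))))
  txs <- loadTranscripts(files$gtf, files$fasta, "sp", verbose = FALSE)
  expect_length(txs, 1L)
  expect_identical(as.character(utr5Seq(txs[[1]])), utr)
  expect_identical(as.character(cdsSeq(txs[[1]])), TOY_CDS)
  expect_identical(tisOffset(txs[[1]]), 13L)
})

test_that("a missing chromosome in the FASTA is a hard error naming it", {
  dir <- withr::local_tempdir()
  gene <- paste0("CCCCC", TOY_CDS)
  files <- writeToyAnnotation(dir, gene, list(list(
    gene = "g1", tx = "t1", strand = "+",
    exons = data.frame(start1 = 1L, end1 = nchar(gene)),
    cds = data.frame(start1 = 6L, end1 = nchar(gene)))),
    chrom = "chrMissing")
  writeLines(c(">chrOther", gene), files$fasta)
  expect_error(loadTranscripts(files$gtf, files$fasta, "sp",
                               verbose = FALSE), "chrMissing")
})

test_that("longest_utr selection takes the longest 5'UTR with ID tie-break", {
  tx40 <- toyTx(strrep("C", 40), id = "tB")
  tx100 <- toyTx(strrep("C", 100), id = "tA")
  gene <- buildGeneIsoformSets(list(tx40, tx100))[[1]]
  expect_identical(transcriptId(selectTranscript(gene, "longest_utr")), "tA")
  txTie <- toyTx(strrep("C", 100), id = "tZ")
  gene2 <- buildGeneIsoformSets(list(txTie, tx100))[[1]]
  expect_identical(transcriptId(selectTranscript(gene2, "longest_utr")), "tA")
})

test_that("random selection is seed-reproducible and near-uniform", {
  txA <- toyTx(strrep("C", 40), id = "tA")
  txB <- toyTx(strrep("C", 60), id = "tB")
  gene <- buildGeneIsoformSets(list(txA, txB))[[1]]
  pick1 <- transcriptId(selectTranscript(gene, "random", seed = 7L))
  pick2 <- transcriptId(selectTranscript(gene, "random", seed = 7L))
  expect_identical(pick1, pick2)
  set.seed(1)
  picks <- vapply(sample.int(1e6, 10000L), function(s)
    transcriptId(selectTranscript(gene, "random", seed = s)), character(1))
  expect_true(abs(mean(picks == "tA") - 0.5) < 0.02)
})

test_that("pure_utr returns only isoforms whose UTR avoids other CDS", {
  # isoform A: long UTR whose genomic footprint contains B's CDS start
  txA <- toyTx(strrep("C", 60), id = "tA", genomicStart = 0L)
  # isoform B: starts downstream; its UTR [40,50) precedes its CDS
  txB <- toyTx(strrep("C", 10), id = "tB", genomicStart = 40L)
  gene <- buildGeneIsoformSets(list(txA, txB))[[1]]
  sel <- selectTranscript(gene, "pure_utr")
  # independent brute-force interval check
  utrOf <- function(tx) {
    st <- IRanges::start(exons(tx)) - 1L
    seq.int(st, st + tisOffset(tx) - 1L)
  }
  cdsOf <- function(tx) {
    st <- IRanges::start(exons(tx)) - 1L + tisOffset(tx)
    seq.int(st, st + length(cdsSeq(tx)) - 1L)
  }
  pureA <- !any(utrOf(txA) %in% cdsOf(txB))
  pureB <- !any(utrOf(txB) %in% cdsOf(txA))
  expect_false(pureA)   # A's UTR covers B's CDS start by construction
  expect_true(pureB)
  expect_identical(transcriptId(sel), "tB")
  # single-isoform gene: vacuously pure
  gene1 <- buildGeneIsoformSets(list(txA))[[1]]
  expect_identical(transcriptId(selectTranscript(gene1, "pure_utr")), "tA")
})

test_that("pure_utr returns NULL when no isoform qualifies", {
  # antisense isoform pair: each isoform's UTR covers the other's CDS
  txA <- toyTx(strrep("C", 60), id = "tA", genomicStart = 0L)
  txB <- toyTx(strrep("C", 60), id = "tB", strand = "-",
               genomicStart = 40L)
  gene <- buildGeneIsoformSets(list(txA, txB))[[1]]
  expect_null(selectTranscript(gene, "pure_utr"))
  expect_error(selectTranscript(gene, "nonsense"))
})

test_that("ortholog table must be one-to-one", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "orth.tsv")
  writeLines(c("a\tb", "g1\th1", "g2\th2"), p)
  expect_identical(nrow(readOrthologPairs(p)), 2L)
  writeLines(c("a\tb", "g1\th1", "g1\th2"), p)
  expect_error(readOrthologPairs(p), "one-to-one")
})

test_that("TranscriptModel validity rejects broken models", {
  expect_error(toyTx(""), "5'UTR")
  expect_error(toyTx("CCC", cds = "ATGAAA"), "stop")
  expect_error(toyTx("CCC", cds = "ATGTAATAA"), "internal")
  expect_error(toyTx("CCC", cds = "TTGGATTAA"), "ATG")
})
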