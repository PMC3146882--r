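# In-code fixtures shared across the test files.

# A valid short CDS: ATG GAT TAT TGC TAA (no internal in-frame stop).
TOY_CDS <- "ATGGATTATTGCTAA"

# Single-exon transcript holding a given 5'UTR (and CDS) at genomic
# offset 0 on the plus strand.
toyTx <- function(utr, cds = TOY_CDS, id = "t1", gene = "g1",
                  species = "sp", chrom = "chr1", strand = "+",
                  genomicStart = 0L) {
  TranscriptModel(gene, id, species, chrom, strand,
    c(genomicStart, genomicStart + nchar(utr) + nchar(cds)),
    tisOffset = nchar(utr), utr5Seq = utr, cdsSeq = cds)
}

# Write a one-chromosome GTF + FASTA pair describing `transcripts`
# (list of lists: gene, tx, strand, exons (data.frame start1/end1),
# cds (start1/end1)) over the genome string `seqstr`.
writeToyAnnotation <- function(dir, seqstr, transcripts, chrom = "chr1") {
  gtf <- file.path(dir, "ann.gtf")
  fa <- file.path(dir, "gen.fa")
  lines <- unlist(lapply(transcripts, function(t) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', t$gene, t$tx)
    c(sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s", chrom,
        t$exons$start1, t$exons$end1, t$strand, attrs),
      sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t%s\t0\t%s", chrom,
        t$cds$start1, t$cds$end1, t$strand, attrs))
  }))
  writeLines(lines, gtf)
  writeLines(c(paste0(">", chrom), seqstr), fa)
  list(gtf = gtf, fasta = fa)
}

# Build an alignment-block row in the readMaf() layout.
toyBlock <- function(refText, othText, refStart = 0L, othStart = 0L,
                     refChrom = "chr1", othChrom = "chr1") {
  refSize <- nchar(gsub("-", "", refText, fixed = TRUE))
  othSize <- nchar(gsub("-", "", othText, fixed = TRUE))
  data.frame(block = 1L, refSpecies = "sp", refChrom = refChrom,
    refStart = refStart, refSize = refSize, refStrand = "+",
    refSrcSize = 10000L, refText = refText,
    othSpecies = "sp2", othChrom = othChrom, othStart = othStart,
    othSize = othSize, othStrand = "+", othSrcSize = 10000L,
    othText = othText, stringsAsFactors = FALSE)
}

# Independent reimplementation of the R statistic for oracle checks.
oracleR <- function(nd, td, nu, tu, c = 0.5) {
  log2(((nd + c) / (td + c)) / ((nu + c) / (tu + c)))
}
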