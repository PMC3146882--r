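#' Load transcript models from a GTF annotation and a genome FASTA
#'
#' Builds \linkS4class{TranscriptModel} objects from Ensembl-dialect GTF
#' (exon and CDS features carrying \code{gene_id}/\code{transcript_id}
#' attributes) and a genome FASTA, applying the transcript-level sanity
#' filters: transcripts without a 5'UTR are excluded, and transcripts whose
#' annotated TIS is inconsistent with the DNA sequence (CDS not starting
#' with ATG, length not a multiple of 3, internal in-frame stop, or missing
#' terminal stop) are excluded as misannotated. Minus-strand transcripts
#' are reverse-complemented so that all sequences and transcript
#' coordinates are cap-to-3' oriented.
#'
#' CDS features are expected to include the stop codon; if separate
#' \code{stop_codon} features are present they are appended to the CDS.
#'
#' @param gtfPath path to a GTF file.
#' @param fastaPath path to the genome FASTA (sequence names matched on the
#'   first whitespace-delimited word).
#' @param species label stored on each model.
#' @param allowList optional character vector (or path to a one-ID-per-line
#'   file) restricting the transcript IDs considered, standing in for an
#'   upstream "experimentally verified" annotation property.
#' @param verbose emit a summary of rejection counts per filter.
#' @return list of \linkS4class{TranscriptModel}.
#' @export
loadTranscripts <- function(gtfPath, fastaPath, species,
                            allowList = NULL, verbose = TRUE) {
  gr <- rtracklayer::import(gtfPath, format = "gtf")
  genome <- Biostrings::readDNAStringSet(fastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))

  if (!is.null(allowList) && length(allowList) == 1L && file.exists(allowList))
    allowList <- readLines(allowList)

  keepTypes <- S4Vectors::mcols(gr)$type %in% c("exon", "CDS", "stop_codon")
  gr <- gr[keepTypes]
  txIds <- S4Vectors::mcols(gr)$transcript_id
  if (!is.null(allowList))
    gr <- gr[txIds %in% allowList]

  byTx <- split(gr, S4Vectors::mcols(gr)$transcript_id)
  nNoUtr <- 0L; nMisannotated <- 0L; nNoCds <- 0L
  out <- list()

  for (txid in names(byTx)) {
    feats <- byTx[[txid]]
    ftype <- as.character(S4Vectors::mcols(feats)$type)
    exn <- feats[ftype == "exon"]
    cdsF <- feats[ftype %in% c("CDS", "stop_codon")]
    if (length(exn) == 0L || length(cdsF) == 0L) { nNoCds <- nNoCds + 1L; next }
    chrom <- as.character(GenomicRanges::seqnames(exn))[1L]
    strand <- as.character(BiocGenerics::strand(exn))[1L]
    if (!chrom %in% names(genome))
      stop("sequence for chromosome '", chrom, "' not found in FASTA")

    ord <- order(GenomicRanges::start(exn), decreasing = (strand == "-"))
    exn <- exn[ord]
    exIr <- IRanges::IRanges(GenomicRanges::start(exn), GenomicRanges::end(exn))

    ## spliced transcript sequence, cap -> 3'
    pieces <- Biostrings::DNAStringSet(genome[[chrom]],
      start = GenomicRanges::start(exn), end = GenomicRanges::end(exn))
    if (strand == "-") pieces <- Biostrings::reverseComplement(pieces)
    txSeq <- unlist(pieces)

    ## transcript offset of the first CDS base (the TIS)
    cdsStartG <- if (strand == "+") min(GenomicRanges::start(cdsF)) - 1L
                 else max(GenomicRanges::end(cdsF)) - 1L
    cdsEndG   <- if (strand == "+") max(GenomicRanges::end(cdsF)) - 1L
                 else min(GenomicRanges::start(cdsF)) - 1L
    protoTx <- new("TranscriptModel", geneId = "g", transcriptId = "t",
      species = species, chrom = chrom, strand = strand, exons = exIr,
      tisOffset = 1L, utr5Seq = Biostrings::DNAString("A"),
      cdsSeq = Biostrings::DNAString("ATGTAA"))
    tis <- .genomicToTx(protoTx, cdsStartG)
    cdsLast <- .genomicToTx(protoTx, cdsEndG)
    if (is.na(tis) || is.na(cdsLast) || cdsLast < tis) {
      nMisannotated <- nMisannotated + 1L; next
    }
    cdsLen <- cdsLast - tis + 1L
    if (tis < 1L) { nNoUtr <- nNoUtr + 1L; next }

    utrSeq <- Biostrings::subseq(txSeq, 1L, tis)
    cdsSeq <- Biostrings::subseq(txSeq, tis + 1L, tis + cdsLen)
    gid <- as.character(S4Vectors::mcols(exn)$gene_id)[1L]

    tx <- tryCatch(
      TranscriptModel(gid, txid, species, chrom, strand, exIr,
                      tisOffset = tis, utr5Seq = utrSeq, cdsSeq = cdsSeq),
      error = function(e) e)
    if (is(tx, "error")) { nMisannotated <- nMisannotated + 1L; next }
    out[[length(out) + 1L]] <- tx
  }

  if (verbose)
    message(sprintf(
      "loadTranscripts: kept %d; rejected %d without 5'UTR, %d misannotated CDS, %d incomplete",
      length(out), nNoUtr, nMisannotated, nNoCds))
  out
}

#' Group transcript models by gene and compute the genomic CDS footprint
#'
#' @param transcripts list of \linkS4class{TranscriptModel}.
#' @return list of \linkS4class{GeneIsoformSet}, one per gene.
#' @export
buildGeneIsoformSets <- function(transcripts) {
  gids <- vapply(transcripts, geneId, character(1))
  lapply(split(transcripts, gids), function(isos) {
    cdsGr <- lapply(isos, function(tx)
      .txToGenomic(tx, tx@tisOffset, tx@tisOffset + length(tx@cdsSeq)))
    fp <- GenomicRanges::reduce(do.call(c, unname(cdsGr)), ignore.strand = TRUE)
    new("GeneIsoformSet", geneId = isos[[1L]]@geneId,
        isoforms = unname(isos), cdsFootprint = fp)
  })
}

#' Select one transcript per gene
#'
#' Implements the three selection criteria used throughout the analysis:
#' \describe{
#'   \item{random}{a uniform seeded choice among the gene's isoforms;}
#'   \item{longest_utr}{the isoform with the longest 5'UTR, ties broken by
#'     lexicographic transcript ID;}
#'   \item{pure_utr}{among isoforms whose 5'UTR genomic footprint does not
#'     intersect the CDS footprint of any \emph{other} isoform of the same
#'     gene, the one with the longest 5'UTR (same tie-break), or
#'     \code{NULL} when no isoform qualifies.}
#' }
#'
#' @param gene a \linkS4class{GeneIsoformSet}.
#' @param criterion one of \code{"random"}, \code{"longest_utr"},
#'   \code{"pure_utr"}.
#' @param seed integer seed used for \code{"random"} (reproducible).
#' @return a \linkS4class{TranscriptModel} or \code{NULL}.
#' @export
selectTranscript <- function(gene,
                             criterion = c("random", "longest_utr", "pure_utr"),
                             seed = NULL) {
  criterion <- match.arg(criterion)
  isos <- gene@isoforms
  utrLens <- vapply(isos, utr5Length, integer(1))
  ids <- vapply(isos, transcriptId, character(1))

  pickLongest <- function(cand) {
    if (!length(cand)) return(NULL)
    lens <- utrLens[cand]
    best <- cand[lens == max(lens)]
    best[order(ids[best])][1L]
  }

  idx <- switch(criterion,
    random = {
      if (!is.null(seed)) set.seed(seed)
      sample.int(length(isos), 1L)
    },
    longest_utr = pickLongest(seq_along(isos)),
    pure_utr = {
      cand <- which(vapply(seq_along(isos), function(i) {
        utrFp <- .txToGenomic(isos[[i]], 0L, isos[[i]]@tisOffset)
        others <- setdiff(seq_along(isos), i)
        if (!length(others)) return(TRUE)
        otherCds <- do.call(c, unname(lapply(isos[others], function(tx)
          .txToGenomic(tx, tx@tisOffset, tx@tisOffset + length(tx@cdsSeq)))))
        length(GenomicRanges::findOverlaps(utrFp, otherCds,
          ignore.strand = TRUE)) == 0L
      }, logical(1)))
      pickLongest(cand)
    })
  if (is.null(idx)) NULL else isos[[idx]]
}

#' Read a two-column one-to-one ortholog pairing table
#'
#' @param path TSV with a header line and two columns of gene IDs.
#' @return data.frame with columns \code{geneId1}, \code{geneId2}.
#' @export
readOrthologPairs <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("ortholog table needs two columns")
  df <- df[, 1:2]
  names(df) <- c("geneId1", "geneId2")
  if (anyDuplicated(df$geneId1) || anyDuplicated(df$geneId2))
    stop("ortholog pairing is not one-to-one: duplicated gene IDs")
  df
}

#' Write a normalized transcript table
#'
#' @param transcripts list of \linkS4class{TranscriptModel}.
#' @param path output TSV path.
#' @export
writeTranscriptTable <- function(transcripts, path) {
  df <- data.frame(
    geneId = vapply(transcripts, geneId, character(1)),
    transcriptId = vapply(transcripts, transcriptId, character(1)),
    species = vapply(transcripts, txSpecies, character(1)),
    chrom = vapply(transcripts, txChrom, character(1)),
    strand = vapply(transcripts, txStrand, character(1)),
    utr5Length = vapply(transcripts, utr5Length, integer(1)),
    cdsLength = vapply(transcripts, function(tx) length(tx@cdsSeq), integer(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write per-transcript 5'UTR and CDS sequences as FASTA
#'
#' @param transcripts list of \linkS4class{TranscriptModel}.
#' @param utrPath,cdsPath output FASTA paths (either may be NULL to skip).
#' @export
writeUtrCdsFasta <- function(transcripts, utrPath = NULL, cdsPath = NULL) {
  ids <- vapply(transcripts, transcriptId, character(1))
  if (!is.null(utrPath)) {
    utrs <- Biostrings::DNAStringSet(vapply(transcripts,
      function(tx) as.character(tx@utr5Seq), character(1)))
    names(utrs) <- ids
    Biostrings::writeXStringSet(utrs, utrPath)
  }
  if (!is.null(cdsPath)) {
    cdss <- Biostrings::DNAStringSet(vapply(transcripts,
      function(tx) as.character(tx@cdsSeq), character(1)))
    names(cdss) <- ids
    Biostrings::writeXStringSet(cdss, cdsPath)
  }
  invisible(NULL)
}
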