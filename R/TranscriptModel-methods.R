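#' Construct a TranscriptModel
#'
#' @param geneId,transcriptId,species,chrom single character identifiers.
#' @param strand "+" or "-".
#' @param exons an \link[IRanges]{IRanges} of genomic exon intervals in
#'   transcript (5' to 3') order, 1-based closed. For a single-exon
#'   transcript an integer vector \code{c(start0, end0)} in 0-based
#'   half-open convention is also accepted.
#' @param tisOffset integer, 0-based offset of the first CDS base from the cap.
#' @param utr5Seq,cdsSeq character or \link[Biostrings]{DNAString}.
#' @return a validated \linkS4class{TranscriptModel}.
#' @examples
#' tx <- TranscriptModel("g1", "t1", "speciesA", "chr1", "+",
#'   c(0L, 22L), tisOffset = 7L,
#'   utr5Seq = "CCCTCCC", cdsSeq = "ATGAAACCCTGGTAA")
#' utr5Length(tx)
#' @export
TranscriptModel <- function(geneId, transcriptId, species, chrom, strand,
                            exons, tisOffset, utr5Seq, cdsSeq) {
  if (is.numeric(exons) && length(exons) == 2L)
    exons <- IRanges::IRanges(start = exons[1L] + 1L, end = exons[2L])
  new("TranscriptModel",
    geneId = as.character(geneId),
    transcriptId = as.character(transcriptId),
    species = as.character(species),
    chrom = as.character(chrom),
    strand = as.character(strand),
    exons = exons,
    tisOffset = as.integer(tisOffset),
    utr5Seq = if (is(utr5Seq, "DNAString")) utr5Seq else
      Biostrings::DNAString(toupper(utr5Seq)),
    cdsSeq = if (is(cdsSeq, "DNAString")) cdsSeq else
      Biostrings::DNAString(toupper(cdsSeq)))
}

#' @rdname accessors
#' @export
setMethod("geneId", "TranscriptModel", function(x) x@geneId)
#' @rdname accessors
#' @export
setMethod("transcriptId", "TranscriptModel", function(x) x@transcriptId)
#' @rdname accessors
#' @export
setMethod("txSpecies", "TranscriptModel", function(x) x@species)
#' @rdname accessors
#' @export
setMethod("txChrom", "TranscriptModel", function(x) x@chrom)
#' @rdname accessors
#' @export
setMethod("txStrand", "TranscriptModel", function(x) x@strand)
#' @rdname accessors
#' @export
setMethod("exons", "TranscriptModel", function(x) x@exons)
#' @rdname accessors
#' @export
setMethod("tisOffset", "TranscriptModel", function(x) x@tisOffset)
#' @rdname accessors
#' @export
setMethod("utr5Seq", "TranscriptModel", function(x) x@utr5Seq)
#' @rdname accessors
#' @export
setMethod("cdsSeq", "TranscriptModel", function(x) x@cdsSeq)
#' @rdname accessors
#' @export
setMethod("utr5Length", "TranscriptModel", function(x) x@tisOffset)

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf(
    "TranscriptModel %s (gene %s, %s) %s:%s\n  5'UTR %d nt | CDS %d nt | %d exon(s)\n",
    object@transcriptId, object@geneId, object@species,
    object@chrom, object@strand,
    object@tisOffset, length(object@cdsSeq), length(object@exons)))
})

#' @rdname accessors
#' @export
setMethod("geneId", "GeneIsoformSet", function(x) x@geneId)
#' @rdname accessors
#' @export
setMethod("isoforms", "GeneIsoformSet", function(x) x@isoforms)
#' @rdname accessors
#' @export
setMethod("cdsFootprint", "GeneIsoformSet", function(x) x@cdsFootprint)

setMethod("show", "GeneIsoformSet", function(object) {
  cat(sprintf("GeneIsoformSet %s: %d isoform(s), CDS footprint %d interval(s)\n",
    object@geneId, length(object@isoforms), length(object@cdsFootprint)))
})

## ---- transcript <-> genomic coordinate mapping -----------------------------

## Cumulative spliced width before each exon (transcript order).
.exonCumWidth <- function(tx) {
  w <- IRanges::width(tx@exons)
  c(0L, cumsum(w))[seq_along(w)]
}

## Map a 0-based genomic position to a 0-based spliced transcript offset,
## or NA if the position falls outside the exons.
.genomicToTx <- function(tx, gpos) {
  ex <- tx@exons
  st0 <- IRanges::start(ex) - 1L      # 0-based starts
  en0 <- IRanges::end(ex)             # 0-based half-open ends
  cum <- .exonCumWidth(tx)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_along(ex)) {
    hit <- !is.na(gpos) & gpos >= st0[i] & gpos < en0[i]
    if (!any(hit)) next
    out[hit] <- if (tx@strand == "+")
      cum[i] + (gpos[hit] - st0[i])
    else
      cum[i] + (en0[i] - 1L - gpos[hit])
  }
  out
}

## Map a 0-based half-open transcript interval [s, e) to genomic intervals
## (GRanges, 1-based). Pieces are returned in transcript order.
.txToGenomic <- function(tx, s, e) {
  ex <- tx@exons
  st0 <- IRanges::start(ex) - 1L
  en0 <- IRanges::end(ex)
  cum <- .exonCumWidth(tx)
  w <- IRanges::width(ex)
  pieces <- list()
  for (i in seq_along(ex)) {
    lo <- max(s, cum[i]); hi <- min(e, cum[i] + w[i])
    if (lo >= hi) next
    if (tx@strand == "+") {
      gs <- st0[i] + (lo - cum[i]); ge <- st0[i] + (hi - cum[i])
    } else {
      ge <- en0[i] - (lo - cum[i]); gs <- en0[i] - (hi - cum[i])
    }
    pieces[[length(pieces) + 1L]] <- c(gs, ge)
  }
  if (!length(pieces))
    return(GenomicRanges::GRanges())
  m <- do.call(rbind, pieces)
  GenomicRanges::GRanges(tx@chrom,
    IRanges::IRanges(start = m[, 1L] + 1L, end = m[, 2L]),
    strand = tx@strand)
}
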