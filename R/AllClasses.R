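#' @import methods
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom Biostrings DNAString
NULL

#' TranscriptModel: one spliced transcript in cap-to-3' orientation
#'
#' Holds a single protein-coding transcript with its exon structure and the
#' spliced 5'UTR and CDS sequences, always oriented cap to 3' end regardless
#' of genomic strand. All transcript coordinates used in this package are
#' 0-based offsets from the cap on the spliced transcript; genomic intervals
#' are 0-based half-open.
#'
#' Validity enforces the model contract: the 5'UTR is non-empty and its
#' length equals \code{tisOffset}; the CDS begins with ATG, has length a
#' multiple of 3, ends with a stop codon and contains no internal in-frame
#' stop; exons are disjoint and ordered 5' to 3' on the transcript strand.
#'
#' @slot geneId,transcriptId,species,chrom single character identifiers.
#' @slot strand \code{"+"} or \code{"-"} (genomic strand of the transcript).
#' @slot exons an \link[IRanges]{IRanges} of genomic exon intervals stored in
#'   transcript (5' to 3') order, 0-based half-open encoded as
#'   \code{start = genomicStart + 1} (1-based closed, the IRanges native
#'   convention).
#' @slot tisOffset integer, 0-based offset of the first CDS base from the cap.
#' @slot utr5Seq,cdsSeq \link[Biostrings]{DNAString} spliced sequences.
#'
#' @export
setClass("TranscriptModel",
  representation(
    geneId = "character",
    transcriptId = "character",
    species = "character",
    chrom = "character",
    strand = "character",
    exons = "IRanges",
    tisOffset = "integer",
    utr5Seq = "DNAString",
    cdsSeq = "DNAString"
  )
)

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.codonsOf <- function(x) {
  n <- nchar(x)
  if (n < 3L) return(character(0))
  starts <- seq.int(1L, n - 2L, by = 3L)
  substring(x, starts, starts + 2L)
}

setValidity("TranscriptModel", function(object) {
  msg <- character(0)
  for (s in c("geneId", "transcriptId", "species", "chrom", "strand")) {
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a single non-NA string", s))
  }
  if (length(msg)) return(msg)
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  utr <- as.character(object@utr5Seq)
  cds <- as.character(object@cdsSeq)
  if (nchar(utr) < 1L)
    msg <- c(msg, "transcript has no 5'UTR")
  if (object@tisOffset != nchar(utr))
    msg <- c(msg, "tisOffset must equal length(utr5Seq)")
  if (nchar(cds) %% 3L != 0L || nchar(cds) < 6L) {
    msg <- c(msg, "CDS length must be a positive multiple of 3 (>= 6)")
  } else {
    cod <- .codonsOf(cds)
    if (cod[1L] != "ATG")
      msg <- c(msg, "CDS does not begin with ATG")
    if (!cod[length(cod)] %in% .STOP_CODONS)
      msg <- c(msg, "CDS does not end with a stop codon")
    if (any(cod[-length(cod)] %in% .STOP_CODONS))
      msg <- c(msg, "CDS contains an internal in-frame stop codon")
  }
  ex <- object@exons
  if (length(ex) >= 1L) {
    if (sum(IRanges::width(ex)) < object@tisOffset + nchar(cds))
      msg <- c(msg, "exons shorter than UTR + CDS")
    if (length(ex) > 1L) {
      st <- IRanges::start(ex)
      ordered <- if (object@strand == "+") all(diff(st) > 0) else all(diff(st) < 0)
      if (!ordered)
        msg <- c(msg, "exons must be sorted 5'->3' on the transcript strand")
      sorted <- IRanges::reduce(ex)
      if (sum(IRanges::width(sorted)) != sum(IRanges::width(ex)))
        msg <- c(msg, "exons overlap")
    }
  } else msg <- c(msg, "transcript needs at least one exon")
  if (length(msg)) msg else TRUE
})

#' GeneIsoformSet: the isoforms of one gene plus its genomic CDS footprint
#'
#' @slot geneId single character.
#' @slot isoforms list of \linkS4class{TranscriptModel}, all sharing
#'   \code{geneId}.
#' @slot cdsFootprint \link[GenomicRanges]{GRanges}: the exact interval union
#'   of the genomic CDS intervals of all isoforms. Used to decide whether a
#'   5'UTR is "pure" (does not overlap any other isoform's CDS).
#'
#' @export
setClass("GeneIsoformSet",
  representation(
    geneId = "character",
    isoforms = "list",
    cdsFootprint = "GRanges"
  )
)

setValidity("GeneIsoformSet", function(object) {
  msg <- character(0)
  if (length(object@geneId) != 1L)
    msg <- c(msg, "geneId must be a single string")
  if (length(object@isoforms) < 1L)
    msg <- c(msg, "need at least one isoform")
  ok <- vapply(object@isoforms, function(tx)
    is(tx, "TranscriptModel") && tx@geneId == object@geneId, logical(1))
  if (!all(ok))
    msg <- c(msg, "all isoforms must be TranscriptModel objects sharing geneId")
  if (length(msg)) msg else TRUE
})

#' NeutralIsiTable: empirical neutral ISI distributions by reference percent
#'
#' The neutral reference for all group comparisons: ISI values of
#' indel-containing uAUG-free (G0) transcripts, computed with an artificial
#' reference point placed at a given percent of each transcript's 5'UTR
#' length. One distribution is stored per percent, all built from the same
#' transcript set.
#'
#' @slot table data.frame with columns \code{percent}, \code{transcriptId},
#'   \code{isi}.
#' @slot percents integer vector of the percents present.
#' @slot nShuffles integer, shuffles used per ISI value.
#' @slot tieRule \code{"strict"} or \code{"midp"}.
#'
#' @export
setClass("NeutralIsiTable",
  representation(
    table = "data.frame",
    percents = "integer",
    nShuffles = "integer",
    tieRule = "character"
  )
)

setValidity("NeutralIsiTable", function(object) {
  msg <- character(0)
  tb <- object@table
  if (!all(c("percent", "transcriptId", "isi") %in% names(tb)))
    msg <- c(msg, "table needs columns percent, transcriptId, isi")
  else {
    if (any(tb$isi < 0 | tb$isi > 1))
      msg <- c(msg, "ISI values must lie in [0, 1]")
    ids <- split(tb$transcriptId, tb$percent)
    if (length(ids) > 1L) {
      ref <- sort(ids[[1L]])
      same <- vapply(ids, function(x) identical(sort(x), ref), logical(1))
      if (!all(same))
        msg <- c(msg, "all percents must cover the same transcript set")
    }
    if (!setequal(unique(tb$percent), object@percents))
      msg <- c(msg, "percents slot disagrees with table")
  }
  if (length(msg)) msg else TRUE
})
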