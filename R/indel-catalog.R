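#' Apply alignment-quality filters to a gene's alignment blocks
#'
#' A gene is kept only if (a) the alignable sequence (columns with bases in
#' both rows) covers strictly more than 80 percent of the annotated exonic
#' bases of each species, evaluated symmetrically, and (b) every base of
#' the annotated 5'UTR lies within some block's reference span. Blocks
#' covering the same reference base twice are a hard error (malformed
#' alignment input).
#'
#' @param blocks data.frame of alignment blocks (see \code{\link{readMaf}})
#'   pertaining to the gene's locus.
#' @param tx annotated-species \linkS4class{TranscriptModel}.
#' @param orthoTx the ortholog's \linkS4class{TranscriptModel} in the other
#'   species (its exons are read in that species' coordinates).
#' @param minExonOverlap coverage threshold (default 0.80, strict).
#' @return list with \code{accepted} (logical), \code{reason} (NA or one of
#'   \code{"exon_overlap<=0.80"}, \code{"utr_not_fully_covered"}) and
#'   \code{blocks} (the input when accepted, otherwise NULL).
#' @export
filterAlignments <- function(blocks, tx, orthoTx, minExonOverlap = 0.80) {
  if (!nrow(blocks))
    return(list(accepted = FALSE, reason = "utr_not_fully_covered",
                blocks = NULL))
  spans <- IRanges::IRanges(blocks$refStart + 1L,
                            blocks$refStart + blocks$refSize)
  if (sum(IRanges::width(IRanges::reduce(spans))) != sum(IRanges::width(spans)))
    stop("malformed alignment: blocks cover the same reference base twice")

  refAligned <- integer(0)   # 0-based ref genomic positions aligned to a base
  othAligned <- integer(0)
  for (i in seq_len(nrow(blocks))) {
    rc <- strsplit(blocks$refText[i], "")[[1L]]
    oc <- strsplit(blocks$othText[i], "")[[1L]]
    refGap <- rc == "-"; othGap <- oc == "-"
    if (any(refGap & othGap))
      stop("malformed alignment: gap aligned to gap")
    refPos <- blocks$refStart[i] + cumsum(!refGap) - 1L
    othPos <- blocks$othStart[i] + cumsum(!othGap) - 1L
    both <- !refGap & !othGap
    refAligned <- c(refAligned, refPos[both])
    othAligned <- c(othAligned, othPos[both])
  }

  exonPos <- function(t) {
    unlist(lapply(seq_along(t@exons), function(i)
      seq.int(IRanges::start(t@exons)[i] - 1L, IRanges::end(t@exons)[i] - 1L)))
  }
  refExonic <- exonPos(tx)
  othExonic <- exonPos(orthoTx)
  cov1 <- mean(refExonic %in% refAligned)
  cov2 <- mean(othExonic %in% othAligned)
  if (cov1 <= minExonOverlap || cov2 <= minExonOverlap)
    return(list(accepted = FALSE,
                reason = sprintf("exon_overlap<=%.2f", minExonOverlap),
                blocks = NULL))

  utrGr <- .txToGenomic(tx, 0L, tx@tisOffset)
  utrPos <- unlist(lapply(seq_along(utrGr), function(i)
    seq.int(GenomicRanges::start(utrGr)[i] - 1L,
            GenomicRanges::end(utrGr)[i] - 1L)))
  spanPos <- unlist(lapply(seq_len(nrow(blocks)), function(i)
    seq.int(blocks$refStart[i],
            blocks$refStart[i] + blocks$refSize[i] - 1L)))
  if (!all(utrPos %in% spanPos))
    return(list(accepted = FALSE, reason = "utr_not_fully_covered",
                blocks = NULL))

  list(accepted = TRUE, reason = NA_character_, blocks = blocks)
}

#' Extract indels from alignment blocks and map them to 5'UTR coordinates
#'
#' Each maximal run of gap characters in either row is one indel; its
#' length is the run length. Insertions and deletions are pooled (the
#' pairwise alignment cannot tell them apart without an outgroup). Runs
#' longer than \code{maxLength} are discarded and counted. The indel's
#' location is the ungapped reference-transcript coordinate of the first
#' matched reference base 3' of the gap feature (for an other-row gap, the
#' first base after the deleted segment), converted to a spliced 5'UTR
#' offset; indels outside the 5'UTR are dropped.
#'
#' @param blocks accepted alignment blocks (see
#'   \code{\link{filterAlignments}}).
#' @param tx the annotated-species \linkS4class{TranscriptModel}.
#' @param maxLength maximum indel length retained (default 100).
#' @return data.frame with columns \code{transcriptId}, \code{utrOffset}
#'   (0-based nt from the cap, in [0, utr5Length]), \code{lengthNt},
#'   \code{sizeClass} (\code{"n3n"} or \code{"3n"}); the number of
#'   discarded oversize gap runs is attached as attribute
#'   \code{"nOversize"} and the total gap columns seen as
#'   \code{"gapColumns"}.
#' @export
extractIndels <- function(blocks, tx, maxLength = 100L) {
  rows <- list()
  nOversize <- 0L
  oversizeColumns <- 0L
  gapColumns <- 0L
  for (i in seq_len(nrow(blocks))) {
    rc <- strsplit(blocks$refText[i], "")[[1L]]
    oc <- strsplit(blocks$othText[i], "")[[1L]]
    refGap <- rc == "-"; othGap <- oc == "-"
    if (any(refGap & othGap))
      stop("malformed alignment: gap aligned to gap in block ", i)
    gapColumns <- gapColumns + sum(refGap) + sum(othGap)
    nBefore <- c(0L, cumsum(!refGap))     # ref bases before each column
    for (row in c("ref", "oth")) {
      g <- if (row == "ref") refGap else othGap
      r <- rle(g)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(r$values)) {
        len <- r$lengths[j]
        if (len > maxLength) {
          nOversize <- nOversize + 1L
          oversizeColumns <- oversizeColumns + len
          next
        }
        if (row == "ref") {
          gAfter <- blocks$refStart[i] + nBefore[starts[j]]
          gpos <- if (tx@strand == "+") gAfter else gAfter - 1L
        } else {
          a <- blocks$refStart[i] + nBefore[starts[j]]
          b <- a + len
          gpos <- if (tx@strand == "+") b else a - 1L
        }
        off <- .genomicToTx(tx, gpos)
        if (is.na(off) || off > tx@tisOffset) next
        rows[[length(rows) + 1L]] <- data.frame(
          transcriptId = tx@transcriptId, utrOffset = off,
          lengthNt = len,
          sizeClass = if (len %% 3L == 0L) "3n" else "n3n",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcriptId = character(0), utrOffset = integer(0),
      lengthNt = integer(0), sizeClass = character(0),
      stringsAsFactors = FALSE)
  out <- out[order(out$utrOffset, out$lengthNt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nOversize") <- nOversize
  attr(out, "oversizeColumns") <- oversizeColumns
  attr(out, "gapColumns") <- gapColumns
  out
}

#' Partition indels upstream/downstream of a reference point
#'
#' An indel is downstream when its \code{utrOffset} is greater than or
#' equal to the reference offset (a gap exactly at the uAUG disrupts the
#' element it starts).
#'
#' @param indels data.frame with columns \code{utrOffset} and
#'   \code{sizeClass} (see \code{\link{extractIndels}}).
#' @param referenceOffset integer in [0, utr5Length].
#' @return named integer vector of counts:
#'   \code{nonTripletDown}, \code{tripletDown},
#'   \code{nonTripletUp}, \code{tripletUp}.
#' @examples
#' ind <- data.frame(utrOffset = c(2, 8, 9),
#'                   sizeClass = c("n3n", "3n", "n3n"))
#' partitionIndels(ind, 8)
#' @export
partitionIndels <- function(indels, referenceOffset) {
  down <- indels$utrOffset >= referenceOffset
  n3n <- indels$sizeClass == "n3n"
  c(nonTripletDown = sum(down & n3n), tripletDown = sum(down & !n3n),
    nonTripletUp = sum(!down & n3n), tripletUp = sum(!down & !n3n))
}
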