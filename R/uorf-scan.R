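#' Scan a 5'UTR for upstream AUGs and classify the resulting uORFs
#'
#' Every ATG trinucleotide lying entirely within the 5'UTR is a candidate
#' uAUG. Translation proceeds on the concatenated 5'UTR + CDS sequence from
#' the uAUG in steps of three until the first stop codon (TAA/TAG/TGA). The
#' resulting uORF is classified:
#' \describe{
#'   \item{strict}{the stop codon lies entirely within the 5'UTR;}
#'   \item{overlapping}{the uAUG is out of frame with the main CDS and the
#'     stop codon lies within the CDS;}
#'   \item{alternative}{the uAUG is in frame with the main CDS with no stop
#'     codon before the TIS, so the uORF shares the main stop codon (the
#'     uAUG is an alternative initiation site).}
#' }
#' An in-frame uAUG with an intervening stop before the TIS terminates in
#' the UTR and is therefore strict. Candidates shorter than 9 nt (including
#' the stop codon) are dropped, as are candidates whose reading runs off
#' the transcript end without a stop, and candidates containing non-ACGT
#' characters (with a warning).
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @return data.frame with one row per uORF, sorted by \code{uaugOffset}:
#'   columns \code{uaugOffset} (0-based from the cap), \code{uorfType},
#'   \code{orfLengthNt} (including the stop codon; for alternative uORFs,
#'   measured to the shared main stop), \code{stopOffset} (0-based offset of
#'   the first stop-codon base), \code{inCdsFrame}.
#' @examples
#' tx <- TranscriptModel("g", "t", "sp", "chr1", "+", c(0L, 28L), 13L,
#'   "CCATGAAATAACC", "ATGGATTATTGCTAA")
#' scanUaugs(tx)
#' @export
scanUaugs <- function(tx) {
  stopifnot(is(tx, "TranscriptModel"))
  .scanUaugsCore(as.character(tx@utr5Seq), as.character(tx@cdsSeq),
                 tx@transcriptId)
}

## String-level scanner shared with the synthetic generator.
.scanUaugsCore <- function(utr, cds, txLabel = "?") {
  full <- paste0(utr, cds)
  tis <- nchar(utr)
  nFull <- nchar(full)

  empty <- data.frame(uaugOffset = integer(0), uorfType = character(0),
    orfLengthNt = integer(0), stopOffset = integer(0),
    inCdsFrame = logical(0), stringsAsFactors = FALSE)

  hits <- gregexpr("ATG", utr, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(empty)
  starts0 <- as.integer(hits) - 1L                  # 0-based offsets of 'A'
  starts0 <- starts0[starts0 + 2L < tis]            # entirely within 5'UTR
  if (!length(starts0)) return(empty)

  rows <- lapply(starts0, function(u) {
    codStarts <- seq.int(u + 1L, nFull, by = 3L)
    codStarts <- codStarts[codStarts + 2L <= nFull]
    cods <- substring(full, codStarts, codStarts + 2L)
    if (any(grepl("[^ACGT]", cods))) {
      bad <- which(grepl("[^ACGT]", cods))[1L]
      stopAt <- which(cods %in% .STOP_CODONS)
      if (!length(stopAt) || stopAt[1L] >= bad) {
        warning("uAUG candidate at offset ", u, " of ", txLabel,
                " dropped: non-ACGT character in ORF")
        return(NULL)
      }
    }
    stopAt <- which(cods %in% .STOP_CODONS)
    if (!length(stopAt)) return(NULL)               # runs off the transcript
    stopOffset <- u + 3L * (stopAt[1L] - 1L)
    orfLen <- stopOffset + 3L - u
    if (orfLen < 9L) return(NULL)
    inFrame <- (tis - u) %% 3L == 0L
    type <- if (stopOffset + 3L <= tis) "strict"
            else if (!inFrame) "overlapping"
            else "alternative"
    data.frame(uaugOffset = u, uorfType = type, orfLengthNt = orfLen,
               stopOffset = stopOffset, inCdsFrame = inFrame,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$uaugOffset), , drop = FALSE]
}

.GROUP_OF_TYPE <- c(strict = "Gs", overlapping = "Gv", alternative = "Ga")

#' Assign a transcript to a uORF group
#'
#' Transcripts are grouped by the uORF types they carry: \code{G0} (no
#' uAUG), \code{Ga} (only alternative), \code{Gs} (only strict), \code{Gv}
#' (only overlapping), or \code{Gmulti} (two or more types present; such
#' transcripts are excluded from downstream comparisons). For the
#' single-type groups the reference point is the first uAUG from the cap.
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @param uorfs result of \code{\link{scanUaugs}} on the same transcript;
#'   computed if missing.
#' @return one-row data.frame: \code{transcriptId}, \code{group},
#'   \code{referenceOffset} (NA for G0/Gmulti), \code{relativePosition}
#'   (referenceOffset / tisOffset).
#' @export
classifyTranscript <- function(tx, uorfs = scanUaugs(tx)) {
  types <- unique(uorfs$uorfType)
  if (length(types) == 0L) {
    group <- "G0"; ref <- NA_integer_
  } else if (length(types) > 1L) {
    group <- "Gmulti"; ref <- NA_integer_
  } else {
    group <- .GROUP_OF_TYPE[[types]]
    ref <- min(uorfs$uaugOffset)
  }
  data.frame(transcriptId = tx@transcriptId, group = group,
    referenceOffset = ref,
    relativePosition = if (is.na(ref)) NA_real_ else ref / tx@tisOffset,
    utr5Length = tx@tisOffset,
    stringsAsFactors = FALSE)
}

#' Classify a list of transcripts
#'
#' @param transcripts list of \linkS4class{TranscriptModel}.
#' @return data.frame, one row per transcript (see
#'   \code{\link{classifyTranscript}}).
#' @export
classifyTranscripts <- function(transcripts) {
  do.call(rbind, lapply(transcripts, classifyTranscript))
}

#' Write uAUGs as BED6 (transcript-relative coordinates)
#'
#' One line per uORF: name is the uORF type, score the ORF length in nt.
#'
#' @param transcripts list of \linkS4class{TranscriptModel}.
#' @param path output BED path.
#' @export
writeUaugBed <- function(transcripts, path) {
  rows <- lapply(transcripts, function(tx) {
    u <- scanUaugs(tx)
    if (!nrow(u)) return(NULL)
    data.frame(chrom = tx@transcriptId, start = u$uaugOffset,
      end = u$uaugOffset + 3L, name = u$uorfType,
      score = u$orfLengthNt, strand = "+", stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
      name = character(0), score = integer(0), strand = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(df)
}
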