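#' Accessors for TranscriptModel and friends
#'
#' Standard slot accessors. \code{utr5Length} is a convenience for
#' \code{tisOffset} (the 5'UTR length in nucleotides equals the 0-based
#' offset of the TIS from the cap).
#'
#' @param x a \linkS4class{TranscriptModel}, \linkS4class{GeneIsoformSet} or
#'   \linkS4class{NeutralIsiTable} as appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @rdname accessors
#' @export
setGeneric("txSpecies", function(x) standardGeneric("txSpecies"))
#' @rdname accessors
#' @export
setGeneric("txChrom", function(x) standardGeneric("txChrom"))
#' @rdname accessors
#' @export
setGeneric("txStrand", function(x) standardGeneric("txStrand"))
#' @rdname accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
#' @rdname accessors
#' @export
setGeneric("tisOffset", function(x) standardGeneric("tisOffset"))
#' @rdname accessors
#' @export
setGeneric("utr5Seq", function(x) standardGeneric("utr5Seq"))
#' @rdname accessors
#' @export
setGeneric("cdsSeq", function(x) standardGeneric("cdsSeq"))
#' @rdname accessors
#' @export
setGeneric("utr5Length", function(x) standardGeneric("utr5Length"))
#' @rdname accessors
#' @export
setGeneric("isoforms", function(x) standardGeneric("isoforms"))
#' @rdname accessors
#' @export
setGeneric("cdsFootprint", function(x) standardGeneric("cdsFootprint"))

#' @rdname neutralIsi
#' @export
setGeneric("neutralIsi", function(x, percent) standardGeneric("neutralIsi"))
#' @rdname neutralIsi
#' @export
setGeneric("neutralPercents", function(x) standardGeneric("neutralPercents"))
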