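#' Build the neutral ISI reference table from uAUG-free transcripts
#'
#' For each requested percent p, an artificial reference point is placed at
#' round(p/100 * utrLength), clamped to [1, utrLength - 1], in every
#' indel-containing G0 transcript, and the ISI is computed there. The
#' resulting per-percent ISI distributions are the neutral reference
#' against which uORF-bearing groups are compared at their matched
#' percent. One set of shuffle draws is made per transcript and evaluated
#' at every percent; marginally each percent's ISI has the usual shuffle
#' distribution, and distributions at different percents share the same
#' transcript set by construction.
#'
#' @param indels data.frame of indels (\code{transcriptId},
#'   \code{utrOffset}, \code{lengthNt}, \code{sizeClass}) for G0
#'   transcripts only.
#' @param utrLengths named integer vector: 5'UTR length per transcript.
#' @param percents integer percents in 1..99 (default the 10..90 deciles).
#' @param nShuffles shuffles per ISI value (default 1000).
#' @param seed optional integer seed.
#' @param tieRule,pseudocount passed to the ISI computation.
#' @return a \linkS4class{NeutralIsiTable}.
#' @export
buildNeutralTable <- function(indels, utrLengths,
                              percents = seq(10L, 90L, by = 10L),
                              nShuffles = 1000L, seed = NULL,
                              tieRule = c("strict", "midp"),
                              pseudocount = 0.5) {
  tieRule <- match.arg(tieRule)
  percents <- sort(unique(as.integer(percents)))
  if (any(percents < 1L | percents > 99L))
    stop("percents must lie in 1..99")
  ids <- unique(indels$transcriptId)
  if (!length(ids)) stop("no indel-containing transcripts supplied")
  if (!all(ids %in% names(utrLengths)))
    stop("utrLengths missing for some transcripts")
  if (!is.null(seed)) set.seed(seed)

  byTx <- split(indels, indels$transcriptId)[ids]
  tol <- 1e-9
  rows <- vector("list", length(ids))
  for (t in seq_along(ids)) {
    ind <- byTx[[t]]
    L <- as.integer(utrLengths[[ids[t]]])
    n3n <- .n3nFlags(ind)
    k <- length(n3n); k1 <- sum(n3n); k2 <- k - k1
    shuf <- matrix(sample.int(L + 1L, k * nShuffles, replace = TRUE) - 1L,
                   nrow = k)
    isiP <- vapply(percents, function(p) {
      ref <- min(max(round(p / 100 * L), 1L), L - 1L)
      counts <- partitionIndels(ind, ref)
      rObs <- computeR(counts, pseudocount)
      down <- shuf >= ref
      d1 <- if (k1) colSums(down[n3n, , drop = FALSE]) else rep(0L, nShuffles)
      d2 <- if (k2) colSums(down[!n3n, , drop = FALSE]) else rep(0L, nShuffles)
      rs <- .rValue(d1, d2, k1 - d1, k2 - d2, pseudocount)
      if (tieRule == "strict") mean(rs < rObs - tol) else
        mean(rs < rObs - tol) + 0.5 * mean(abs(rs - rObs) <= tol)
    }, numeric(1))
    rows[[t]] <- data.frame(percent = percents, transcriptId = ids[t],
                            isi = isiP, stringsAsFactors = FALSE)
  }
  tb <- do.call(rbind, rows)
  rownames(tb) <- NULL
  new("NeutralIsiTable", table = tb, percents = percents,
      nShuffles = as.integer(nShuffles), tieRule = tieRule)
}

#' Query a NeutralIsiTable
#'
#' \code{neutralIsi} returns the ISI values stored at one percent;
#' \code{neutralPercents} lists the percents present.
#'
#' @param x a \linkS4class{NeutralIsiTable}.
#' @param percent integer percent present in the table.
#' @return numeric vector of ISI values (named by transcript ID), or the
#'   integer percents.
#' @name neutralIsi
NULL

#' @rdname neutralIsi
#' @export
setMethod("neutralIsi", "NeutralIsiTable", function(x, percent) {
  percent <- as.integer(percent)
  if (!percent %in% x@percents)
    stop("percent ", percent, " not present in the neutral table")
  sub <- x@table[x@table$percent == percent, ]
  stats::setNames(sub$isi, sub$transcriptId)
})

#' @rdname neutralIsi
#' @export
setMethod("neutralPercents", "NeutralIsiTable", function(x) x@percents)

setMethod("show", "NeutralIsiTable", function(object) {
  nTx <- length(unique(object@table$transcriptId))
  cat(sprintf(
    "NeutralIsiTable: %d transcripts x %d percents (%s tie rule, %d shuffles)\n",
    nTx, length(object@percents), object@tieRule, object@nShuffles))
})

#' Median neutral ISI by percent
#'
#' Convenience summary of the neutral sweep (the per-percent medians that
#' are plotted against reference-point position).
#'
#' @param x a \linkS4class{NeutralIsiTable}.
#' @return data.frame with columns \code{percent}, \code{medianIsi},
#'   \code{n}.
#' @export
neutralSweepMedians <- function(x) {
  stopifnot(is(x, "NeutralIsiTable"))
  sp <- split(x@table$isi, x@table$percent)
  data.frame(percent = as.integer(names(sp)),
             medianIsi = vapply(sp, stats::median, numeric(1)),
             n = lengths(sp), row.names = NULL)
}
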