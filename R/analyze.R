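#' Analyse a simulated dataset in memory
#'
#' Runs the statistical stages of the pipeline directly on the objects
#' returned by \code{\link{simulateDataset}}, without writing or re-reading
#' files: classify every reference transcript, compute per-transcript ISIs
#' for indel-containing uORF groups (reference point = first uAUG), build
#' the neutral table from indel-containing G0 transcripts at the matched
#' percents (plus any extra percents requested), and run the matched
#' group-vs-neutral comparisons and, optionally, the size-equalising
#' bootstrap at the Ga sample size. File-route equivalence (that the full
#' pipeline on emitted files recovers exactly the same indel catalogue) is
#' a separate guarantee of \code{\link{emitDataset}}.
#'
#' @param sim result of \code{\link{simulateDataset}}.
#' @param nShuffles,tieRule,pseudocount ISI settings.
#' @param nResamples bootstrap resamples (used when \code{bootstrap}).
#' @param percents extra neutral percents to tabulate (e.g. the deciles).
#' @param bootstrap run the size-equalising bootstrap for all uORF groups
#'   with at least 2 indel-containing transcripts (needs Ga n >= 2).
#' @param seed optional integer seed (set before any randomness).
#' @return list: \code{classes}, \code{isiTable} (with \code{group}
#'   column), \code{neutral} (\linkS4class{NeutralIsiTable} or NULL),
#'   \code{comparisons}, \code{bootstrap}.
#' @export
analyzeSimulation <- function(sim, nShuffles = 1000L, nResamples = 1000L,
                              tieRule = "strict", pseudocount = 0.5,
                              percents = integer(0), bootstrap = FALSE,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  classes <- classifyTranscripts(sim$refTranscripts)
  indels <- sim$truthIndels[sim$truthIndels$kept, , drop = FALSE]
  utrLengths <- stats::setNames(
    vapply(sim$refTranscripts, utr5Length, integer(1)),
    vapply(sim$refTranscripts, transcriptId, character(1)))
  indByTx <- split(indels, indels$transcriptId)

  isiRows <- list()
  for (tid in names(indByTx)) {
    cl <- classes[classes$transcriptId == tid, ]
    if (!cl$group %in% c("Ga", "Gs", "Gv")) next
    L <- utrLengths[[tid]]
    if (cl$referenceOffset <= 0L || cl$referenceOffset >= L) next
    row <- computeIsi(indByTx[[tid]], L, cl$referenceOffset, nShuffles,
      tieRule = tieRule, pseudocount = pseudocount, transcriptId = tid)
    row$group <- cl$group
    isiRows[[length(isiRows) + 1L]] <- row
  }
  isiTable <- if (length(isiRows)) do.call(rbind, isiRows) else NULL

  presentGroups <- if (is.null(isiTable)) character(0) else
    names(which(table(isiTable$group) >= 2L))
  matched <- vapply(presentGroups, function(g) matchNeutral(
    classes[classes$transcriptId %in%
            isiTable$transcriptId[isiTable$group == g], ]), integer(1))

  g0Ids <- intersect(classes$transcriptId[classes$group == "G0"],
                     names(indByTx))
  neutral <- NULL
  if (length(g0Ids) >= 2L && (length(matched) || length(percents)))
    neutral <- buildNeutralTable(
      indels[indels$transcriptId %in% g0Ids, ], utrLengths[g0Ids],
      percents = sort(unique(c(matched, as.integer(percents)))),
      nShuffles = nShuffles, tieRule = tieRule,
      pseudocount = pseudocount)

  comparisons <- NULL; boot <- NULL
  if (!is.null(neutral) && length(presentGroups)) {
    comparisons <- do.call(rbind, lapply(presentGroups, function(g)
      compareGroup(isiTable$isi[isiTable$group == g],
        neutralIsi(neutral, matched[[g]]), group = g,
        matchedPercent = matched[[g]])))
    nGa <- sum(isiTable$group == "Ga")
    if (bootstrap && nGa >= 2L) {
      gIsis <- lapply(presentGroups, function(g)
        isiTable$isi[isiTable$group == g])
      names(gIsis) <- presentGroups
      nIsis <- lapply(presentGroups, function(g)
        neutralIsi(neutral, matched[[g]]))
      names(nIsis) <- presentGroups
      boot <- bootstrapEqualized(gIsis, nIsis, targetN = nGa,
                                 nResamples = nResamples)
    }
  }
  list(classes = classes, isiTable = isiTable, neutral = neutral,
       comparisons = comparisons, bootstrap = boot)
}
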