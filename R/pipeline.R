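#' Run the full indel-selection analysis pipeline
#'
#' Orchestrates every stage on one annotation species: load transcripts,
#' select one isoform per gene, classify uORF groups, filter alignments
#' and extract 5'UTR indels, compute per-transcript ISIs, build the
#' neutral reference from G0 transcripts, and run the group comparisons
#' (matched Mann-Whitney U, Gv tertiles, size-equalising bootstrap with
#' pairwise KS tests). Stage tables are written to \code{outDir} as TSV,
#' together with a machine-readable \code{results.json} and a plain-text
#' report.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{simulate}{arguments for \code{\link{simulationConfig}}; the
#'       dataset is generated and written under \code{outDir/input}.
#'       Mutually exclusive with \code{inputs}.}
#'     \item{inputs}{list of paths: \code{refGtf}, \code{refFasta},
#'       \code{othGtf}, \code{othFasta}, \code{maf}, \code{orthologs}.}
#'     \item{annotationSpecies}{label of the annotated species (defaults
#'       to the MAF reference species).}
#'     \item{selectionCriterion}{\code{"random"}, \code{"longest_utr"} or
#'       \code{"pure_utr"} (default \code{"longest_utr"}).}
#'     \item{pseudocount, nShuffles, nResamples, tieRule}{statistic
#'       settings (defaults 0.5, 1000, 1000, \code{"strict"}).}
#'     \item{seed}{mandatory integer.}
#'     \item{outDir}{output directory.}
#'   }
#' @param indelTable optional precomputed indel data.frame (columns as
#'   from \code{\link{extractIndels}}); when supplied, alignment filtering
#'   and extraction are skipped, so a run can resume from a cached stage
#'   table.
#' @return (invisibly) a list with the stage tables and test results.
#' @export
runPipeline <- function(config, indelTable = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config error: seed is mandatory")
  hasSim <- !is.null(config$simulate)
  hasInp <- !is.null(config$inputs)
  if (hasSim == hasInp)
    stop("config error: exactly one of 'simulate' or 'inputs' required")
  outDir <- config$outDir %||% stop("config error: outDir required")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  criterion <- config$selectionCriterion %||% "longest_utr"
  pseudocount <- config$pseudocount %||% 0.5
  nShuffles <- as.integer(config$nShuffles %||% 1000L)
  nResamples <- as.integer(config$nResamples %||% 1000L)
  tieRule <- config$tieRule %||% "strict"

  if (hasSim) {
    simArgs <- config$simulate
    if (is.null(simArgs$seed)) simArgs$seed <- config$seed
    simCfg <- do.call(simulationConfig, simArgs)
    paths <- emitDataset(simCfg, file.path(outDir, "input"))
    config$inputs <- list(refGtf = paths[["refGtf"]],
      refFasta = paths[["refFasta"]], othGtf = paths[["othGtf"]],
      othFasta = paths[["othFasta"]], maf = paths[["maf"]],
      orthologs = paths[["orthologs"]])
    config$annotationSpecies <- config$annotationSpecies %||%
      simCfg$species[1L]
  }
  inp <- config$inputs

  set.seed(config$seed)

  ## ---- load + select -------------------------------------------------------
  maf <- readMaf(inp$maf)
  annSpecies <- config$annotationSpecies %||% maf$refSpecies[1L]
  refTxs <- loadTranscripts(inp$refGtf, inp$refFasta, annSpecies)
  othTxs <- loadTranscripts(inp$othGtf, inp$othFasta, "other",
                            verbose = FALSE)
  ortho <- readOrthologPairs(inp$orthologs)
  genes <- buildGeneIsoformSets(refTxs)
  othGenes <- buildGeneIsoformSets(othTxs)

  selected <- list(); rejections <- list()
  for (i in seq_len(nrow(ortho))) {
    g1 <- ortho$geneId1[i]; g2 <- ortho$geneId2[i]
    if (is.null(genes[[g1]]) || is.null(othGenes[[g2]])) next
    tx <- selectTranscript(genes[[g1]], criterion,
                           seed = config$seed + i)
    otx <- selectTranscript(othGenes[[g2]], criterion,
                            seed = config$seed + i)
    if (is.null(tx) || is.null(otx)) {
      rejections[[length(rejections) + 1L]] <- data.frame(geneId = g1,
        reason = "no_qualifying_isoform", stringsAsFactors = FALSE)
      next
    }
    selected[[length(selected) + 1L]] <- list(tx = tx, otx = otx)
  }

  ## ---- indel catalogue -----------------------------------------------------
  if (is.null(indelTable)) {
    indRows <- list()
    keptTx <- list()
    for (s in selected) {
      tx <- s$tx
      exSpan <- range(c(IRanges::start(tx@exons) - 1L,
                        IRanges::end(tx@exons)))
      sub <- maf[maf$refChrom == tx@chrom &
                 maf$refStart < exSpan[2L] &
                 maf$refStart + maf$refSize > exSpan[1L], , drop = FALSE]
      fl <- filterAlignments(sub, tx, s$otx)
      if (!fl$accepted) {
        rejections[[length(rejections) + 1L]] <- data.frame(
          geneId = tx@geneId, reason = fl$reason, stringsAsFactors = FALSE)
        next
      }
      keptTx[[length(keptTx) + 1L]] <- tx
      ind <- extractIndels(fl$blocks, tx)
      if (nrow(ind)) indRows[[length(indRows) + 1L]] <- ind
    }
    indelTable <- if (length(indRows)) do.call(rbind, indRows) else
      data.frame(transcriptId = character(0), utrOffset = integer(0),
        lengthNt = integer(0), sizeClass = character(0),
        stringsAsFactors = FALSE)
  } else {
    keptTx <- lapply(selected, `[[`, "tx")
  }
  txList <- keptTx
  names(txList) <- vapply(txList, transcriptId, character(1))

  ## ---- classification + ISI ------------------------------------------------
  classes <- classifyTranscripts(txList)
  utrLengths <- stats::setNames(
    vapply(txList, utr5Length, integer(1)), names(txList))
  indByTx <- split(indelTable, indelTable$transcriptId)

  isiRows <- list()
  for (tid in names(indByTx)) {
    cl <- classes[classes$transcriptId == tid, ]
    if (!nrow(cl) || !cl$group %in% c("Ga", "Gs", "Gv")) next
    L <- utrLengths[[tid]]
    ref <- cl$referenceOffset
    if (ref <= 0L || ref >= L) next
    row <- computeIsi(indByTx[[tid]], L, ref, nShuffles,
      tieRule = tieRule, pseudocount = pseudocount, transcriptId = tid)
    row$group <- cl$group
    isiRows[[length(isiRows) + 1L]] <- row
  }
  isiTable <- if (length(isiRows)) do.call(rbind, isiRows) else NULL

  ## ---- neutral table -------------------------------------------------------
  g0Ids <- intersect(classes$transcriptId[classes$group == "G0"],
                     names(indByTx))
  deciles <- seq(10L, 90L, by = 10L)
  groupPercents <- integer(0)
  presentGroups <- if (is.null(isiTable)) character(0) else
    intersect(c("Ga", "Gs", "Gv"), unique(isiTable$group))
  for (g in presentGroups)
    groupPercents <- c(groupPercents, matchNeutral(
      classes[classes$transcriptId %in%
              isiTable$transcriptId[isiTable$group == g], ]))
  gvCl <- if ("Gv" %in% presentGroups)
    classes[classes$transcriptId %in%
            isiTable$transcriptId[isiTable$group == "Gv"], ] else NULL
  tertPercents <- integer(0)
  if (!is.null(gvCl) && nrow(gvCl) >= 3L) {
    ord <- order(gvCl$relativePosition, gvCl$transcriptId)
    nGv <- nrow(gvCl)
    sizes <- rep(nGv %/% 3L, 3L)
    if (nGv %% 3L) sizes[seq_len(nGv %% 3L)] <- sizes[seq_len(nGv %% 3L)] + 1L
    bnd <- cumsum(sizes); st <- c(1L, bnd[-3L] + 1L)
    tertPercents <- vapply(1:3, function(j)
      matchNeutral(gvCl[ord, ][st[j]:bnd[j], ]), integer(1))
  }
  neutral <- NULL
  if (length(g0Ids) >= 2L) {
    neutral <- buildNeutralTable(
      indelTable[indelTable$transcriptId %in% g0Ids, ],
      utrLengths[g0Ids],
      percents = sort(unique(c(deciles, groupPercents, tertPercents))),
      nShuffles = nShuffles, tieRule = tieRule, pseudocount = pseudocount)
  }

  ## ---- comparisons ---------------------------------------------------------
  comparisons <- NULL; tertiles <- NULL; bootstrap <- NULL
  if (!is.null(neutral) && !is.null(isiTable)) {
    comp <- list()
    for (g in presentGroups) {
      gi <- isiTable$isi[isiTable$group == g]
      if (length(gi) < 2L) next
      mp <- matchNeutral(classes[classes$transcriptId %in%
        isiTable$transcriptId[isiTable$group == g], ])
      comp[[g]] <- compareGroup(gi, neutralIsi(neutral, mp),
                                group = g, matchedPercent = mp)
    }
    comparisons <- if (length(comp)) do.call(rbind, comp) else NULL

    if (!is.null(gvCl) && nrow(gvCl) >= 3L) {
      gvIsis <- stats::setNames(
        isiTable$isi[isiTable$group == "Gv"],
        isiTable$transcriptId[isiTable$group == "Gv"])
      tertiles <- tertileAnalysis(gvCl, gvIsis, neutral, group = "Gv")
    }

    nGa <- sum(isiTable$group == "Ga")
    bootGroups <- presentGroups[vapply(presentGroups, function(g)
      sum(isiTable$group == g) >= 2L, logical(1))]
    if (nGa >= 2L && length(bootGroups)) {
      gIsis <- lapply(bootGroups, function(g)
        isiTable$isi[isiTable$group == g])
      names(gIsis) <- bootGroups
      nIsis <- lapply(bootGroups, function(g)
        neutralIsi(neutral, comparisons$matchedPercent[
          comparisons$group == g]))
      names(nIsis) <- bootGroups
      bootstrap <- bootstrapEqualized(gIsis, nIsis, targetN = nGa,
        nResamples = nResamples, seed = config$seed + 104729L)
    }
  }

  ## ---- outputs -------------------------------------------------------------
  wt <- function(df, name) if (!is.null(df))
    utils::write.table(df, file.path(outDir, name), sep = "\t",
      quote = FALSE, row.names = FALSE)
  writeTranscriptTable(txList, file.path(outDir, "transcripts.tsv"))
  wt(classes, "classes.tsv")
  wt(indelTable, "indels.tsv")
  wt(isiTable, "isi.tsv")
  if (!is.null(neutral)) wt(neutral@table, "neutral_isi.tsv")
  wt(comparisons, "comparisons.tsv")
  wt(tertiles, "tertiles.tsv")
  rej <- if (length(rejections)) do.call(rbind, rejections) else
    data.frame(geneId = character(0), reason = character(0))
  wt(rej, "rejections.tsv")
  if (!is.null(bootstrap)) {
    wt(bootstrap$summary, "bootstrap_summary.tsv")
    wt(bootstrap$ks, "bootstrap_ks.tsv")
    pv <- do.call(cbind, bootstrap$pValues)
    utils::write.table(pv, file.path(outDir, "bootstrap_pvalues.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  results <- list(
    nTranscripts = length(txList),
    groupCounts = as.list(table(classes$group)),
    nIndels = nrow(indelTable),
    comparisons = comparisons, tertiles = tertiles,
    bootstrapSummary = if (!is.null(bootstrap)) bootstrap$summary else NULL,
    bootstrapKs = if (!is.null(bootstrap)) bootstrap$ks else NULL,
    neutralSweep = if (!is.null(neutral)) {
      sw <- neutralSweepMedians(neutral)
      sw[sw$percent %in% deciles, ]
    } else NULL,
    rejections = as.list(table(rej$reason)))
  jsonlite::write_json(results, file.path(outDir, "results.json"),
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)

  rpt <- file.path(outDir, "report.txt")
  lines <- c("Indel selection analysis report", "",
    sprintf("Transcripts analysed: %d; indels: %d",
            length(txList), nrow(indelTable)),
    sprintf("Group sizes: %s", paste(names(table(classes$group)),
            table(classes$group), sep = "=", collapse = ", ")))
  if (!is.null(comparisons))
    lines <- c(lines, "", "Group vs matched neutral (Mann-Whitney U):",
      sprintf("  %s (G0 at %d%%): median %.3f vs %.3f, U=%.1f, P=%.3g %s",
        comparisons$group, comparisons$matchedPercent,
        comparisons$medianGroupIsi, comparisons$medianNeutralIsi,
        comparisons$uStatistic, comparisons$pValue,
        comparisons$significance))
  if (!is.null(bootstrap))
    lines <- c(lines, "", "Size-equalised bootstrap:",
      sprintf("  %s: F_sig = %.3f (n = %d resamples of %d)",
        bootstrap$summary$group, bootstrap$summary$fSig,
        bootstrap$summary$nResamples, bootstrap$summary$targetN))
  writeLines(lines, rpt)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
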