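#' Simulation configuration for the synthetic-evolution generator
#'
#' Defines the generative model for complete synthetic inputs: spliced
#' transcripts with a 5'UTR and CDS, a planted uAUG of a chosen uORF type
#' per non-G0 transcript, indels placed uniformly along the 5'UTR, and an
#' optional purifying-selection step that removes non-3n indels downstream
#' of the uAUG with probability \code{selectionStrength}.
#'
#' Defaults emulate the magnitudes reported for mammalian 5'UTRs: group
#' mixture 0.55/0.02/0.30/0.13 (G0/Ga/Gs/Gv), log-normal UTR lengths with
#' median 300 nt and 90th percentile under 1 kb, mean uAUG relative
#' positions 0.25 (Gs), 0.55 (Ga) and 0.60 (Gv) with a concentrated Beta
#' (sd about 0.03) so that one matched neutral percent represents a group,
#' Poisson(3) indels per transcript, and truncated-geometric indel lengths
#' on 1..100.
#'
#' @param nGenes number of genes (ignored when \code{groupCounts} given).
#' @param groupMixture named probabilities over G0/Ga/Gs/Gv.
#' @param groupCounts optional named integer vector of exact group sizes.
#' @param utrLogMean,utrLogSd log-normal parameters of the UTR length.
#' @param utrMin,utrMax UTR length bounds (resampled outside them).
#' @param uaugPosMean named means of the Beta relative-position
#'   distributions per group.
#' @param uaugPosConcentration Beta concentration (alpha + beta).
#' @param indelRate Poisson mean indels per transcript.
#' @param indelLengthProb geometric parameter of the length distribution.
#' @param maxIndelLength truncation bound (default 100).
#' @param selectionStrength s in [0, 1]: removal probability for a non-3n
#'   indel downstream of the uAUG.
#' @param selectedGroups subset of c("Ga", "Gs", "Gv") under selection.
#' @param cdsCodons number of CDS codons between the ATG and the stop.
#' @param species labels of the annotated and the aligned species.
#' @param seed mandatory integer seed.
#' @return validated config list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nGenes = 1000L,
    groupMixture = c(G0 = 0.55, Ga = 0.02, Gs = 0.30, Gv = 0.13),
    groupCounts = NULL,
    utrLogMean = log(300), utrLogSd = 0.7, utrMin = 30L, utrMax = 3000L,
    uaugPosMean = c(Ga = 0.55, Gs = 0.25, Gv = 0.60),
    uaugPosConcentration = 180,
    indelRate = 3, indelLengthProb = 0.25, maxIndelLength = 100L,
    selectionStrength = 0, selectedGroups = character(0),
    cdsCodons = 60L, species = c("speciesA", "speciesB"), seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(abs(sum(groupMixture) - 1) < 1e-8,
            all(groupMixture >= 0),
            all(c("G0", "Ga", "Gs", "Gv") %in% names(groupMixture)),
            indelRate >= 0, indelLengthProb > 0, indelLengthProb < 1,
            selectionStrength >= 0, selectionStrength <= 1,
            all(selectedGroups %in% c("Ga", "Gs", "Gv")),
            cdsCodons >= 8L, utrMin >= 20L, length(species) == 2L)
  structure(list(nGenes = as.integer(nGenes), groupMixture = groupMixture,
    groupCounts = groupCounts, utrLogMean = utrLogMean, utrLogSd = utrLogSd,
    utrMin = as.integer(utrMin), utrMax = as.integer(utrMax),
    uaugPosMean = uaugPosMean,
    uaugPosConcentration = uaugPosConcentration,
    indelRate = indelRate, indelLengthProb = indelLengthProb,
    maxIndelLength = as.integer(maxIndelLength),
    selectionStrength = selectionStrength,
    selectedGroups = selectedGroups, cdsCodons = as.integer(cdsCodons),
    species = species, seed = as.integer(seed)),
    class = "SimulationConfig")
}

## ---- alphabet-controlled sequence construction -----------------------------

## Random sequence (character vector) containing no ATG trinucleotide, also
## accounting for up to two context characters preceding it.
.randSeqNoATG <- function(n, prev = "") {
  if (n <= 0L) return(character(0))
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  ctx <- if (nzchar(prev)) strsplit(prev, "")[[1L]] else character(0)
  m <- length(ctx)
  repeat {
    y <- c(ctx, x)
    i <- which(y == "A")
    i <- i[i + 2L <= length(y)]
    viol <- i[y[i + 1L] == "T" & y[i + 2L] == "G"]
    viol <- viol[viol + 2L > m]          # must involve a new character
    if (!length(viol)) return(x)
    for (v in viol)                      # replace the G; cannot recreate ATG here
      x[v + 2L - m] <- sample(c("A", "C", "T"), 1L)
  }
}

.NO_A_CODONS <- apply(expand.grid(c("C", "G", "T"), c("C", "G", "T"),
                                  c("C", "G", "T")), 1L, paste0, collapse = "")

.ALL_CODONS <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 c("A", "C", "G", "T")), 1L, paste0,
                     collapse = "")
.NONSTOP_CODONS <- setdiff(.ALL_CODONS, .STOP_CODONS)

## CDS with guaranteed stop codons in both off-frames: the codon pairs
## ATA|AGG and CCT|AAC embed TAA in frames +1 and +2 respectively, so any
## out-of-frame uORF reading into the CDS terminates early.
.makeCds <- function(cdsCodons) {
  inner <- sample(.NONSTOP_CODONS, cdsCodons, replace = TRUE)
  inner[2:3] <- c("ATA", "AGG")
  inner[5:6] <- c("CCT", "AAC")
  paste0("ATG", paste(inner, collapse = ""),
         sample(.STOP_CODONS, 1L))
}

.drawUtrLength <- function(config) {
  repeat {
    L <- as.integer(round(stats::rlnorm(1L, config$utrLogMean,
                                        config$utrLogSd)))
    if (L >= config$utrMin && L <= config$utrMax) return(L)
  }
}

## Draw a uAUG offset for a group and make it satisfy the group's frame
## constraint; returns NA when no valid offset exists near the draw.
.drawUaugOffset <- function(config, group, L) {
  mu <- config$uaugPosMean[[group]]
  conc <- config$uaugPosConcentration
  u <- as.integer(round(stats::rbeta(1L, mu * conc, (1 - mu) * conc) * L))
  switch(group,
    Gs = { u <- min(max(u, 1L), L - 9L); if (u < 1L) NA_integer_ else u },
    Gv = {
      u <- min(max(u, 1L), L - 4L)
      if ((L - u) %% 3L == 0L)
        u <- if (u > 1L) u - 1L else u + 1L
      if (u < 1L || u > L - 4L || (L - u) %% 3L == 0L) NA_integer_ else u
    },
    Ga = {
      d <- (L - u) %% 3L
      if (d != 0L) {
        cand <- c(u - (3L - d), u + d)
        cand <- cand[cand >= 1L & cand <= L - 3L]
        if (!length(cand)) return(NA_integer_)
        u <- cand[1L]
      }
      if (u < 1L || u > L - 3L) NA_integer_ else u
    })
}

## Build a 5'UTR string with exactly the planted uORF structure (or none).
.buildUtr <- function(config, group, L, u) {
  if (group == "G0")
    return(paste(.randSeqNoATG(L), collapse = ""))
  prefix <- paste(.randSeqNoATG(u), collapse = "")
  if (group == "Gs") {
    nInner <- sample.int(min(8L, (L - u - 6L) %/% 3L), 1L)
    body <- paste(sample(.NO_A_CODONS, nInner, replace = TRUE),
                  collapse = "")
    stopC <- sample(.STOP_CODONS, 1L)
    tailLen <- L - u - 3L - nchar(body) - 3L
    tail <- paste(.randSeqNoATG(tailLen,
      prev = substr(stopC, 2L, 3L)), collapse = "")
    paste0(prefix, "ATG", body, stopC, tail)
  } else {
    ## Gv / Ga: no stop between the uAUG and the TIS (A-free tail)
    tailLen <- L - u - 3L
    tail <- sample(c("C", "G", "T"), tailLen, replace = TRUE)
    if (group == "Gv" && (L - u) %% 3L == 2L && tailLen >= 2L) {
      ## avoid a TGA stop straddling the TIS (..TG | A.. of the main ATG)
      if (tail[tailLen - 1L] == "T" && tail[tailLen] == "G")
        tail[tailLen] <- "C"
    }
    paste0(prefix, "ATG", paste(tail, collapse = ""))
  }
}

.TYPE_OF_GROUP <- c(Gs = "strict", Gv = "overlapping", Ga = "alternative")

## ---- indels ----------------------------------------------------------------

## Draw indels for one transcript. Each indel has a point location on
## 0..L (the transcript coordinate recovered by the alignment scanner: an
## insertion sits at the junction before that base; a deletion removes the
## preceding lengthNt bases). Features are spaced so that realized gap
## runs never merge in the alignment.
.drawIndels <- function(config, L) {
  k <- stats::rpois(1L, config$indelRate)
  empty <- data.frame(utrOffset = integer(0), lengthNt = integer(0),
    sizeClass = character(0), gapType = character(0),
    stringsAsFactors = FALSE)
  if (k == 0L) return(empty)
  len <- 1L + stats::rgeom(k, config$indelLengthProb)
  while (any(len > config$maxIndelLength))
    len[len > config$maxIndelLength] <-
      1L + stats::rgeom(sum(len > config$maxIndelLength),
                        config$indelLengthProb)
  for (try in 1:50) {
    o <- sample.int(L + 1L, k) - 1L            # distinct points on 0..L
    type <- ifelse(stats::runif(k) < 0.5 & o - len >= 0L, "del", "ins")
    lo <- ifelse(type == "del", o - len, o)
    ord <- order(lo)
    oS <- o[ord]; loS <- lo[ord]; lenS <- len[ord]; typeS <- type[ord]
    hi <- ifelse(typeS == "del", oS, oS)       # feature right edge = point
    if (k == 1L || all(loS[-1L] >= hi[-k] + 1L)) {
      return(data.frame(utrOffset = oS, lengthNt = lenS,
        sizeClass = ifelse(lenS %% 3L == 0L, "3n", "n3n"),
        gapType = typeS, stringsAsFactors = FALSE))
    }
  }
  ## fall back: greedy subset that satisfies the spacing constraint
  ord <- order(lo)
  keep <- logical(k); lastHi <- -2L
  for (i in ord) {
    if (lo[i] >= lastHi + 1L) { keep[i] <- TRUE; lastHi <- o[i] }
  }
  data.frame(utrOffset = o[keep], lengthNt = len[keep],
    sizeClass = ifelse(len[keep] %% 3L == 0L, "3n", "n3n"),
    gapType = type[keep], stringsAsFactors = FALSE)[order(o[keep]), ]
}

## Realize surviving indels as a gapped pairwise alignment of the full
## reference transcript sequence against a derived sequence.
.buildAlignment <- function(refSeq, indels) {
  n <- nchar(refSeq)
  if (!nrow(indels)) {
    oth <- refSeq
    return(list(refText = refSeq, othText = oth, othSeq = oth))
  }
  ind <- indels[order(ifelse(indels$gapType == "del",
    indels$utrOffset - indels$lengthNt, indels$utrOffset)), , drop = FALSE]
  refParts <- character(0); othParts <- character(0)
  cursor <- 0L
  for (i in seq_len(nrow(ind))) {
    o <- ind$utrOffset[i]; len <- ind$lengthNt[i]
    if (ind$gapType[i] == "ins") {
      if (o > cursor) {
        seg <- substr(refSeq, cursor + 1L, o)
        refParts <- c(refParts, seg); othParts <- c(othParts, seg)
      }
      refParts <- c(refParts, strrep("-", len))
      othParts <- c(othParts, paste(sample(c("A", "C", "G", "T"), len,
        replace = TRUE), collapse = ""))
      cursor <- o
    } else {
      a <- o - len
      if (a > cursor) {
        seg <- substr(refSeq, cursor + 1L, a)
        refParts <- c(refParts, seg); othParts <- c(othParts, seg)
      }
      refParts <- c(refParts, substr(refSeq, a + 1L, o))
      othParts <- c(othParts, strrep("-", len))
      cursor <- o
    }
  }
  if (cursor < n) {
    seg <- substr(refSeq, cursor + 1L, n)
    refParts <- c(refParts, seg); othParts <- c(othParts, seg)
  }
  refText <- paste(refParts, collapse = "")
  othText <- paste(othParts, collapse = "")
  list(refText = refText, othText = othText,
       othSeq = gsub("-", "", othText, fixed = TRUE))
}

## ---- gene-level generation -------------------------------------------------

## Core generator: draws one gene under the current RNG state.
.genGeneCore <- function(config, group = NULL) {
  if (is.null(group))
    group <- sample(names(config$groupMixture), 1L,
                    prob = config$groupMixture)
  cds <- .makeCds(config$cdsCodons)
  for (attempt in 1:40) {
    L <- .drawUtrLength(config)
    u <- if (group == "G0") NA_integer_ else
      .drawUaugOffset(config, group, L)
    if (group != "G0" && is.na(u)) next
    utr <- .buildUtr(config, group, L, u)
    uorfs <- .scanUaugsCore(utr, cds)
    ok <- if (group == "G0") nrow(uorfs) == 0L else
      nrow(uorfs) == 1L && uorfs$uaugOffset == u &&
        uorfs$uorfType == .TYPE_OF_GROUP[[group]]
    if (!ok) next

    indels <- .drawIndels(config, L)
    kept <- rep(TRUE, nrow(indels))
    if (group %in% config$selectedGroups && nrow(indels)) {
      target <- indels$sizeClass == "n3n" & indels$utrOffset >= u
      kept[target] <- stats::runif(sum(target)) >= config$selectionStrength
    }
    refSeq <- paste0(utr, cds)
    aln <- .buildAlignment(refSeq, indels[kept, , drop = FALSE])
    othUtrLen <- L +
      sum(indels$lengthNt[kept & indels$gapType == "ins"]) -
      sum(indels$lengthNt[kept & indels$gapType == "del"])
    if (othUtrLen < 1L) next
    return(list(group = group, L = L, uaugOffset = u,
      uorfType = if (group == "G0") NA_character_ else
        .TYPE_OF_GROUP[[group]],
      utr = utr, cds = cds, refSeq = refSeq,
      indels = cbind(indels, kept = kept),
      refText = aln$refText, othText = aln$othText, othSeq = aln$othSeq,
      othUtrLen = othUtrLen))
  }
  stop("could not generate a ", group,
       " transcript satisfying its planted structure")
}

#' Generate one synthetic gene
#'
#' Draws a gene under the configured distributions: its group, 5'UTR
#' length, planted uAUG (engineered to exactly the planted uORF type by
#' alphabet control: no incidental ATG can arise in the UTR), indels, the
#' selection step, and the derived (aligned) sequence. The emitted
#' transcript pair is placed at position 0 of a standalone chromosome.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param geneIndex integer used for the gene/transcript IDs and, together
#'   with the config seed, for the RNG stream.
#' @return list with \code{transcript} and \code{otherTranscript}
#'   (\linkS4class{TranscriptModel}) and \code{truth} (group, planted
#'   uAUG offset and type, indel table with \code{kept} flags).
#' @export
generateGene <- function(config, geneIndex = 1L) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 7919L * (geneIndex %% 100000L))
  g <- .genGeneCore(config)
  gid <- sprintf("g%05d", geneIndex)
  tid <- sprintf("t%05d", geneIndex)
  tx <- TranscriptModel(gid, tid, config$species[1L], "chr1", "+",
    c(0L, nchar(g$refSeq)), nchar(g$utr), g$utr, g$cds)
  othTx <- TranscriptModel(gid, tid, config$species[2L], "chr1", "+",
    c(0L, nchar(g$othSeq)), g$othUtrLen,
    substr(g$othSeq, 1L, g$othUtrLen),
    substr(g$othSeq, g$othUtrLen + 1L, nchar(g$othSeq)))
  list(transcript = tx, otherTranscript = othTx,
    truth = list(group = g$group, uaugOffset = g$uaugOffset,
      uorfType = g$uorfType, utr5Length = g$L, indels = g$indels))
}

#' Simulate a complete two-species dataset
#'
#' Generates \code{nGenes} genes (or the exact \code{groupCounts}), lays
#' them out with 100-nt spacers on one chromosome per species, and
#' produces everything the pipeline consumes: transcript models for both
#' species, pairwise alignment blocks realizing exactly the surviving
#' indels as gaps, the ortholog pairing, and the ground truth.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with elements \code{config}, \code{refTranscripts},
#'   \code{othTranscripts}, \code{truthTranscripts} (data.frame),
#'   \code{truthIndels} (data.frame with \code{kept}), \code{blocks}
#'   (alignment data.frame as from \code{\link{readMaf}}),
#'   \code{orthologs}, \code{refGenome}, \code{othGenome}
#'   (\link[Biostrings]{DNAStringSet}).
#' @export
simulateDataset <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  groups <- if (!is.null(config$groupCounts)) {
    stopifnot(all(names(config$groupCounts) %in% c("G0", "Ga", "Gs", "Gv")))
    rep(names(config$groupCounts), config$groupCounts)
  } else if (config$nGenes > 0L) {
    sample(names(config$groupMixture), config$nGenes, replace = TRUE,
           prob = config$groupMixture)
  } else character(0)

  spacer <- 100L
  n <- length(groups)
  genes <- vector("list", n)
  for (i in seq_len(n)) genes[[i]] <- .genGeneCore(config, groups[i])

  refLens <- vapply(genes, function(g) nchar(g$refSeq), integer(1))
  othLens <- vapply(genes, function(g) nchar(g$othSeq), integer(1))
  refStarts <- spacer + c(0L, cumsum(refLens + spacer))[seq_len(n)]
  othStarts <- spacer + c(0L, cumsum(othLens + spacer))[seq_len(n)]
  refChromLen <- spacer + sum(refLens + spacer)
  othChromLen <- spacer + sum(othLens + spacer)

  mkSpacer <- function() paste(sample(c("A", "C", "G", "T"), spacer,
                                      replace = TRUE), collapse = "")
  refChunks <- character(0); othChunks <- character(0)
  for (i in seq_len(n)) {
    refChunks <- c(refChunks, mkSpacer(), genes[[i]]$refSeq)
    othChunks <- c(othChunks, mkSpacer(), genes[[i]]$othSeq)
  }
  refChunks <- c(refChunks, mkSpacer())
  othChunks <- c(othChunks, mkSpacer())
  refGenome <- Biostrings::DNAStringSet(paste(refChunks, collapse = ""))
  othGenome <- Biostrings::DNAStringSet(paste(othChunks, collapse = ""))
  names(refGenome) <- names(othGenome) <- "chr1"

  refTx <- vector("list", n); othTx <- vector("list", n)
  truthTx <- vector("list", n); truthInd <- vector("list", n)
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    g <- genes[[i]]
    gid <- sprintf("g%05d", i); tid <- sprintf("t%05d", i)
    refTx[[i]] <- TranscriptModel(gid, tid, config$species[1L], "chr1", "+",
      c(refStarts[i], refStarts[i] + refLens[i]), g$L, g$utr, g$cds)
    othTx[[i]] <- TranscriptModel(gid, tid, config$species[2L], "chr1", "+",
      c(othStarts[i], othStarts[i] + othLens[i]), g$othUtrLen,
      substr(g$othSeq, 1L, g$othUtrLen),
      substr(g$othSeq, g$othUtrLen + 1L, nchar(g$othSeq)))
    truthTx[[i]] <- data.frame(geneId = gid, transcriptId = tid,
      group = g$group, uaugOffset = g$uaugOffset,
      uorfType = g$uorfType, utr5Length = g$L, stringsAsFactors = FALSE)
    if (nrow(g$indels))
      truthInd[[i]] <- cbind(data.frame(transcriptId = tid,
        stringsAsFactors = FALSE), g$indels)
    blocks[[i]] <- data.frame(block = i,
      refSpecies = config$species[1L], refChrom = "chr1",
      refStart = refStarts[i], refSize = refLens[i], refStrand = "+",
      refSrcSize = refChromLen, refText = g$refText,
      othSpecies = config$species[2L], othChrom = "chr1",
      othStart = othStarts[i], othSize = othLens[i], othStrand = "+",
      othSrcSize = othChromLen, othText = g$othText,
      stringsAsFactors = FALSE)
  }
  truthInd <- truthInd[!vapply(truthInd, is.null, logical(1))]
  emptyInd <- data.frame(transcriptId = character(0),
    utrOffset = integer(0), lengthNt = integer(0),
    sizeClass = character(0), gapType = character(0), kept = logical(0),
    stringsAsFactors = FALSE)
  list(config = config,
    refTranscripts = refTx, othTranscripts = othTx,
    truthTranscripts = if (n) do.call(rbind, truthTx) else NULL,
    truthIndels = if (length(truthInd)) do.call(rbind, truthInd)
                  else emptyInd,
    blocks = if (n) do.call(rbind, blocks) else
      data.frame(block = integer(0)),
    orthologs = data.frame(geneId1 = sprintf("g%05d", seq_len(n)),
      geneId2 = sprintf("g%05d", seq_len(n)), stringsAsFactors = FALSE),
    refGenome = refGenome, othGenome = othGenome)
}

.writeGtf <- function(transcripts, path, source = "synth") {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in transcripts) {
    ex <- tx@exons
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx@geneId, tx@transcriptId)
    for (i in seq_along(ex))
      writeLines(sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
        tx@chrom, source, IRanges::start(ex)[i], IRanges::end(ex)[i],
        tx@strand, attrs), con)
    cdsGr <- .txToGenomic(tx, tx@tisOffset,
                          tx@tisOffset + length(tx@cdsSeq))
    for (i in seq_along(cdsGr))
      writeLines(sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\t%s",
        tx@chrom, source, GenomicRanges::start(cdsGr)[i],
        GenomicRanges::end(cdsGr)[i], tx@strand, attrs), con)
  }
  invisible(path)
}

#' Write a simulated dataset to disk
#'
#' Emits, per species, a genome FASTA and a GTF (Ensembl dialect; CDS
#' features include the stop codon), plus the pairwise MAF, the ortholog
#' TSV, the ground-truth JSON and a config echo (YAML). Running the full
#' pipeline on these files reproduces the in-memory indel catalogue
#' exactly. Reruns with the same config are byte-identical.
#'
#' @param sim result of \code{\link{simulateDataset}} (or a
#'   \code{\link{simulationConfig}}, which is simulated first).
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
emitDataset <- function(sim, dir) {
  if (inherits(sim, "SimulationConfig")) sim <- simulateDataset(sim)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- sim$config$species
  paths <- c(
    refFasta = file.path(dir, paste0("genome_", sp[1L], ".fa")),
    othFasta = file.path(dir, paste0("genome_", sp[2L], ".fa")),
    refGtf = file.path(dir, paste0("annotation_", sp[1L], ".gtf")),
    othGtf = file.path(dir, paste0("annotation_", sp[2L], ".gtf")),
    maf = file.path(dir, "alignment.maf"),
    orthologs = file.path(dir, "orthologs.tsv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml"))
  Biostrings::writeXStringSet(sim$refGenome, paths[["refFasta"]])
  Biostrings::writeXStringSet(sim$othGenome, paths[["othFasta"]])
  .writeGtf(sim$refTranscripts, paths[["refGtf"]])
  .writeGtf(sim$othTranscripts, paths[["othGtf"]])
  writeMaf(sim$blocks, paths[["maf"]])
  utils::write.table(sim$orthologs, paths[["orthologs"]], sep = "\t",
    quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    transcripts = sim$truthTranscripts, indels = sim$truthIndels),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, na = "null")
  cfg <- sim$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, paths[["config"]])
  paths
}
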