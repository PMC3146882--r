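#' Matched neutral percent for a transcript group
#'
#' The neutral distribution used for a uORF group is the one whose
#' artificial reference point sits at the group's median uAUG position:
#' round(100 * median(relativePosition)), clamped to [1, 99].
#'
#' @param groupClasses data.frame of transcript classes (see
#'   \code{\link{classifyTranscript}}) for one group.
#' @return integer percent in 1..99.
#' @export
matchNeutral <- function(groupClasses) {
  pos <- groupClasses$relativePosition
  pos <- pos[!is.na(pos)]
  if (!length(pos)) stop("empty group: no relative positions")
  min(max(as.integer(round(100 * stats::median(pos))), 1L), 99L)
}

.stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Compare a group's ISI distribution with its matched neutral reference
#'
#' Two-sided Mann-Whitney U test (exact for small tie-free samples, normal
#' approximation with tie correction otherwise, as implemented by
#' \code{\link[stats]{wilcox.test}}).
#'
#' @param groupIsis,neutralIsis numeric vectors of ISI values (each of
#'   length >= 2).
#' @param group label carried into the result.
#' @param matchedPercent integer percent carried into the result.
#' @return one-row data.frame: \code{group}, \code{matchedPercent},
#'   \code{nGroup}, \code{nNeutral}, \code{medianGroupIsi},
#'   \code{medianNeutralIsi}, \code{uStatistic}, \code{pValue},
#'   \code{significance} (star band).
#' @export
compareGroup <- function(groupIsis, neutralIsis, group = NA_character_,
                         matchedPercent = NA_integer_) {
  if (length(groupIsis) < 2L || length(neutralIsis) < 2L)
    stop("each ISI multiset needs at least 2 values")
  wt <- suppressWarnings(stats::wilcox.test(groupIsis, neutralIsis,
    alternative = "two.sided"))
  data.frame(group = group, matchedPercent = matchedPercent,
    nGroup = length(groupIsis), nNeutral = length(neutralIsis),
    medianGroupIsi = stats::median(groupIsis),
    medianNeutralIsi = stats::median(neutralIsis),
    uStatistic = unname(wt$statistic), pValue = wt$p.value,
    significance = .stars(wt$p.value), stringsAsFactors = FALSE)
}

#' Tertile analysis of uAUG position within a group
#'
#' Sorts the group's indel-containing transcripts by the relative position
#' of their uAUG and splits them into three contiguous subgroups whose
#' sizes differ by at most one (remainder to the earliest subgroups; ties
#' in position broken by transcript ID). Each subgroup is matched to the
#' neutral table at its own median percent and compared independently;
#' subgroup 1 is closest to the cap.
#'
#' @param groupClasses data.frame of transcript classes for the group
#'   (indel-containing transcripts only).
#' @param isis named numeric vector of ISI values, names are transcript
#'   IDs covering \code{groupClasses$transcriptId}.
#' @param table a \linkS4class{NeutralIsiTable} covering the matched
#'   percents.
#' @param group base label; subgroups are suffixed \code{_1.._3}.
#' @return data.frame of three \code{\link{compareGroup}} rows.
#' @export
tertileAnalysis <- function(groupClasses, isis, table, group = "Gv") {
  n <- nrow(groupClasses)
  if (n < 3L) stop("tertile analysis needs at least 3 transcripts")
  ord <- order(groupClasses$relativePosition, groupClasses$transcriptId)
  cls <- groupClasses[ord, , drop = FALSE]
  sizes <- rep(n %/% 3L, 3L)
  if (n %% 3L) sizes[seq_len(n %% 3L)] <- sizes[seq_len(n %% 3L)] + 1L
  bounds <- cumsum(sizes)
  starts <- c(1L, bounds[-3L] + 1L)
  out <- lapply(1:3, function(i) {
    sub <- cls[starts[i]:bounds[i], , drop = FALSE]
    mp <- matchNeutral(sub)
    compareGroup(isis[sub$transcriptId], neutralIsi(table, mp),
                 group = sprintf("%s_%d", group, i), matchedPercent = mp)
  })
  do.call(rbind, out)
}

#' Size-equalising bootstrap of group-vs-neutral P values
#'
#' For each group, \code{nResamples} bootstrap samples of size
#' \code{targetN} are drawn with replacement from the group's ISI values
#' and each is compared with the group's matched neutral distribution
#' (held fixed) by the Mann-Whitney U test. F_sig is the fraction of the
#' resulting P values below 0.05; P-value distributions of different
#' groups are compared pairwise with the two-sample Kolmogorov-Smirnov
#' test.
#'
#' @param groupIsis named list of numeric ISI vectors, one per group.
#' @param neutralIsis named list (same names) of matched neutral ISI
#'   vectors.
#' @param targetN resample size (>= 2); the size-equalising target,
#'   conventionally the smallest group's n.
#' @param nResamples number of bootstrap resamples (default 1000).
#' @param seed optional integer seed.
#' @return list with \code{summary} (data.frame: \code{group},
#'   \code{targetN}, \code{nResamples}, \code{fSig}), \code{pValues}
#'   (named list of numeric vectors) and \code{ks} (data.frame of pairwise
#'   \code{ksStatistic}, \code{ksP}).
#' @export
bootstrapEqualized <- function(groupIsis, neutralIsis, targetN,
                               nResamples = 1000L, seed = NULL) {
  if (nResamples < 1L) stop("nResamples must be >= 1")
  if (targetN < 2L) stop("targetN must be >= 2")
  stopifnot(identical(names(groupIsis), names(neutralIsis)))
  if (!is.null(seed)) set.seed(seed)
  pValues <- lapply(names(groupIsis), function(g) {
    gi <- groupIsis[[g]]; ni <- neutralIsis[[g]]
    vapply(seq_len(nResamples), function(i) {
      suppressWarnings(stats::wilcox.test(
        sample(gi, targetN, replace = TRUE), ni,
        alternative = "two.sided", exact = FALSE))$p.value
    }, numeric(1))
  })
  names(pValues) <- names(groupIsis)
  summary <- data.frame(group = names(pValues),
    targetN = as.integer(targetN), nResamples = as.integer(nResamples),
    fSig = vapply(pValues, function(p) mean(p < 0.05), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  ks <- NULL
  gn <- names(pValues)
  if (length(gn) > 1L) {
    pairs <- utils::combn(gn, 2L)
    ks <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1L, i]; b <- pairs[2L, i]
      kt <- suppressWarnings(stats::ks.test(pValues[[a]], pValues[[b]]))
      data.frame(groupA = a, groupB = b,
        ksStatistic = unname(kt$statistic), ksP = kt$p.value,
        stringsAsFactors = FALSE)
    }))
  }
  list(summary = summary, pValues = pValues, ks = ks)
}
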