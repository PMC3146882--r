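## Vectorized R statistic on downstream/upstream counts.
.rValue <- function(n3nDown, t3nDown, n3nUp, t3nUp, pseudocount = 0.5,
                    base = 2) {
  log(((n3nDown + pseudocount) / (t3nDown + pseudocount)) /
      ((n3nUp + pseudocount) / (t3nUp + pseudocount)), base = base)
}

#' The R statistic: log ratio-of-ratios of non-3n to 3n indel counts
#'
#' \deqn{R = \log_2 \frac{(N_{n3n,d}+c)/(N_{3n,d}+c)}
#'                       {(N_{n3n,u}+c)/(N_{3n,u}+c)}}
#' where the subscripts d and u denote the 5'UTR regions downstream and
#' upstream of the reference point and c is a pseudocount (default 0.5)
#' that keeps every term finite. The upstream non-3n/3n ratio serves as
#' the background: R equals zero when selection has no preference on indel
#' sizes across the 5'UTR, and is negative when non-3n indels are depleted
#' downstream. The log base only rescales R; the ISI, which depends on the
#' rank order of R values, is base-invariant.
#'
#' @param counts named or positional numeric vector of length 4 in the
#'   order \code{nonTripletDown}, \code{tripletDown}, \code{nonTripletUp},
#'   \code{tripletUp} (as returned by \code{\link{partitionIndels}}).
#' @param pseudocount positive real, default 0.5.
#' @param base logarithm base, default 2.
#' @return the R value (numeric scalar).
#' @examples
#' computeR(c(1, 3, 4, 2))   # log2((1.5/3.5)/(4.5/2.5)) ~ -2.07
#' @export
computeR <- function(counts, pseudocount = 0.5, base = 2) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  stopifnot(length(counts) == 4L, all(counts >= 0))
  if (!is.null(names(counts))) {
    want <- c("nonTripletDown", "tripletDown", "nonTripletUp", "tripletUp")
    if (all(want %in% names(counts))) counts <- counts[want]
  }
  .rValue(counts[[1L]], counts[[2L]], counts[[3L]], counts[[4L]],
          pseudocount, base)
}

## Normalise an indel argument to a logical vector: TRUE = non-3n.
.n3nFlags <- function(indels) {
  if (is.data.frame(indels)) {
    if ("sizeClass" %in% names(indels)) indels$sizeClass == "n3n"
    else indels$lengthNt %% 3L != 0L
  } else if (is.logical(indels)) indels
  else as.integer(indels) %% 3L != 0L   # lengths
}

.indelOffsets <- function(indels) {
  if (is.data.frame(indels)) indels$utrOffset else
    stop("observed offsets require a data.frame with a utrOffset column")
}

#' Shuffle-null distribution of R for one transcript
#'
#' Each shuffle redraws, independently for every indel, a location uniform
#' on the integer positions 0..utrLength (lengths and size classes are
#' retained), partitions the configuration at the reference point and
#' scores it with the R statistic.
#'
#' @param indels data.frame with \code{sizeClass} (or \code{lengthNt})
#'   columns, or a logical vector flagging non-3n indels.
#' @param utrLength 5'UTR length in nt.
#' @param referenceOffset integer reference point, strictly inside
#'   (0, utrLength).
#' @param nShuffles number of shuffles (default 1000).
#' @param seed optional integer seed.
#' @param pseudocount,base passed to the R statistic.
#' @return numeric vector of \code{nShuffles} shuffled R values.
#' @export
shuffleNull <- function(indels, utrLength, referenceOffset,
                        nShuffles = 1000L, seed = NULL,
                        pseudocount = 0.5, base = 2) {
  n3n <- .n3nFlags(indels)
  k <- length(n3n)
  if (k < 1L) stop("need at least one indel")
  if (nShuffles < 1L) stop("nShuffles must be >= 1")
  if (referenceOffset <= 0L || referenceOffset >= utrLength)
    stop("referenceOffset must lie strictly inside (0, utrLength)")
  if (!is.null(seed)) set.seed(seed)
  down <- matrix(sample.int(utrLength + 1L, k * nShuffles, replace = TRUE) - 1L
                 >= referenceOffset, nrow = k)
  k1 <- sum(n3n); k2 <- k - k1
  d1 <- if (k1) colSums(down[n3n, , drop = FALSE]) else rep(0L, nShuffles)
  d2 <- if (k2) colSums(down[!n3n, , drop = FALSE]) else rep(0L, nShuffles)
  .rValue(d1, d2, k1 - d1, k2 - d2, pseudocount, base)
}

.isiRow <- function(transcriptId, rObserved, nShuffles, nSmaller, nTied,
                    isi, exact) {
  data.frame(transcriptId = transcriptId, rObserved = rObserved,
    nShuffles = nShuffles, nSmaller = nSmaller, nTied = nTied,
    isi = isi, exact = exact, stringsAsFactors = FALSE)
}

#' The Indel Selection Index (ISI) by positional shuffling
#'
#' The ISI is the proportion of shuffled indel configurations whose R
#' value is smaller than the observed R (strict rule, the default). A low
#' ISI indicates depletion of non-3n indels downstream of the reference
#' point. The \code{midp} rule adds half of the tied shuffles, which
#' centres the null ISI at 0.5; under the strict rule, configurations
#' whose shuffles always tie (e.g. no non-3n indel anywhere) get ISI 0.
#'
#' @inheritParams shuffleNull
#' @param indels data.frame with \code{utrOffset} and \code{sizeClass}
#'   columns for the observed configuration.
#' @param tieRule \code{"strict"} (proportion strictly smaller) or
#'   \code{"midp"}.
#' @param transcriptId label carried into the result.
#' @return one-row data.frame: \code{transcriptId}, \code{rObserved},
#'   \code{nShuffles}, \code{nSmaller}, \code{nTied}, \code{isi},
#'   \code{exact} (FALSE).
#' @export
computeIsi <- function(indels, utrLength, referenceOffset,
                       nShuffles = 1000L, seed = NULL,
                       tieRule = c("strict", "midp"),
                       pseudocount = 0.5, base = 2,
                       transcriptId = NA_character_) {
  tieRule <- match.arg(tieRule)
  counts <- partitionIndels(indels, referenceOffset)
  rObs <- computeR(counts, pseudocount, base)
  rs <- shuffleNull(indels, utrLength, referenceOffset, nShuffles, seed,
                    pseudocount, base)
  tol <- 1e-9
  nSmaller <- sum(rs < rObs - tol)
  nTied <- sum(abs(rs - rObs) <= tol)
  isi <- if (tieRule == "strict") nSmaller / nShuffles else
    (nSmaller + 0.5 * nTied) / nShuffles
  .isiRow(transcriptId, rObs, as.integer(nShuffles), nSmaller, nTied,
          isi, FALSE)
}

#' Exact ISI by enumeration of the placement distribution
#'
#' Under uniform independent placement on the integer positions
#' 0..utrLength, the downstream counts of the two size classes are
#' independent binomials with success probability
#' p = (utrLength - referenceOffset + 1) / (utrLength + 1). Since R
#' depends only on the four counts, P(R_shuffled < R_observed) (and the
#' tie mass) is obtained exactly by summing binomial probabilities over
#' the (k_n3n + 1)(k_3n + 1) downstream-count outcomes. Serves as the
#' closed-form oracle for \code{\link{computeIsi}}.
#'
#' @inheritParams computeIsi
#' @param maxIndels guard: enumeration is refused above this many indels.
#' @return one-row data.frame as \code{\link{computeIsi}}, with
#'   \code{exact = TRUE} and expected shuffle counts scaled to
#'   \code{nShuffles = 1}.
#' @export
exactIsi <- function(indels, utrLength, referenceOffset,
                     tieRule = c("strict", "midp"),
                     pseudocount = 0.5, base = 2, maxIndels = 12L,
                     transcriptId = NA_character_) {
  tieRule <- match.arg(tieRule)
  n3n <- .n3nFlags(indels)
  k <- length(n3n)
  if (k < 1L) stop("need at least one indel")
  if (k > maxIndels)
    stop("too many indels for enumeration; use computeIsi")
  if (referenceOffset <= 0L || referenceOffset >= utrLength)
    stop("referenceOffset must lie strictly inside (0, utrLength)")
  counts <- partitionIndels(indels, referenceOffset)
  rObs <- computeR(counts, pseudocount, base)
  k1 <- sum(n3n); k2 <- k - k1
  p <- (utrLength - referenceOffset + 1) / (utrLength + 1)
  grid <- expand.grid(d1 = 0:k1, d2 = 0:k2)
  pr <- stats::dbinom(grid$d1, k1, p) * stats::dbinom(grid$d2, k2, p)
  rv <- .rValue(grid$d1, grid$d2, k1 - grid$d1, k2 - grid$d2,
                pseudocount, base)
  tol <- 1e-9
  pSmaller <- sum(pr[rv < rObs - tol])
  pTied <- sum(pr[abs(rv - rObs) <= tol])
  isi <- if (tieRule == "strict") pSmaller else pSmaller + 0.5 * pTied
  .isiRow(transcriptId, rObs, 1L, pSmaller, pTied, isi, TRUE)
}
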