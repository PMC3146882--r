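#' Read a pairwise MAF alignment file
#'
#' Minimal reader for pairwise MAF: each alignment block must contain
#' exactly two \code{s} lines; the first is taken as the reference species.
#' Sources of the form \code{species.chrom} are split into species and
#' chromosome. Only plus-strand reference rows are supported.
#'
#' @param path MAF file path.
#' @return data.frame with one row per block: reference and other species
#'   locator columns (\code{refSpecies}, \code{refChrom}, \code{refStart}
#'   0-based, \code{refSize}, \code{refStrand}, \code{refSrcSize},
#'   \code{refText}, and the \code{oth*} mirror) plus \code{block} index.
#' @export
readMaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  sIdx <- grep("^s\\s", lines)
  aIdx <- grep("^a", lines)
  if (length(sIdx) %% 2L != 0L)
    stop("malformed MAF: expected pairs of 's' lines")
  parseS <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    list(src = f[2L], start = as.integer(f[3L]), size = as.integer(f[4L]),
         strand = f[5L], srcSize = as.integer(f[6L]), text = toupper(f[7L]))
  }
  n <- length(sIdx) %/% 2L
  rows <- vector("list", n)
  for (b in seq_len(n)) {
    r <- parseS(lines[sIdx[2L * b - 1L]])
    o <- parseS(lines[sIdx[2L * b]])
    if (nchar(r$text) != nchar(o$text))
      stop("malformed MAF block ", b, ": rows of unequal length")
    ungapped <- nchar(gsub("-", "", r$text, fixed = TRUE))
    if (ungapped != r$size)
      stop("malformed MAF block ", b, ": ref size disagrees with text")
    splitSrc <- function(src) {
      dot <- regexpr(".", src, fixed = TRUE)
      if (dot < 0) c(src, src) else
        c(substr(src, 1L, dot - 1L), substr(src, dot + 1L, nchar(src)))
    }
    rs <- splitSrc(r$src); os <- splitSrc(o$src)
    rows[[b]] <- data.frame(block = b,
      refSpecies = rs[1L], refChrom = rs[2L], refStart = r$start,
      refSize = r$size, refStrand = r$strand, refSrcSize = r$srcSize,
      refText = r$text,
      othSpecies = os[1L], othChrom = os[2L], othStart = o$start,
      othSize = o$size, othStrand = o$strand, othSrcSize = o$srcSize,
      othText = o$text, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(block = integer(0))
  if (nrow(out) && any(out$refStrand != "+"))
    stop("only plus-strand reference rows are supported")
  out
}

#' Write pairwise alignment blocks as MAF
#'
#' @param blocks data.frame in the layout returned by \code{\link{readMaf}}.
#' @param path output path.
#' @export
writeMaf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    writeLines(c("a score=0.0",
      sprintf("s %s.%s %d %d %s %d %s", b$refSpecies, b$refChrom,
        b$refStart, b$refSize, b$refStrand, b$refSrcSize, b$refText),
      sprintf("s %s.%s %d %d %s %d %s", b$othSpecies, b$othChrom,
        b$othStart, b$othSize, b$othStrand, b$othSrcSize, b$othText),
      ""), con)
  }
  invisible(path)
}
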