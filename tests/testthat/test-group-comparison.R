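# Neutral matching, Mann-Whitney comparisons, tertiles and the bootstrap.

test_that("matched percent is the rounded median relative position", {
  cl <- function(p) data.frame(transcriptId = paste0("t", seq_along(p)),
    relativePosition = p)
  expect_identical(matchNeutral(cl(c(0.2, 0.5, 0.8))), 50L)
  expect_identical(matchNeutral(cl(c(0.695, 0.696))), 70L)
  expect_identical(matchNeutral(cl(0.254)), 25L)
  expect_identical(matchNeutral(cl(0.001)), 1L)   # clamped into 1..99
  expect_error(matchNeutral(data.frame(relativePosition = numeric(0))),
               "empty")
})

test_that("comparing a distribution with itself is non-significant", {
  x <- c(0.1, 0.2, 0.3, 0.5, 0.6, 0.9, 0.4, 0.7)
  r <- compareGroup(x, x)
  expect_gte(r$pValue, 0.95)
  expect_identical(r$significance, "")
  expect_error(compareGroup(0.5, x), "at least 2")
})

test_that("small-sample MWU matches full rank-arrangement enumeration", {
  g <- c(0.11, 0.52, 0.93)
  n <- c(0.27, 0.35, 0.81)
  r <- compareGroup(g, n)
  # brute-force permutation null over all 20 splits of the pooled values
  pool <- c(g, n)
  uOf <- function(a, b) sum(outer(a, b, ">")) # Mann-Whitney U of a over b
  uObs <- uOf(g, n)
  splits <- combn(6, 3)
  uAll <- apply(splits, 2, function(ix) uOf(pool[ix], pool[-ix]))
  pExact <- mean(abs(uAll - 4.5) >= abs(uObs - 4.5))
  expect_equal(r$pValue, pExact, tolerance = 1e-12)
  # wilcox.test's W equals the U statistic of the first sample
  expect_equal(r$uStatistic, uObs)
})

test_that("the comparison P value is symmetric under swapping the samples", {
  set.seed(8)
  a <- runif(30); b <- runif(25) * 0.8
  expect_equal(compareGroup(a, b)$pValue, compareGroup(b, a)$pValue,
               tolerance = 1e-12)
})

test_that("a constructed downward shift is strongly significant with stars", {
  set.seed(9)
  neutral <- runif(400)
  group <- pmax(0, runif(150) - 0.3)
  r <- compareGroup(group, neutral)
  expect_lt(r$pValue, 0.001)
  expect_identical(r$significance, "***")
  expect_lt(r$medianGroupIsi, r$medianNeutralIsi)
})

test_that("tertile split sizes follow the remainder-first convention", {
  mkcl <- function(n) data.frame(transcriptId = sprintf("t%02d", 1:n),
    relativePosition = seq(0.05, 0.95, length.out = n))
  tb <- buildNeutralTable(
    data.frame(transcriptId = rep(sprintf("g%02d", 1:30), each = 2),
      utrOffset = rep(c(20L, 150L), 30), lengthNt = rep(c(1L, 2L), 30),
      sizeClass = "n3n"),
    setNames(rep(200L, 30), sprintf("g%02d", 1:30)),
    percents = 1:99, nShuffles = 100L, seed = 1L)
  isis <- setNames(runif(10), sprintf("t%02d", 1:10))
  res10 <- tertileAnalysis(mkcl(10), isis, tb)
  expect_identical(res10$nGroup, c(4L, 3L, 3L))
  isis9 <- setNames(runif(9), sprintf("t%02d", 1:9))
  res9 <- tertileAnalysis(mkcl(9), isis9, tb)
  expect_identical(res9$nGroup, c(3L, 3L, 3L))
  # subgroup 1 is closest to the cap: matched percents increase
  expect_true(all(diff(res9$matchedPercent) > 0))
  expect_error(tertileAnalysis(mkcl(2), isis, tb), "at least 3")
})

test_that("tertiles of a selected Gv set all fall below matched neutral", {
  cfg <- simulationConfig(groupCounts = c(G0 = 400, Gv = 240),
    uaugPosMean = c(Ga = 0.55, Gs = 0.25, Gv = 0.50),
    uaugPosConcentration = 12,          # wide spread to give real tertiles
    selectionStrength = 0.9, selectedGroups = "Gv", seed = 77L)
  sim <- simulateDataset(cfg)
  res <- analyzeSimulation(sim, nShuffles = 300L)
  gvIds <- res$isiTable$transcriptId[res$isiTable$group == "Gv"]
  gvCl <- res$classes[res$classes$transcriptId %in% gvIds, ]
  tertPct <- integer(0)
  ord <- order(gvCl$relativePosition, gvCl$transcriptId)
  n <- nrow(gvCl); sizes <- rep(n %/% 3L, 3L)
  if (n %% 3L) sizes[seq_len(n %% 3L)] <- sizes[seq_len(n %% 3L)] + 1L
  bnd <- cumsum(sizes); st <- c(1L, bnd[-3L] + 1L)
  for (j in 1:3) tertPct <- c(tertPct, matchNeutral(gvCl[ord, ][st[j]:bnd[j], ]))
  ind <- sim$truthIndels[sim$truthIndels$kept, ]
  g0Ids <- intersect(res$classes$transcriptId[res$classes$group == "G0"],
                     unique(ind$transcriptId))
  L <- setNames(vapply(sim$refTranscripts, utr5Length, integer(1)),
                vapply(sim$refTranscripts, transcriptId, character(1)))
  tb <- buildNeutralTable(ind[ind$transcriptId %in% g0Ids, ], L[g0Ids],
    percents = tertPct, nShuffles = 300L, seed = 2L)
  gvIsis <- setNames(res$isiTable$isi[res$isiTable$group == "Gv"], gvIds)
  tert <- tertileAnalysis(gvCl, gvIsis, tb)
  expect_true(all(tert$medianGroupIsi < tert$medianNeutralIsi))
})

test_that("bootstrap of identical P-value vectors gives KS statistic 0", {
  set.seed(5)
  g <- runif(50)
  res <- bootstrapEqualized(list(A = g, B = g), list(A = g, B = g),
    targetN = 20L, nResamples = 50L, seed = 6L)
  # same seed stream is not shared across groups, so compare a vector
  # against itself directly
  kt <- suppressWarnings(ks.test(res$pValues$A, res$pValues$A))
  expect_identical(unname(kt$statistic), 0)
  expect_identical(kt$p.value, 1)
  expect_identical(nrow(res$summary), 2L)
  expect_true(all(res$summary$fSig >= 0 & res$summary$fSig <= 1))
  expect_error(bootstrapEqualized(list(A = g), list(A = g), targetN = 1L))
})

test_that("KS on P values is invariant to the -log10 display transform", {
  set.seed(12)
  pa <- runif(200); pb <- runif(200)^2
  k1 <- ks.test(pa, pb)$statistic
  k2 <- ks.test(-log10(pa), -log10(pb))$statistic
  expect_equal(unname(k1), unname(k2), tolerance = 1e-12)
})

test_that("stronger selection gives larger F_sig at fixed sample size", {
  fsigAt <- function(s, seed) {
    cfg <- simulationConfig(groupCounts = c(G0 = 250, Ga = 40, Gv = 120),
      selectionStrength = s, selectedGroups = "Gv", seed = seed)
    sim <- simulateDataset(cfg)
    res <- analyzeSimulation(sim, nShuffles = 300L, nResamples = 200L,
                             bootstrap = TRUE)
    res$bootstrap$summary$fSig[res$bootstrap$summary$group == "Gv"]
  }
  f <- vapply(c(0, 0.4, 0.8), fsigAt, numeric(1), seed = 41L)
  expect_true(f[1] <= f[2] + 0.05 && f[2] <= f[3] + 0.05)
  expect_gt(f[3], f[1])
})
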