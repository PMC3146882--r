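# The R statistic, the shuffle-null ISI and the enumeration oracle.

test_that("computeR matches the hand-evaluated log-odds on a count grid", {
  grid <- expand.grid(nd = 0:3, td = 0:3, nu = 0:3, tu = 0:3)
  for (c0 in c(0.25, 0.5, 1.0)) {
    got <- apply(grid, 1, function(x) computeR(x, pseudocount = c0))
    want <- oracleR(grid$nd, grid$td, grid$nu, grid$tu, c0)
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # worked example
  expect_equal(computeR(c(1, 3, 4, 2)), log2((1.5 / 3.5) / (4.5 / 2.5)),
               tolerance = 1e-12)
  expect_equal(computeR(c(1, 3, 4, 2)), -2.0704, tolerance = 1e-4)
})

test_that("R is antisymmetric under up/down swap and zero under no preference", {
  grid <- expand.grid(nd = 0:3, td = 0:3, nu = 0:3, tu = 0:3)
  for (c0 in c(0.25, 0.5, 1.0)) {
    a <- oracleR(grid$nd, grid$td, grid$nu, grid$tu, c0)
    b <- apply(grid[, c(3, 4, 1, 2)], 1, function(x)
      computeR(x, pseudocount = c0))
    expect_equal(b, -a, tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_identical(computeR(c(0, 0, 0, 0)), 0)
  expect_identical(computeR(c(2, 1, 2, 1)), 0)   # equal up/down ratios
  expect_error(computeR(c(1, 1, 1, 1), pseudocount = 0), "positive")
})

test_that("shuffled R for a single non-3n indel takes two values near 50:50", {
  ind <- data.frame(utrOffset = 60L, lengthNt = 1L, sizeClass = "n3n")
  rs <- shuffleNull(ind, utrLength = 100L, referenceOffset = 50L,
                    nShuffles = 4000L, seed = 1L)
  expect_setequal(round(unique(rs), 10), round(c(log2(3), -log2(3)), 10))
  expect_lt(abs(mean(rs > 0) - 51 / 101), 0.03)
  expect_error(shuffleNull(ind, 100L, 50L, nShuffles = 0L))
  expect_error(shuffleNull(ind, 100L, 0L), "strictly inside")
})

test_that("single-indel ISI equals the exact placement enumeration 50/101", {
  ind <- data.frame(utrOffset = 60L, lengthNt = 1L, sizeClass = "n3n")
  ex <- exactIsi(ind, 100L, 50L)
  expect_equal(ex$isi, 50 / 101, tolerance = 1e-12)
  expect_true(ex$exact)
  mc <- computeIsi(ind, 100L, 50L, nShuffles = 1000L, seed = 2L)
  expect_lt(abs(mc$isi - 50 / 101), 3 * sqrt(0.5 * 0.5 / 1000))
})

test_that("tie rules behave as defined when no shuffle can be smaller", {
  # single 3n indel observed downstream: R_obs = -log2(3) is the minimum
  # attainable value, so no shuffle is strictly smaller; downstream
  # shuffles (probability 51/101) tie exactly
  ind <- data.frame(utrOffset = 60L, lengthNt = 3L, sizeClass = "3n")
  exS <- exactIsi(ind, 100L, 50L)
  exM <- exactIsi(ind, 100L, 50L, tieRule = "midp")
  expect_identical(exS$isi, 0)
  expect_equal(exM$isi, 0.5 * 51 / 101, tolerance = 1e-12)
  strict <- computeIsi(ind, 100L, 50L, nShuffles = 400L, seed = 3L)
  expect_identical(strict$isi, 0)
  midp <- computeIsi(ind, 100L, 50L, nShuffles = 400L, seed = 3L,
                     tieRule = "midp")
  expect_lt(abs(midp$isi - 0.5 * 51 / 101), 3 * sqrt(0.25 / 400))
})

test_that("exactIsi agrees with brute-force enumeration of all placements", {
  # 10-nt UTR: enumerate the full 11^k placement grid independently
  bruteIsi <- function(n3nFlags, L, ref, obsCounts, tieRule = "strict") {
    k <- length(n3nFlags)
    pos <- as.matrix(expand.grid(rep(list(0:L), k)))
    rObs <- oracleR(obsCounts[1], obsCounts[2], obsCounts[3], obsCounts[4])
    rAll <- apply(pos, 1, function(p) {
      dn <- p >= ref
      oracleR(sum(dn & n3nFlags), sum(dn & !n3nFlags),
              sum(!dn & n3nFlags), sum(!dn & !n3nFlags))
    })
    tol <- 1e-9
    if (tieRule == "strict") mean(rAll < rObs - tol) else
      mean(rAll < rObs - tol) + 0.5 * mean(abs(rAll - rObs) <= tol)
  }
  set.seed(17)
  for (i in 1:12) {
    k <- sample(1:3, 1)
    flags <- sample(c(TRUE, FALSE), k, replace = TRUE)
    ind <- data.frame(utrOffset = sample(0:10, k, replace = TRUE),
      lengthNt = ifelse(flags, 1L, 3L),
      sizeClass = ifelse(flags, "n3n", "3n"))
    ref <- sample(1:9, 1)
    obs <- partitionIndels(ind, ref)
    for (tr in c("strict", "midp")) {
      expect_equal(exactIsi(ind, 10L, ref, tieRule = tr)$isi,
                   bruteIsi(flags, 10L, ref, obs, tr), tolerance = 1e-12)
    }
  }
  expect_error(exactIsi(data.frame(utrOffset = rep(1L, 13),
    lengthNt = rep(1L, 13), sizeClass = rep("n3n", 13)), 100L, 50L),
    "too many")
})

test_that("midp ISI is 0.5 by symmetry at an exactly central reference", {
  # utrLength 99, reference 50: p = 50/100 = 0.5 exactly; the observed
  # configuration is balanced (one non-3n up, one down), so R_obs = 0 and
  # the shuffle distribution is symmetric about it
  indSym <- data.frame(utrOffset = c(10L, 70L), lengthNt = c(1L, 2L),
                       sizeClass = c("n3n", "n3n"))
  expect_equal(exactIsi(indSym, 99L, 50L, tieRule = "midp")$isi, 0.5,
               tolerance = 1e-12)
})

test_that("ISI is invariant to the log base of R", {
  ind <- data.frame(utrOffset = c(5L, 60L, 90L), lengthNt = c(1L, 4L, 6L),
                    sizeClass = c("n3n", "n3n", "3n"))
  a <- computeIsi(ind, 100L, 40L, nShuffles = 500L, seed = 4L, base = 2)
  b <- computeIsi(ind, 100L, 40L, nShuffles = 500L, seed = 4L,
                  base = exp(1))
  expect_identical(a$isi, b$isi)
  expect_identical(a$nSmaller, b$nSmaller)
})

test_that("identical seeds give bit-identical ISI results", {
  ind <- data.frame(utrOffset = c(5L, 60L), lengthNt = c(2L, 3L),
                    sizeClass = c("n3n", "3n"))
  a <- computeIsi(ind, 200L, 80L, nShuffles = 1000L, seed = 99L)
  b <- computeIsi(ind, 200L, 80L, nShuffles = 1000L, seed = 99L)
  expect_identical(a, b)
})

test_that("Monte-Carlo ISI tracks the enumeration oracle", {
  set.seed(23)
  ok <- 0L
  for (i in 1:25) {
    k <- sample(1:6, 1)
    flags <- sample(c(TRUE, FALSE), k, replace = TRUE)
    L <- sample(50:300, 1)
    ind <- data.frame(utrOffset = sample(0:L, k, replace = TRUE),
      lengthNt = ifelse(flags, 1L, 3L),
      sizeClass = ifelse(flags, "n3n", "3n"))
    ref <- sample(seq.int(1L, L - 1L), 1)
    ex <- exactIsi(ind, L, ref)$isi
    mc <- computeIsi(ind, L, ref, nShuffles = 1000L)$isi
    sd3 <- 3 * sqrt(max(ex * (1 - ex), 1e-4) / 1000)
    if (abs(mc - ex) <= sd3) ok <- ok + 1L
  }
  expect_gte(ok, 24L)
})

test_that("pseudocount changes R magnitude but rarely its sign on typical data", {
  cfg <- simulationConfig(groupCounts = c(G0 = 150), indelRate = 4,
                          seed = 31L)
  sim <- simulateDataset(cfg)
  ind <- sim$truthIndels
  byTx <- split(ind, ind$transcriptId)
  L <- stats::setNames(sim$truthTranscripts$utr5Length,
                       sim$truthTranscripts$transcriptId)
  signs <- vapply(names(byTx), function(tid) {
    ref <- max(1L, round(0.5 * L[[tid]]))
    cnt <- partitionIndels(byTx[[tid]], ref)
    s <- sign(vapply(c(0.25, 0.5, 1.0), function(c0)
      computeR(cnt, pseudocount = c0), numeric(1)))
    all(s == s[1])
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})
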