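test_that("precursor-region removal discards peaks within the window, inclusive", {
  s <- Ms2Spectrum("s", 300.0, "positive", 1,
                   mz = c(100.0, 284.0, 290.0), intensity = c(10, 20, 30))
  out <- removePrecursorRegion(s, 17)
  expect_equal(unname(peakMatrix(out)[, "mz"]), 100.0)
  ## peaks far from the precursor are untouched
  far <- Ms2Spectrum("s", 300.0, "positive", 1,
                     mz = c(100.0, 150.0), intensity = c(1, 2))
  expect_equal(peakMatrix(removePrecursorRegion(far, 17)),
               peakMatrix(far))
  ## boundary: exactly 17 Da away is removed
  edge <- Ms2Spectrum("s", 300.0, "positive", 1, mz = 283.0, intensity = 5)
  expect_equal(peakCount(removePrecursorRegion(edge, 17)), 0L)
  ## input unmodified
  expect_equal(peakCount(s), 3L)
})

test_that("window filter keeps the top-k most intense peaks per centered window", {
  ## <= k peaks: unchanged
  small <- Ms2Spectrum("s", 500, "positive", 1,
                       mz = c(100, 200), intensity = c(1, 2))
  expect_equal(peakMatrix(windowFilterTopK(small, 50, 6)), peakMatrix(small))

  ## 8 peaks within a 10-Da span, k = 6: the 6 most intense survive
  mz <- seq(100, 101.4, by = 0.2)
  int <- c(8, 3, 7, 1, 5, 6, 4, 2)
  s <- Ms2Spectrum("s", 500, "positive", 1, mz = mz, intensity = int)
  out <- windowFilterTopK(s, 10, 6)
  expect_equal(sort(peakMatrix(out)[, "intensity"]), 3:8)

  ## two clusters of 7 peaks, 200 Da apart, k = 6: 6 kept per cluster
  mz2 <- c(seq(100, 103, by = 0.5), seq(300, 303, by = 0.5))
  int2 <- c(7:1, 1:7)
  s2 <- Ms2Spectrum("s", 500, "positive", 1, mz = mz2, intensity = int2)
  out2 <- windowFilterTopK(s2, 50, 6)
  expect_equal(peakCount(out2), 12L)
  expect_equal(sum(peakMatrix(out2)[, "mz"] < 200), 6)
})

test_that("both spectral filters are idempotent on random spectra", {
  set.seed(101)
  tol <- ToleranceConfig()
  for (i in 1:50) {
    s <- randomSpectrum(paste0("s", i), nPeaks = sample(5:30, 1))
    f1 <- removePrecursorRegion(s, tol@precursorWindowDa)
    expect_equal(peakMatrix(removePrecursorRegion(f1, tol@precursorWindowDa)),
                 peakMatrix(f1))
    w1 <- windowFilterTopK(s, tol@windowDa, tol@windowTopK)
    expect_equal(peakMatrix(windowFilterTopK(w1, tol@windowDa,
                                             tol@windowTopK)),
                 peakMatrix(w1))
    full <- filterSpectrum(s, tol)
    expect_equal(peakMatrix(filterSpectrum(full, tol)), peakMatrix(full))
  }
})

test_that("modified cosine reproduces hand-computed scores", {
  ## shared peaks at equal m/z: score = sum of normalized products
  a <- Ms2Spectrum("a", 200, "positive", 1,
                   mz = c(50, 100), intensity = c(4, 9))
  b <- Ms2Spectrum("b", 200, "positive", 1,
                   mz = c(50, 100), intensity = c(1, 4))
  r <- modifiedCosine(a, b)
  expect_equal(similarityScore(r), 8 / sqrt(65), tolerance = 1e-12)
  expect_equal(nMatched(r), 2L)

  ## self-similarity is exactly 1 with all peaks matched
  s <- Ms2Spectrum("s", 321.2, "positive", 2,
                   mz = c(60.1, 120.7, 180.2, 240.9),
                   intensity = c(5, 50, 12, 80))
  rs <- modifiedCosine(s, s)
  expect_equal(similarityScore(rs), 1.0, tolerance = 1e-12)
  expect_equal(nMatched(rs), peakCount(s))

  ## precursor-difference shift rule pairs mass-shifted fragments
  a2 <- Ms2Spectrum("a", 200.0, "positive", 1, mz = 100.0, intensity = 7)
  b2 <- Ms2Spectrum("b", 214.0157, "positive", 1, mz = 114.0157,
                    intensity = 3)
  r2 <- modifiedCosine(a2, b2)
  expect_equal(nMatched(r2), 1L)
  expect_equal(similarityScore(r2), 1.0, tolerance = 1e-12)

  ## empty spectrum gives zero
  e <- Ms2Spectrum("e", 100, "positive", 1)
  expect_equal(similarityScore(modifiedCosine(a, e)), 0)
  expect_equal(nMatched(modifiedCosine(a, e)), 0L)
})

test_that("modified cosine is symmetric, bounded, and respects peak counts", {
  set.seed(202)
  tol <- ToleranceConfig()
  for (i in 1:300) {
    pr <- randomRelatedPair()
    r1 <- modifiedCosine(pr$a, pr$b, tol)
    r2 <- modifiedCosine(pr$b, pr$a, tol)
    expect_equal(similarityScore(r1), similarityScore(r2),
                 tolerance = 1e-10)
    expect_equal(nMatched(r1), nMatched(r2))
    expect_gte(similarityScore(r1), 0)
    expect_lte(similarityScore(r1), 1 + 1e-9)
    expect_lte(nMatched(r1), min(peakCount(pr$a), peakCount(pr$b)))
    ## each peak used at most once
    mp <- matchedPairs(r1)
    expect_equal(anyDuplicated(mp[, 1]), 0L)
    expect_equal(anyDuplicated(mp[, 2]), 0L)
  }
})
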