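## small helper: network with given nodes and edge triples
mkNet <- function(ids, ...) {
  tr <- list(...)
  e <- if (length(tr)) data.frame(
    from = vapply(tr, `[[`, character(1), 1),
    to = vapply(tr, `[[`, character(1), 2),
    score = vapply(tr, function(x) as.numeric(x[[3]]), numeric(1)),
    nMatched = 6L, stringsAsFactors = FALSE) else NULL
  MolecularNetwork(S4Vectors::DataFrame(row.names = ids), e)
}

test_that("edge thresholds require both score and matched-peak count", {
  tol <- ToleranceConfig()
  mk <- function(id, mz, int, prec = 400)
    Ms2Spectrum(id, prec, "positive", 1, mz = mz, intensity = int)
  ## identical 6-peak spectra: one edge with score 1
  mz <- c(60, 90, 130, 170, 210, 250)
  net <- buildNetwork(list(mk("x", mz, 1:6), mk("y", mz, 1:6)))
  expect_equal(numEdges(net), 1L)
  expect_equal(networkEdges(net)$score, 1.0, tolerance = 1e-12)
  ## only 3 shared peaks: no edge regardless of score
  net3 <- buildNetwork(list(mk("x", mz[1:3], c(5, 5, 5)),
                            mk("y", mz[1:3], c(5, 5, 5))))
  expect_equal(numEdges(net3), 0L)
  ## mixed polarities refused
  expect_error(buildNetwork(list(mk("x", mz, 1:6),
                                 Ms2Spectrum("y", 400, "negative", 1,
                                             mz = mz, intensity = 1:6))),
               "polarity")
})

test_that("mutual top-k filter keeps only mutually ranked edges", {
  ## k = 1 triangle: only the strongest edge survives
  net <- mkNet(c("A", "B", "C"), list("A", "B", 0.9), list("B", "C", 0.8),
               list("A", "C", 0.75))
  out <- mutualTopkFilter(net, 1)
  expect_equal(edgeKeys(networkEdges(out)), edgeKeys(
    data.frame(from = "A", to = "B", score = 0.9)))
  expect_equal(numNodes(out), 3L)

  ## degree <= k everywhere: unchanged
  expect_equal(edgeKeys(networkEdges(mutualTopkFilter(net, 2))),
               edgeKeys(networkEdges(net)))

  ## star with center degree k+1: exactly the weakest spoke is dropped
  k <- 3
  leaves <- paste0("L", 1:(k + 1))
  spokes <- lapply(seq_along(leaves), function(i)
    list("hub", leaves[i], 0.7 + i / 100))
  star <- do.call(mkNet, c(list(c("hub", leaves)), spokes))
  kept <- mutualTopkFilter(star, k)
  expect_equal(numEdges(kept), k)
  expect_false("L1" %in% c(networkEdges(kept)$from, networkEdges(kept)$to))
})

test_that("family capping removes lowest-scoring edges until families fit", {
  ## all components already small: unchanged
  net <- mkNet(c("A", "B", "C"), list("A", "B", 0.9))
  expect_equal(edgeKeys(networkEdges(capFamilySize(net, 2))),
               edgeKeys(networkEdges(net)))

  ## path A-B-C-D-E, cap 3: the weakest edge (B-C) goes first
  path <- mkNet(LETTERS[1:5], list("A", "B", 0.9), list("B", "C", 0.8),
                list("C", "D", 0.95), list("D", "E", 0.85))
  capped <- capFamilySize(path, 3)
  fam <- families(capped)
  expect_equal(sort(as.integer(table(fam))), c(2L, 3L))
  expect_false("B|C" %in% paste(networkEdges(capped)$from,
                                networkEdges(capped)$to, sep = "|"))

  ## K4 with uniform scores, cap 2: fixed deterministic outcome via the
  ## node-id tie-break; nodes are never removed
  prs <- combn(LETTERS[1:4], 2)
  k4 <- do.call(mkNet, c(list(LETTERS[1:4]),
                         lapply(seq_len(ncol(prs)), function(i)
                           list(prs[1, i], prs[2, i], 0.8))))
  out <- capFamilySize(k4, 2)
  expect_equal(numNodes(out), 4L)
  expect_true(all(table(families(out)) <= 2))
  brute <- bruteNetworkRules(LETTERS[1:4], networkEdges(k4),
                             NetworkConfig(scoreThreshold = 0,
                                           minMatched = 1,
                                           mutualK = 10,
                                           maxFamilySize = 2))
  expect_equal(edgeKeys(networkEdges(out)), edgeKeys(brute))
})

test_that("singleton truncation affects only the display network", {
  net <- mkNet(c("A", "B", "Z"), list("A", "B", 0.9))
  disp <- dropSingletons(net)
  expect_equal(sort(rownames(networkNodes(disp))), c("A", "B"))
  expect_equal(numNodes(net), 3L)
  ## all-singleton network empties completely
  lone <- mkNet(c("A", "B"))
  expect_equal(numNodes(dropSingletons(lone)), 0L)
  ## fully connected network unchanged
  expect_equal(numNodes(dropSingletons(mkNet(c("A", "B"),
                                             list("A", "B", 0.9)))), 2L)
})

test_that("library search filters entries, applies both criteria and sorts", {
  mz <- c(60, 90, 130, 170, 210, 250)
  query <- filterSpectrum(Ms2Spectrum("q", 400, "positive", 1,
                                      mz = mz, intensity = 6:1))
  exact <- Ms2Spectrum("lib_exact", 400, "positive", 1,
                       mz = mz, intensity = 6:1)
  near <- Ms2Spectrum("lib_near", 400, "positive", 1,
                      mz = mz, intensity = c(6:2, 0.5))
  five <- Ms2Spectrum("lib_five", 400, "positive", 1,
                      mz = mz[1:5], intensity = 5:1)
  hits <- librarySearch(query, list(near, five, exact))
  expect_equal(hits$libraryId[1], "lib_exact")
  expect_equal(hits$score[1], 1.0, tolerance = 1e-12)
  ## 5 shared peaks can never be a match
  expect_false("lib_five" %in% hits$libraryId)
  expect_true(all(diff(hits$score) <= 0))
  ## library spectra are filtered like input data: a peak inside the
  ## precursor window cannot contribute to the match
  contaminated <- Ms2Spectrum("lib_cont", 400, "positive", 1,
                              mz = c(mz[1:5], 395), intensity = c(5:1, 99))
  hits2 <- librarySearch(query, list(contaminated))
  expect_equal(nrow(hits2), 0L)
  expect_equal(nrow(librarySearch(query, list())), 0L)
})

test_that("planted families are recovered as connected components", {
  cfg <- SimulationConfig(nFamilies = 3L, compoundsPerFamily = 3L,
                          seed = 7L)
  cmp <- generateCompounds(cfg)
  spectra <- lapply(generateSpectra(cmp, "positive", cfg), filterSpectrum)
  net <- buildNetwork(spectra)
  truth <- setNames(cmp$familyId, paste0(cmp$compoundId, "_pos"))
  expect_true(samePartition(families(net), truth[names(families(net))]))
})
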