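test_that("compound generation is deterministic and structurally valid", {
  cfg <- SimulationConfig()
  c1 <- generateCompounds(cfg)
  c2 <- generateCompounds(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), cfg@nFamilies * cfg@compoundsPerFamily)
  ## family base masses separated by >= 50 Da
  bases <- c1$neutralMass[c1$modificationDelta == 0]
  expect_true(all(diff(sort(bases)) >= 50))
  ## members differ by the cumulative modification deltas
  fam1 <- c1[c1$familyId == 1, ]
  expect_equal(diff(fam1$neutralMass),
               diff(vapply(seq_len(nrow(fam1)), function(m)
                 if (m == 1) 0 else sum(rep_len(cfg@modificationDeltas,
                                                m - 1)), numeric(1))))
  ## planted enrichment: coculture mean = fc x monoculture mean
  expect_equal(c1$meanCoculture, c1$plantedFc * c1$meanFungal)
  expect_equal(sum(c1$enriched), cfg@nPlantedEnriched)
  ## dual-mode fraction honored
  expect_equal(sum(c1$ionizesNegative),
               round(cfg@dualModeFraction * nrow(c1)))
  ## single-compound config degenerates cleanly
  tiny <- generateCompounds(SimulationConfig(nFamilies = 1L,
                                             compoundsPerFamily = 1L,
                                             nPlantedEnriched = 0L,
                                             seed = 3L))
  expect_equal(nrow(tiny), 1L)
  expect_equal(tiny$modificationDelta, 0)
})

test_that("spectra carry the adduct arithmetic and family shift structure", {
  cfg <- SimulationConfig(massErrorPpm = 0, nNoisePeaks = 0L,
                          rtJitterMin = 0, seed = 5L)
  cmp <- generateCompounds(cfg)
  pos <- generateSpectra(cmp, "positive", cfg)
  neg <- generateSpectra(cmp, "negative", cfg)
  ## positive and negative spectra of a dual compound differ by 2 protons
  dual <- cmp$compoundId[cmp$ionizesNegative][1]
  pSpec <- pos[[which(vapply(pos, featureId, character(1)) ==
                        paste0(dual, "_pos"))]]
  nSpec <- neg[[which(vapply(neg, featureId, character(1)) ==
                        paste0(dual, "_neg"))]]
  expect_equal(precursorMz(pSpec) - precursorMz(nSpec), 2 * PROTON_MASS,
               tolerance = 1e-9)
  ## with no noise/mass error, a family base and its modified member
  ## share the full backbone through direct plus shifted matching
  ids <- vapply(pos, featureId, character(1))
  base <- pos[[match(paste0(cmp$compoundId[1], "_pos"), ids)]]
  member <- pos[[match(paste0(cmp$compoundId[2], "_pos"), ids)]]
  r <- modifiedCosine(filterSpectrum(base), filterSpectrum(member))
  expect_equal(nMatched(r), cfg@nBackboneFragments)
  expect_gt(similarityScore(r), 0.99)
})

test_that("within-family similarity is high and between-family low", {
  cfg <- SimulationConfig()
  cmp <- generateCompounds(cfg)
  spectra <- lapply(generateSpectra(cmp, "positive", cfg), filterSpectrum)
  fam <- cmp$familyId
  n <- length(spectra)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    s <- similarityScore(modifiedCosine(spectra[[i]], spectra[[j]]))
    if (fam[i] == fam[j]) expect_gte(s, 0.85) else expect_lte(s, 0.3)
  }
})

test_that("feature table heights follow the planted group means", {
  ## no noise, no dropout: heights equal the true means exactly
  cfg0 <- SimulationConfig(replicateCv = 0, dropoutProb = 0,
                           nBackgroundFeatures = 0L, seed = 9L)
  cmp <- generateCompounds(cfg0)
  tab <- generateFeatureTable(cmp, cfg0)
  gm <- groupMeans(tab)
  truth <- S4Vectors::metadata(tab)$groundTruth
  i <- match(truth$compoundId, cmp$compoundId)
  expect_equal(unname(gm[truth$featureId, "coculture"]),
               cmp$meanCoculture[i])
  expect_equal(unname(gm[truth$featureId, "fungal_mono"]),
               cmp$meanFungal[i])
  ## determinism of the noisy table
  cfg <- SimulationConfig()
  t1 <- generateFeatureTable(generateCompounds(cfg), cfg)
  t2 <- generateFeatureTable(generateCompounds(cfg), cfg)
  expect_identical(heights(t1), heights(t2))
  ## ground truth covers every feature and labels background as null
  gt <- S4Vectors::metadata(t1)$groundTruth
  expect_setequal(gt$featureId, rownames(heights(t1)))
  expect_true(all(!gt$enriched[is.na(gt$compoundId)]))
})

test_that("generated MGF files round-trip bit-identically", {
  cfg <- SimulationConfig(nFamilies = 2L, seed = 21L)
  cmp <- generateCompounds(cfg)
  spectra <- generateSpectra(cmp, "positive", cfg)
  path <- withr::local_tempfile(fileext = ".mgf")
  writeMgf(spectra, path)
  back <- readMgf(path)
  expect_equal(length(back), length(spectra))
  for (k in seq_along(spectra)) {
    expect_identical(featureId(back[[k]]), featureId(spectra[[k]]))
    expect_identical(peakMatrix(back[[k]]), peakMatrix(spectra[[k]]))
    expect_identical(precursorMz(back[[k]]), precursorMz(spectra[[k]]))
    expect_identical(rtMinutes(back[[k]]), rtMinutes(spectra[[k]]))
    expect_identical(polarity(back[[k]]), polarity(spectra[[k]]))
  }
})
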