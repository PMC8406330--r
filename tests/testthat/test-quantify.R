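mkTable <- function(h, groups, condition = "avicel") {
  n <- nrow(h)
  FeatureTable(h,
               data.frame(featureId = rownames(h),
                          mz = seq(100, by = 10, length.out = n),
                          rt = seq(1, by = 0.5, length.out = n),
                          polarity = "positive"),
               data.frame(sampleId = colnames(h), group = groups,
                          condition = condition))
}

screenTable <- function(coc, fun, bac) {
  ## feature x replicate blocks for the three groups, 4 replicates each
  h <- cbind(fun, bac, coc)
  colnames(h) <- c(paste0("f", 1:4), paste0("b", 1:4), paste0("c", 1:4))
  mkTable(h, rep(c("fungal_mono", "bacterial_mono", "coculture"),
                 each = 4))
}

test_that("row-sum normalization scales each sample to the target total", {
  h <- rbind(x = c(1, 10), y = c(2, 30), z = c(2, 60))
  colnames(h) <- c("s1", "s2")
  tab <- mkTable(h, groups = c("coculture", "coculture"))
  out <- heights(rowSumNormalize(tab))
  expect_equal(out[, "s1"], c(x = 2e5, y = 4e5, z = 4e5))
  expect_equal(colSums(out), c(s1 = 1e6, s2 = 1e6))
  ## proportions conserved and idempotent
  expect_equal(out[, "s2"] / sum(out[, "s2"]), h[, "s2"] / sum(h[, "s2"]))
  expect_equal(heights(rowSumNormalize(rowSumNormalize(tab))), out)
  ## all-zero sample is an error naming the sample
  h0 <- h; h0[, 2] <- 0
  expect_error(rowSumNormalize(mkTable(h0, c("coculture", "coculture"))),
               "s2")
})

test_that("group means are replicate arithmetic means", {
  h <- rbind(f1 = c(100, 110, 90, 100, 7, 7), f2 = c(1, 2, 3, 4, 5, 6))
  colnames(h) <- paste0("s", 1:6)
  tab <- mkTable(h, c(rep("coculture", 4), rep("fungal_mono", 2)))
  gm <- groupMeans(tab)
  expect_equal(gm["f1", "coculture"], 100)
  expect_equal(gm["f1", "fungal_mono"], 7)
  expect_equal(gm["f2", "coculture"], sum(1:4) / 4)
  set.seed(5)
  r <- runif(4)
  h2 <- rbind(g = c(r, 1, 1)); colnames(h2) <- paste0("s", 1:6)
  tab2 <- mkTable(h2, c(rep("coculture", 4), rep("fungal_mono", 2)))
  expect_equal(groupMeans(tab2)["g", "coculture"], sum(r) / 4)
})

test_that("fold change handles detectable and non-detectable denominators", {
  expect_equal(foldChange(100, 10), 10)
  expect_equal(foldChange(50, 50), 1)
  expect_true(is.infinite(foldChange(10, 0)))   # the table dash
  expect_true(is.nan(foldChange(0, 0)))         # undefined, fails screens
  expect_error(foldChange(-1, 5))
})

test_that("one-tailed pooled t matches hand computation and t.test", {
  coc <- c(100, 110, 90, 100); mono <- c(10, 12, 8, 10)
  r <- oneTailedT(coc, mono)
  ## hand: pooled var (200 + 8) / 6, se = sqrt(34.667 / 2), t = 90 / se
  expect_equal(unname(r["t"]), 90 / sqrt((208 / 6) / 2), tolerance = 1e-9)
  expect_equal(unname(r["t"]), 21.6173, tolerance = 1e-4)
  expect_lt(r["p"], 1e-5)
  ## independent route: stats::t.test with pooled variance
  tt <- t.test(coc, mono, var.equal = TRUE, alternative = "greater")
  expect_equal(unname(r["t"]), unname(tt$statistic), tolerance = 1e-12)
  expect_equal(unname(r["p"]), tt$p.value, tolerance = 1e-12)
  ## degenerate conventions
  expect_equal(unname(oneTailedT(c(5, 5), c(5, 5))["p"]), 0.5)
  expect_equal(unname(oneTailedT(c(9, 9), c(5, 5))["p"]), 0)
  expect_equal(unname(oneTailedT(c(2, 2), c(5, 5))["p"]), 1)
  ## wrong-direction means can never look enriched
  r2 <- oneTailedT(c(1, 2, 1, 2), c(10, 11, 10, 11))
  expect_lt(r2["t"], 0)
  expect_gt(r2["p"], 0.5)
  expect_error(oneTailedT(1, c(1, 2)), "2 replicates")
})

test_that("the enrichment screen applies all three criteria jointly", {
  coc <- rbind(c(100, 110, 90, 100))
  fun <- rbind(c(10, 12, 8, 10))
  bac <- rbind(c(9, 11, 10, 10))
  mk1 <- function(coc, fun, bac, id = "f1") {
    rownames(coc) <- id
    screenTable(coc, fun, bac)
  }
  ## clean 10-fold enrichment passes (normalization off to keep the
  ## constructed numbers exact)
  rep1 <- enrichmentScreen(mk1(coc, fun, bac), normalize = FALSE)
  expect_true(reportTable(rep1)$pass)
  expect_equal(reportTable(rep1)$fcVsFungal, 10)

  ## fold change below threshold vs one monoculture fails
  rep2 <- enrichmentScreen(mk1(coc, coc / 3.5, bac), normalize = FALSE)
  expect_false(reportTable(rep2)$pass)

  ## a missed coculture replicate fails the all-replicates criterion
  cocMiss <- coc; cocMiss[1, 2] <- 0
  rep3 <- enrichmentScreen(mk1(cocMiss, fun, bac), normalize = FALSE)
  tab3 <- reportTable(rep3)
  expect_false(tab3$detectedAllReplicates)
  expect_false(tab3$pass)

  ## not-detectable monoculture: dash convention passes the FC criterion
  rep4 <- enrichmentScreen(mk1(coc, fun * 0, bac), normalize = FALSE)
  tab4 <- reportTable(rep4)
  expect_true(tab4$notDetectableFungal)
  expect_true(is.infinite(tab4$fcVsFungal))
  expect_true(tab4$pass)

  ## missing group is an error naming it
  h <- rbind(f1 = rep(1, 8))
  colnames(h) <- paste0("s", 1:8)
  twoGroups <- mkTable(h, rep(c("coculture", "fungal_mono"), each = 4))
  expect_error(enrichmentScreen(twoGroups, normalize = FALSE),
               "bacterial_mono")
})

test_that("the screen is monotone in the fold-change threshold", {
  cfg <- SimulationConfig(nFamilies = 10L, nPlantedEnriched = 10L,
                          dropoutProb = 0, seed = 11L)
  tab <- generateFeatureTable(generateCompounds(cfg), cfg)
  pass4 <- passingFeatures(enrichmentScreen(tab, ScreenConfig(fcThreshold = 4)))
  pass8 <- passingFeatures(enrichmentScreen(tab, ScreenConfig(fcThreshold = 8)))
  expect_true(all(pass8 %in% pass4))
})
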