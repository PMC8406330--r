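#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Normalization and aggregation
## ---------------------------------------------------------------------------

#' Row-sum normalize peak heights per sample
#'
#' Scales every sample (file) so its total peak height equals `total`
#' (default 1,000,000), leaving within-sample proportions unchanged.
#' Idempotent.
#'
#' @param table a [FeatureTable-class].
#' @param total the per-sample target sum.
#' @return The normalized [FeatureTable-class].
#' @export
rowSumNormalize <- function(table, total = 1e6) {
  stopifnot(is(table, "FeatureTable"), total > 0)
  h <- heights(table)
  sums <- colSums(h)
  if (any(sums <= 0))
    stop("cannot normalize all-zero sample(s): ",
         paste(colnames(h)[sums <= 0], collapse = ", "))
  SummarizedExperiment::assay(table, "heights") <-
    sweep(h, 2L, total / sums, `*`)
  table
}

#' Per-feature, per-group mean heights
#'
#' Arithmetic mean of replicate peak heights within each sample group
#' (the aggregation used for network coloring and fold changes).
#'
#' @param table a (normalized) [FeatureTable-class].
#' @return Numeric matrix, features x groups.
#' @export
groupMeans <- function(table) {
  stopifnot(is(table, "FeatureTable"))
  grp <- sampleGroups(table)
  h <- heights(table)
  groups <- sort(unique(grp))
  out <- vapply(groups, function(g) {
    cols <- which(grp == g)
    if (length(cols) == 0L) stop("group with zero samples: ", g)
    rowMeans(h[, cols, drop = FALSE])
  }, numeric(nrow(h)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = nrow(h), dimnames = list(rownames(h), groups))
  out
}

#' Fold change between two group means
#'
#' Ratio of numerator to denominator group means, with the table dash
#' convention for features absent from the denominator group: a positive
#' numerator over a zero denominator returns `Inf` (rendered "-" in
#' reports; it satisfies any fold-change criterion because the feature is
#' not detectable in the reference culture), and 0/0 returns `NaN`
#' (undefined; fails any screen). Vectorized.
#'
#' @param numMean,denMean non-negative group means.
#' @return Numeric vector of ratios with `Inf`/`NaN` flags as above.
#' @export
foldChange <- function(numMean, denMean) {
  stopifnot(all(numMean >= 0), all(denMean >= 0))
  numMean / denMean
}

#' One-tailed two-sample Student's t test (pooled variance)
#'
#' Tests whether the first group's mean exceeds the second's, using the
#' pooled-variance two-sample t statistic with `n1 + n2 - 2` degrees of
#' freedom; the p-value is the upper-tail probability. Degenerate
#' zero-variance cases follow the limit convention: equal means give
#' p = 0.5, a strictly greater first mean gives p = 0 (t = Inf), a
#' strictly smaller one p = 1 (t = -Inf).
#'
#' @param x replicate values of the group hypothesized to be enriched
#'   (e.g. coculture).
#' @param y replicate values of the reference group (e.g. a monoculture).
#' @return Named numeric: `t`, `p`, `df`.
#' @examples
#' oneTailedT(c(100, 110, 90, 100), c(10, 12, 8, 10))
#' @export
oneTailedT <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stop("at least 2 replicates per group are required")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * var(x) + (n2 - 1L) * var(y)) / df
  dm <- mean(x) - mean(y)
  if (sp2 <= 0) {
    t <- if (dm > 0) Inf else if (dm < 0) -Inf else 0
    p <- if (dm > 0) 0 else if (dm < 0) 1 else 0.5
  } else {
    t <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- pt(t, df, lower.tail = FALSE)
  }
  c(t = t, p = p, df = df)
}

## ---------------------------------------------------------------------------
## Coculture enrichment screen
## ---------------------------------------------------------------------------

#' Screen features for coculture enrichment
#'
#' The replicate-consistent enrichment screen: a feature passes for a
#' condition iff (a) it is detected (height above `detectionFloor`) in
#' every coculture replicate; (b) its coculture mean is at least
#' `fcThreshold`-fold the fungal monoculture mean AND the bacterial
#' monoculture mean, where absence from a monoculture (zero mean, the
#' "-" dash convention) satisfies that comparison; and (c) the one-tailed
#' pooled-variance t test against each monoculture gives p below `alpha`.
#' No multiple-testing correction enters the pass flag; BH-adjusted
#' p-values are reported as extra columns for transparency.
#'
#' The screen is run separately within each condition (e.g. growth
#' substrate) present in the design.
#'
#' @param table a [FeatureTable-class]; normalized internally unless
#'   `normalize = FALSE`.
#' @param cfg a [ScreenConfig-class].
#' @param groups named character of length 3 mapping the roles
#'   `coculture`, `fungal`, `bacterial` to group labels in the design.
#' @param normalize apply [rowSumNormalize()] first (default TRUE).
#' @param logScale compute the t test on `log(height + 1)` instead of the
#'   linear scale (default FALSE; fold changes are always linear).
#' @return An [EnrichmentReport-class].
#' @export
enrichmentScreen <- function(table, cfg = ScreenConfig(),
                             groups = c(coculture = "coculture",
                                        fungal = "fungal_mono",
                                        bacterial = "bacterial_mono"),
                             normalize = TRUE, logScale = FALSE) {
  stopifnot(is(table, "FeatureTable"))
  if (!all(c("coculture", "fungal", "bacterial") %in% names(groups)))
    stop("groups must name the roles coculture, fungal, bacterial")
  if (normalize) table <- rowSumNormalize(table, cfg@rowSumTotal)

  cond <- sampleConditions(table)
  grp <- sampleGroups(table)
  rd <- featureData(table)
  h <- heights(table)

  perCondition <- lapply(sort(unique(cond)), function(cc) {
    inCond <- cond == cc
    cols <- lapply(groups, function(g) which(inCond & grp == g))
    missing <- names(groups)[vapply(cols, length, integer(1)) == 0L]
    if (length(missing))
      stop("condition '", cc, "' is missing group(s): ",
           paste(groups[missing], collapse = ", "))

    coc <- h[, cols$coculture, drop = FALSE]
    fun <- h[, cols$fungal, drop = FALSE]
    bac <- h[, cols$bacterial, drop = FALSE]
    tx <- if (logScale) function(m) log(m + 1) else identity

    mCoc <- rowMeans(coc); mFun <- rowMeans(fun); mBac <- rowMeans(bac)
    detected <- apply(coc > cfg@detectionFloor, 1L, all)
    fcF <- foldChange(mCoc, mFun)
    fcB <- foldChange(mCoc, mBac)
    tF <- t(apply(cbind(tx(coc), tx(fun)), 1L, function(r)
      oneTailedT(r[seq_len(ncol(coc))], r[-seq_len(ncol(coc))])[c("t", "p")]))
    tB <- t(apply(cbind(tx(coc), tx(bac)), 1L, function(r)
      oneTailedT(r[seq_len(ncol(coc))], r[-seq_len(ncol(coc))])[c("t", "p")]))

    ## Inf fold change = not detectable in that monoculture ("-"):
    ## passes the fold-change criterion; NaN (0/0) fails everything
    fcPassF <- !is.nan(fcF) & (is.infinite(fcF) | fcF >= cfg@fcThreshold)
    fcPassB <- !is.nan(fcB) & (is.infinite(fcB) | fcB >= cfg@fcThreshold)
    pass <- detected & fcPassF & fcPassB &
      tF[, "p"] < cfg@alpha & tB[, "p"] < cfg@alpha

    data.frame(
      featureId = rownames(h), condition = cc,
      mz = rd$mz, rt = rd$rt, polarity = rd$polarity,
      meanCoculture = mCoc, meanFungal = mFun, meanBacterial = mBac,
      fcVsFungal = fcF, fcVsBacterial = fcB,
      notDetectableFungal = mFun == 0 & mCoc > 0,
      notDetectableBacterial = mBac == 0 & mCoc > 0,
      detectedAllReplicates = detected,
      tVsFungal = tF[, "t"], pVsFungal = tF[, "p"],
      tVsBacterial = tB[, "t"], pVsBacterial = tB[, "p"],
      padjVsFungal = p.adjust(tF[, "p"], method = "BH"),
      padjVsBacterial = p.adjust(tB[, "p"], method = "BH"),
      pass = pass, row.names = NULL, stringsAsFactors = FALSE)
  })

  tab <- do.call(rbind, perCondition)
  new("EnrichmentReport", table = tab, config = cfg)
}
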