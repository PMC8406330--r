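#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## GNPS-style spectral filters
## ---------------------------------------------------------------------------

#' Remove fragment peaks near the precursor m/z
#'
#' Discards every fragment whose m/z lies within `window` Da of the
#' precursor m/z (inclusive at the boundary: a peak exactly `window` Da
#' away is removed). This strips residual precursor and isotope signal
#' before similarity scoring.
#'
#' @param spectrum an [Ms2Spectrum-class].
#' @param window half-width of the exclusion window in Da (default 17).
#' @return A new [Ms2Spectrum-class]; the input is not modified.
#' @seealso [windowFilterTopK()], [filterSpectrum()]
#' @export
removePrecursorRegion <- function(spectrum, window = 17) {
  stopifnot(is(spectrum, "Ms2Spectrum"), window > 0)
  p <- spectrum@peaks
  keep <- abs(p[, "mz"] - spectrum@precursorMz) > window
  out <- spectrum
  out@peaks <- p[keep, , drop = FALSE]
  out
}

#' Window filter: keep the top-k most intense peaks per sliding window
#'
#' A peak is retained iff it ranks within the top `k` by intensity among
#' all peaks whose m/z lies within `window` Da of that peak's own m/z
#' (itself included). The window is centered on each peak, so the filter
#' is idempotent: peaks that survive still rank top-k among the survivors.
#' Intensity ties are broken by ascending m/z.
#'
#' @param spectrum an [Ms2Spectrum-class].
#' @param window half-width of the sliding window in Da (default 50).
#' @param k number of peaks retained per window (default 6).
#' @return A new [Ms2Spectrum-class].
#' @export
windowFilterTopK <- function(spectrum, window = 50, k = 6L) {
  stopifnot(is(spectrum, "Ms2Spectrum"), window > 0, k >= 1L)
  p <- spectrum@peaks
  n <- nrow(p)
  if (n <= k) return(spectrum)
  mz <- p[, "mz"]; int <- p[, "intensity"]
  keep <- logical(n)
  for (i in seq_len(n)) {
    inWin <- which(abs(mz - mz[i]) <= window)
    o <- inWin[order(-int[inWin], mz[inWin])]
    keep[i] <- i %in% o[seq_len(min(k, length(o)))]
  }
  out <- spectrum
  out@peaks <- p[keep, , drop = FALSE]
  out
}

#' Apply the full spectral filtering pipeline
#'
#' Precursor-region removal followed by the windowed top-k intensity
#' filter, with parameters from a [ToleranceConfig-class]. Both steps are
#' idempotent, so re-filtering a filtered spectrum is a no-op.
#'
#' @param spectrum an [Ms2Spectrum-class].
#' @param tol a [ToleranceConfig-class].
#' @return The filtered [Ms2Spectrum-class].
#' @export
filterSpectrum <- function(spectrum, tol = ToleranceConfig()) {
  s <- removePrecursorRegion(spectrum, tol@precursorWindowDa)
  windowFilterTopK(s, tol@windowDa, tol@windowTopK)
}

## ---------------------------------------------------------------------------
## Modified cosine
## ---------------------------------------------------------------------------

## sqrt-transform intensities and scale to unit Euclidean norm; a spectrum
## with zero total intensity gets all-zero weights (score 0 downstream)
.cosineWeights <- function(intensity) {
  w <- sqrt(as.numeric(intensity))
  nrm <- sqrt(sum(w * w))
  if (nrm > 0) w / nrm else w
}

#' Modified cosine similarity between two MS/MS spectra
#'
#' Computes the GNPS-style modified cosine score: intensities are
#' square-root transformed and scaled to unit Euclidean norm; two peaks
#' may be paired either directly (m/z difference within the fragment
#' tolerance) or shifted by the precursor mass difference (capturing a
#' shared fragment backbone between structurally modified analogs). A
#' one-to-one pairing is chosen greedily by descending intensity product,
#' with ties broken by ascending m/z in the first spectrum, then the
#' second. The score is the sum of matched intensity products, so
#' identical spectra score exactly 1.
#'
#' Both spectra should already be filtered (see [filterSpectrum()]).
#'
#' @param a,b [Ms2Spectrum-class] objects.
#' @param tol a [ToleranceConfig-class]; `fragmentTolDa` governs pairing.
#' @return A [SimilarityResult-class] with the score, matched-peak count
#'   and matched index pairs. Empty spectra give score 0.
#' @examples
#' a <- Ms2Spectrum("a", 200, "positive", 1,
#'                  mz = c(50, 100), intensity = c(4, 9))
#' b <- Ms2Spectrum("b", 200, "positive", 1,
#'                  mz = c(50, 100), intensity = c(1, 4))
#' similarityScore(modifiedCosine(a, b))  # 8 / sqrt(65)
#' @export
modifiedCosine <- function(a, b, tol = ToleranceConfig()) {
  stopifnot(is(a, "Ms2Spectrum"), is(b, "Ms2Spectrum"))
  pa <- a@peaks; pb <- b@peaks
  na <- nrow(pa); nb <- nrow(pb)
  if (na == 0L || nb == 0L)
    return(.SimilarityResult(0, matrix(integer(), ncol = 2L)))
  wa <- .cosineWeights(pa[, "intensity"])
  wb <- .cosineWeights(pb[, "intensity"])
  dprec <- b@precursorMz - a@precursorMz
  ftol <- tol@fragmentTolDa

  ## candidate pairs: direct or precursor-difference-shifted m/z match
  dmz <- outer(pa[, "mz"], pb[, "mz"], function(x, y) abs(x - y))
  cand <- dmz <= ftol
  if (abs(dprec) > .Machine$double.eps) {
    dshift <- outer(pa[, "mz"] + dprec, pb[, "mz"], function(x, y) abs(x - y))
    cand <- cand | (dshift <= ftol)
  }
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(.SimilarityResult(0, matrix(integer(), ncol = 2L)))

  prod <- wa[idx[, 1L]] * wb[idx[, 2L]]
  o <- order(-prod, pa[idx[, 1L], "mz"], pb[idx[, 2L], "mz"])
  idx <- idx[o, , drop = FALSE]
  prod <- prod[o]

  usedA <- logical(na); usedB <- logical(nb)
  accA <- integer(); accB <- integer(); score <- 0
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <- TRUE; usedB[j] <- TRUE
      accA <- c(accA, i); accB <- c(accB, j)
      score <- score + prod[r]
    }
  }
  .SimilarityResult(min(score, 1), cbind(accA, accB))
}
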